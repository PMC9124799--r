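# Shared toy builders and independent oracles.

# neuron_params with an exact membrane decay factor
params_with_alpha <- function(alpha, ...) {
  neuron_params(tau_m = -1 / log(alpha), ...)
}

# Small fully specified network for gradient checks.
toy_network <- function(n_in = 3, n_rec = 4, n_out = 2, seed = 1,
                        gain = 2, kind = "alif", adaptive = TRUE,
                        t_refrac = 2, beta_adapt = 0.3, d = 1L) {
  p <- neuron_params(t_refrac = t_refrac, beta_adapt = beta_adapt, d = d)
  w <- network_weights(n_in, n_rec, n_out, seed = seed, gain = gain)
  snn_network(w, p, kind = kind, adaptive = adaptive)
}

random_input <- function(B, n_in, T, p = 0.3, seed = 1) {
  set.seed(seed)
  array(rbinom(B * n_in * T, 1, p), c(B, n_in, T))
}

# Explicit (non-recursive) readout sum of the leaky readout definition:
# y_k(t) = (1 - nu) sum_{t' <= t} nu^(t - t') (z(t') W_out)_k + b_k.
explicit_readout <- function(z_mat, W_out, b_out, nu) {
  Tn <- ncol(z_mat)
  K <- ncol(W_out)
  y <- matrix(0, K, Tn)
  for (t in seq_len(Tn)) {
    acc <- numeric(K)
    for (tp in seq_len(t)) {
      acc <- acc + nu^(t - tp) * as.numeric(z_mat[, tp] %*% W_out)
    }
    y[, t] <- (1 - nu) * acc + b_out
  }
  y
}

# Generic forward accumulation of the eligibility vector by its defining
# recursion eps(t) = (dh(t)/dh(t-1)) eps(t-1) + dh(t)/dW, with the hidden
# state h = (v, a) and explicit 2x2 Jacobian products per step —
# independent of the closed-form trace recursions in the package.
# `pre` is the raw (already delay-lagged) presynaptic signal: the direct
# dependence dv(t)/dW is pre[t].
jacobian_eligibility <- function(psi, pre, alpha, beta, rho) {
  Tn <- length(psi)
  eps_v <- eps_a <- e <- numeric(Tn)
  ev <- ea <- 0
  for (t in seq_len(Tn)) {
    if (t > 1) {
      J <- matrix(c(alpha, 0,
                    psi[t - 1], rho - beta * psi[t - 1]), 2, 2, byrow = TRUE)
      en <- J %*% c(ev, ea)
      ev <- en[1]; ea <- en[2]
    }
    ev <- ev + pre[t]
    eps_v[t] <- ev; eps_a[t] <- ea
    e[t] <- psi[t] * (ev - beta * ea)
  }
  list(eps_v = eps_v, eps_a = eps_a, e = e)
}

# Loss of a *smoothed* recurrent model in which the spike nonlinearity is
# a scaled steep sigmoid, z = (1.2/k) * sigmoid(k (v - v_th)), whose
# derivative at threshold is 0.3 (matching the triangular surrogate).
# Central differences on this model provide an independent oracle for
# hidden-weight gradients on subthreshold toys.
smooth_model_loss <- function(W_in, W_rec, W_out, b_out, x, p, k = 20) {
  Tn <- ncol(x)
  N <- ncol(W_in)
  v <- numeric(N); z <- numeric(N)
  y <- b_out
  total <- 0
  for (t in seq_len(Tn)) {
    zd <- z # transmission delay of 1 step
    v <- p$alpha * v + as.numeric(x[, t] %*% W_in) + as.numeric(zd %*% W_rec)
    z <- (1.2 / k) * stats::plogis(k * (v - p$v_th))
    y <- p$nu * (y - b_out) + (1 - p$nu) * as.numeric(z %*% W_out) + b_out
    total <- total + sum(y^2) / 2
  }
  total
}
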