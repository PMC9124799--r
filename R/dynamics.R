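#' Neuron state
#'
#' Container for the per-step state of a batch of recurrent spiking neurons:
#' membrane potentials `v`, adaptation variables `a`, effective thresholds
#' `A = beta_adapt * a + v_th`, spike outputs `z`, remaining refractory steps
#' `refrac_count`, and (two-compartment neurons only) dendritic potentials
#' `v_b`. All matrices are `batch x neurons`.
#'
#' @param n_batch Number of trials simulated in parallel.
#' @param n_rec Number of neurons.
#' @param v_th Baseline threshold used to initialize `A`.
#' @return An object of class `neuron_state`.
#' @export
neuron_state <- function(n_batch, n_rec, v_th = 1.0) {
  z0 <- matrix(0, n_batch, n_rec)
  structure(list(v = z0, a = z0, A = matrix(v_th, n_batch, n_rec),
                 z = z0, refrac_count = z0, v_b = z0),
            class = "neuron_state")
}

#' Threshold-adaptation update (ALIF)
#'
#' Advances the adaptation variable one step,
#' `a(t) = mu * a(t-1) + z(t-1)`, and recomputes the effective threshold
#' `A(t) = beta_adapt * a(t) + v_th`. With `beta_adapt = 0` the threshold
#' stays at `v_th` and the neuron behaves as a plain LIF.
#'
#' @param state A `neuron_state`; `state$z` must hold the spikes of the
#'   previous step.
#' @param params A `neuron_params`.
#' @param beta Per-neuron adaptation impact (scalar or length-`n` vector);
#'   defaults to `params$beta_adapt`.
#' @return The updated `neuron_state`.
#' @export
alif_threshold_update <- function(state, params, beta = params$beta_adapt) {
  state$a <- params$mu * state$a + state$z
  state$A <- sweep(state$a, 2, rep_len(beta, ncol(state$a)), `*`) + params$v_th
  state
}

# Shared spike emission: thresholding, refractoriness, soft reset bookkeeping.
# The soft reset itself (v <- v - v_th at the spike step) is applied by the
# *next* membrane update, which subtracts v_th * z(t-1) before decaying.
.emit_spikes <- function(state, params) {
  can_spike <- state$refrac_count == 0
  z <- (state$v >= state$A) * can_spike
  state$refrac_count <- pmax(state$refrac_count - 1, 0)
  if (params$n_refrac > 0) {
    state$refrac_count[z == 1] <- params$n_refrac
  }
  state$z <- z
  state$can_spike <- can_spike
  state
}

#' One step of leaky integrate-and-fire dynamics
#'
#' Advances the membrane potential by leaky integration,
#' `v(t) = alpha * (v(t-1) - v_th * z(t-1)) + I(t) + W_rec' z(t-d)`,
#' emits spikes `z = H(v - A)` outside the refractory period, and arms the
#' refractory counter so that `z = 0` for `t_refrac / dt` steps after each
#' spike. The `- v_th * z(t-1)` term is the soft reset.
#'
#' @param state A `neuron_state` whose threshold `A` is current (see
#'   [alif_threshold_update()]).
#' @param syn_input `batch x neurons` matrix of external input currents
#'   (typically `x(t) %*% W_in`).
#' @param params A `neuron_params`.
#' @param weights A `network_weights` (for the recurrent matrix).
#' @param delayed_spikes `batch x neurons` spikes from step `t - d` (zeros
#'   for `t <= d`).
#' @return The updated `neuron_state` with new `v` and `z`.
#' @export
lif_step <- function(state, syn_input, params, weights, delayed_spikes) {
  if (!all(dim(syn_input) == dim(state$v)) ||
      !identical(ncol(delayed_spikes), ncol(weights$W_rec)))
    stop("shape mismatch between weights and state: contract violation")
  state$v <- params$alpha * (state$v - params$v_th * state$z) +
    syn_input + delayed_spikes %*% weights$W_rec
  .emit_spikes(state, params)
}

#' One step of two-compartment (TLIF) dynamics
#'
#' The basal dendrite potential is `V_b = s_input %*% W_in + b_in`, and the
#' soma advances one Euler step of
#' `tau * dV/dt = -V + (g_b/g_l) * (V_b - V) + sum_rec W_rec z(t-d)`,
#' i.e. `V(t) = (1 - (dt/tau)(1 + g_b/g_l)) * (V(t-1) - v_th z(t-1)) +
#' (dt/tau)(g_b/g_l) V_b + (dt/tau) * rec`. Spiking, threshold and
#' refractoriness are handled exactly as in [lif_step()].
#'
#' @param state A `neuron_state`.
#' @param input_filtered `batch x n_in` matrix of kernel-filtered input
#'   traces `s_input(t)` (see [input_response_filter()]).
#' @param dparams A `dendrite_params`.
#' @param params A `neuron_params`.
#' @param weights A `network_weights`.
#' @param delayed_spikes Spikes from step `t - d`.
#' @return The updated `neuron_state` (including the dendritic potential
#'   `v_b`).
#' @export
tlif_step <- function(state, input_filtered, dparams, params, weights,
                      delayed_spikes) {
  if (dparams$tau <= 0) stop("configuration error: somatic tau must be > 0")
  step_fac <- params$dt / dparams$tau
  decay <- 1 - step_fac * (1 + dparams$g_b / dparams$g_l)
  state$v_b <- sweep(input_filtered %*% weights$W_in, 2, weights$b_in, `+`)
  state$v <- decay * (state$v - params$v_th * state$z) +
    step_fac * (dparams$g_b / dparams$g_l) * state$v_b +
    step_fac * (delayed_spikes %*% weights$W_rec)
  .emit_spikes(state, params)
}

#' Double-exponential synaptic filtering of input spikes
#'
#' Convolves each input channel with the causal response kernel
#' `kappa(t) = (exp(-t/tau_L) - exp(-t/tau_s)) / (tau_L - tau_s)` (units
#' 1/ms; `kappa(0) = 0` and its integral is 1). Implemented with two
#' exponential accumulators, so arbitrary (also analog) input traces are
#' accepted.
#'
#' @param input Either a `spike_raster` / `batch x channels x time` array, a
#'   `channels x time` matrix, or a list of per-channel spike-time vectors
#'   (ms, converted at resolution `dt` over `T` steps).
#' @param dparams A `dendrite_params` (for `tau_L`, `tau_s`).
#' @param T Number of steps (required for spike-time input).
#' @param dt Step size in ms.
#' @return Filtered trace with the same shape as the (array form of the)
#'   input.
#' @export
input_response_filter <- function(input, dparams, T = NULL, dt = 1) {
  if (dparams$tau_L == dparams$tau_s)
    stop("degenerate kernel: tau_L == tau_s")
  if (is.list(input) && !is.array(input)) {
    if (is.null(T)) stop("T is required for spike-time input")
    x <- array(0, c(1L, length(input), T))
    for (j in seq_along(input)) {
      idx <- as.integer(round(input[[j]] / dt)) + 1L
      idx <- idx[idx >= 1 & idx <= T]
      x[1, j, idx] <- 1
    }
    input <- x
  }
  squeeze <- FALSE
  if (is.matrix(input)) {
    input <- array(input, c(1L, nrow(input), ncol(input)))
    squeeze <- TRUE
  }
  out <- .filter_with_state(unclass(input), dparams, dt)$out
  if (squeeze) out <- matrix(out, dim(out)[2], dim(out)[3])
  out
}

# Double-exponential filter with carryable accumulator state.
.filter_with_state <- function(x, dparams, dt, state = NULL) {
  dL <- exp(-dt / dparams$tau_L)
  dS <- exp(-dt / dparams$tau_s)
  if (is.null(state)) {
    aL <- aS <- matrix(0, dim(x)[1], dim(x)[2])
  } else {
    aL <- state$aL; aS <- state$aS
  }
  out <- array(0, dim(x))
  B <- dim(x)[1]
  for (t in seq_len(dim(x)[3])) {
    xt <- matrix(x[, , t], B)
    aL <- dL * aL + xt
    aS <- dS * aS + xt
    out[, , t] <- (aL - aS) / (dparams$tau_L - dparams$tau_s)
  }
  list(out = out, state = list(aL = aL, aS = aS))
}

#' Leaky readout update
#'
#' One step of the low-pass readout
#' `y_k(t) = (1 - nu) * sum_{t' <= t} nu^(t - t') (W_out' z(t'))_k + b_k`,
#' evaluated in its exactly equivalent recursive form
#' `y(t) = nu * (y(t-1) - b_out) + (1 - nu) * z(t) %*% W_out + b_out`.
#'
#' @param y_prev `batch x n_out` readout values from the previous step (use
#'   a matrix of `b_out` rows, or zeros plus `b_out`, at `t = 0`).
#' @param z_t `batch x neurons` spikes of the current step.
#' @param weights A `network_weights`.
#' @param params A `neuron_params` (for `nu`).
#' @return `batch x n_out` readout values.
#' @export
readout_update <- function(y_prev, z_t, weights, params) {
  sweep(params$nu * sweep(y_prev, 2, weights$b_out, `-`) +
          (1 - params$nu) * (z_t %*% weights$W_out),
        2, weights$b_out, `+`)
}

#' Pseudo-derivative (surrogate gradient) of the spike function
#'
#' The bounded triangular surrogate used in place of the Heaviside
#' derivative: `psi = 0.3 * max(0, 1 - |A - v| / v_th)`, where for a plain
#' LIF neuron the effective threshold is the constant `v_th` and for
#' adaptive neurons it is `A(t)`. The value is 0.3 exactly at threshold and
#' 0 during the refractory period (no gradient flows through silenced
#' neurons).
#'
#' @param v Membrane potentials (any numeric shape).
#' @param A Effective thresholds (recycled against `v`). Ignored for
#'   `kind = "lif"`, which uses `v_th`.
#' @param params A `neuron_params`.
#' @param kind One of `"lif"`, `"alif"`, `"tlif"`.
#' @param refractory Optional logical mask (same shape as `v`); `TRUE`
#'   entries get `psi = 0`.
#' @return Values in `[0, 0.3]`, same shape as `v`.
#' @export
#' @examples
#' pseudo_derivative(1.0, 1.0, neuron_params()) # 0.3 at threshold
pseudo_derivative <- function(v, A = NULL, params = neuron_params(),
                              kind = c("alif", "lif", "tlif"),
                              refractory = NULL) {
  kind <- match.arg(kind)
  if (kind == "lif" || is.null(A)) A <- params$v_th
  psi <- 0.3 * pmax(0, 1 - abs(A - v) / params$v_th)
  if (!is.null(refractory)) psi <- psi * !refractory
  psi
}

#' Forward rollout of a recurrent spiking network
#'
#' Simulates an `snn_network` for the full duration of an input, recording
#' everything the losses and gradients need: spikes, membrane potentials,
#' effective thresholds, surrogate derivatives and readout. The forward
#' dynamics are deterministic; identical inputs give bit-identical outputs.
#'
#' @param network An [snn_network()].
#' @param input A `spike_raster` or a `batch x n_in x time` numeric array
#'   (analog input currents are allowed).
#' @param state0 Optional initial `neuron_state` (zeros by default), e.g.
#'   the final state of a preceding rollout.
#' @param y0 Optional initial `batch x n_out` readout matrix (defaults to
#'   rows of `b_out`).
#' @param z_pre Optional `batch x neurons x d` array of spikes preceding
#'   step 1 (slice `k` holds the spikes of step `1 - k`), for continuing a
#'   rollout across a segment boundary with the transmission delay intact.
#' @param filt0 Optional input-filter accumulator state (element
#'   `filt_state` of a preceding rollout).
#' @return An object of class `snn_rollout`: arrays `z`, `v`, `A`, `psi`
#'   (`batch x neurons x time`), `y` (`batch x n_out x time`), the input
#'   `x` and its filtered version `x_filt` (`NULL` when no neuron reads the
#'   filtered trace), and the final `state`.
#' @export
simulate_network <- function(network, input, state0 = NULL, y0 = NULL,
                             z_pre = NULL, filt0 = NULL) {
  p <- network$params
  if (inherits(input, "spike_raster") && !is.null(attr(input, "dt")) &&
      attr(input, "dt") != p$dt)
    stop("input raster dt does not match network dt")
  x <- unclass(input)
  attributes(x) <- list(dim = dim(input))
  if (is.matrix(x)) x <- array(x, c(1L, nrow(x), ncol(x)))
  B <- dim(x)[1]; Tn <- dim(x)[3]
  if (dim(x)[2] != network$n_in) stop("input has wrong number of channels")
  N <- network$n_rec; K <- network$n_out
  w <- network$weights
  x_filt <- NULL
  filt_state <- NULL
  any_filt <- any(network$filtered_input)
  if (any_filt) {
    fs <- .filter_with_state(x, network$dparams, dt = p$dt, state = filt0)
    x_filt <- fs$out
    filt_state <- fs$state
  }

  st <- if (is.null(state0)) neuron_state(B, N, p$v_th) else state0
  y <- if (is.null(y0)) matrix(w$b_out, B, K, byrow = TRUE) else y0

  Dm <- matrix(network$decay, B, N, byrow = TRUE)
  Gi <- matrix(network$in_gain, B, N, byrow = TRUE)
  Gr <- matrix(network$rec_gain, B, N, byrow = TRUE)
  Bm <- matrix(network$beta, B, N, byrow = TRUE)
  b_in <- matrix(w$b_in, B, N, byrow = TRUE)
  fmask <- matrix(network$filtered_input, B, N, byrow = TRUE)

  Z <- V <- A <- PSI <- array(0, c(B, N, Tn))
  Y <- array(0, c(B, K, Tn))
  d <- p$d
  for (t in seq_len(Tn)) {
    xt <- matrix(x[, , t], B)
    drive <- xt %*% w$W_in
    if (any_filt) {
      xft <- matrix(x_filt[, , t], B)
      drive_f <- xft %*% w$W_in
      drive[fmask] <- drive_f[fmask]
    }
    zd <- if (t > d) {
      matrix(Z[, , t - d], B)
    } else if (!is.null(z_pre)) {
      matrix(z_pre[, , d - t + 1], B)
    } else {
      matrix(0, B, N)
    }
    # threshold adaptation from last step's spikes, then membrane update
    st$a <- p$mu * st$a + st$z
    st$A <- Bm * st$a + p$v_th
    st$v <- Dm * (st$v - p$v_th * st$z) + Gi * (drive + b_in) + zd %*% w$W_rec * Gr
    st <- .emit_spikes(st, p)
    y <- readout_update(y, st$z, w, p)
    if (anyNA(st$v) || any(is.infinite(st$v)))
      stop(sprintf("numerical failure (NaN/Inf membrane potential) at step %d", t))
    Z[, , t] <- st$z; V[, , t] <- st$v; A[, , t] <- st$A
    PSI[, , t] <- 0.3 * pmax(0, 1 - abs(st$A - st$v) / p$v_th) * st$can_spike
    Y[, , t] <- y
  }
  structure(list(z = Z, v = V, A = A, psi = PSI, y = Y,
                 x = x, x_filt = x_filt, state = st, n_batch = B, T = Tn,
                 z_pre = z_pre, filt_state = filt_state,
                 y_continued = !is.null(y0)),
            class = "snn_rollout")
}

#' @export
print.snn_rollout <- function(x, ...) {
  cat(sprintf("snn_rollout: %d trial(s), %d neurons, %d steps; %d spikes (%.2f Hz mean)\n",
              x$n_batch, dim(x$z)[2], x$T, sum(x$z),
              mean(x$z) * 1000))
  invisible(x)
}

#' Mean per-neuron firing rates of a rollout or raster (Hz)
#'
#' `f_j = sum_{n,t} z_j(n,t) / (n_batch * T * dt)`, expressed in Hz.
#'
#' @param z A `spike_raster`, `snn_rollout`, or `batch x neurons x time`
#'   array.
#' @param dt Step size in ms (taken from the object when available).
#' @return Numeric vector of per-neuron rates in Hz.
#' @export
firing_rates <- function(z, dt = 1) {
  if (inherits(z, "snn_rollout")) z <- z$z
  if (inherits(z, "spike_raster")) { dt <- attr(z, "dt"); z <- unclass(z) }
  d <- dim(z)
  apply(z, 2, sum) / (d[1] * d[3] * dt / 1000)
}
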