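#' Low-pass filtered spike trains
#'
#' `zbar_i(t) = sum_{t' <= t} alpha^(t - t') z_i(t')`, computed with the
#' equivalent recursion `zbar(t) = alpha * zbar(t-1) + z(t)`.
#'
#' @param raster A `spike_raster`, `batch x neurons x time` array, or
#'   `neurons x time` matrix.
#' @param alpha Decay factor in `[0, 1)`.
#' @return Filtered trace, same shape as the input array.
#' @export
low_pass_spikes <- function(raster, alpha) {
  if (alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)")
  z <- unclass(raster)
  squeeze <- is.matrix(z)
  if (squeeze) z <- array(z, c(1L, nrow(z), ncol(z)))
  out <- array(0, dim(z))
  acc <- matrix(0, dim(z)[1], dim(z)[2])
  for (t in seq_len(dim(z)[3])) {
    acc <- alpha * acc + matrix(z[, , t], dim(z)[1])
    out[, , t] <- acc
  }
  if (squeeze) out <- matrix(out, dim(out)[2], dim(out)[3])
  out
}

#' Eligibility traces for LIF synapses
#'
#' `e_ji(t) = psi_j(t) * zbar_i(t - d)`: the outer product of the
#' postsynaptic surrogate derivative with the delayed low-pass filtered
#' presynaptic activity, per time step.
#'
#' @param psi `n_post x time` matrix of surrogate derivatives.
#' @param zbar `n_pre x time` matrix of filtered presynaptic spikes.
#' @param d Transmission delay in steps.
#' @return Array `n_post x n_pre x time` of eligibility traces.
#' @export
eligibility_lif <- function(psi, zbar, d = 1L) {
  Tn <- ncol(psi)
  e <- array(0, c(nrow(psi), nrow(zbar), Tn))
  for (t in seq_len(Tn)) {
    zd <- if (t > d) zbar[, t - d] else numeric(nrow(zbar))
    e[, , t] <- outer(psi[, t], zd)
  }
  e
}

#' Eligibility traces for adaptive (ALIF) synapses
#'
#' Advances the adaptation component of the eligibility vector,
#' `eps_a(t) = (rho - beta * psi(t-1)) * eps_a(t-1) + psi(t-1) * zbar(t-d-1)`,
#' and the trace `e_ji(t) = psi_j(t) * (zbar_i(t-d) - beta * eps_a_ji(t))`.
#' With `beta = 0` this reduces exactly to [eligibility_lif()].
#'
#' @param psi `n_post x time` matrix of surrogate derivatives.
#' @param zbar `n_pre x time` matrix of filtered presynaptic spikes.
#' @param params A `neuron_params` (for `rho` and the delay `d`).
#' @param beta Adaptation impact (scalar or per-postsynaptic-neuron vector);
#'   defaults to `params$beta_adapt`.
#' @return List with `e` (`n_post x n_pre x time`) and `eps_a`, the final
#'   adaptation component matrix.
#' @export
eligibility_alif <- function(psi, zbar, params, beta = params$beta_adapt) {
  Tn <- ncol(psi)
  n_post <- nrow(psi); n_pre <- nrow(zbar)
  beta <- rep_len(beta, n_post)
  d <- params$d
  eps_a <- matrix(0, n_post, n_pre)
  e <- array(0, c(n_post, n_pre, Tn))
  for (t in seq_len(Tn)) {
    if (t > 1) {
      zdm1 <- if (t - 1 > d) zbar[, t - 1 - d] else numeric(n_pre)
      eps_a <- (params$rho - beta * psi[, t - 1]) * eps_a +
        outer(psi[, t - 1], zdm1)
    }
    zd <- if (t > d) zbar[, t - d] else numeric(n_pre)
    e[, , t] <- psi[, t] * (outer(rep(1, n_post), zd) - beta * eps_a)
  }
  list(e = e, eps_a = eps_a)
}
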