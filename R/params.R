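#' Neuron parameters
#'
#' Constants of the discrete-time spiking neuron models: a leaky
#' integrate-and-fire (LIF) soma with optional threshold adaptation (ALIF)
#' and a leaky readout. Decay factors are derived from the time constants as
#' `exp(-dt / tau)`.
#'
#' @param tau_m Membrane time constant (ms).
#' @param tau_out Readout time constant (ms).
#' @param tau_a Threshold-adaptation time constant (ms).
#' @param v_th Baseline firing threshold (dimensionless).
#' @param beta_adapt Impact of threshold adaptation on the effective
#'   threshold (dimensionless). `0` disables adaptation (plain LIF).
#' @param t_refrac Refractory duration (ms); spiking is suppressed for
#'   `t_refrac / dt` steps after each spike.
#' @param d Recurrent transmission delay in steps (>= 1).
#' @param dt Integration step (ms).
#'
#' @return An object of class `neuron_params`: the arguments plus the derived
#'   decay factors `alpha` (membrane), `mu` (adaptation), `nu` (readout) and
#'   `rho` (adaptation-trace decay used by the eligibility recursion, set
#'   equal to `mu`), and `n_refrac`, the refractory duration in steps.
#' @export
#' @examples
#' p <- neuron_params()
#' p$alpha # exp(-1/15)
neuron_params <- function(tau_m = 15, tau_out = 10, tau_a = 200,
                          v_th = 1.0, beta_adapt = 0.4902,
                          t_refrac = 5, d = 1L, dt = 1) {
  stopifnot(tau_m > 0, tau_out > 0, tau_a > 0, dt > 0)
  if (v_th <= 0) stop("v_th must be > 0")
  if (t_refrac < 0) stop("t_refrac must be >= 0")
  d <- as.integer(d)
  if (d < 1L) stop("transmission delay d must be >= 1 step")
  p <- list(
    tau_m = tau_m, tau_out = tau_out, tau_a = tau_a,
    v_th = v_th, beta_adapt = beta_adapt,
    t_refrac = t_refrac, d = d, dt = dt,
    alpha = exp(-dt / tau_m),
    mu = exp(-dt / tau_a),
    nu = exp(-dt / tau_out),
    rho = exp(-dt / tau_a),
    n_refrac = as.integer(round(t_refrac / dt))
  )
  stopifnot(p$alpha > 0, p$alpha < 1, p$mu > 0, p$mu < 1, p$nu > 0, p$nu < 1)
  structure(p, class = "neuron_params")
}

#' Dendrite (two-compartment) parameters
#'
#' Constants of the two-compartment (TLIF) neuron: a passive basal dendrite
#' with conductance coupling into the soma, and the double-exponential
#' synaptic response kernel that filters input spike trains,
#' `kappa(t) = (exp(-t/tau_L) - exp(-t/tau_s)) / (tau_L - tau_s)` for
#' `t >= 0`.
#'
#' @param g_l Leak conductance.
#' @param g_b Basal dendrite conductance.
#' @param C_m Membrane capacitance; the somatic time constant is
#'   `tau = C_m / g_l` (ms).
#' @param tau_L Long synaptic time constant (ms).
#' @param tau_s Short synaptic time constant (ms); must satisfy
#'   `tau_L > tau_s > 0`.
#'
#' @return An object of class `dendrite_params` with fields `g_l`, `g_b`,
#'   `C_m`, `tau`, `tau_L`, `tau_s`.
#' @export
dendrite_params <- function(g_l = 1, g_b = 1, C_m = 15,
                            tau_L = 10, tau_s = 2) {
  if (g_l <= 0) stop("g_l must be > 0")
  if (g_b < 0) stop("g_b must be >= 0")
  if (tau_L == tau_s) stop("degenerate kernel: tau_L must differ from tau_s")
  if (!(tau_L > tau_s && tau_s > 0)) stop("need tau_L > tau_s > 0")
  tau <- C_m / g_l
  if (tau <= 0) stop("somatic time constant C_m/g_l must be > 0")
  structure(list(g_l = g_l, g_b = g_b, C_m = C_m, tau = tau,
                 tau_L = tau_L, tau_s = tau_s),
            class = "dendrite_params")
}

#' Network weights
#'
#' Create the weight matrices of a recurrent spiking network: input-to-hidden
#' `W_in` (`n_in x n_rec`), hidden-to-hidden `W_rec` (`n_rec x n_rec`, zero
#' diagonal: no self-connections), hidden-to-readout `W_out`
#' (`n_rec x n_out`) and readout bias `b_out`. Entries are drawn from
#' `N(0, 1/fan_in)` (standard deviation `1/sqrt(fan_in)` per matrix),
#' optionally scaled by `gain`.
#'
#' @param n_in,n_rec,n_out Layer sizes.
#' @param seed Integer seed for reproducible initialization.
#' @param gain Multiplier applied to the input and recurrent matrices.
#' @return An object of class `network_weights` with elements `W_in`,
#'   `W_rec`, `W_out`, `b_out`, `b_in` (per-neuron dendritic bias, zero by
#'   default) and `W_init`, a snapshot of the initial matrices.
#' @export
network_weights <- function(n_in, n_rec, n_out, seed = 1L, gain = 1) {
  stopifnot(n_in >= 1, n_rec >= 1, n_out >= 1)
  set.seed(as.integer(seed))
  W_in <- matrix(stats::rnorm(n_in * n_rec, sd = gain / sqrt(n_in)), n_in, n_rec)
  W_rec <- matrix(stats::rnorm(n_rec * n_rec, sd = gain / sqrt(n_rec)), n_rec, n_rec)
  diag(W_rec) <- 0
  W_out <- matrix(stats::rnorm(n_rec * n_out, sd = 1 / sqrt(n_rec)), n_rec, n_out)
  w <- list(W_in = W_in, W_rec = W_rec, W_out = W_out,
            b_out = numeric(n_out), b_in = numeric(n_rec))
  w$W_init <- w[c("W_in", "W_rec", "W_out")]
  structure(w, class = "network_weights")
}

#' Validate weight shapes against a network size
#' @param weights A `network_weights` object.
#' @param n_in,n_rec,n_out Expected layer sizes.
#' @return Invisibly `TRUE`; signals an error on mismatch.
#' @keywords internal
check_weight_shapes <- function(weights, n_in, n_rec, n_out) {
  if (!identical(dim(weights$W_in), c(as.integer(n_in), as.integer(n_rec))) ||
      !identical(dim(weights$W_rec), c(as.integer(n_rec), as.integer(n_rec))) ||
      !identical(dim(weights$W_out), c(as.integer(n_rec), as.integer(n_out))))
    stop("weight shape mismatch: contract violation")
  if (any(diag(weights$W_rec) != 0))
    stop("W_rec must have an exactly zero diagonal (no self-connections)")
  invisible(TRUE)
}

#' Recurrent spiking network specification
#'
#' Bundle weights, neuron constants and per-neuron kinds into one simulatable
#' network. Neuron kinds are `"lif"` (plain soma, raw input current),
#' `"alif"` (adaptive threshold) and `"tlif"` (two-compartment: the input
#' arrives through a basal dendrite driven by the kernel-filtered input
#' trace). Adaptation is controlled per neuron by the `adaptive` flag;
#' non-adaptive neurons have an effective `beta_adapt` of 0, which makes
#' their rollouts bit-identical to plain LIF.
#'
#' @param weights A `network_weights` object.
#' @param params A `neuron_params` object.
#' @param dparams A `dendrite_params` object (required when any neuron is
#'   `"tlif"`).
#' @param kind Character vector (length `n_rec` or 1) of neuron kinds.
#' @param adaptive Logical vector (length `n_rec` or 1); which neurons carry
#'   an adaptive threshold. Defaults to `kind == "alif"`.
#' @return An object of class `snn_network` with derived per-neuron constant
#'   vectors: `decay` (membrane decay per step), `in_gain` and `rec_gain`
#'   (drive scalings; for TLIF neurons the Euler step scales drive by
#'   `dt/tau` and dendritic input additionally by `g_b/g_l`), `beta`
#'   (per-neuron adaptation impact) and `filtered_input` (which neurons read
#'   the kernel-filtered input trace).
#' @export
snn_network <- function(weights, params, dparams = NULL,
                        kind = "lif", adaptive = NULL) {
  n_rec <- ncol(weights$W_in)
  check_weight_shapes(weights, nrow(weights$W_in), n_rec, ncol(weights$W_out))
  kind <- rep_len(match.arg(kind, c("lif", "alif", "tlif"), several.ok = TRUE),
                  n_rec)
  if (is.null(adaptive)) adaptive <- kind == "alif"
  adaptive <- rep_len(as.logical(adaptive), n_rec)
  if (any(kind == "tlif") && is.null(dparams))
    stop("dendrite_params required for two-compartment (tlif) neurons")
  is_t <- kind == "tlif"
  decay <- rep(params$alpha, n_rec)
  in_gain <- rep(1, n_rec)
  rec_gain <- rep(1, n_rec)
  if (any(is_t)) {
    step_fac <- params$dt / dparams$tau
    decay[is_t] <- 1 - step_fac * (1 + dparams$g_b / dparams$g_l)
    if (any(decay[is_t] <= 0))
      stop("unstable Euler step for tlif soma: decrease dt or increase C_m/g_l")
    in_gain[is_t] <- step_fac * dparams$g_b / dparams$g_l
    rec_gain[is_t] <- step_fac
  }
  structure(list(
    weights = weights, params = params, dparams = dparams,
    kind = kind, adaptive = adaptive,
    n_in = nrow(weights$W_in), n_rec = n_rec, n_out = ncol(weights$W_out),
    decay = decay, in_gain = in_gain, rec_gain = rec_gain,
    beta = ifelse(adaptive, params$beta_adapt, 0),
    filtered_input = is_t
  ), class = "snn_network")
}

#' @export
print.snn_network <- function(x, ...) {
  cat(sprintf(
    "snn_network: %d inputs -> %d hidden (%s) -> %d outputs\n",
    x$n_in, x$n_rec,
    paste(sprintf("%d %s", table(x$kind), names(table(x$kind))), collapse = ", "),
    x$n_out))
  cat(sprintf("  adaptive threshold on %d neurons; dt = %g ms, delay = %d step(s)\n",
              sum(x$adaptive), x$params$dt, x$params$d))
  invisible(x)
}
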