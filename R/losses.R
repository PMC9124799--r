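#' Correntropy configuration
#'
#' Settings of the two-kernel mixture correntropy estimator: Gaussian kernel
#' widths `sigma1`, `sigma2` (same units as the error) and the mixture
#' weight `lam_mix` between them. The number of kernels is fixed to 2.
#'
#' @param sigma1,sigma2 Kernel widths (> 0).
#' @param lam_mix Mixture weight in `[0, 1]`; 1 reduces to a single kernel
#'   of width `sigma1`, 0 to width `sigma2`.
#' @return An object of class `correntropy_config`.
#' @export
correntropy_config <- function(sigma1 = 1.0, sigma2 = 4.0, lam_mix = 0.5) {
  if (sigma1 <= 0 || sigma2 <= 0) stop("configuration error: sigma must be > 0")
  if (lam_mix < 0 || lam_mix > 1) stop("lam_mix must lie in [0, 1]")
  structure(list(sigma1 = sigma1, sigma2 = sigma2, lam_mix = lam_mix, S = 2L),
            class = "correntropy_config")
}

#' Regularizer configuration
#'
#' @param f_target Target firing rate (Hz).
#' @param lam_f Firing-rate regularizer scale.
#' @param lam_v Membrane-voltage regularizer scale.
#' @param v_th Threshold used by the lower voltage bound.
#' @return An object of class `regularizer_config`.
#' @export
regularizer_config <- function(f_target = 20, lam_f = 1.0, lam_v = 1e-2,
                               v_th = 1.0) {
  if (f_target < 0 || lam_f < 0 || lam_v < 0)
    stop("regularizer scales and target rate must be >= 0")
  structure(list(f_target = f_target, lam_f = lam_f, lam_v = lam_v,
                 v_th = v_th), class = "regularizer_config")
}

#' Ensemble-loss configuration
#'
#' The heterogeneous ensemble objective combines `K = 4` base losses
#' (mixture-correntropy, cross-entropy, firing-rate and voltage
#' regularizers, in that order) with trainable weights `lambda`, squared in
#' the objective and softly constrained to `sum(lambda^2) = 1` by an
#' augmented Lagrangian with multipliers `eta1` and `eta2`.
#'
#' @param lam Numeric vector of 4 combination weights; also the initial
#'   value when `trainable`. The default is the best-performing reported
#'   ensemble configuration (0.2, 0.8, 0.5, 0.5), rescaled onto the
#'   constraint surface `sum(lam^2) = 1`.
#' @param eta1,eta2 Lagrangian weights (`eta2 >= 0`).
#' @param trainable Should the weights be updated during training?
#' @return An object of class `ensemble_loss_config`.
#' @export
ensemble_loss_config <- function(lam = c(0.2, 0.8, 0.5, 0.5) /
                                   sqrt(sum(c(0.2, 0.8, 0.5, 0.5)^2)),
                                 eta1 = 0.1, eta2 = 10,
                                 trainable = TRUE) {
  if (length(lam) != 4L) stop("the ensemble combines exactly K = 4 base losses")
  if (eta2 < 0) stop("eta2 must be >= 0")
  structure(list(lam = as.numeric(lam), eta1 = eta1, eta2 = eta2,
                 trainable = isTRUE(trainable), K = 4L),
            class = "ensemble_loss_config")
}

#' Random initialization of ensemble weights
#'
#' Draws the four combination weights uniformly in `(0, 1)` and rescales
#' them so that `sum(lambda^2) = 1`, the constraint surface of the ensemble
#' objective.
#'
#' @param seed Integer seed.
#' @return Numeric vector of length 4.
#' @export
init_ensemble_weights <- function(seed = 1L) {
  set.seed(as.integer(seed))
  lam <- stats::runif(4)
  lam / sqrt(sum(lam^2))
}

#' Gaussian correntropy kernel
#'
#' `G_sigma(e) = exp(-||e||^2 / (2 sigma^2))`, evaluated elementwise.
#'
#' @param e Error value(s).
#' @param sigma Kernel width (> 0).
#' @return Kernel values in `(0, 1]`; 1 iff `e = 0`.
#' @export
gaussian_kernel <- function(e, sigma) {
  if (sigma <= 0) stop("configuration error: sigma must be > 0")
  exp(-e^2 / (2 * sigma^2))
}

#' Mixture-correntropy estimator
#'
#' Sample estimator of the two-kernel mixture correntropy between paired
#' samples,
#' `V = mean_i [ lam * G_sigma1(e_i) + (1 - lam) * G_sigma2(e_i) ]` with
#' `e_i = ||x_i - y_i||`. For multivariate rows the Euclidean norm of the
#' row difference is used.
#'
#' @param x,y Numeric vectors of equal length, or matrices with matching
#'   dimensions (rows are samples).
#' @param cfg A [correntropy_config()].
#' @return The estimate in `(0, 1]`; equals 1 iff `x == y` elementwise.
#' @export
mixture_correntropy <- function(x, y, cfg = correntropy_config()) {
  e <- .pairwise_errors(x, y)
  mean(cfg$lam_mix * gaussian_kernel(e, cfg$sigma1) +
         (1 - cfg$lam_mix) * gaussian_kernel(e, cfg$sigma2))
}

.pairwise_errors <- function(x, y) {
  if (is.matrix(x) || is.matrix(y)) {
    x <- as.matrix(x); y <- as.matrix(y)
    if (!all(dim(x) == dim(y))) stop("x and y must have matching dimensions")
    if (nrow(x) == 0) stop("empty samples")
    sqrt(rowSums((x - y)^2))
  } else {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) == 0) stop("empty samples")
    abs(x - y)
  }
}

#' Mixture-correntropy loss
#'
#' The loss minimized in place of maximizing the mixture correntropy:
#' `L = 1 - V(x, y)`. It is zero iff the fit is perfect, bounded above by 1
#' (saturating for gross outliers, like a 0-1 loss), and locally quadratic
#' near zero error.
#'
#' @inheritParams mixture_correntropy
#' @param gradient If `TRUE`, attach the gradient with respect to the
#'   predictions `y` as attribute `"gradient"`.
#' @return Scalar loss in `[0, 1)`.
#' @export
mmcc_loss <- function(x, y, cfg = correntropy_config(), gradient = FALSE) {
  e <- .pairwise_errors(x, y)
  k1 <- gaussian_kernel(e, cfg$sigma1)
  k2 <- gaussian_kernel(e, cfg$sigma2)
  loss <- 1 - mean(cfg$lam_mix * k1 + (1 - cfg$lam_mix) * k2)
  if (gradient) {
    # d(1 - V)/dy_i = (lam/sigma1^2 k1 + (1-lam)/sigma2^2 k2) * (y_i - x_i) / N
    n <- if (is.matrix(x)) nrow(as.matrix(x)) else length(x)
    coef <- (cfg$lam_mix * k1 / cfg$sigma1^2 +
               (1 - cfg$lam_mix) * k2 / cfg$sigma2^2) / n
    g <- if (is.matrix(x) || is.matrix(y)) {
      as.matrix(y) - as.matrix(x)
    } else {
      y - x
    }
    attr(loss, "gradient") <- g * coef
  }
  loss
}

#' Correntropy influence function
#'
#' Derivative of the Gaussian kernel with respect to the error,
#' `psi(e) = -e / sigma^2 * exp(-e^2 / (2 sigma^2))`: odd, bounded, with
#' extrema at `e = +/- sigma` and redescending to 0 for large errors —
#' unlike the linearly growing influence of a squared-error criterion.
#'
#' @param e Error value(s).
#' @param sigma Kernel width.
#' @return Influence values, same shape as `e`.
#' @export
influence_function <- function(e, sigma) {
  -e / sigma^2 * exp(-e^2 / (2 * sigma^2))
}

#' Multiclass cross-entropy
#'
#' `L = -sum_i y_i log(p_i)` per sample, averaged over rows for matrix
#' input. Probabilities are clamped at `eps` inside the logarithm.
#'
#' @param y_true One-hot labels (vector, or matrix with samples in rows).
#' @param y_pred Predicted class probabilities, same shape.
#' @param eps Numerical clamp inside the logarithm.
#' @return Mean cross-entropy (>= 0; 0 iff all mass on the true class).
#' @export
cross_entropy <- function(y_true, y_pred, eps = 1e-12) {
  if (is.matrix(y_true)) {
    mean(-rowSums(y_true * log(pmax(y_pred, eps))))
  } else {
    -sum(y_true * log(pmax(y_pred, eps)))
  }
}

#' Two-phase (matching protocol) cross-entropy
#'
#' Binary cross-entropy of the readout sampled once per query item, after
#' that item has been fully presented: for query `n` the readout at step
#' `t_phase1 + n * t_img` is passed through a sigmoid and scored against the
#' match label `l_n` (1 iff the query belongs to the support class),
#' `E = sum_n -l_n log sigmoid(y) - (1 - l_n) log(1 - sigmoid(y))`.
#'
#' @param readout_trace Numeric vector of readout values over time (one
#'   output channel), or a `1 x 1 x T` array.
#' @param labels Binary vector `l_n`, one entry per query item.
#' @param t_img Steps per item.
#' @param t_phase1 Steps occupied by the support phase (defaults to
#'   `t_img`, i.e. one support item).
#' @param eps Numerical clamp inside the logarithm.
#' @return The summed binary cross-entropy over the query items.
#' @export
phase_cross_entropy <- function(readout_trace, labels, t_img,
                                t_phase1 = t_img, eps = 1e-12) {
  y <- as.numeric(readout_trace)
  steps <- t_phase1 + t_img * seq_along(labels)
  if (max(steps) > length(y))
    stop("readout trace too short for the requested query items")
  p <- stats::plogis(y[steps])
  sum(-labels * log(pmax(p, eps)) - (1 - labels) * log(pmax(1 - p, eps)))
}

#' Firing-rate regularizer
#'
#' Penalizes the deviation of each neuron's average firing rate from a
#' target rate: `L = lam_f * sum_j (f_j - f_target)^2`, with
#' `f_j = sum_{n,t} z_j(n,t) / (n_batch * T * dt)` in Hz.
#'
#' @param raster A `spike_raster`, `snn_rollout`, or `batch x neurons x
#'   time` array.
#' @param cfg A [regularizer_config()].
#' @param dt Step size in ms (taken from the raster when available).
#' @return Scalar loss with attribute `"rates"` holding the per-neuron rates
#'   (Hz).
#' @export
rate_regularizer <- function(raster, cfg = regularizer_config(), dt = 1) {
  f <- firing_rates(raster, dt = dt)
  loss <- cfg$lam_f * sum((f - cfg$f_target)^2)
  attr(loss, "rates") <- f
  loss
}

#' Membrane-voltage regularizer
#'
#' Penalizes membrane-potential excursions above the effective threshold and
#' below `-v_th`:
#' `L = lam_v / (n_batch * T) * sum_{n,t,j} [max(0, v - A)^2 +
#' max(0, -v - v_th)^2]`.
#'
#' @param v_trace,A_trace Aligned `batch x neurons x time` arrays (or
#'   matrices) of membrane potentials and effective thresholds.
#' @param cfg A [regularizer_config()].
#' @return Scalar loss (>= 0; 0 when all potentials lie in `[-v_th, A]`).
#' @export
voltage_regularizer <- function(v_trace, A_trace, cfg = regularizer_config()) {
  if (!all(dim(as.array(v_trace)) == dim(as.array(A_trace))))
    stop("v and A traces must be aligned")
  d <- dim(as.array(v_trace))
  nt <- if (length(d) == 3) d[1] * d[3] else d[2]
  cfg$lam_v / nt * sum(pmax(0, v_trace - A_trace)^2 +
                         pmax(0, -v_trace - cfg$v_th)^2)
}

#' Heterogeneous ensemble objective
#'
#' Combines the four base losses with squared trainable weights under the
#' augmented-Lagrangian constraint:
#' `total = sum_j lam_j^2 L_j + eta1 (sum lam^2 - 1) + eta2 (sum lam^2 - 1)^2`.
#'
#' @param base_losses Numeric vector of the 4 base-loss values, ordered
#'   (mixture-correntropy, cross-entropy, rate, voltage).
#' @param cfg An [ensemble_loss_config()].
#' @return An object of class `loss_breakdown`: list with `base_losses`,
#'   `lam`, `weighted` (the `sum lam_j^2 L_j` term), `penalty` (the two
#'   Lagrangian terms), `total`, and `grad_lam`, the exact gradient of the
#'   total with respect to each weight,
#'   `2 lam_j (L_j + eta1 + 2 eta2 (sum lam^2 - 1))`.
#' @export
ensemble_objective <- function(base_losses, cfg = ensemble_loss_config()) {
  if (length(base_losses) != cfg$K)
    stop(sprintf("expected %d base losses", cfg$K))
  if (anyNA(base_losses) || any(!is.finite(base_losses))) {
    bad <- which(!is.finite(base_losses))[1]
    nm <- c("mixture-correntropy", "cross-entropy", "rate", "voltage")[bad]
    stop(sprintf("non-finite base loss: %s", nm))
  }
  base_losses <- as.numeric(base_losses)
  lam <- cfg$lam
  S <- sum(lam^2)
  weighted <- sum(lam^2 * base_losses)
  penalty <- cfg$eta1 * (S - 1) + cfg$eta2 * (S - 1)^2
  structure(list(
    base_losses = base_losses, lam = lam,
    weighted = weighted, penalty = penalty, total = weighted + penalty,
    grad_lam = 2 * lam * (base_losses + cfg$eta1 + 2 * cfg$eta2 * (S - 1))
  ), class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("ensemble loss: total %.6g (weighted %.6g + penalty %.6g)\n",
              x$total, x$weighted, x$penalty))
  cat(sprintf("  L = (%s), lambda = (%s)\n",
              paste(signif(x$base_losses, 4), collapse = ", "),
              paste(signif(x$lam, 4), collapse = ", ")))
  invisible(x)
}

#' Softmax over rows
#' @param x Numeric matrix (samples in rows) or vector.
#' @return Probabilities summing to 1 per row.
#' @export
softmax <- function(x) {
  if (!is.matrix(x)) x <- matrix(x, 1)
  e <- exp(x - apply(x, 1, max))
  e / rowSums(e)
}
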