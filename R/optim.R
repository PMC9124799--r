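#' Adam optimizer state
#'
#' @param shapes Named list of parameter arrays (templates; values ignored).
#' @param beta1,beta2 Moment decay rates.
#' @param eps Numerical stabilizer.
#' @return An object of class `adam_state` with zeroed first/second moment
#'   accumulators and a step counter.
#' @export
adam_init <- function(shapes, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  zero <- lapply(shapes, function(p) { p[] <- 0; p })
  structure(list(m = zero, v = zero, t = 0L,
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "adam_state")
}

#' One Adam update
#'
#' Standard Adam with bias correction. A zero gradient leaves the
#' parameters unchanged; the first step with any nonzero gradient moves
#' each coordinate by approximately `lr` in the negative gradient
#' direction.
#'
#' @param opt An `adam_state`.
#' @param params Named list of parameter arrays.
#' @param grads Named list of gradients, same shapes.
#' @param lr Learning rate.
#' @return List with updated `params` and `opt`.
#' @export
adam_step <- function(opt, params, grads, lr) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + opt$eps)
  }
  list(params = params, opt = opt)
}

#' Gradient-descent update of the ensemble weights
#'
#' One plain gradient step on the augmented-Lagrangian objective with the
#' base losses held fixed:
#' `lam_j <- lam_j - lr * 2 lam_j (L_j + eta1 + 2 eta2 (sum lam^2 - 1))`.
#' `lam_j = 0` is a fixed point of its own coordinate.
#'
#' @param lam Current weights (length 4).
#' @param base_losses Base-loss values treated as constants.
#' @param eta1,eta2 Lagrangian weights.
#' @param lr Step size.
#' @param clip Optional per-coordinate gradient magnitude clip (default
#'   none); used by the trainers for stability when a base loss is large.
#' @return Updated weight vector.
#' @export
update_ensemble_weights <- function(lam, base_losses, eta1, eta2, lr,
                                    clip = Inf) {
  g <- 2 * lam * (base_losses + eta1 + 2 * eta2 * (sum(lam^2) - 1))
  if (is.finite(clip)) g <- pmax(pmin(g, clip), -clip)
  lam - lr * g
}

#' Clip a gradient list by global norm
#' @param grads Named list of gradient arrays.
#' @param max_norm Maximum global L2 norm.
#' @return The (possibly rescaled) gradient list.
#' @keywords internal
clip_gradients <- function(grads, max_norm = 100) {
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(nrm) && nrm > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / nrm))
  }
  grads
}
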