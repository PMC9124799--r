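#' Surrogate-gradient backpropagation through time
#'
#' Reverse-time accumulation of loss gradients through a recorded rollout of
#' the recurrent dynamics and leaky readout, with the Heaviside derivative
#' replaced by the recorded surrogate `psi` wherever a spike enters the
#' backward path. Recurrent credit flows through the transmission delay `d`
#' and the adaptation variable; the Jacobian of the soft reset through the
#' spike is dropped (stop-gradient on the reset), the convention under
#' which the forward eligibility recursions are exact.
#'
#' @param rollout An `snn_rollout` from [simulate_network()].
#' @param network The [snn_network()] that produced it.
#' @param g_y `batch x n_out x time` array of direct loss gradients with
#'   respect to the readout `y(t)` (may be `NULL`).
#' @param g_z,g_v,g_A Optional direct gradient arrays with respect to
#'   spikes, membrane potentials and effective thresholds
#'   (`batch x neurons x time`), e.g. from the rate and voltage
#'   regularizers.
#' @param da_final Optional `batch x neurons` matrix added to the
#'   adaptation-variable gradient at the last step (used when a later
#'   rollout continued from this one).
#' @param return_dx Also return the gradient with respect to the raw input
#'   channels (`batch x n_in x time`); input arriving through the dendritic
#'   filter is treated as data and not differentiated.
#' @param return_boundary Also return gradients with respect to the
#'   pre-rollout state (`dv0`, `da0`, `gy0`, and `dz_pre`, the gradients of
#'   the `d` spike slices preceding step 1), for stitching a rollout to the
#'   one it continued from.
#' @return List with `grads` (named list `W_in`, `W_rec`, `W_out`, `b_out`,
#'   `b_in`) and, on request, `dx` and `boundary`.
#' @export
surrogate_bptt <- function(rollout, network, g_y = NULL, g_z = NULL,
                           g_v = NULL, g_A = NULL, da_final = NULL,
                           return_dx = FALSE, return_boundary = FALSE) {
  p <- network$params
  w <- network$weights
  B <- rollout$n_batch; Tn <- rollout$T
  N <- network$n_rec; K <- network$n_out
  d <- p$d
  Dm <- matrix(network$decay, B, N, byrow = TRUE)
  Gi <- matrix(network$in_gain, B, N, byrow = TRUE)
  Gr <- matrix(network$rec_gain, B, N, byrow = TRUE)
  Bm <- matrix(network$beta, B, N, byrow = TRUE)
  raw_mask <- matrix(!network$filtered_input, B, N, byrow = TRUE)
  any_filt <- any(network$filtered_input)
  tWrec <- t(w$W_rec)
  tWout <- t(w$W_out)

  zero_N <- matrix(0, B, N)
  gW_in <- matrix(0, network$n_in, N)
  gW_rec <- matrix(0, N, N)
  gW_out <- matrix(0, N, K)
  gb_out <- numeric(K)
  gb_in <- numeric(N)
  dx <- if (return_dx) array(0, c(B, network$n_in, Tn)) else NULL

  # backward buffers: dv/da for up to d steps ahead
  dv_buf <- vector("list", Tn + d)
  da_buf <- vector("list", Tn + 1)
  for (i in seq_along(dv_buf)) dv_buf[[i]] <- zero_N
  for (i in seq_along(da_buf)) da_buf[[i]] <- zero_N
  gacc_y <- matrix(0, B, K)

  slice <- function(arr, t, nc) if (is.null(arr)) NULL else matrix(arr[, , t], B, nc)

  for (t in Tn:1) {
    gy_t <- slice(g_y, t, K)
    gacc_y <- p$nu * gacc_y
    if (!is.null(gy_t)) gacc_y <- gacc_y + gy_t
    # local dependence of each step's readout on the bias is (1 - nu);
    # the remaining credit reaches b_out through y(0) below
    gb_out <- gb_out + (1 - p$nu) * colSums(gacc_y)
    psi_t <- matrix(rollout$psi[, , t], B, N)
    z_t <- matrix(rollout$z[, , t], B, N)

    dz <- (1 - p$nu) * (gacc_y %*% tWout) + da_buf[[t + 1]]
    if (t + d <= Tn) dz <- dz + (dv_buf[[t + d]] * Gr) %*% tWrec
    gz_t <- slice(g_z, t, N)
    if (!is.null(gz_t)) dz <- dz + gz_t

    dA <- -psi_t * dz
    gA_t <- slice(g_A, t, N)
    if (!is.null(gA_t)) dA <- dA + gA_t

    dv <- psi_t * dz
    gv_t <- slice(g_v, t, N)
    if (!is.null(gv_t)) dv <- dv + gv_t
    if (t + 1 <= Tn) dv <- dv + Dm * dv_buf[[t + 1]]
    da <- Bm * dA + p$mu * da_buf[[t + 1]]
    if (t == Tn && !is.null(da_final)) da <- da + da_final
    dv_buf[[t]] <- dv
    da_buf[[t]] <- da

    gW_out <- gW_out + (1 - p$nu) * crossprod(z_t, gacc_y)
    dvGr <- dv * Gr
    if (t > d) {
      gW_rec <- gW_rec + crossprod(matrix(rollout$z[, , t - d], B, N), dvGr)
    } else if (!is.null(rollout$z_pre)) {
      gW_rec <- gW_rec + crossprod(matrix(rollout$z_pre[, , d - t + 1], B, N), dvGr)
    }
    dvGi <- dv * Gi
    x_t <- matrix(rollout$x[, , t], B, network$n_in)
    if (any_filt) {
      dvGi_raw <- dvGi * raw_mask
      dvGi_f <- dvGi - dvGi_raw
      xf_t <- matrix(rollout$x_filt[, , t], B, network$n_in)
      gW_in <- gW_in + crossprod(x_t, dvGi_raw) + crossprod(xf_t, dvGi_f)
      if (return_dx) dx[, , t] <- dvGi_raw %*% t(w$W_in)
    } else {
      gW_in <- gW_in + crossprod(x_t, dvGi)
      if (return_dx) dx[, , t] <- dvGi %*% t(w$W_in)
    }
    gb_in <- gb_in + colSums(dvGi)
  }
  diag(gW_rec) <- 0
  gy0 <- p$nu * gacc_y
  if (!isTRUE(rollout$y_continued)) {
    # y(0) was initialized to rows of b_out, so its credit belongs to the bias
    gb_out <- gb_out + colSums(gy0)
  }
  for (g in list(gW_in, gW_rec, gW_out)) {
    if (anyNA(g) || any(is.infinite(g)))
      stop("non-finite gradient in weight block")
  }
  out <- list(grads = list(W_in = gW_in, W_rec = gW_rec, W_out = gW_out,
                           b_out = gb_out, b_in = gb_in))
  if (return_dx) out$dx <- dx
  if (return_boundary) {
    dz_pre <- array(0, c(B, N, d))
    for (k in seq_len(d)) {
      # spike slice at step 1 - k: feeds v(1 - k + d) and (k == 1) a(1)
      tt <- 1 - k + d
      acc <- if (tt >= 1 && tt <= Tn) (dv_buf[[tt]] * Gr) %*% tWrec else zero_N
      if (k == 1) acc <- acc + da_buf[[1]]
      dz_pre[, , k] <- acc
    }
    out$boundary <- list(
      dv0 = Dm * dv_buf[[1]],
      da0 = p$mu * da_buf[[1]],
      gy0 = gy0,
      dz_pre = dz_pre
    )
  }
  out
}
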