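#' Spike raster
#'
#' The in-memory currency for spike trains: a binary `batch x neurons x time`
#' array of spike events `z_j(n, t)` together with the step size `dt` (ms).
#'
#' @param events Binary array (`batch x neurons x time`), or a
#'   `neurons x time` matrix (treated as batch size 1).
#' @param dt Step size in ms.
#' @return An object of class `spike_raster` (the array with attributes
#'   `dt`).
#' @export
#' @examples
#' r <- spike_raster(matrix(rbinom(50, 1, .2), 5, 10), dt = 1)
#' dim(r) # 1 x 5 x 10
spike_raster <- function(events, dt = 1) {
  if (is.matrix(events)) {
    events <- array(events, dim = c(1L, nrow(events), ncol(events)))
  }
  if (length(dim(events)) != 3L)
    stop("events must be a batch x neurons x time array")
  if (!all(events %in% c(0, 1)))
    stop("spike raster entries must be 0 or 1")
  storage.mode(events) <- "double"
  structure(events, dt = dt, class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("spike_raster: %d trial(s) x %d neurons x %d steps (dt = %g ms), %d spikes\n",
              d[1], d[2], d[3], attr(x, "dt"), sum(x)))
  invisible(x)
}

#' Number of trials, neurons and steps of a raster
#' @param raster A `spike_raster`.
#' @return Named integer vector `(n_batch, n_neurons, T)`.
#' @export
raster_dims <- function(raster) {
  d <- dim(raster)
  c(n_batch = d[1], n_neurons = d[2], T = d[3])
}

#' Convert a raster to a plain-text event list
#'
#' @param raster A `spike_raster` (single trial or batched; trial index is
#'   included for batched rasters).
#' @return A data frame with columns `trial`, `neuron_id`, `time_ms`.
#' @export
as_event_list <- function(raster) {
  idx <- which(raster == 1, arr.ind = TRUE)
  dt <- attr(raster, "dt")
  data.frame(trial = idx[, 1], neuron_id = idx[, 2],
             time_ms = (idx[, 3] - 1) * dt)[order(idx[, 1], idx[, 3], idx[, 2]), ,
                                            drop = FALSE]
}

#' Write / read a spike raster as a two-column plain-text event list
#'
#' The interchange format is a whitespace-separated table
#' (`trial neuron_id time_ms`) preceded by comment lines recording the raster
#' dimensions and step size, so the raster round-trips exactly.
#'
#' @param raster A `spike_raster`.
#' @param path File path.
#' @return `write_spike_events` returns `path` invisibly; `read_spike_events`
#'   returns a `spike_raster`.
#' @export
write_spike_events <- function(raster, path) {
  d <- dim(raster)
  ev <- as_event_list(raster)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_batch %d n_neurons %d n_steps %d dt %.17g",
                     d[1], d[2], d[3], attr(raster, "dt")), con)
  writeLines("# trial neuron_id time_ms", con)
  utils::write.table(ev, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_events
#' @export
read_spike_events <- function(path) {
  hdr <- scan(path, what = character(), nlines = 1, quiet = TRUE)
  d <- as.integer(hdr[c(3, 5, 7)])
  dt <- as.numeric(hdr[9])
  ev <- utils::read.table(path, comment.char = "#",
                          col.names = c("trial", "neuron_id", "time_ms"))
  events <- array(0, dim = d)
  if (nrow(ev) > 0) {
    events[cbind(ev$trial, ev$neuron_id, as.integer(round(ev$time_ms / dt)) + 1L)] <- 1
  }
  spike_raster(events, dt = dt)
}

#' Export a trace array as CSV
#'
#' Writes a `batch x neurons x time` trace (membrane potential, threshold,
#' readout, ...) in long format with columns `trial`, `step`, `neuron`,
#' `value`.
#'
#' @param trace Numeric 3-d array (`batch x units x time`) or matrix
#'   (`units x time`).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  if (is.matrix(trace)) trace <- array(trace, c(1L, nrow(trace), ncol(trace)))
  d <- dim(trace)
  df <- data.frame(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    neuron = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    step = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.vector(trace)
  )
  utils::write.csv(df[order(df$trial, df$step, df$neuron), ], path,
                   row.names = FALSE)
  invisible(path)
}
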