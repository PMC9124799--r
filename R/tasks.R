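#' Noise specification
#'
#' @param kind One of `"poisson"` (Gaussian-perturbed firing rates followed
#'   by a Poisson redraw), `"deletion"` (each spike independently deleted)
#'   or `"salt_pepper"` (pixel inversion).
#' @param sigma_noise SD of the per-neuron rate perturbation (Hz).
#' @param p_del Per-spike deletion probability.
#' @param flip_frac Fraction of pixels flipped.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("poisson", "deletion", "salt_pepper"),
                       sigma_noise = 0, p_del = 0, flip_frac = 0.15) {
  kind <- match.arg(kind)
  if (p_del < 0 || p_del > 1) stop("p_del must lie in [0, 1]")
  if (flip_frac < 0 || flip_frac > 1) stop("flip_frac must lie in [0, 1]")
  if (sigma_noise < 0) stop("sigma_noise must be >= 0")
  structure(list(kind = kind, sigma_noise = sigma_noise, p_del = p_del,
                 flip_frac = flip_frac), class = "noise_spec")
}

# Draw one Bernoulli raster (at most one spike per bin) from per-neuron
# rates (Hz); rate upper bound must stay below 1000/dt.
.draw_raster <- function(rates, duration_ms, dt, sparse = FALSE) {
  Tn <- as.integer(round(duration_ms / dt))
  p <- rates * dt / 1000
  m <- matrix(stats::runif(length(rates) * Tn), length(rates), Tn) <
    matrix(p, length(rates), Tn)
  if (sparse) {
    idx <- which(m, arr.ind = TRUE)
    structure(list(neuron = idx[, 1], step = idx[, 2],
                   n_neurons = length(rates), T = Tn, dt = dt),
              class = "sparse_raster")
  } else {
    spike_raster(m * 1, dt = dt)
  }
}

#' Expand a sparse event raster to a dense `spike_raster`
#' @param x A `sparse_raster` (as stored in large pattern datasets) or a
#'   `spike_raster` (returned unchanged).
#' @return A `spike_raster`.
#' @export
as_spike_raster <- function(x) {
  if (inherits(x, "spike_raster")) return(x)
  m <- matrix(0, x$n_neurons, x$T)
  m[cbind(x$neuron, x$step)] <- 1
  spike_raster(m, dt = x$dt)
}

#' Generate spike-pattern class templates
#'
#' Each class is defined by a per-neuron firing-rate profile drawn uniformly
#' from `rate_range`; its template raster is one inhomogeneous Bernoulli
#' (discretized Poisson) draw from those rates.
#'
#' @param n_classes Number of classes.
#' @param n_neurons Neurons per pattern.
#' @param duration_ms Pattern duration (ms).
#' @param rate_range Per-neuron firing-rate bounds in Hz (default 2-50).
#' @param dt Step size (ms).
#' @param seed Integer seed; generation is a pure function of the arguments
#'   and the seed.
#' @param sparse Store rasters as sparse event lists (recommended for large
#'   datasets).
#' @return An object of class `spike_pattern_dataset` with `rates`
#'   (`n_classes x n_neurons` Hz matrix), `templates` (list of rasters) and
#'   an empty `instances` list; see [instantiate_poisson_noise()].
#' @export
generate_templates <- function(n_classes, n_neurons = 100, duration_ms = 200,
                               rate_range = c(2, 50), dt = 1, seed = 1L,
                               sparse = n_classes > 100) {
  stopifnot(n_classes >= 1, n_neurons >= 1, duration_ms > 0)
  if (rate_range[2] > 1000 / dt)
    stop("rate upper bound exceeds one spike per bin (1000/dt Hz)")
  set.seed(as.integer(seed))
  rates <- matrix(stats::runif(n_classes * n_neurons, rate_range[1], rate_range[2]),
                  n_classes, n_neurons)
  templates <- lapply(seq_len(n_classes), function(cl)
    .draw_raster(rates[cl, ], duration_ms, dt, sparse = sparse))
  structure(list(rates = rates, templates = templates,
                 instances = vector("list", n_classes),
                 n_classes = n_classes, n_per_class = 0L,
                 n_neurons = n_neurons, duration_ms = duration_ms,
                 rate_range = rate_range, dt = dt, seed = as.integer(seed),
                 sparse = sparse),
            class = "spike_pattern_dataset")
}

#' @export
print.spike_pattern_dataset <- function(x, ...) {
  cat(sprintf(
    "spike_pattern_dataset: %d classes x %d instances, %d neurons, %g ms (dt %g ms), rates %g-%g Hz\n",
    x$n_classes, x$n_per_class, x$n_neurons, x$duration_ms, x$dt,
    x$rate_range[1], x$rate_range[2]))
  invisible(x)
}

#' Instantiate noisy samples from pattern templates
#'
#' Each instance redraws spikes from the class rate profile after perturbing
#' every neuron's rate by a Gaussian offset with standard deviation
#' `sigma_noise` (clamped at 0 Hz). With `sigma_noise = 0` instances still
#' differ from the template through Poisson resampling variability alone.
#'
#' @param dataset A `spike_pattern_dataset` (all classes), or a single
#'   class's rate vector.
#' @param sigma_noise Rate-perturbation SD in Hz.
#' @param n_instances Instances per class.
#' @param seed Integer seed.
#' @return For a dataset input: the dataset with `instances[[class]]` filled
#'   with `n_instances` rasters each. For a rate vector: a list of rasters.
#' @export
instantiate_poisson_noise <- function(dataset, sigma_noise = 0,
                                      n_instances = 25, seed = 1L) {
  set.seed(as.integer(seed))
  draw_for <- function(rates, duration_ms, dt, sparse) {
    lapply(seq_len(n_instances), function(i) {
      r <- pmax(rates + stats::rnorm(length(rates), sd = sigma_noise), 0)
      .draw_raster(r, duration_ms, dt, sparse = sparse)
    })
  }
  if (inherits(dataset, "spike_pattern_dataset")) {
    dataset$instances <- lapply(seq_len(dataset$n_classes), function(cl)
      draw_for(dataset$rates[cl, ], dataset$duration_ms, dataset$dt,
               dataset$sparse))
    dataset$n_per_class <- as.integer(n_instances)
    dataset$sigma_noise <- sigma_noise
    dataset
  } else {
    draw_for(as.numeric(dataset), attr(dataset, "duration_ms"),
             attr(dataset, "dt") %||% 1, FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random spike-deletion noise
#'
#' Each spike is independently retained with probability `1 - p_del`; empty
#' bins are untouched, so deletion never creates spikes.
#'
#' @param raster A `spike_raster` (any batch shape).
#' @param p_del Per-spike deletion probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A raster of the same shape.
#' @export
apply_deletion_noise <- function(raster, p_del, seed = 1L) {
  if (p_del < 0 || p_del > 1) stop("p_del must lie in [0, 1]")
  set.seed(as.integer(seed))
  idx <- which(raster == 1)
  drop <- idx[stats::runif(length(idx)) < p_del]
  out <- unclass(raster)
  out[drop] <- 0
  spike_raster(out, dt = attr(raster, "dt"))
}

#' Salt-and-pepper pixel noise
#'
#' Inverts a uniformly random subset of pixels whose expected size is
#' `flip_frac * n_pixels` (each pixel flips independently with probability
#' `flip_frac`). Grayscale values are inverted as `1 - x`.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param flip_frac Flip probability per pixel.
#' @param seed Integer seed.
#' @return The corrupted image, with attribute `"flipped"` giving the
#'   realized flipped fraction.
#' @export
salt_pepper <- function(image, flip_frac = 0.15, seed = 1L) {
  if (flip_frac < 0 || flip_frac > 1) stop("flip_frac must lie in [0, 1]")
  set.seed(as.integer(seed))
  flip <- matrix(stats::runif(length(image)) < flip_frac, nrow(image))
  out <- ifelse(flip, 1 - image, image)
  attr(out, "flipped") <- mean(flip)
  out
}

#' Build a few-shot matching episode
#'
#' The two-phase matching protocol: phase 1 presents one support item per
#' sampled class (`k_shot` of them), phase 2 presents `n_way` query items of
#' which exactly one belongs to the support class. A phase-identity channel
#' (0 during phase 1, 1 during phase 2) is appended to the item channels,
#' and no raster instance is reused across phases.
#'
#' @param dataset A `spike_pattern_dataset` with instances.
#' @param n_way Number of query items (candidate classes).
#' @param k_shot Support items per episode (from the single support class).
#' @param noise A [noise_spec()] applied to every item (deletion noise), or
#'   `NULL`.
#' @param support_repeats Number of consecutive presentations of each
#'   support item during phase 1 (the support can be shown longer than one
#'   item slot to give the teacher's learning signals more time to act).
#' @param seed Integer seed.
#' @return An object of class `fewshot_episode`: `support` / `queries`
#'   (lists of `n_neurons x T_item` matrices), `labels` (`l_n`, 1 for the
#'   matching query), `match` (index of the matching query),
#'   `support_class`, `query_classes`, `t_item`, and `input`, the assembled
#'   `(n_neurons + 1) x T_total` input array with the phase-ID channel
#'   last.
#' @export
build_episode <- function(dataset, n_way = 5, k_shot = 1, noise = NULL,
                          support_repeats = 1L, seed = 1L) {
  if (dataset$n_classes < n_way)
    stop("dataset has fewer classes than n_way")
  if (dataset$n_per_class < k_shot + 1)
    stop("need at least k_shot + 1 instances per class")
  set.seed(as.integer(seed))
  classes <- sample.int(dataset$n_classes, n_way)
  support_class <- classes[1]
  match_pos <- sample.int(n_way, 1)
  query_classes <- integer(n_way)
  query_classes[match_pos] <- support_class
  query_classes[-match_pos] <- classes[-1][sample.int(n_way - 1)]

  inst_ids <- sample.int(dataset$n_per_class, k_shot + 1)
  support_ids <- inst_ids[seq_len(k_shot)]
  match_id <- inst_ids[k_shot + 1]

  fetch <- function(cl, id) {
    m <- as_spike_raster(dataset$instances[[cl]][[id]])
    matrix(m, dim(m)[2], dim(m)[3])
  }
  support <- lapply(support_ids, function(id) fetch(support_class, id))
  queries <- lapply(seq_len(n_way), function(q) {
    id <- if (q == match_pos) match_id else sample.int(dataset$n_per_class, 1)
    fetch(query_classes[q], id)
  })
  if (!is.null(noise) && noise$kind == "deletion" && noise$p_del > 0) {
    item_seeds <- sample.int(.Machine$integer.max, k_shot + n_way)
    corrupt <- function(m, s) {
      r <- apply_deletion_noise(spike_raster(m, dt = dataset$dt), noise$p_del,
                                seed = s)
      matrix(r, dim(r)[2], dim(r)[3])
    }
    support <- Map(corrupt, support, item_seeds[seq_len(k_shot)])
    queries <- Map(corrupt, queries, item_seeds[k_shot + seq_len(n_way)])
  }
  t_item <- ncol(support[[1]])
  support_shown <- rep(support, each = as.integer(support_repeats))
  t_phase1 <- length(support_shown) * t_item
  items <- c(support_shown, queries)
  x <- do.call(cbind, items)
  phase <- rep(c(0, 1), c(t_phase1, n_way * t_item))
  input <- rbind(x, phase)
  labels <- as.integer(seq_len(n_way) == match_pos)
  structure(list(support = support, queries = queries, labels = labels,
                 match = match_pos, support_class = support_class,
                 query_classes = query_classes, t_item = t_item,
                 t_phase1 = t_phase1, input = input, dt = dataset$dt,
                 n_way = n_way, k_shot = k_shot,
                 support_repeats = as.integer(support_repeats)),
            class = "fewshot_episode")
}

#' @export
print.fewshot_episode <- function(x, ...) {
  cat(sprintf("fewshot_episode: %d-way %d-shot, item length %d steps, match at query %d\n",
              x$n_way, x$k_shot, x$t_item, x$match))
  invisible(x)
}
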