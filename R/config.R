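#' Default experiment configuration
#'
#' The full flat key-value configuration of an experiment, with neural and
#' optimization constants at their reference values: membrane constant
#' 15 ms, readout constant 10 ms, transmission delay 1 ms, refractory
#' period 5 ms, target rate 20 Hz, outer-loop rate 2e-3, rate
#' regularization 1.0, threshold 1.0, voltage regularization 1e-2, 20
#' steps per item, adaptation constant 200 ms, learning rate 1.915e-3,
#' adaptive fraction 40.5 %, adaptation impact 0.4902, batch size 285,
#' teacher size 239, learning-signal constant 10 ms, teacher target rate
#' 20 Hz, and the learner split of 180 two-compartment plus 260 plain LIF
#' neurons.
#'
#' @param task `"patterns"`, `"matching"` or `"motor"`.
#' @return A named list of class `experiment_config`.
#' @export
default_config <- function(task = c("patterns", "matching", "motor")) {
  task <- match.arg(task)
  cfg <- list(
    task = task,
    # neuron constants
    tau_m = 15, tau_out = 10, tau_a = 200, tau_ls = 10,
    v_th = 1.0, beta_adapt = 0.4902, t_refrac = 5, d = 1, dt = 1,
    # dendrite constants
    g_l = 1, g_b = 1, C_m = 15, tau_L = 10, tau_s = 2,
    # regularizers
    f_target = 20, f_target_psnn = 20, lam_f = 1.0, lam_v = 1e-2,
    # ensemble loss
    eta1 = 0.1, eta2 = 10, sigma1 = 1.0, sigma2 = 4.0, lam_mix = 0.5,
    lam_trainable = TRUE,
    # optimization
    lr = 1.915e-3, lr_out = 2e-3, lr_lam = 2e-4, n_batch = 285, n_iters = 100,
    eta_inner = 1e-2, grad_clip = 100,
    # architecture
    n_tlif = 180, n_lif = 260, n_psnn = 239, q_ada = 0.405,
    t_img = 20,
    # task family
    n_classes = 1000, n_per_class = 25, n_neurons = 100,
    duration_ms = 200, rate_min = 2, rate_max = 50,
    sigma_noise = 0, p_del = 0, flip_frac = 0.15,
    n_way = 5, k_shot = 1,
    motor_duration_ms = 500, n_clock = 20, L1 = 0.5, L2 = 0.5,
    init_gain = 1,
    seed = 1
  )
  structure(cfg, class = "experiment_config")
}

#' Read / write a plain-text key-value configuration
#'
#' The on-disk format is one `key: value` pair per line; `#` starts a
#' comment. Values are parsed as numeric or logical where possible.
#' Unknown keys raise an error naming the key.
#'
#' @param path File path.
#' @param base Configuration supplying defaults for unlisted keys.
#' @return An `experiment_config`.
#' @export
read_config <- function(path, base = default_config()) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- base
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3)
      stop(sprintf("malformed configuration line: '%s'", ln))
    key <- m[2]; val <- trimws(m[3])
    if (!key %in% names(cfg))
      stop(sprintf("unknown configuration key: '%s'", key))
    cfg[[key]] <- if (val %in% c("TRUE", "FALSE", "true", "false")) {
      toupper(val) == "TRUE"
    } else if (grepl("^[-+0-9.eE]+$", val) && !is.na(suppressWarnings(as.numeric(val)))) {
      as.numeric(val)
    } else {
      val
    }
  }
  if (identical(cfg$task, "patterns") || identical(cfg$task, "matching") ||
      identical(cfg$task, "motor")) cfg else
    stop(sprintf("unknown task: '%s'", cfg$task))
}

#' @rdname read_config
#' @param cfg An `experiment_config`.
#' @export
write_config <- function(cfg, path) {
  fmt <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    sprintf("%s: %s", k, format(v, scientific = FALSE, trim = TRUE))
  }, character(1))
  writeLines(fmt, path)
  invisible(path)
}

#' Hash of a configuration (for run provenance)
#' @param cfg An `experiment_config`.
#' @return MD5 hex string of the canonical serialized form.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(vapply(sort(names(cfg)), function(k)
    sprintf("%s=%s", k, paste(format(cfg[[k]], digits = 17), collapse = ",")),
    character(1)), tf)
  unname(tools::md5sum(tf))
}

# Build the pieces of an experiment from a flat configuration.
.cfg_params <- function(cfg) {
  neuron_params(tau_m = cfg$tau_m, tau_out = cfg$tau_out, tau_a = cfg$tau_a,
                v_th = cfg$v_th, beta_adapt = cfg$beta_adapt,
                t_refrac = cfg$t_refrac, d = cfg$d, dt = cfg$dt)
}

.cfg_dparams <- function(cfg) {
  dendrite_params(g_l = cfg$g_l, g_b = cfg$g_b, C_m = cfg$C_m,
                  tau_L = cfg$tau_L, tau_s = cfg$tau_s)
}

.cfg_train <- function(cfg) {
  train_config(
    ensemble = ensemble_loss_config(eta1 = cfg$eta1, eta2 = cfg$eta2,
                                    trainable = isTRUE(cfg$lam_trainable)),
    correntropy = correntropy_config(cfg$sigma1, cfg$sigma2, cfg$lam_mix),
    regularizer = regularizer_config(cfg$f_target, cfg$lam_f, cfg$lam_v,
                                     cfg$v_th),
    batch_size = cfg$n_batch, lr_w = cfg$lr, lr_lam = cfg$lr_lam,
    grad_clip = cfg$grad_clip)
}

.cfg_meta <- function(cfg) {
  meta_config(
    eta_inner = cfg$eta_inner, lr_w = cfg$lr_out, lr_lam = cfg$lr_lam,
    ensemble = ensemble_loss_config(eta1 = cfg$eta1, eta2 = cfg$eta2,
                                    trainable = isTRUE(cfg$lam_trainable)),
    correntropy = correntropy_config(cfg$sigma1, cfg$sigma2, cfg$lam_mix),
    regularizer = regularizer_config(cfg$f_target, cfg$lam_f, cfg$lam_v,
                                     cfg$v_th),
    regularizer_psnn = regularizer_config(cfg$f_target_psnn, cfg$lam_f,
                                          cfg$lam_v, cfg$v_th),
    grad_clip = cfg$grad_clip)
}
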