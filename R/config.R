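#' Run configuration
#'
#' A run config is a YAML document fully specifying a run: dataset
#' generation, noise-model calibration, the three network specs, the
#' training plan, and the evaluation convention. Unknown keys are rejected
#' by name so typos cannot silently change a run. The config round-trips
#' losslessly through [write_run_config()] / [read_run_config()].
#'
#' @return `default_run_config()` returns the complete default config as a
#'   nested list.
#' @export
default_run_config <- function() {
  list(
    schema = 1L,
    seed = 1L,
    data = list(dir = "data", n_phantom = 4L, n_patient = 8L,
                doses = c(20, 30, 60), train_fraction = 0.8, size = 64L),
    noise = list(reference_mAs = 175, k = 190),
    networks = list(
      simulator = list(depth = 2L, width = 8L),
      denoiser = list(depth = 5L, width = 8L, init = "zero-residual"),
      discriminator = list(depth = 3L, width = 8L),
      hu_window = c(-1024, 1024)),
    plan = list(stage1_steps = 200L, stage2_steps = 300L, batch_size = 2L,
                patch_size = 32L, s2d_d2s_ratio = c(1L, 1L),
                lr_g = 1e-4, lr_d = 2e-3, lr_den = 2e-3,
                lambda = c(1, 1, 10, 10),
                sim_feedback = "none", d2s_inputs = "mixed",
                sim_ema_decay = 0.995, val_every = 25,
                checkpoint_every = Inf),
    evaluate = list(data_range = 2048))
}

check_known_keys <- function(cfg, ref, prefix = "") {
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown)) {
    stop("unknown config key: ", prefix, unknown[1], call. = FALSE)
  }
  for (k in names(cfg)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
      if (!is.list(cfg[[k]])) {
        stop("config key ", prefix, k, " must be a mapping", call. = FALSE)
      }
      check_known_keys(cfg[[k]], ref[[k]], paste0(prefix, k, "."))
    }
  }
  invisible(TRUE)
}

#' @rdname default_run_config
#' @param path YAML file path.
#' @return `read_run_config()` returns the validated config (defaults filled
#'   in); `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  ref <- default_run_config()
  check_known_keys(cfg, ref)
  deep_merge(ref, cfg)
}

deep_merge <- function(ref, cfg) {
  for (k in names(cfg)) {
    ref[[k]] <- if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) &&
                    is.list(cfg[[k]])) {
      deep_merge(ref[[k]], cfg[[k]])
    } else {
      cfg[[k]]
    }
  }
  ref
}

#' @rdname default_run_config
#' @param config A config list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# materialize package objects from a config
config_noise_model <- function(cfg) {
  noise_model(reference_mAs = cfg$noise$reference_mAs, k = cfg$noise$k)
}

config_plan <- function(cfg) {
  nw <- cfg$networks
  win <- as.numeric(nw$hu_window)
  training_plan(
    stage1_steps = cfg$plan$stage1_steps,
    stage2_steps = cfg$plan$stage2_steps,
    batch_size = cfg$plan$batch_size,
    patch_size = cfg$plan$patch_size,
    s2d_d2s_ratio = as.integer(cfg$plan$s2d_d2s_ratio),
    lr_g = cfg$plan$lr_g, lr_d = cfg$plan$lr_d, lr_den = cfg$plan$lr_den,
    lambda = as.numeric(cfg$plan$lambda),
    seed = cfg$seed,
    simulator_spec = network_spec("simulator", nw$simulator$depth,
                                  nw$simulator$width, hu_window = win),
    denoiser_spec = network_spec("denoiser", nw$denoiser$depth,
                                 nw$denoiser$width,
                                 init = nw$denoiser$init %||% "he",
                                 hu_window = win),
    discriminator_spec = network_spec("discriminator",
                                      nw$discriminator$depth,
                                      nw$discriminator$width,
                                      hu_window = win),
    sim_feedback = cfg$plan$sim_feedback,
    d2s_inputs = cfg$plan$d2s_inputs,
    sim_ema_decay = cfg$plan$sim_ema_decay,
    val_every = cfg$plan$val_every,
    checkpoint_every = cfg$plan$checkpoint_every)
}
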