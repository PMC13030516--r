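#' Default pipeline configuration
#'
#' The full set of tunable constants, as a nested list mirroring the YAML
#' config file layout: `network`, `schedule`, `loss`, `optim`, `data`
#' (preprocessing/patching) and `postprocess` keys.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    network = list(in_channels = 1L, base_channels = 16L, n_classes = 24L,
                   bottleneck_op = "state_space",
                   bottleneck_placement = "bottleneck_only",
                   cbam_placement = "id_only", cbam_reduction = 4L),
    schedule = list(E_cons = 40L, E_ramp = 80L,
                    tau_cls_range = c(0.30, 0.55),
                    tau_seg_range = c(0.50, 0.90),
                    temperature = 0.5, ema_alpha = 0.99, total_epochs = 100L),
    loss = list(alpha_cls = 1.0, alpha_seg = 0.5,
                scale_weights = c(4, 2, 1) / 7, epsilon = 1e-6,
                kl_inst_mix = c(1, 1)),
    optim = list(lr = 0.01, momentum = 0.9, seed = 42L,
                 batch_labeled = 2L, batch_unlabeled = 2L),
    data = list(spacing = 1.0, hu_lo = -500, hu_hi = 1500,
                patch = c(128L, 64L, 64L), overlap = 0.5, aug_seed = 1L),
    postprocess = list(thr = 0.5, min_fragment = 200L, floor_frac = 0.1)
  )
}

#' Read a YAML config file merged over the defaults
#' @param path YAML file path; `NULL` returns the defaults.
#' @return nested named list as [default_config()].
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (top in names(user)) {
      cfg[[top]] <- modifyList(cfg[[top]] %||% list(), user[[top]])
    }
  }
  cfg
}

#' Build typed configuration objects from a config list
#' @param cfg nested list from [read_config()].
#' @param total_epochs optional override that rescales the schedule.
#' @return a [train_config()].
#' @export
config_to_train <- function(cfg, total_epochs = NULL) {
  net <- do.call(network_config, cfg$network)
  sched <- do.call(schedule_config, cfg$schedule)
  if (!is.null(total_epochs)) sched <- scale_schedule(sched, total_epochs)
  loss <- do.call(loss_config, cfg$loss)
  train_config(network = net, schedule = sched, loss = loss,
               lr = cfg$optim$lr, momentum = cfg$optim$momentum,
               seed = cfg$optim$seed,
               batch_labeled = cfg$optim$batch_labeled,
               batch_unlabeled = cfg$optim$batch_unlabeled,
               patch_shape = cfg$data$patch)
}
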