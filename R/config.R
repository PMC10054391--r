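#' Pipeline configuration
#'
#' All tunable parameters of the pipeline with their defaults: frame
#' rate 21 fps, detector input 960 px, 21-frame analysis sequences
#' (one second of video), 8-frame recognition units, tubelet-linking
#' gap threshold `k = 15` frames, matching distance cutoff 100
#' (equivalent to requiring `IoU * dot >= 0.01`), 300 x 650 px unified
#' crop target, 224 px square crop output, the 12-behavior catalogue
#' with its active/static category map, and the poor-welfare thresholds.
#' `training` records the hyperparameters a training harness for the
#' reference two-stream model would use; training is not executed by
#' this package.
#'
#' @return Named list of class `pw_config`.
#' @export
default_config <- function() {
  structure(list(
    fps = 21,
    detector_input_size = 960,
    image_size = 960,
    sequence_len = 21,
    unit_len = 8,
    k = 15,
    max_distance = 100,
    crop_target_w = 300,
    crop_target_h = 650,
    crop_out = 224,
    heatmap_grid = 32,
    session_window_min = 5,
    behavior_labels = behavior_labels(),
    behavior_categories = behavior_categories(),
    welfare_thresholds = welfare_thresholds(),
    backends = "mock",
    seed = 1,
    training = list(
      optimizer = "adam", lr_cnn = 5e-5, lr_lstm = 5e-4,
      epochs_rgb = 60, epochs_flow = 150, epochs_lstm = 200,
      dropout = 0.5, recurrent_dropout = 0.1, input_size = 224,
      lstm_hidden = 60
    )
  ), class = "pw_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file, applies [default_config()] for missing keys, and
#' validates the result. The welfare-threshold table may be overridden
#' with a list of `{behavior, measure_kind, threshold}` records.
#'
#' @param path Path to a YAML file; an empty file yields the defaults.
#' @return A validated `pw_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  if (!is.null(raw)) {
    if ("welfare_thresholds" %in% names(raw)) {
      raw$welfare_thresholds <- dplyr::bind_rows(raw$welfare_thresholds)
    }
    for (key in names(raw)) cfg[[key]] <- raw[[key]]
  }
  validate_config(cfg)
}

#' @rdname load_config
#' @param config A configuration list to validate.
#' @export
validate_config <- function(config) {
  check <- function(ok, key, why) {
    if (!ok) stop("invalid config value for '", key, "': ", why, call. = FALSE)
  }
  check(config$unit_len >= 2, "unit_len", "must be >= 2")
  check(config$k >= 1, "k", "must be >= 1")
  for (key in c("fps", "detector_input_size", "image_size", "sequence_len",
                "crop_target_w", "crop_target_h", "crop_out",
                "heatmap_grid", "max_distance")) {
    check(is.numeric(config[[key]]) && config[[key]] > 0, key,
          "must be a positive number")
  }
  check(all(behavior_labels() %in% names(config$behavior_categories)),
        "behavior_categories", "must cover all 12 behavior labels")
  check(all(c("behavior", "measure_kind", "threshold") %in%
              names(config$welfare_thresholds)),
        "welfare_thresholds", "needs behavior/measure_kind/threshold")
  structure(config, class = "pw_config")
}
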