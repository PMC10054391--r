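#' Turn a frame store into an on-demand frame source
#'
#' The pipeline fetches frames lazily, one recognition unit at a time,
#' so long sessions never need all frames in memory. A frame source is
#' a function taking a 0-based frame index and returning a frame array;
#' this helper builds one from a directory of image files, a named list
#' of arrays, a `scenario_script` (frames rendered on demand), or an
#' existing function (returned as-is).
#'
#' @param x Directory path, named list of arrays, `scenario_script`, or
#'   `function(frame) -> array`.
#' @param resize_to Optional square resize applied by the directory
#'   reader.
#' @return `function(frame_index) -> array`.
#' @export
frame_source <- function(x, resize_to = NULL) {
  if (is.function(x)) return(x)
  if (inherits(x, "scenario_script")) {
    truth <- scenario_truth(x)
    return(function(i) render_one_frame(x, truth[truth$frame == i, ], i))
  }
  if (is.character(x) && length(x) == 1) {
    frames <- ingest_frames(x, resize_to = resize_to)
    return(function(i) frames[[as.character(i)]])
  }
  if (is.list(x)) return(function(i) x[[as.character(i)]])
  stop("cannot interpret frame source", call. = FALSE)
}

#' Run the full summarization pipeline
#'
#' Executes every stage on a detection stream: windowing and screening,
#' tubelet building and gap-limited linking, dog-alone retrieval,
#' unified-box cropping, two-stream behavior recognition, and session
#' summarization. When `out_dir` is given, writes the location log,
#' behavior log, episode table, welfare indicators (JSON), alerts, the
#' five summary figures (PNG), and a small `report.json`.
#'
#' @param detections Detection tibble or path to a detection CSV.
#' @param n_frames Total number of frames in the stream.
#' @param frames Frame source (see [frame_source()]); only needed when
#'   recognition is run, i.e. when any dog-alone unit exists.
#' @param config Pipeline configuration ([default_config()]).
#' @param backends Backend set ([mock_backends()],
#'   [reference_backends()]); defaults to the set named in
#'   `config$backends`.
#' @param out_dir Optional output directory for the report files.
#' @return List of class `pw_run`: `retrieval` (windows, tubelets, runs,
#'   units, locations), `log` (behavior log), `summary` ([summarize_session()]
#'   result), `crop_windows` (per-unit crop boxes).
#' @export
run_pipeline <- function(detections, n_frames, frames = NULL,
                         config = default_config(), backends = NULL,
                         out_dir = NULL) {
  config <- validate_config(config)
  if (is.character(detections)) detections <- read_detections(detections)
  if (is.null(backends)) {
    backends <- switch(config$backends,
                       mock = mock_backends(),
                       reference = reference_backends(seed = config$seed),
                       stop("unknown backend set '", config$backends, "'",
                            call. = FALSE))
  }
  ret <- retrieve_units(detections, n_frames, config)
  log <- empty_behavior_log()
  crop_windows <- list()
  if (nrow(ret$units) > 0) {
    if (is.null(frames)) {
      stop("run_pipeline: dog-alone units found but no frame source given",
           call. = FALSE)
    }
    get_frame <- frame_source(frames)
    dog_rows <- ret$tubelets[ret$tubelets$label == "dog", ]
    preds <- vector("list", nrow(ret$units))
    for (u in seq_len(nrow(ret$units))) {
      fr <- ret$units$start_frame[u]:ret$units$end_frame[u]
      boxes <- dog_rows[dog_rows$frame %in% fr, ]
      window <- unit_crop_window(boxes, config)
      unit_frames <- lapply(fr, get_frame)
      cropped <- crop_unit(unit_frames, window, out_size = config$crop_out)
      preds[[u]] <- recognize(cropped, ret$units$start_frame[u], backends)
      crop_windows[[u]] <- window
    }
    log <- dplyr::bind_rows(preds)
  }
  summary <- summarize_session(log, ret$locations, config)
  out <- structure(list(retrieval = ret, log = log, summary = summary,
                        crop_windows = crop_windows, config = config),
                   class = "pw_run")
  if (!is.null(out_dir)) write_report(out, out_dir)
  out
}

#' Write the report files of a pipeline run
#'
#' @param run A `pw_run` from [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_locations(run$retrieval$locations, p("locations.csv"))
  write_behavior_log(run$log, p("behavior_log.csv"))
  write_episodes(run$summary$episodes, p("episodes.csv"))
  jsonlite::write_json(run$summary$welfare, p("indicators.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.csv(run$summary$alerts, p("alerts.csv"), row.names = FALSE,
                   quote = FALSE)
  save_fig <- function(plot, name, w = 6, h = 5) {
    grDevices::png(p(name), width = w * 100, height = h * 100, res = 100)
    print(plot)
    grDevices::dev.off()
  }
  save_fig(plot_gauges(run$summary$welfare), "gauges.png", 7, 3.2)
  save_fig(plot_heatmap(run$summary$heatmap), "heatmap.png")
  save_fig(plot_trajectory(run$summary$trajectory), "trajectory.png")
  if (!is.null(run$summary$proportions)) {
    save_fig(plot_doughnut(run$summary$proportions), "proportions.png")
  }
  save_fig(plot_timeline(run$summary$timeline), "timeline.png", 8, 5)
  jsonlite::write_json(list(
    n_windows = nrow(run$retrieval$windows),
    n_kept = sum(run$retrieval$windows$decision == "keep"),
    n_dog_alone_units = nrow(run$retrieval$units),
    n_location_records = nrow(run$retrieval$locations),
    n_episodes = nrow(run$summary$episodes),
    n_flagged = sum(run$summary$welfare$flagged),
    note = if (nrow(run$retrieval$units) == 0)
      "zero dog-alone sequences retrieved" else "ok"
  ), p("report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
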