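#' Group a detection stream into fixed-length frame sequences
#'
#' Splits frames `0 .. n_frames - 1` into consecutive non-overlapping
#' windows of `n` frames (default 21, one second at the reference
#' camera's frame rate). A trailing partial window at stream end is kept
#' and processed as-is.
#'
#' @param detections Detection tibble for the whole stream.
#' @param n_frames Total number of frames in the stream (frames without
#'   detections still exist and count).
#' @param n Window length in frames.
#' @return Tibble with one row per window: `seq_id`, `start_frame`,
#'   `end_frame` (inclusive) and a `detections` list-column holding each
#'   window's detection rows.
#' @export
group_stream <- function(detections, n_frames, n = 21) {
  stopifnot(n_frames >= 1, n >= 1)
  starts <- seq.int(0L, n_frames - 1L, by = n)
  ends <- pmin(starts + n - 1L, n_frames - 1L)
  tibble::tibble(
    seq_id = seq_along(starts),
    start_frame = as.integer(starts),
    end_frame = as.integer(ends),
    detections = purrr::map2(starts, ends, function(s, e) {
      detections[detections$frame >= s & detections$frame <= e, ]
    })
  )
}

#' Screen a frame sequence for further analysis
#'
#' A window is discarded when it contains no detection at all
#' (`"discard_empty"`: an empty room) or when at least one person is
#' detected in every one of its frames (`"discard_person_everywhere"`:
#' the dog is never alone). Otherwise it is kept.
#'
#' @param detections Detection tibble of the window.
#' @param start_frame,end_frame Inclusive frame range of the window.
#' @return One of `"discard_empty"`, `"discard_person_everywhere"`,
#'   `"keep"`.
#' @export
screen_sequence <- function(detections, start_frame, end_frame) {
  frames <- seq.int(start_frame, end_frame)
  if (nrow(detections) == 0) return("discard_empty")
  person_frames <- unique(detections$frame[detections$label == "person"])
  if (all(frames %in% person_frames)) return("discard_person_everywhere")
  "keep"
}

#' Select the frame runs where the dog is alone
#'
#' A frame counts as dog-alone when at least one dog tubelet has an
#' entry there and no person tubelet has one. Interpolated entries count
#' as presence for both classes: the selection runs on postprocessed
#' tubelets, after missed detections have been filled in.
#'
#' @param tubelets Linked tubelet tibble (dog and person together).
#' @param start_frame,end_frame Inclusive frame range to scan.
#' @return Tibble of maximal dog-alone runs with columns `start`, `end`
#'   (inclusive frame indices).
#' @export
select_dog_alone <- function(tubelets, start_frame, end_frame) {
  frames <- seq.int(start_frame, end_frame)
  dog <- unique(tubelets$frame[tubelets$label == "dog"])
  person <- unique(tubelets$frame[tubelets$label == "person"])
  alone <- frames[frames %in% dog & !(frames %in% person)]
  runs_from_frames(alone)
}

runs_from_frames <- function(frames) {
  if (length(frames) == 0) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  frames <- sort(unique(as.integer(frames)))
  brk <- c(0L, which(diff(frames) > 1L), length(frames))
  tibble::tibble(
    start = frames[brk[-length(brk)] + 1L],
    end = frames[brk[-1L]]
  )
}

#' Regroup dog-alone runs into fixed-length recognition units
#'
#' Cuts each run into consecutive non-overlapping units of `unit_len`
#' frames (default 8, the input length of the sequence classifier). A
#' trailing remainder shorter than `unit_len` is dropped, except when
#' the run touches `window_end`: those frames are returned as the carry
#' and can be prepended to a temporally contiguous run of the next
#' window (pass them back via `carry`).
#'
#' @param runs Run tibble (`start`, `end`) as from [select_dog_alone()].
#' @param unit_len Unit length in frames.
#' @param carry Optional one-row run tibble carried over from the
#'   previous call; prepended when contiguous with the first run.
#' @param window_end Last frame index of the current analysis window
#'   (`NULL` for batch processing: all remainders are dropped).
#' @return List with `units` (tibble `start_frame`, `end_frame`) and
#'   `carry` (run tibble, possibly empty).
#' @export
regroup_eight <- function(runs, unit_len = 8, carry = NULL,
                          window_end = NULL) {
  stopifnot(unit_len >= 2)
  no_carry <- tibble::tibble(start = integer(), end = integer())
  if (!is.null(carry) && nrow(carry) > 0 && nrow(runs) > 0 &&
      carry$end[1] + 1L == runs$start[1]) {
    runs$start[1] <- carry$start[1]
  } else if (!is.null(carry) && nrow(carry) > 0 && nrow(runs) == 0) {
    runs <- carry
  }
  units <- list()
  new_carry <- no_carry
  for (r in seq_len(nrow(runs))) {
    s <- runs$start[r]; e <- runs$end[r]
    len <- e - s + 1L
    n_units <- len %/% unit_len
    if (n_units > 0) {
      us <- s + unit_len * (seq_len(n_units) - 1L)
      units[[length(units) + 1]] <- tibble::tibble(
        start_frame = as.integer(us),
        end_frame = as.integer(us + unit_len - 1L)
      )
    }
    rem <- len %% unit_len
    if (rem > 0 && !is.null(window_end) && e == window_end) {
      new_carry <- tibble::tibble(start = as.integer(e - rem + 1L),
                                  end = as.integer(e))
    }
  }
  units <- if (length(units)) dplyr::bind_rows(units) else
    tibble::tibble(start_frame = integer(), end_frame = integer())
  list(units = units, carry = new_carry)
}

#' Location log from dog tubelet entries
#'
#' One record per dog-alone frame: frame index, timestamp in seconds
#' (`frame / fps`), and the dog's bounding box. This is the movement log
#' consumed by the heatmap and trajectory summaries.
#'
#' @param dog_entries Tubelet tibble rows of the dog (any provenance).
#' @param fps Frame rate in frames per second.
#' @return Tibble `frame`, `timestamp_s`, `xmin`, `ymin`, `xmax`,
#'   `ymax`, ordered by frame.
#' @export
log_locations <- function(dog_entries, fps = 21) {
  stopifnot(fps > 0)
  out <- tibble::tibble(
    frame = as.integer(dog_entries$frame),
    timestamp_s = dog_entries$frame / fps,
    xmin = dog_entries$xmin, ymin = dog_entries$ymin,
    xmax = dog_entries$xmax, ymax = dog_entries$ymax
  )
  out[order(out$frame), ]
}

#' Full retrieval pass over a detection stream
#'
#' Runs the whole retrieval stage: windows the stream
#' ([group_stream()]), screens each window ([screen_sequence()]), builds
#' and links tubelets over the kept windows ([build_tubelets()],
#' [link_tubelets()] — linking also bridges gaps that span adjacent
#' windows), selects dog-alone runs ([select_dog_alone()]), cuts them
#' into recognition units ([regroup_eight()]) and logs the dog's
#' locations ([log_locations()]).
#'
#' @param detections Detection tibble for the whole stream.
#' @param n_frames Total frame count of the stream.
#' @param config Pipeline configuration, see [default_config()].
#' @return List with `windows` (screening decisions), `tubelets`
#'   (linked), `runs` (dog-alone runs), `units` (8-frame units),
#'   `locations` (location log restricted to dog-alone frames).
#' @export
retrieve_units <- function(detections, n_frames, config = default_config()) {
  windows <- group_stream(detections, n_frames, n = config$sequence_len)
  windows$decision <- purrr::pmap_chr(
    list(windows$detections, windows$start_frame, windows$end_frame),
    screen_sequence
  )
  kept <- windows[windows$decision == "keep", ]
  tubelets <- empty_tubelets()
  if (nrow(kept) > 0) {
    per_window <- purrr::map(kept$detections, build_tubelets,
                             max_distance = config$max_distance)
    offset <- 0L
    for (i in seq_along(per_window)) {
      ids <- per_window[[i]]$tubelet_id
      per_window[[i]]$tubelet_id <- ids + offset
      offset <- offset + max(0L, ids)
    }
    tubelets <- link_tubelets(dplyr::bind_rows(per_window), k = config$k)
  }
  kept_frames <- unlist(purrr::map2(kept$start_frame, kept$end_frame, seq.int))
  runs <- select_dog_alone(tubelets,
                           start_frame = 0L, end_frame = n_frames - 1L)
  # dog-alone frames must lie in kept windows
  alone_frames <- unlist(purrr::map2(runs$start, runs$end, seq.int))
  alone_frames <- alone_frames[alone_frames %in% kept_frames]
  runs <- runs_from_frames(alone_frames)
  units <- regroup_eight(runs, unit_len = config$unit_len)$units
  dog_rows <- tubelets[tubelets$label == "dog" &
                         tubelets$frame %in% alone_frames, ]
  dog_rows <- dog_rows[order(dog_rows$frame), ]
  dog_rows <- dog_rows[!duplicated(dog_rows$frame), ]
  locations <- log_locations(dog_rows, fps = config$fps)
  list(windows = windows[, c("seq_id", "start_frame", "end_frame", "decision")],
       tubelets = tubelets, runs = runs, units = units,
       locations = locations)
}
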