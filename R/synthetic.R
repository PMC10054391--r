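#' Scripted monitoring scenarios with known ground truth
#'
#' Builds a scenario script describing a monitored room: which actors
#' (dog, person) are present and when, how they move, what behavior the
#' dog displays over time, and how noisy the simulated detector is.
#' Everything downstream — rendered frames, ground-truth boxes,
#' detection streams, behavior labels — derives deterministically from
#' the script and its seed, so every pipeline stage can be tested
#' against exact ground truth without real video or trained weights.
#'
#' The scenario taxonomy mirrors the situations a home camera sees:
#' an empty room, a person only, a dog alone, a dog with a person, and
#' `"mixed"` (dog present throughout, person entering and leaving
#' mid-session while the dog works through a behavior script).
#'
#' @param scenario One of `"empty"`, `"person"`, `"dog"`,
#'   `"dog_person"`, `"mixed"`.
#' @param duration_s Session length in seconds.
#' @param fps Frame rate (frames per second).
#' @param image_size Square frame side length in pixels.
#' @param behavior_script Tibble/data frame with columns `label`,
#'   `duration_s`: the dog's scripted behaviors, played in order from
#'   t = 0 (frames beyond the script are `"idle"`). Ignored for
#'   dog-less scenarios.
#' @param person_interval Numeric `c(start_s, end_s)`: when the person
#'   is present in the `"mixed"` scenario (default: the middle fifth of
#'   the session).
#' @param miss_rate Probability that a ground-truth box is dropped by
#'   [simulate_detections()].
#' @param jitter_px Half-width of the uniform box-coordinate noise.
#' @param seed Integer seed; fixed seed means byte-identical outputs.
#' @return A `scenario_script` object (list).
#' @export
scenario_script <- function(scenario = c("dog", "empty", "person",
                                         "dog_person", "mixed"),
                            duration_s = 30, fps = 21, image_size = 960,
                            behavior_script = NULL, person_interval = NULL,
                            miss_rate = 0, jitter_px = 0, seed = 1) {
  scenario <- match.arg(scenario)
  n_frames <- as.integer(round(duration_s * fps))
  if (is.null(behavior_script)) {
    behavior_script <- tibble::tibble(label = "idle", duration_s = duration_s)
  }
  behavior_script <- tibble::as_tibble(behavior_script)
  stopifnot(all(behavior_script$label %in% behavior_labels()),
            sum(behavior_script$duration_s) <= duration_s + 1e-9,
            miss_rate >= 0, miss_rate <= 1, jitter_px >= 0)
  dog_present <- scenario %in% c("dog", "dog_person", "mixed")
  person_present <- switch(scenario,
    empty = NULL, dog = NULL,
    person = c(0, duration_s),
    dog_person = c(0, duration_s),
    mixed = if (is.null(person_interval))
      c(0.4 * duration_s, 0.6 * duration_s) else person_interval)
  structure(list(scenario = scenario, duration_s = duration_s, fps = fps,
                 n_frames = n_frames, image_size = image_size,
                 dog_present = dog_present,
                 person_interval = person_present,
                 behavior_script = behavior_script,
                 miss_rate = miss_rate, jitter_px = jitter_px,
                 seed = as.integer(seed)),
            class = "scenario_script")
}

#' Dog behavior label at each frame of a script
#'
#' @param script A `scenario_script`.
#' @param frames Integer frame indices.
#' @return Character vector of behavior labels (`"idle"` past the end of
#'   the behavior script).
#' @export
behavior_at_frame <- function(script, frames) {
  bs <- script$behavior_script
  ends <- cumsum(bs$duration_s) * script$fps   # exclusive frame bounds
  t <- frames + 0.5
  idx <- findInterval(t, c(0, ends), rightmost.closed = FALSE)
  out <- rep("idle", length(frames))
  ok <- idx >= 1 & idx <= nrow(bs)
  out[ok] <- bs$label[idx[ok]]
  out
}

dog_path <- function(script, frames) {
  # smooth loop around the right-center of the room; constant box size
  s <- script$image_size
  ang <- 2 * pi * frames / (script$fps * 20)    # one lap per 20 s
  cx <- 0.60 * s + 0.22 * s * cos(ang)
  cy <- 0.50 * s + 0.22 * s * sin(ang)
  bw <- 0.12 * s; bh <- 0.09 * s
  tibble::tibble(frame = as.integer(frames), label = "dog",
                 xmin = cx - bw / 2, ymin = cy - bh / 2,
                 xmax = cx + bw / 2, ymax = cy + bh / 2)
}

person_path <- function(script, frames) {
  s <- script$image_size
  cy <- 0.5 * s + 0.25 * s * sin(2 * pi * frames / (script$fps * 12))
  cx <- 0.13 * s
  bw <- 0.10 * s; bh <- 0.26 * s
  tibble::tibble(frame = as.integer(frames), label = "person",
                 xmin = cx - bw / 2, ymin = cy - bh / 2,
                 xmax = cx + bw / 2, ymax = cy + bh / 2)
}

#' Ground-truth boxes of a scenario
#'
#' @param script A `scenario_script`.
#' @return Tibble `frame`, `label`, `xmin`, `ymin`, `xmax`, `ymax`,
#'   `behavior` (dog rows only; `NA` for person rows).
#' @export
scenario_truth <- function(script) {
  frames <- seq_len(script$n_frames) - 1L
  parts <- list()
  if (script$dog_present) {
    dg <- dog_path(script, frames)
    dg$behavior <- behavior_at_frame(script, frames)
    parts[[length(parts) + 1]] <- dg
  }
  if (!is.null(script$person_interval)) {
    pi_ <- script$person_interval
    pf <- frames[frames / script$fps >= pi_[1] & frames / script$fps < pi_[2]]
    if (length(pf) > 0) {
      pr <- person_path(script, pf)
      pr$behavior <- NA_character_
      parts[[length(parts) + 1]] <- pr
    }
  }
  if (length(parts) == 0) {
    return(tibble::tibble(frame = integer(), label = character(),
                          xmin = numeric(), ymin = numeric(),
                          xmax = numeric(), ymax = numeric(),
                          behavior = character()))
  }
  out <- dplyr::bind_rows(parts)
  out[order(out$frame, out$label), ]
}

#' Ground truth for a constant-velocity track
#'
#' A single object moving in a straight line at constant velocity with a
#' constant box size — the canonical input for testing that gap-limited
#' tubelet linking with linear interpolation reconstructs deleted
#' detections exactly.
#'
#' @param n_frames Number of frames.
#' @param start Numeric `c(x, y)` of the initial box center.
#' @param velocity Numeric `c(vx, vy)` in pixels per frame.
#' @param box_w,box_h Box size in pixels.
#' @param label Actor class.
#' @return Ground-truth tibble as in [scenario_truth()].
#' @export
constant_velocity_truth <- function(n_frames, start = c(200, 200),
                                    velocity = c(0.4, 0.25),
                                    box_w = 110, box_h = 80, label = "dog") {
  f <- seq_len(n_frames) - 1L
  cx <- start[1] + velocity[1] * f
  cy <- start[2] + velocity[2] * f
  tibble::tibble(frame = as.integer(f), label = label,
                 xmin = cx - box_w / 2, ymin = cy - box_h / 2,
                 xmax = cx + box_w / 2, ymax = cy + box_h / 2,
                 behavior = NA_character_)
}

#' Simulate a noisy detector on ground-truth boxes
#'
#' Each ground-truth box is independently dropped with probability
#' `miss_rate`; surviving boxes receive bounded uniform coordinate noise
#' (`jitter_px` half-width, clamped to the image) and a class-score
#' vector peaked on the true class (0.9 / 0.1 by default).
#'
#' @param truth Ground-truth tibble ([scenario_truth()]).
#' @param miss_rate Drop probability in \eqn{[0, 1]}.
#' @param jitter_px Half-width of the uniform coordinate noise.
#' @param seed Integer seed.
#' @param image_size Image side length, for clamping.
#' @param peak Score of the true class (the other class gets
#'   `1 - peak`).
#' @return Detection tibble (see [detection()]).
#' @export
simulate_detections <- function(truth, miss_rate = 0, jitter_px = 0,
                                seed = 1, image_size = 960, peak = 0.9) {
  set.seed(seed)
  keep <- stats::runif(nrow(truth)) >= miss_rate
  d <- truth[keep, c("frame", "label", "xmin", "ymin", "xmax", "ymax")]
  if (jitter_px > 0 && nrow(d) > 0) {
    for (col in c("xmin", "ymin", "xmax", "ymax")) {
      d[[col]] <- d[[col]] + stats::runif(nrow(d), -jitter_px, jitter_px)
    }
    d$xmin <- pmax(0, pmin(d$xmin, d$xmax - 1))
    d$ymin <- pmax(0, pmin(d$ymin, d$ymax - 1))
    d$xmax <- pmin(image_size, d$xmax)
    d$ymax <- pmin(image_size, d$ymax)
  }
  d$score_dog <- ifelse(d$label == "dog", peak, 1 - peak)
  d$score_person <- ifelse(d$label == "person", peak, 1 - peak)
  d <- d[, c("frame", "label", "score_dog", "score_person",
             "xmin", "ymin", "xmax", "ymax")]
  validate_detections(d)
  d
}

#' Drop interior detections with bounded gap lengths
#'
#' Deletes detections at the given rate while guaranteeing that every
#' run of consecutive deletions is shorter than `max_gap + 1` frames and
#' that the first and last frame of each contiguous presence interval
#' are never deleted — the regime in which gap-limited tubelet linking
#' can reconstruct every deleted box.
#'
#' @param truth Ground-truth tibble.
#' @param rate Target drop probability for eligible frames.
#' @param max_gap Longest permitted run of consecutive deletions
#'   (frames); keep it below the linking threshold `k`.
#' @param seed Integer seed.
#' @return List with `detections`-shaped `kept` truth rows and the
#'   integer `dropped` frame/label rows removed.
#' @export
inject_misses <- function(truth, rate = 0.2, max_gap = 14, seed = 1) {
  set.seed(seed)
  drop <- logical(nrow(truth))
  for (lab in unique(truth$label)) {
    idx <- which(truth$label == lab)
    idx <- idx[order(truth$frame[idx])]
    fr <- truth$frame[idx]
    run_break <- c(0L, which(diff(fr) > 1L), length(fr))
    for (r in seq_len(length(run_break) - 1)) {
      seg <- idx[(run_break[r] + 1L):run_break[r + 1L]]
      if (length(seg) <= 2) next
      interior <- seg[-c(1, length(seg))]
      consec <- 0L
      for (i in interior) {
        if (consec < max_gap && stats::runif(1) < rate) {
          drop[i] <- TRUE; consec <- consec + 1L
        } else consec <- 0L
      }
    }
  }
  list(kept = truth[!drop, ], dropped = truth[drop, ])
}

#' Render the frames of a scenario
#'
#' Draws each frame as a `[x, y, 3]` array in \eqn{[0, 1]}: a static
#' background pattern, the person as a dark textured block, and the dog
#' as a bright textured block whose texture moves with it. The dog's
#' blue channel carries a constant level encoding the scripted behavior
#' (`index / 13`), which is what [feature_backend_mock_rgb()] decodes;
#' a real appearance backend simply ignores it.
#'
#' @param script A `scenario_script`.
#' @param frames Integer frame indices to render (default: all — mind
#'   the memory; prefer rendering on demand for long sessions).
#' @return Named list of frame arrays (names are the frame indices).
#' @export
render_frames <- function(script, frames = seq_len(script$n_frames) - 1L) {
  truth <- scenario_truth(script)
  stats::setNames(lapply(frames, function(f) {
    render_one_frame(script, truth[truth$frame == f, ], f)
  }), frames)
}

#' @rdname render_frames
#' @param frame A single frame index.
#' @export
render_frame <- function(script, frame) {
  truth <- scenario_truth(script)
  render_one_frame(script, truth[truth$frame == frame, ], frame)
}

render_one_frame <- function(script, rows, frame) {
  s <- script$image_size
  xs <- matrix(seq_len(s), s, s)
  ys <- matrix(seq_len(s), s, s, byrow = TRUE)
  bg <- 0.35 + 0.08 * sin(2 * pi * xs / 97) * cos(2 * pi * ys / 71)
  img <- array(0, dim = c(s, s, 3))
  img[, , 1] <- bg; img[, , 2] <- bg
  for (r in seq_len(nrow(rows))) {
    x0 <- max(1L, floor(rows$xmin[r]) + 1L); x1 <- min(s, ceiling(rows$xmax[r]))
    y0 <- max(1L, floor(rows$ymin[r]) + 1L); y1 <- min(s, ceiling(rows$ymax[r]))
    if (x1 < x0 || y1 < y0) next
    rx <- matrix(x0:x1 - rows$xmin[r], x1 - x0 + 1, y1 - y0 + 1)
    ry <- matrix(y0:y1 - rows$ymin[r], x1 - x0 + 1, y1 - y0 + 1, byrow = TRUE)
    tex <- 0.5 + 0.45 * sin(2 * pi * rx / 7) * sin(2 * pi * ry / 5)
    if (rows$label[r] == "dog") {
      img[x0:x1, y0:y1, 1] <- 0.55 + 0.4 * tex
      img[x0:x1, y0:y1, 2] <- 0.3 * tex
      idx <- match(rows$behavior[r], behavior_labels())
      img[x0:x1, y0:y1, 3] <- if (is.na(idx)) 0 else encode_behavior_level(idx)
    } else {
      img[x0:x1, y0:y1, 1] <- 0.1 + 0.2 * tex
      img[x0:x1, y0:y1, 2] <- 0.1 + 0.2 * tex
      img[x0:x1, y0:y1, 3] <- 0
    }
  }
  img[img > 1] <- 1
  img[img < 0] <- 0
  img
}

#' Scripted per-unit feature patterns with ground-truth labels
#'
#' Emits, for each complete 8-frame unit of the session, the fused
#' feature matrix that the mock backends would produce (a one-hot label
#' signature per time step in the appearance block, zero motion
#' features) together with the unit's ground-truth label (majority of
#' the scripted labels over the 7 aligned time steps; ties resolved by
#' catalogue order).
#' By construction [classifier_backend_mock()] decodes these patterns to
#' the scripted labels exactly.
#'
#' @param script A `scenario_script` with a nonempty behavior script.
#' @param rgb_dim,flow_dim Feature block dimensions.
#' @return Tibble `start_frame`, `end_frame`, `truth_label`, and a
#'   `features` list-column of 7-row matrices.
#' @export
script_behavior_features <- function(script, rgb_dim = 16, flow_dim = 16) {
  n_units <- script$n_frames %/% 8L
  starts <- 8L * (seq_len(n_units) - 1L)
  n <- length(behavior_labels())
  rows <- purrr::map(starts, function(s) {
    fr <- s:(s + 7L)
    labs <- behavior_at_frame(script, fr)
    feats <- matrix(0, 7, rgb_dim + flow_dim)
    for (t in 1:7) {
      idx <- match(labs[t + 1], behavior_labels())  # first RGB frame dropped
      feats[t, idx] <- 1
    }
    tibble::tibble(start_frame = s, end_frame = s + 7L,
                   truth_label = majority_label(labs[2:8]),
                   features = list(feats))
  })
  if (length(rows) == 0) {
    return(tibble::tibble(start_frame = integer(), end_frame = integer(),
                          truth_label = character(), features = list()))
  }
  dplyr::bind_rows(rows)
}

majority_label <- function(labs) {
  # majority over the 7 aligned time steps; ties resolved by catalogue
  # order, matching the mock classifier's argmax
  counts <- table(factor(labs, levels = behavior_labels()))
  names(counts)[which.max(counts)]
}
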