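#' Merge per-unit behavior predictions into episodes
#'
#' Temporally adjacent recognition units (the next unit starts exactly
#' one frame after the previous ends) with identical labels are merged
#' into one episode with its temporal boundaries and duration. Any gap
#' in the unit sequence — frames where the dog was not alone — always
#' splits episodes; continuity is never fabricated across a gap.
#'
#' @param log Behavior-log tibble (`start_frame`, `end_frame`, `label`,
#'   ...), ordered by `start_frame`, units non-overlapping.
#' @param fps Frame rate, for durations in seconds.
#' @return Episode tibble: `label`, `start_frame`, `end_frame`
#'   (inclusive), `duration_s = (end - start + 1) / fps`.
#' @export
episodes_from_log <- function(log, fps = 21) {
  if (nrow(log) == 0) {
    return(tibble::tibble(label = character(), start_frame = integer(),
                          end_frame = integer(), duration_s = numeric()))
  }
  log <- log[order(log$start_frame), ]
  if (any(log$start_frame[-1] <= log$end_frame[-nrow(log)])) {
    stop("episodes_from_log: overlapping units", call. = FALSE)
  }
  new_ep <- c(TRUE, log$label[-1] != log$label[-nrow(log)] |
                log$start_frame[-1] != log$end_frame[-nrow(log)] + 1L)
  ep_id <- cumsum(new_ep)
  log |>
    dplyr::mutate(.ep = ep_id) |>
    dplyr::group_by(.data$.ep) |>
    dplyr::summarise(label = .data$label[1],
                     start_frame = min(.data$start_frame),
                     end_frame = max(.data$end_frame),
                     .groups = "drop") |>
    dplyr::mutate(duration_s = (.data$end_frame - .data$start_frame + 1) / fps) |>
    dplyr::select(-".ep") |>
    dplyr::select("label", "start_frame", "end_frame", "duration_s")
}

#' Default poor-welfare thresholds
#'
#' Behaviors that suggest poor welfare when displayed excessively, with
#' the occurrence measure and threshold beyond which each becomes
#' significant: barking (excessive vocalization when alone) more than 1
#' cumulative minute; wall bouncing more than 3 distinct episodes;
#' grooming (repeated self-licking) more than 5 cumulative minutes.
#'
#' @return Tibble `behavior`, `measure_kind`, `threshold`.
#' @export
welfare_thresholds <- function() {
  tibble::tibble(
    behavior = c("barking", "wall_bouncing", "grooming"),
    measure_kind = c("cumulative_minutes", "episode_count",
                     "cumulative_minutes"),
    threshold = c(1, 3, 5)
  )
}

#' Welfare-indicator state over a session window
#'
#' For each monitored behavior, computes its occurrence measure over the
#' supplied episodes — cumulative minutes for the duration-based
#' indicators, number of distinct episodes for the count-based one — and
#' flags the indicator when the value strictly exceeds its threshold.
#'
#' @param episodes Episode tibble from [episodes_from_log()]; restrict
#'   it to the session window of interest before calling.
#' @param thresholds Threshold table, see [welfare_thresholds()].
#' @return Tibble `behavior`, `measure_kind`, `value`, `threshold`,
#'   `flagged`.
#' @export
welfare_state <- function(episodes, thresholds = welfare_thresholds()) {
  values <- vapply(seq_len(nrow(thresholds)), function(i) {
    eps <- episodes[episodes$label == thresholds$behavior[i], ]
    if (thresholds$measure_kind[i] == "episode_count") nrow(eps)
    else sum(eps$duration_s) / 60
  }, numeric(1))
  dplyr::mutate(thresholds, value = values,
                flagged = values > .data$threshold) |>
    dplyr::select("behavior", "measure_kind", "value", "threshold", "flagged")
}

#' Threshold-crossing alert events
#'
#' Replays the episodes in temporal order, accumulating each indicator's
#' measure, and emits one alert per indicator at the moment its value
#' first exceeds the threshold (a false-to-true transition; no repeats,
#' since the cumulative measure never decreases within a session).
#'
#' @inheritParams welfare_state
#' @param fps Frame rate, to timestamp the alerts.
#' @return Tibble `behavior`, `frame`, `time_s`, `value` with one row
#'   per indicator that crossed its threshold.
#' @export
welfare_alerts <- function(episodes, thresholds = welfare_thresholds(),
                           fps = 21) {
  episodes <- episodes[order(episodes$start_frame), ]
  alerts <- list()
  for (i in seq_len(nrow(thresholds))) {
    beh <- thresholds$behavior[i]
    thr <- thresholds$threshold[i]
    count_based <- thresholds$measure_kind[i] == "episode_count"
    eps <- episodes[episodes$label == beh, ]
    if (nrow(eps) == 0) next
    if (count_based) {
      if (nrow(eps) > thr) {
        cross <- eps[ceiling(thr) + 1L, ]
        alerts[[length(alerts) + 1]] <- tibble::tibble(
          behavior = beh, frame = cross$start_frame,
          time_s = cross$start_frame / fps, value = ceiling(thr) + 1)
      }
    } else {
      cum <- cumsum(eps$duration_s) / 60
      idx <- which(cum > thr)
      if (length(idx) > 0) {
        j <- idx[1]
        # threshold reached partway through episode j: the first frame
        # after which the cumulative measure strictly exceeds thr
        before <- if (j > 1) cum[j - 1] else 0
        need <- (thr - before) * 60 * fps            # frames still needed
        fr <- eps$start_frame[j] + floor(need + 1e-9)
        alerts[[length(alerts) + 1]] <- tibble::tibble(
          behavior = beh, frame = as.integer(fr),
          time_s = fr / fps, value = thr)
      }
    }
  }
  if (length(alerts) == 0) {
    return(tibble::tibble(behavior = character(), frame = integer(),
                          time_s = numeric(), value = numeric()))
  }
  dplyr::bind_rows(alerts)
}

#' Occupancy heatmap from the location log
#'
#' Each location record contributes total weight 1, spread uniformly
#' over the grid cells its bounding box covers (partial cells weighted
#' by area fraction), so the grid sum equals the number of records and
#' dwell time — not box size — is the signal.
#'
#' @param locations Location-log tibble (`xmin`, `ymin`, `xmax`, `ymax`).
#' @param image_w,image_h Image dimensions in pixels.
#' @param grid_w,grid_h Grid resolution in cells.
#' @return A `grid_w` x `grid_h` matrix of occupancy weights with class
#'   `pw_heatmap` (cell `[i, j]` covers x in
#'   `[(i-1) * image_w / grid_w, i * image_w / grid_w)`, y likewise).
#' @export
occupancy_heatmap <- function(locations, image_w, image_h,
                              grid_w = 32, grid_h = 32) {
  grid <- matrix(0, grid_w, grid_h)
  cw <- image_w / grid_w; ch <- image_h / grid_h
  for (r in seq_len(nrow(locations))) {
    xo <- axis_overlap(locations$xmin[r], locations$xmax[r], cw, grid_w)
    yo <- axis_overlap(locations$ymin[r], locations$ymax[r], ch, grid_h)
    w <- outer(xo, yo)
    grid <- grid + w / sum(w)
  }
  structure(grid, class = c("pw_heatmap", "matrix", "array"),
            image_w = image_w, image_h = image_h)
}

axis_overlap <- function(lo, hi, cell, n) {
  edges_lo <- (seq_len(n) - 1) * cell
  edges_hi <- seq_len(n) * cell
  pmax(0, pmin(hi, edges_hi) - pmax(lo, edges_lo))
}

#' Movement trajectory from the location log
#'
#' The center of each logged bounding box, ordered in time, with the
#' first and last points marked as start and end and a color index in
#' \eqn{[0, 1]} assigned linearly in time for rendering the trajectory's
#' timeline.
#'
#' @param locations Location-log tibble with `timestamp_s` and box
#'   columns.
#' @return Tibble `timestamp_s`, `x`, `y`, `color_index`, `marker`
#'   (`"start"`, `"end"`, or `NA`), of class `pw_trajectory`.
#' @export
trajectory <- function(locations) {
  n <- nrow(locations)
  out <- tibble::tibble(
    timestamp_s = locations$timestamp_s,
    x = (locations$xmin + locations$xmax) / 2,
    y = (locations$ymin + locations$ymax) / 2,
    color_index = if (n > 1) (seq_len(n) - 1) / (n - 1) else rep(0, n),
    marker = rep(NA_character_, n)
  )
  if (n > 0) {
    out$marker[1] <- "start"
    out$marker[n] <- "end"   # a single record is both start and end
    if (n == 1) out$marker[1] <- "start"
  }
  out <- out[order(out$timestamp_s), ]
  class(out) <- c("pw_trajectory", class(out))
  out
}

#' Nested behavior proportions (time budget)
#'
#' Splits the total observed duration first into the active/static
#' categories (outer ring of the nested doughnut) and then into the
#' individual behaviors (inner ring). Both levels are fractions of the
#' same total, so each sums to 1 and the behaviors of a category sum to
#' that category's fraction.
#'
#' @param episodes Episode tibble with durations.
#' @return Tibble `level` (`"category"`/`"behavior"`), `name`,
#'   `category`, `fraction`, of class `pw_proportions`.
#' @export
proportions <- function(episodes) {
  total <- sum(episodes$duration_s)
  if (total <= 0) stop("proportions: zero total duration", call. = FALSE)
  cats <- behavior_categories()
  by_beh <- episodes |>
    dplyr::group_by(name = .data$label) |>
    dplyr::summarise(duration = sum(.data$duration_s), .groups = "drop") |>
    dplyr::mutate(category = unname(cats[.data$name]),
                  fraction = .data$duration / total, level = "behavior")
  by_cat <- by_beh |>
    dplyr::group_by(name = .data$category) |>
    dplyr::summarise(fraction = sum(.data$fraction), .groups = "drop") |>
    dplyr::mutate(category = .data$name, level = "category")
  out <- dplyr::bind_rows(by_cat, by_beh) |>
    dplyr::select("level", "name", "category", "fraction")
  class(out) <- c("pw_proportions", class(out))
  out
}

#' Behavior timeline plot data
#'
#' One lane per behavior, active behaviors in the upper lanes and static
#' ones grouped below them; each episode becomes a horizontal span in
#' minutes. The lane order follows the catalogue order within each
#' category.
#'
#' @param episodes Episode tibble.
#' @param fps Frame rate, to place spans on the time axis.
#' @return Tibble `label`, `category`, `lane` (1 = top), `start_min`,
#'   `end_min`, of class `pw_timeline`.
#' @export
timeline <- function(episodes, fps = 21) {
  cats <- behavior_categories()
  labels <- behavior_labels()
  lane_order <- c(labels[cats[labels] == "active"],
                  labels[cats[labels] == "static"])
  out <- tibble::tibble(
    label = episodes$label,
    category = unname(cats[episodes$label]),
    lane = match(episodes$label, lane_order),
    start_min = episodes$start_frame / fps / 60,
    end_min = (episodes$end_frame + 1) / fps / 60
  )
  out <- out[order(out$start_min), ]
  attr(out, "lanes") <- tibble::tibble(
    label = lane_order, lane = seq_along(lane_order),
    category = unname(cats[lane_order]))
  class(out) <- c("pw_timeline", class(out))
  out
}

#' Behavior and movement summary of a session
#'
#' Bundles the summarization stage: episodes, welfare indicators and
#' alerts, occupancy heatmap, trajectory, nested proportions and
#' timeline, from a behavior log and location log.
#'
#' @param log Behavior-log tibble.
#' @param locations Location-log tibble.
#' @param config Pipeline configuration, see [default_config()].
#' @return List of class `pw_summary` with components `episodes`,
#'   `welfare`, `alerts`, `heatmap`, `trajectory`, `proportions`
#'   (`NULL` when no behavior was observed), `timeline`.
#' @export
summarize_session <- function(log, locations, config = default_config()) {
  eps <- episodes_from_log(log, fps = config$fps)
  thr <- config$welfare_thresholds
  structure(list(
    episodes = eps,
    welfare = welfare_state(eps, thr),
    alerts = welfare_alerts(eps, thr, fps = config$fps),
    heatmap = occupancy_heatmap(locations, config$image_size,
                                config$image_size,
                                config$heatmap_grid, config$heatmap_grid),
    trajectory = trajectory(locations),
    proportions = if (nrow(eps) > 0) proportions(eps) else NULL,
    timeline = timeline(eps, fps = config$fps)
  ), class = "pw_summary")
}
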