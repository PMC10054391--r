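#' Estimate optical flow across a recognition unit
#'
#' Applies the flow backend to every pair of consecutive frames of an
#' 8-frame unit, producing 7 motion fields: flow `i` describes the
#' motion from frame `i` to frame `i + 1`.
#'
#' @param unit List of 8 same-size frame arrays (`[x, y, channel]`).
#' @param backend Flow backend, e.g. [flow_backend_blockmatch()].
#' @return List of 7 flow arrays (`[x, y, 2]`).
#' @export
estimate_flow <- function(unit, backend) {
  stopifnot(length(unit) >= 2)
  d0 <- dim(unit[[1]])
  if (!all(vapply(unit, function(f) identical(dim(f)[1:2], d0[1:2]), logical(1)))) {
    stop("estimate_flow: frames differ in size", call. = FALSE)
  }
  lapply(seq_len(length(unit) - 1), function(i) {
    tryCatch(backend$fn(unit[[i]], unit[[i + 1]]),
             error = function(e) stop("flow backend failed on pair ", i, ": ",
                                      conditionMessage(e), call. = FALSE))
  })
}

#' Align the RGB and flow streams
#'
#' A unit of 8 RGB frames yields only 7 flow fields, so the first RGB
#' frame is dropped: after alignment `rgb[[i]]` is the frame that flow
#' `i` ends on, and both streams have 7 time steps of consistent length
#' for the sequence classifier.
#'
#' @param rgb List of 8 frame arrays.
#' @param flow List of 7 flow arrays.
#' @return List with `rgb` and `flow`, both length 7.
#' @export
align_streams <- function(rgb, flow) {
  if (length(rgb) != length(flow) + 1) {
    stop("align_streams: need one more RGB frame than flow fields (got ",
         length(rgb), " and ", length(flow), ")", call. = FALSE)
  }
  list(rgb = rgb[-1], flow = flow)
}

#' Extract per-stream features and fuse them
#'
#' For each of the 7 aligned time steps the appearance feature of the
#' RGB frame and the motion feature of the flow field are computed and
#' concatenated in that fixed order (appearance block first), giving one
#' fused vector per step of dimension `rgb_backend$dim + flow_backend$dim`.
#'
#' @param rgb7,flow7 Aligned streams from [align_streams()].
#' @param rgb_backend,flow_backend Feature backends declaring their
#'   output dimension, e.g. [feature_backend_pool()],
#'   [feature_backend_flow_stats()].
#' @return Matrix of 7 rows (time steps) by fused dimension.
#' @export
extract_and_fuse <- function(rgb7, flow7, rgb_backend, flow_backend) {
  stopifnot(length(rgb7) == length(flow7))
  out <- matrix(NA_real_, length(rgb7), rgb_backend$dim + flow_backend$dim)
  for (t in seq_along(rgb7)) {
    fr <- rgb_backend$fn(rgb7[[t]])
    fl <- flow_backend$fn(flow7[[t]])
    if (length(fr) != rgb_backend$dim || length(fl) != flow_backend$dim) {
      stop("feature backend dimension mismatch at time step ", t, call. = FALSE)
    }
    out[t, ] <- c(fr, fl)
  }
  out
}

#' Classify a fused feature sequence
#'
#' Runs the sequence-classifier backend on the 7 fused vectors and
#' validates its output: 12 probabilities on the simplex (sum 1 within
#' 1e-6), the label being the argmax.
#'
#' @param features 7 x d fused feature matrix.
#' @param backend Classifier backend, e.g. [classifier_backend_mock()]
#'   or [classifier_backend_bilstm()].
#' @return List with `label` (character) and `probabilities` (named
#'   numeric vector over [behavior_labels()]).
#' @export
classify_unit <- function(features, backend) {
  p <- backend$fn(features)
  labels <- behavior_labels()
  if (length(p) != length(labels)) {
    stop("classifier backend returned ", length(p), " probabilities; expected ",
         length(labels), call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-6 || any(p < 0)) {
    stop("classifier backend output is not a probability vector", call. = FALSE)
  }
  names(p) <- labels
  list(label = labels[which.max(p)], probabilities = p)
}

#' Recognize the behavior of one 8-frame unit
#'
#' The full two-stream orchestration: [estimate_flow()] over the cropped
#' frames, [align_streams()] (first RGB frame dropped),
#' [extract_and_fuse()] per time step, [classify_unit()]. Deterministic
#' given fixed backends and inputs.
#'
#' @param unit List of 8 cropped frame arrays.
#' @param start_frame First frame index of the unit in the stream.
#' @param backends Backend set, see [mock_backends()].
#' @return One-row behavior-log tibble: `start_frame`, `end_frame`,
#'   `label`, and the 12 probability columns `p_barking` ... `p_idle`.
#' @export
recognize <- function(unit, start_frame, backends) {
  stopifnot(length(unit) == 8)
  flow <- estimate_flow(unit, backends$flow)
  al <- align_streams(unit, flow)
  feats <- extract_and_fuse(al$rgb, al$flow,
                            backends$rgb_features, backends$flow_features)
  pred <- classify_unit(feats, backends$classifier)
  row <- tibble::tibble(start_frame = as.integer(start_frame),
                        end_frame = as.integer(start_frame + length(unit) - 1L),
                        label = pred$label)
  probs <- tibble::as_tibble(as.list(stats::setNames(pred$probabilities,
                                                     prob_cols())))
  dplyr::bind_cols(row, probs)
}

empty_behavior_log <- function() {
  probs <- stats::setNames(rep(list(numeric()), length(prob_cols())),
                           prob_cols())
  dplyr::bind_cols(
    tibble::tibble(start_frame = integer(), end_frame = integer(),
                   label = character()),
    tibble::as_tibble(probs)
  )
}
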