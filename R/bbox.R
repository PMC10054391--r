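#' Axis-aligned bounding boxes and detection tables
#'
#' Throughout the package a bounding box is four pixel coordinates
#' `xmin, ymin, xmax, ymax` (continuous, origin top-left), and a
#' *detection table* is a tibble with one row per detected object and
#' columns `frame`, `label` (`"dog"` or `"person"`), `score_dog`,
#' `score_person`, `xmin`, `ymin`, `xmax`, `ymax`. All geometry
#' functions are vectorised over rows.
#'
#' @param xmin,ymin,xmax,ymax Box coordinates in pixels.
#' @return `bbox()` returns a one-row tibble with the four coordinate
#'   columns, validated.
#' @examples
#' bbox(0, 0, 10, 10)
#' @export
bbox <- function(xmin, ymin, xmax, ymax) {
  b <- tibble::tibble(xmin = as.numeric(xmin), ymin = as.numeric(ymin),
                      xmax = as.numeric(xmax), ymax = as.numeric(ymax))
  validate_bbox(b)
  b
}

validate_bbox <- function(b) {
  stopifnot(all(c("xmin", "ymin", "xmax", "ymax") %in% names(b)))
  if (any(b$xmin >= b$xmax) || any(b$ymin >= b$ymax)) {
    stop("invalid geometry: degenerate bounding box (xmin >= xmax or ymin >= ymax)",
         call. = FALSE)
  }
  if (any(b$xmin < 0) || any(b$ymin < 0)) {
    stop("invalid geometry: negative bounding box coordinates", call. = FALSE)
  }
  invisible(b)
}

#' Intersection over union of two bounding boxes
#'
#' The overlap area of two axis-aligned boxes divided by the area of
#' their union; 1 for identical boxes, 0 for disjoint ones. Vectorised:
#' `a` and `b` may be multi-row tibbles of equal length.
#'
#' @param a,b Tibbles (or one-row data frames) with columns
#'   `xmin`, `ymin`, `xmax`, `ymax`.
#' @return Numeric vector of IoU ratios in \eqn{[0, 1]}.
#' @examples
#' iou(bbox(0, 0, 2, 2), bbox(1, 1, 3, 3))  # 1/7
#' @export
iou <- function(a, b) {
  validate_bbox(a); validate_bbox(b)
  iw <- pmax(0, pmin(a$xmax, b$xmax) - pmax(a$xmin, b$xmin))
  ih <- pmax(0, pmin(a$ymax, b$ymax) - pmax(a$ymin, b$ymin))
  inter <- iw * ih
  union <- (a$xmax - a$xmin) * (a$ymax - a$ymin) +
    (b$xmax - b$xmin) * (b$ymax - b$ymin) - inter
  inter / union
}

#' Distance score between two detections
#'
#' The matching distance used for tubelet construction:
#' `1 / (IoU * dot(scores_a, scores_b))`, the reciprocal of a similarity
#' that combines geometric proximity (IoU of the two boxes) with
#' semantic agreement (dot product of the two class-score vectors).
#' When either factor is zero the detections can never correspond to the
#' same object and `Inf` is returned.
#'
#' @param a,b One-row detection tibbles (columns `score_dog`,
#'   `score_person` plus box coordinates). Vectorised over rows.
#' @return Nonnegative numeric distance, `Inf` for impossible pairs.
#' @export
pair_distance <- function(a, b) {
  ov <- iou(a, b)
  dt <- score_dot(a, b)
  d <- ifelse(ov <= 0 | dt <= 0, Inf, 1 / (ov * dt))
  as.numeric(d)
}

score_dot <- function(a, b) {
  a$score_dog * b$score_dog + a$score_person * b$score_person
}

#' @rdname bbox
#' @param frame Frame index (0-based).
#' @param label Class label, `"dog"` or `"person"`.
#' @param score_dog,score_person Per-class confidences in \eqn{[0, 1]};
#'   `label` must equal the argmax of the score vector.
#' @return `detection()` returns a one-row detection tibble.
#' @export
detection <- function(frame, label, score_dog, score_person,
                      xmin, ymin, xmax, ymax) {
  d <- tibble::tibble(frame = as.integer(frame), label = label,
                      score_dog = score_dog, score_person = score_person,
                      xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax)
  validate_detections(d)
  d
}

validate_detections <- function(d) {
  needed <- c("frame", "label", "score_dog", "score_person",
              "xmin", "ymin", "xmax", "ymax")
  missing <- setdiff(needed, names(d))
  if (length(missing)) {
    stop("detection table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(d) == 0) return(invisible(d))
  validate_bbox(d)
  if (!all(d$label %in% c("dog", "person"))) {
    stop("detection labels must be 'dog' or 'person'", call. = FALSE)
  }
  argmax <- ifelse(d$score_dog >= d$score_person, "dog", "person")
  if (!all(d$label == argmax)) {
    stop("detection label must equal the argmax of its score vector",
         call. = FALSE)
  }
  invisible(d)
}

empty_detections <- function() {
  tibble::tibble(frame = integer(), label = character(),
                 score_dog = numeric(), score_person = numeric(),
                 xmin = numeric(), ymin = numeric(),
                 xmax = numeric(), ymax = numeric())
}
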