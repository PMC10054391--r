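#' Unified bounding box of a recognition unit
#'
#' The smallest axis-aligned box containing every member box: the
#' coordinate-wise minimum of `xmin`/`ymin` and maximum of
#' `xmax`/`ymax` over all rows. Using one box for all frames of a unit
#' keeps the dog's proportions identical across the unit, which
#' per-frame tight cropping would destroy.
#'
#' @param bboxes Tibble of member boxes (one row per frame of the unit).
#' @return One-row box tibble.
#' @export
unify <- function(bboxes) {
  if (nrow(bboxes) == 0) stop("unify: no boxes to unify", call. = FALSE)
  validate_bbox(bboxes)
  tibble::tibble(xmin = min(bboxes$xmin), ymin = min(bboxes$ymin),
                 xmax = max(bboxes$xmax), ymax = max(bboxes$ymax))
}

pad_axis <- function(lo, hi, target, limit) {
  size <- hi - lo
  if (target > limit) return(c(0, limit))       # target exceeds image: full span
  if (size >= target) return(c(lo, hi))         # larger than target: pass through
  total <- target - size
  pad_lo <- floor(total / 2)                    # odd pixel goes to the far side
  pad_hi <- total - pad_lo
  lo2 <- lo - pad_lo; hi2 <- hi + pad_hi
  if (lo2 < 0) { hi2 <- hi2 - lo2; lo2 <- 0 }   # overflow moved to the far side
  if (hi2 > limit) { lo2 <- lo2 - (hi2 - limit); hi2 <- limit }
  c(max(0, lo2), min(limit, hi2))
}

#' Pad a box to a fixed target size within the image
#'
#' Expands `box` to `target_w` by `target_h` pixels by adding padding
#' equally on both sides of each axis; when the padding would cross an
#' image edge the excess is shifted to the opposite side, so the output
#' reaches the target size whenever the image can accommodate it. A box
#' already exceeding the target in one dimension passes that dimension
#' through unchanged; a target larger than the image yields the full
#' image span in that dimension. The output always contains the input
#' box (when it fits the target) and always lies within the image.
#'
#' @param box One-row box tibble.
#' @param target_w,target_h Target width and height in pixels (defaults
#'   300 and 650, sized to cover the largest unified box expected for a
#'   small dog under a ceiling camera).
#' @param image_w,image_h Image dimensions in pixels.
#' @return One-row box tibble of the padded crop window.
#' @export
pad <- function(box, target_w = 300, target_h = 650,
                image_w, image_h) {
  validate_bbox(box)
  x <- pad_axis(box$xmin, box$xmax, target_w, image_w)
  y <- pad_axis(box$ymin, box$ymax, target_h, image_h)
  tibble::tibble(xmin = x[1], ymin = y[1], xmax = x[2], ymax = y[2])
}

#' Crop all frames of a unit with one window and resize
#'
#' Applies the identical crop window to all frames of a unit and
#' resizes each crop to `out_size` by `out_size` pixels with bilinear
#' interpolation (no antialiasing), preserving order. Frames are arrays
#' in the `[x, y, channel]` convention with values in \eqn{[0, 1]}.
#'
#' @param frames List of frame arrays, all the same size.
#' @param box One-row box tibble, the unified padded crop window; must
#'   lie within every frame.
#' @param out_size Output side length in pixels (default 224, the input
#'   size of the appearance feature extractor).
#' @return List of cropped, resized frame arrays.
#' @export
crop_unit <- function(frames, box, out_size = 224) {
  validate_bbox(box)
  lapply(frames, function(fr) {
    d <- dim(fr)
    if (box$xmax > d[1] || box$ymax > d[2] || box$xmin < 0 || box$ymin < 0) {
      stop("crop_unit: crop window exceeds frame bounds", call. = FALSE)
    }
    xs <- (floor(box$xmin) + 1L):ceiling(box$xmax)
    ys <- (floor(box$ymin) + 1L):ceiling(box$ymax)
    crop <- if (length(d) == 3) fr[xs, ys, , drop = FALSE] else
      array(fr[xs, ys], dim = c(length(xs), length(ys), 1L))
    out <- EBImage::resize(EBImage::Image(crop, colormode = "Color"),
                           w = out_size, h = out_size,
                           filter = "bilinear", antialias = FALSE)
    a <- as.array(out)
    dim(a) <- c(out_size, out_size, dim(crop)[3])
    a
  })
}

#' Crop window for a unit of dog boxes
#'
#' Convenience composition: [unify()] the unit's boxes then [pad()] the
#' result to the configured target size.
#'
#' @param bboxes Member boxes of the unit.
#' @param config Pipeline configuration, see [default_config()].
#' @param image_w,image_h Image dimensions in pixels.
#' @return One-row box tibble.
#' @export
unit_crop_window <- function(bboxes, config = default_config(),
                             image_w = config$image_size,
                             image_h = config$image_size) {
  pad(unify(bboxes), target_w = config$crop_target_w,
      target_h = config$crop_target_h,
      image_w = image_w, image_h = image_h)
}
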