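#' Read and write pipeline tables
#'
#' Plain-CSV and JSON readers/writers for the pipeline's interchange
#' formats: detection streams
#' (`frame,label,score_dog,score_person,xmin,ymin,xmax,ymax`), location
#' logs (`frame,timestamp_s,xmin,ymin,xmax,ymax`), behavior logs
#' (`start_frame,end_frame,label,p_barking,...,p_idle`), episode tables
#' (`label,start_frame,end_frame,duration_s`), and tubelet JSON. All
#' round-trip losslessly through their counterparts.
#'
#' @param path File path.
#' @param x Table to write.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_detections <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$frame <- as.integer(d$frame)
  d <- tibble::as_tibble(d)
  validate_detections(d)
  d
}

#' @rdname pipeline_io
#' @export
write_detections <- function(x, path) {
  validate_detections(x)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_locations <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$frame <- as.integer(d$frame)
  tibble::as_tibble(d)
}

#' @rdname pipeline_io
#' @export
write_locations <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_behavior_log <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$start_frame <- as.integer(d$start_frame)
  d$end_frame <- as.integer(d$end_frame)
  tibble::as_tibble(d)
}

#' @rdname pipeline_io
#' @export
write_behavior_log <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_episodes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$start_frame <- as.integer(d$start_frame)
  d$end_frame <- as.integer(d$end_frame)
  tibble::as_tibble(d)
}

#' @rdname pipeline_io
#' @export
write_episodes <- function(x, path) {
  utils::write.csv(x[, c("label", "start_frame", "end_frame", "duration_s")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
write_tubelets_json <- function(x, path) {
  tubs <- lapply(split(x, x$tubelet_id), function(tb) {
    list(label = tb$label[1],
         entries = lapply(seq_len(nrow(tb)), function(i) list(
           frame = tb$frame[i],
           bbox = c(tb$xmin[i], tb$ymin[i], tb$xmax[i], tb$ymax[i]),
           scores = c(tb$score_dog[i], tb$score_person[i]),
           provenance = tb$provenance[i])))
  })
  jsonlite::write_json(unname(tubs), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_tubelets_json <- function(path) {
  raw <- jsonlite::read_json(path)
  rows <- purrr::imap(raw, function(tb, id) {
    purrr::map(tb$entries, function(e) tibble::tibble(
      frame = as.integer(e$frame), label = tb$label,
      score_dog = e$scores[[1]], score_person = e$scores[[2]],
      xmin = e$bbox[[1]], ymin = e$bbox[[2]],
      xmax = e$bbox[[3]], ymax = e$bbox[[4]],
      tubelet_id = as.integer(id), provenance = e$provenance)) |>
      dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) empty_tubelets() else out
}

#' Ingest image frames from a directory
#'
#' Reads the image files of a directory in natural sort order (numeric
#' runs compared as numbers, so `f2.png` precedes `f10.png`), assigns
#' 0-based frame indices, and optionally resizes every frame to a square
#' detector input size.
#'
#' @param source Directory containing PNG/JPEG/TIFF frames.
#' @param resize_to Optional square side length in pixels.
#' @return Named list of `[x, y, channel]` arrays; names are the frame
#'   indices as characters, in order.
#' @export
ingest_frames <- function(source, resize_to = NULL) {
  if (!dir.exists(source)) stop("cannot read frames: no directory at ",
                                source, call. = FALSE)
  files <- list.files(source, pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0) stop("no image files in ", source, call. = FALSE)
  files <- files[natural_order(basename(files))]
  frames <- lapply(files, function(f) {
    img <- EBImage::readImage(f)
    if (!is.null(resize_to)) {
      img <- EBImage::resize(img, w = resize_to, h = resize_to,
                             filter = "bilinear", antialias = FALSE)
    }
    a <- as.array(img)
    if (length(dim(a)) == 2) dim(a) <- c(dim(a), 1L)
    a
  })
  stats::setNames(frames, seq_along(frames) - 1L)
}

natural_order <- function(x) {
  padded <- gsub("([0-9]+)", "~\\1", x)
  parts <- lapply(strsplit(padded, "~"), function(p) {
    nums <- suppressWarnings(as.numeric(sub("^([0-9]+).*", "\\1", p)))
    paste0(ifelse(is.na(nums), p,
                  paste0(formatC(nums, width = 12, flag = "0"),
                         sub("^[0-9]+", "", p))), collapse = "")
  })
  order(unlist(parts), x)
}

#' Write a frame array as PNG
#'
#' @param frame `[x, y, channel]` array in \eqn{[0, 1]}.
#' @param path Output path.
#' @export
write_frame_png <- function(frame, path) {
  # png::writePNG expects [row = y, col = x, channel]
  png::writePNG(aperm(frame, c(2, 1, 3)), path)
  invisible(path)
}
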