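#' Match detections between two consecutive frames
#'
#' Exact one-to-one matching of the detections of frame *t* against
#' those of frame *t+1* under the [pair_distance()] score: among all
#' one-to-one matchings it maximizes the number of matched pairs and,
#' among those, minimizes the total distance. Candidate pairs with
#' infinite distance (disjoint boxes or orthogonal score vectors) or
#' distance above `max_distance` are never matched. When several
#' optimal matchings exist, the one whose pair list is
#' lexicographically smallest is returned (lower index in frame *t*
#' first, then lower index in frame *t+1*). Frames with more than 16
#' detections on the *t+1* side fall back to a greedy
#' ascending-distance approximation; detection counts in room
#' monitoring never approach that.
#'
#' @param dets_t,dets_t1 Detection tibbles for frames *t* and *t+1*
#'   (see [detection()]).
#' @param max_distance Largest acceptable distance score; the default
#'   100 corresponds to requiring `IoU * dot >= 0.01`.
#' @return A tibble of matched pairs with columns `idx_t`, `idx_t1`
#'   (1-based row indices into the two inputs) and `distance`.
#'   Attributes `unmatched_t` and `unmatched_t1` carry the indices left
#'   unmatched on either side.
#' @export
match_consecutive <- function(dets_t, dets_t1, max_distance = 100) {
  n_t <- nrow(dets_t); n_t1 <- nrow(dets_t1)
  empty <- tibble::tibble(idx_t = integer(), idx_t1 = integer(),
                          distance = numeric())
  if (n_t == 0 || n_t1 == 0) {
    attr(empty, "unmatched_t") <- seq_len(n_t)
    attr(empty, "unmatched_t1") <- seq_len(n_t1)
    return(empty)
  }
  sub <- function(d, i) {
    list(xmin = d$xmin[i], ymin = d$ymin[i], xmax = d$xmax[i],
         ymax = d$ymax[i], score_dog = d$score_dog[i],
         score_person = d$score_person[i])
  }
  idx_a <- rep(seq_len(n_t), times = n_t1)
  idx_b <- rep(seq_len(n_t1), each = n_t)
  d <- pair_distance(sub(dets_t, idx_a), sub(dets_t1, idx_b))
  dmat <- matrix(d, n_t, n_t1)
  dmat[!is.finite(dmat) | dmat > max_distance] <- Inf
  assign <- if (n_t1 <= 16L) assign_exact(dmat) else assign_greedy(dmat)
  idx_t <- which(!is.na(assign))
  pairs <- tibble::new_tibble(
    list(idx_t = idx_t, idx_t1 = assign[idx_t],
         distance = dmat[cbind(idx_t, assign[idx_t])]),
    nrow = length(idx_t))
  attr(pairs, "unmatched_t") <- which(is.na(assign))
  attr(pairs, "unmatched_t1") <- setdiff(seq_len(n_t1), pairs$idx_t1)
  pairs
}

# Exact maximum-cardinality, minimum-total-distance assignment by
# dynamic programming over subsets of frame-t+1 detections. Matched
# pairs contribute `big - distance` so cardinality dominates cost; the
# reconstruction walks rows in order preferring the smallest feasible
# column, which yields the lexicographically smallest optimal pair
# list. Returns an integer vector over frame-t rows (NA = unmatched).
assign_exact <- function(dmat) {
  n1 <- nrow(dmat); n2 <- ncol(dmat)
  big <- sum(dmat[is.finite(dmat)]) + 1
  nmask <- bitwShiftL(1L, n2)
  masks <- 0:(nmask - 1L)
  H <- vector("list", n1 + 1L)
  H[[n1 + 1L]] <- numeric(nmask)
  for (r in n1:1) {
    h <- H[[r + 1L]]
    best <- h  # leaving row r unmatched
    for (cc in which(is.finite(dmat[r, ]))) {
      bit <- bitwShiftL(1L, cc - 1L)
      free <- which(bitwAnd(masks, bit) == 0L)
      cand <- big - dmat[r, cc] + h[free + bit]
      upd <- cand > best[free]
      best[free][upd] <- cand[upd]
    }
    H[[r]] <- best
  }
  tol <- 1e-9 * big
  assign <- rep(NA_integer_, n1)
  m <- 0L
  for (r in seq_len(n1)) {
    target <- H[[r]][m + 1L]
    nxt <- H[[r + 1L]]
    for (cc in which(is.finite(dmat[r, ]))) {
      bit <- bitwShiftL(1L, cc - 1L)
      if (bitwAnd(m, bit) == 0L &&
          abs(big - dmat[r, cc] + nxt[m + bit + 1L] - target) <= tol) {
        assign[r] <- cc
        m <- bitwOr(m, bit)
        break
      }
    }
  }
  assign
}

# Greedy ascending-distance approximation for implausibly crowded
# frames; same tie-break order as the exact solver.
assign_greedy <- function(dmat) {
  n1 <- nrow(dmat)
  fin <- which(is.finite(dmat))
  rows <- ((fin - 1L) %% n1) + 1L
  cols <- ((fin - 1L) %/% n1) + 1L
  ord <- order(dmat[fin], rows, cols)
  assign <- rep(NA_integer_, n1)
  used_col <- logical(ncol(dmat))
  for (i in ord) {
    r <- rows[i]; cc <- cols[i]
    if (is.na(assign[r]) && !used_col[cc]) {
      assign[r] <- cc
      used_col[cc] <- TRUE
    }
  }
  assign
}

#' Build tubelets from per-frame detections
#'
#' Chains consecutive-frame matches ([match_consecutive()]) transitively
#' into tubelets: ordered per-object sequences of (frame, box, scores).
#' Every input detection ends up in exactly one tubelet; a detection
#' matched on neither side forms a singleton tubelet. Matching only
#' happens between frames `f` and `f + 1`; any gap in the frame index
#' splits tubelets (bridge them afterwards with [link_tubelets()]).
#'
#' @param detections Detection tibble over any number of frames.
#' @param max_distance Passed to [match_consecutive()].
#' @return A tubelet tibble: the detection columns plus `tubelet_id`
#'   (integer, numbered by first frame of appearance) and `provenance`
#'   (`"detected"` here; [link_tubelets()] adds `"interpolated"` rows).
#'   The `label` column holds the tubelet's label (that of its first
#'   entry).
#' @export
build_tubelets <- function(detections, max_distance = 100) {
  validate_detections(detections)
  if (nrow(detections) == 0) return(empty_tubelets())
  detections <- detections[order(detections$frame), ]
  rid <- seq_len(nrow(detections))
  parent <- rid
  find <- function(x) { while (parent[x] != x) x <- parent[x] <<- parent[parent[x]]; x }
  frames <- sort(unique(detections$frame))
  by_frame <- split(rid, factor(detections$frame, levels = frames))
  for (i in seq_along(frames)[-1]) {
    if (frames[i] != frames[i - 1] + 1L) next
    ia <- by_frame[[i - 1]]; ib <- by_frame[[i]]
    pairs <- match_consecutive(detections[ia, ], detections[ib, ],
                               max_distance = max_distance)
    for (p in seq_len(nrow(pairs))) {
      ra <- find(ia[pairs$idx_t[p]]); rb <- find(ib[pairs$idx_t1[p]])
      if (ra != rb) parent[rb] <- ra
    }
  }
  comp <- vapply(rid, find, integer(1))
  out <- detections
  out$tubelet_id <- match(comp, unique(comp))
  out$provenance <- "detected"
  out <- out |>
    dplyr::group_by(.data$tubelet_id) |>
    dplyr::mutate(label = .data$label[1]) |>
    dplyr::ungroup()
  renumber_tubelets(out)
}

empty_tubelets <- function() {
  dplyr::mutate(empty_detections(), tubelet_id = integer(),
                provenance = character())
}

renumber_tubelets <- function(tb) {
  if (nrow(tb) == 0) return(tb)
  starts <- tb |>
    dplyr::group_by(.data$tubelet_id) |>
    dplyr::summarise(start = min(.data$frame), .groups = "drop")
  order_ids <- starts$tubelet_id[order(starts$start, starts$tubelet_id)]
  tb$tubelet_id <- match(tb$tubelet_id, order_ids)
  tb[order(tb$tubelet_id, tb$frame), ]
}

#' Interpolate the missing boxes between two tubelet anchor entries
#'
#' Fills the frames strictly between `end_entry` and `start_entry` with
#' boxes obtained by independent linear interpolation of each of the
#' four box coordinates over the frame index. Interpolated entries are
#' marked `provenance = "interpolated"`; their score vector is copied
#' from the nearer anchor (ties go to the earlier one).
#'
#' @param end_entry,start_entry One-row tubelet tibbles: the last entry
#'   of the earlier tubelet and the first entry of the later one.
#'   `start_entry$frame` must exceed `end_entry$frame + 1`.
#' @return A tubelet tibble with one row per intermediate frame.
#' @export
interpolate_gap <- function(end_entry, start_entry) {
  f0 <- end_entry$frame; f1 <- start_entry$frame
  if (f1 <= f0 + 1L) {
    stop("interpolate_gap: no gap between frames ", f0, " and ", f1,
         call. = FALSE)
  }
  frames <- seq.int(f0 + 1L, f1 - 1L)
  t <- (frames - f0) / (f1 - f0)
  lerp <- function(col) (1 - t) * end_entry[[col]] + t * start_entry[[col]]
  near_start <- (frames - f0) > (f1 - frames)  # tie -> earlier anchor
  tibble::tibble(
    frame = as.integer(frames),
    label = end_entry$label,
    score_dog = ifelse(near_start, start_entry$score_dog, end_entry$score_dog),
    score_person = ifelse(near_start, start_entry$score_person,
                          end_entry$score_person),
    xmin = lerp("xmin"), ymin = lerp("ymin"),
    xmax = lerp("xmax"), ymax = lerp("ymax"),
    tubelet_id = end_entry$tubelet_id,
    provenance = "interpolated"
  )
}

#' Link tubelets across short temporal gaps
#'
#' Bridges missed detections: a tubelet ending at frame *e* may be
#' linked to a same-label tubelet starting at frame *s* > *e* when the
#' number of frames between them (*s* - *e* - 1) is strictly less than
#' `k` and the [pair_distance()] between the first tubelet's last entry
#' and the second's first entry is finite. Qualifying pairs are merged
#' greedily by ascending distance (each tubelet end and each start used
#' at most once, so chains of several fragments merge into one), and
#' the gap frames are filled with [interpolate_gap()]. Detected entries
#' are never modified; different labels are never linked.
#'
#' @param tubelets Tubelet tibble from [build_tubelets()] covering one
#'   analysis window (or two adjacent windows for cross-window linking).
#' @param k Gap threshold in frames (default 15): gaps of `k` or more
#'   frames are never bridged.
#' @return Tubelet tibble with merged ids (renumbered by start frame)
#'   and interpolated rows inserted; frame indices within each tubelet
#'   are contiguous.
#' @export
link_tubelets <- function(tubelets, k = 15) {
  if (nrow(tubelets) == 0) return(tubelets)
  stopifnot(k >= 1)
  info <- tubelets |>
    dplyr::group_by(.data$tubelet_id) |>
    dplyr::summarise(label = .data$label[1],
                     start = min(.data$frame), end = max(.data$frame),
                     .groups = "drop")
  rows_first <- tubelets[match(info$tubelet_id, tubelets$tubelet_id), ]
  last_idx <- vapply(info$tubelet_id, function(id) {
    idx <- which(tubelets$tubelet_id == id)
    idx[which.max(tubelets$frame[idx])]
  }, integer(1))
  rows_last <- tubelets[last_idx, ]

  n <- nrow(info)
  cand <- expand.grid(i = seq_len(n), j = seq_len(n))
  gap <- info$start[cand$j] - info$end[cand$i] - 1L
  ok <- info$label[cand$i] == info$label[cand$j] &
    info$start[cand$j] > info$end[cand$i] & gap < k
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) > 0) {
    cand$distance <- pair_distance(rows_last[cand$i, ], rows_first[cand$j, ])
    cand <- cand[is.finite(cand$distance), , drop = FALSE]
    cand <- cand[order(cand$distance, cand$i, cand$j), , drop = FALSE]
  }
  succ <- rep(NA_integer_, n)
  used_start <- logical(n)
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (is.na(succ[i]) && !used_start[j]) {
      succ[i] <- j; used_start[j] <- TRUE
    }
  }
  heads <- which(!used_start)
  pieces <- list()
  for (h in heads) {
    chain <- h
    while (!is.na(succ[chain[length(chain)]])) {
      chain <- c(chain, succ[chain[length(chain)]])
    }
    seg <- tubelets[tubelets$tubelet_id == info$tubelet_id[chain[1]], ]
    if (length(chain) > 1) {
      for (ci in seq_along(chain)[-1]) {
        nxt <- tubelets[tubelets$tubelet_id == info$tubelet_id[chain[ci]], ]
        gap_rows <- NULL
        if (info$start[chain[ci]] > info$end[chain[ci - 1]] + 1L) {
          gap_rows <- interpolate_gap(rows_last[chain[ci - 1], ],
                                      rows_first[chain[ci], ])
        }
        seg <- dplyr::bind_rows(seg, gap_rows, nxt)
      }
    }
    seg$tubelet_id <- h
    pieces[[length(pieces) + 1]] <- seg
  }
  renumber_tubelets(dplyr::bind_rows(pieces))
}
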