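# Shared fixtures and independent oracles used across the suite.

# A detection row with sensible defaults.
det_row <- function(frame, label = "dog", xmin, ymin, xmax, ymax,
                    score = 0.9) {
  detection(frame, label,
            score_dog = if (label == "dog") score else 1 - score,
            score_person = if (label == "person") score else 1 - score,
            xmin, ymin, xmax, ymax)
}

# Exhaustive one-to-one matching oracle: maximum cardinality over the
# allowed pairs (finite distance <= max_distance), then minimum total
# distance; near-equal-cost ties (1e-9) resolved by the
# lexicographically smallest pair list (unmatched rows sort last).
# Independent of the package implementation: enumerates every partial
# assignment vector and scores them all.
exhaustive_match <- function(dets_t, dets_t1, max_distance = 100) {
  n1 <- nrow(dets_t); n2 <- nrow(dets_t1)
  if (n1 == 0 || n2 == 0) return(data.frame(idx_t = integer(), idx_t1 = integer()))
  sub <- function(d, i) {
    list(xmin = d$xmin[i], ymin = d$ymin[i], xmax = d$xmax[i],
         ymax = d$ymax[i], score_dog = d$score_dog[i],
         score_person = d$score_person[i])
  }
  grid <- expand.grid(i = seq_len(n1), j = seq_len(n2))
  dvec <- pair_distance(sub(dets_t, grid$i), sub(dets_t1, grid$j))
  dvec[!is.finite(dvec) | dvec > max_distance] <- Inf
  dmat <- matrix(dvec, n1, n2)
  # candidate assignment vectors: column index per row, 0 = unmatched
  cand <- as.matrix(expand.grid(rep(list(0:n2), n1)))
  injective <- apply(cand, 1, function(v) !anyDuplicated(v[v > 0]))
  cand <- cand[injective, , drop = FALSE]
  cost <- numeric(nrow(cand))
  for (r in seq_len(n1)) {
    has <- cand[, r] > 0
    cost[has] <- cost[has] + dmat[r, ][cand[has, r]]
  }
  card <- rowSums(cand > 0)
  sel <- which(is.finite(cost))
  if (length(sel) == 0 || max(card[sel]) == 0) {
    return(data.frame(idx_t = integer(), idx_t1 = integer()))
  }
  sel <- sel[card[sel] == max(card[sel])]
  sel <- sel[cost[sel] <= min(cost[sel]) + 1e-9]
  if (length(sel) > 1) {
    key <- cand[sel, , drop = FALSE]
    key[key == 0] <- n2 + 1L
    sel <- sel[do.call(order, as.data.frame(key))[1]]
  }
  a <- cand[sel, ]
  idx_t <- which(a > 0)
  data.frame(idx_t = idx_t, idx_t1 = as.integer(a[idx_t]))
}

# Random two-frame instance resembling simulated detector output:
# up to `max_obj` well-defined objects whose frame-t+1 boxes are
# jittered copies, with random drops on both sides.
random_match_instance <- function(max_obj = 3, image = 400, box = 60,
                                  jitter = 8, drop = 0.2) {
  n <- sample.int(max_obj, 1)
  cx <- runif(n, box, image - box); cy <- runif(n, box, image - box)
  lab <- sample(c("dog", "person"), n, replace = TRUE)
  mk <- function(keep, jit) {
    k <- which(keep)
    if (length(k) == 0) return(pupwatch:::empty_detections())
    j <- if (jit) matrix(runif(4 * length(k), -jitter, jitter), ncol = 4)
         else matrix(0, length(k), 4)
    tibble::new_tibble(list(
      frame = rep(0L, length(k)), label = lab[k],
      score_dog = ifelse(lab[k] == "dog", 0.9, 0.1),
      score_person = ifelse(lab[k] == "person", 0.9, 0.1),
      xmin = cx[k] - box / 2 + j[, 1], ymin = cy[k] - box / 2 + j[, 2],
      xmax = cx[k] + box / 2 + j[, 3], ymax = cy[k] + box / 2 + j[, 4]),
      nrow = length(k))
  }
  keep1 <- runif(n) >= drop; keep2 <- runif(n) >= drop
  list(t = mk(keep1, FALSE), t1 = mk(keep2, TRUE))
}

# Textured random image for flow tests, [x, y] grayscale matrix.
textured_image <- function(w, h) {
  matrix(runif(w * h), w, h)
}

# Shift an image rightward (positive x) by an integer number of pixels,
# wrapping at the border.
shift_image <- function(img, dx) {
  w <- nrow(img)
  img[((seq_len(w) - 1 - dx) %% w) + 1, ]
}

# Behavior log of contiguous 8-frame units from a label vector.
units_log <- function(labels, start = 0L, unit_len = 8L) {
  n <- length(labels)
  tibble::tibble(
    start_frame = start + unit_len * (seq_len(n) - 1L),
    end_frame = start + unit_len * seq_len(n) - 1L,
    label = labels
  )
}

# Small-scale pipeline configuration used by end-to-end tests: reduced
# image and crop geometry so rendering stays cheap.
small_config <- function(image_size = 192) {
  cfg <- default_config()
  cfg$image_size <- image_size
  cfg$crop_target_w <- round(image_size * 0.3)
  cfg$crop_target_h <- round(image_size * 0.55)
  cfg$crop_out <- 64
  cfg
}
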