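#' Pluggable model backends
#'
#' Every learned component of the recognition stage — the optical-flow
#' estimator, the two per-stream feature extractors, and the sequence
#' classifier — sits behind a small backend object so that trained
#' models can be swapped in without touching the orchestration. A
#' backend is a named list with a `name`, a declared output dimension
#' where applicable, and a function implementing the component. The
#' package ships deterministic mocks (for testing the orchestration),
#' a classical block-matching flow estimator, and an untrained
#' reference bidirectional-LSTM classifier.
#'
#' @name backends
NULL

#' Block-matching dense optical flow estimator
#'
#' A classical flow estimator: the first image is divided into square
#' blocks and each block's integer displacement into the second image is
#' found by exhaustive search over `[-search, search]^2`, minimizing the
#' mean absolute intensity difference over the pixels that stay inside
#' the image. Ties prefer the smaller displacement (zero motion on
#' identical frames). The per-block displacement is expanded to a
#' per-pixel field.
#'
#' @param block Block side length in pixels.
#' @param search Maximum displacement searched, in pixels per axis.
#' @return A flow backend: list with `name` and `fn(prev, next)`
#'   returning an `[x, y, 2]` array (dx, dy in pixels).
#' @export
flow_backend_blockmatch <- function(block = 16, search = 5) {
  stopifnot(block >= 2, search >= 1)
  fn <- function(prev, nxt) {
    g1 <- to_gray(prev); g2 <- to_gray(nxt)
    w <- nrow(g1); h <- ncol(g1)
    bx <- ceiling(seq_len(w) / block); by <- ceiling(seq_len(h) / block)
    nbx <- max(bx); nby <- max(by)
    shifts <- expand.grid(dx = -search:search, dy = -search:search)
    shifts <- shifts[order(abs(shifts$dx) + abs(shifts$dy),
                           abs(shifts$dx), shifts$dx, shifts$dy), ]
    best_cost <- matrix(Inf, nbx, nby)
    best_dx <- matrix(0, nbx, nby); best_dy <- matrix(0, nbx, nby)
    for (s in seq_len(nrow(shifts))) {
      dx <- shifts$dx[s]; dy <- shifts$dy[s]
      x1 <- max(1, 1 - dx):min(w, w - dx)
      y1 <- max(1, 1 - dy):min(h, h - dy)
      diffs <- abs(g1[x1, y1, drop = FALSE] -
                     g2[x1 + dx, y1 + dy, drop = FALSE])
      sums <- block_sum(diffs, bx[x1], by[y1], nbx, nby)
      counts <- block_sum(matrix(1, length(x1), length(y1)),
                          bx[x1], by[y1], nbx, nby)
      cost <- ifelse(counts > 0, sums / counts, Inf)
      upd <- cost < best_cost
      best_cost[upd] <- cost[upd]
      best_dx[upd] <- dx; best_dy[upd] <- dy
    }
    flow <- array(0, dim = c(w, h, 2))
    flow[, , 1] <- best_dx[cbind(rep(bx, times = h), rep(by, each = w))]
    flow[, , 2] <- best_dy[cbind(rep(bx, times = h), rep(by, each = w))]
    flow
  }
  list(name = "blockmatch", fn = fn)
}

block_sum <- function(m, gx, gy, nbx, nby) {
  # sum m over blocks indexed by (gx, gy); returns nbx x nby matrix
  r <- rowsum(m, gx)                             # sum over x within block rows
  r2 <- rowsum(t(r), gy)                         # then over y
  out <- matrix(0, nbx, nby)
  out[as.integer(rownames(r)), as.integer(rownames(r2))] <- t(r2)
  out
}

to_gray <- function(img) {
  d <- dim(img)
  if (length(d) == 2) return(img)
  apply(img, c(1, 2), mean)
}

#' Mock flow backend: all-zero fields
#'
#' @return A flow backend whose `fn` returns a zero displacement field
#'   of the input size. Used to test the orchestration without paying
#'   for flow estimation.
#' @export
flow_backend_zero <- function() {
  list(name = "zero_flow",
       fn = function(prev, nxt) array(0, dim = c(dim(prev)[1], dim(prev)[2], 2)))
}

#' Mock appearance feature backend keyed to scripted frames
#'
#' Decodes the behavior signature that [render_frames()] paints into the
#' dog's blue channel (level `index / (n_labels + 1)`) and emits a
#' one-hot feature vector at that label index, zero-padded to `dim`.
#' Pairs with [classifier_backend_mock()] so that scripted scenarios are
#' recognized exactly, making the orchestration (not the learning) the
#' thing under test.
#'
#' @param dim Declared output dimension (at least the number of labels).
#' @return An appearance feature backend: list with `name`, `dim`,
#'   `fn(image)`.
#' @export
feature_backend_mock_rgb <- function(dim = 16) {
  n <- length(behavior_labels())
  stopifnot(dim >= n)
  fn <- function(img) {
    d <- dim(img)
    blue <- if (length(d) == 3 && d[3] >= 3) img[, , 3] else img
    idx <- decode_behavior_level(max(blue))
    v <- numeric(dim)
    if (!is.na(idx)) v[idx] <- 1
    v
  }
  list(name = "mock_rgb", dim = dim, fn = fn)
}

encode_behavior_level <- function(idx) idx / (length(behavior_labels()) + 1)

decode_behavior_level <- function(level) {
  n <- length(behavior_labels())
  idx <- round(level * (n + 1))
  if (idx < 1 || idx > n) NA_integer_ else as.integer(idx)
}

#' Motion feature backend from flow-field statistics
#'
#' Deterministic non-learned motion features: mean horizontal and
#' vertical displacement, mean magnitude, and magnitude standard
#' deviation, zero-padded to `dim`.
#'
#' @param dim Declared output dimension (>= 4).
#' @return A motion feature backend: list with `name`, `dim`, `fn(flow)`.
#' @export
feature_backend_flow_stats <- function(dim = 16) {
  stopifnot(dim >= 4)
  fn <- function(flow) {
    mag <- sqrt(flow[, , 1]^2 + flow[, , 2]^2)
    v <- numeric(dim)
    v[1:4] <- c(mean(flow[, , 1]), mean(flow[, , 2]), mean(mag), stats::sd(mag))
    v
  }
  list(name = "flow_stats", dim = dim, fn = fn)
}

#' Generic pooled-intensity appearance backend
#'
#' A non-learned appearance featurizer for use with the untrained
#' reference classifier: the image is converted to grayscale, resized to
#' a small square grid with bilinear interpolation, and flattened; the
#' first `dim` values form the feature vector.
#'
#' @param dim Declared output dimension.
#' @return An appearance feature backend.
#' @export
feature_backend_pool <- function(dim = 64) {
  side <- ceiling(sqrt(dim))
  fn <- function(img) {
    g <- to_gray(img)
    small <- as.array(EBImage::resize(EBImage::Image(g), w = side, h = side,
                                      filter = "bilinear", antialias = FALSE))
    as.numeric(small)[seq_len(dim)]
  }
  list(name = "pool", dim = dim, fn = fn)
}

#' Mock sequence classifier keyed to scripted feature patterns
#'
#' Decodes, per time step, the one-hot label signature emitted by
#' [feature_backend_mock_rgb()] (or [script_behavior_features()]) from
#' the appearance block of the fused vector, and predicts the majority
#' label across the 7 time steps (ties go to the earlier label index).
#' The probability vector is the normalized vote count, so it lies on
#' the simplex and its argmax is the predicted label.
#'
#' @param rgb_dim Dimension of the appearance block within the fused
#'   feature vector (the signature occupies its first 12 entries).
#' @return A classifier backend: list with `name`, `n_classes`,
#'   `fn(features)` taking a 7 x d matrix and returning a 12-probability
#'   vector.
#' @export
classifier_backend_mock <- function(rgb_dim = 16) {
  n <- length(behavior_labels())
  fn <- function(features) {
    sig <- features[, seq_len(n), drop = FALSE]
    votes <- numeric(n)
    for (t in seq_len(nrow(sig))) {
      if (any(sig[t, ] > 0)) {
        idx <- which.max(sig[t, ])
        votes[idx] <- votes[idx] + 1
      }
    }
    if (sum(votes) == 0) votes[n] <- 1  # featureless unit: fall back to idle
    votes / sum(votes)
  }
  list(name = "mock_classifier", n_classes = n, fn = fn)
}

#' Untrained reference bidirectional LSTM classifier
#'
#' The reference sequence-classifier architecture: one bidirectional
#' LSTM layer with `hidden` units per direction over the 7 fused feature
#' vectors, final forward and backward hidden states concatenated and
#' passed through a dense softmax layer over the 12 behaviors. Weights
#' are randomly initialized from a fixed seed (Glorot-style scaling) and
#' not trained: the backend exercises the full computational path
#' deterministically and is the architecture a training harness would
#' fit.
#'
#' @param input_dim Fused feature dimension per time step.
#' @param hidden Hidden units per direction (default 60).
#' @param seed Integer seed for weight initialization.
#' @return A classifier backend (list with `name`, `n_classes`, `fn`).
#' @export
classifier_backend_bilstm <- function(input_dim, hidden = 60, seed = 0) {
  n_classes <- length(behavior_labels())
  rng <- local({ set.seed(seed); function(r, c) {
    matrix(stats::rnorm(r * c, sd = sqrt(2 / (r + c))), r, c) } })
  mk <- function() list(W = rng(4 * hidden, input_dim),
                        U = rng(4 * hidden, hidden),
                        b = numeric(4 * hidden))
  fwd_w <- mk(); bwd_w <- mk()
  W_out <- rng(n_classes, 2 * hidden); b_out <- numeric(n_classes)
  sigm <- function(x) 1 / (1 + exp(-x))
  step <- function(p, x, h, cc) {
    z <- p$W %*% x + p$U %*% h + p$b
    i <- sigm(z[1:hidden]); f <- sigm(z[hidden + 1:hidden])
    o <- sigm(z[2 * hidden + 1:hidden]); g <- tanh(z[3 * hidden + 1:hidden])
    cc2 <- f * cc + i * g
    list(h = o * tanh(cc2), c = cc2)
  }
  run_dir <- function(p, xs) {
    h <- numeric(hidden); cc <- numeric(hidden)
    for (t in seq_len(nrow(xs))) {
      st <- step(p, xs[t, ], h, cc); h <- st$h; cc <- st$c
    }
    h
  }
  fn <- function(features) {
    hf <- run_dir(fwd_w, features)
    hb <- run_dir(bwd_w, features[rev(seq_len(nrow(features))), , drop = FALSE])
    logits <- as.numeric(W_out %*% c(hf, hb) + b_out)
    e <- exp(logits - max(logits))
    e / sum(e)
  }
  list(name = "bilstm_reference", n_classes = n_classes, fn = fn)
}

#' Assemble the standard backend sets
#'
#' `mock_backends()` wires the deterministic mocks together (zero flow,
#' signature appearance features, flow statistics, majority-vote
#' classifier); `reference_backends()` wires the non-learned reference
#' path (block-matching flow, pooled appearance features, flow
#' statistics, untrained bidirectional-LSTM classifier).
#'
#' @param rgb_dim,flow_dim Declared per-stream feature dimensions.
#' @param seed Seed for the reference classifier's weight init.
#' @return Named list with elements `flow`, `rgb_features`,
#'   `flow_features`, `classifier`.
#' @export
mock_backends <- function(rgb_dim = 16, flow_dim = 16) {
  list(flow = flow_backend_zero(),
       rgb_features = feature_backend_mock_rgb(rgb_dim),
       flow_features = feature_backend_flow_stats(flow_dim),
       classifier = classifier_backend_mock(rgb_dim))
}

#' @rdname mock_backends
#' @export
reference_backends <- function(rgb_dim = 64, flow_dim = 16, seed = 0) {
  list(flow = flow_backend_blockmatch(),
       rgb_features = feature_backend_pool(rgb_dim),
       flow_features = feature_backend_flow_stats(flow_dim),
       classifier = classifier_backend_bilstm(rgb_dim + flow_dim, seed = seed))
}
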