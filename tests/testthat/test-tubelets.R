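test_that("iou matches area arithmetic and handles edge cases", {
  expect_equal(iou(bbox(0, 0, 10, 10), bbox(0, 0, 10, 10)), 1.0)
  expect_equal(iou(bbox(0, 0, 10, 10), bbox(20, 20, 30, 30)), 0.0)
  # intersection 1, union 7
  expect_equal(iou(bbox(0, 0, 2, 2), bbox(1, 1, 3, 3)), 1 / 7)
  # symmetry on random boxes
  set.seed(11)
  for (i in 1:20) {
    a <- bbox(runif(1, 0, 50), runif(1, 0, 50),
              runif(1, 60, 100), runif(1, 60, 100))
    b <- bbox(runif(1, 0, 50), runif(1, 0, 50),
              runif(1, 60, 100), runif(1, 60, 100))
    expect_identical(iou(a, b), iou(b, a))
  }
  expect_error(bbox(5, 0, 5, 10), "degenerate")
})

test_that("pair_distance is the reciprocal of IoU times the score dot product", {
  a <- det_row(0, "dog", 0, 0, 10, 10, score = 1)
  b <- det_row(1, "dog", 0, 0, 10, 10, score = 1)
  expect_equal(pair_distance(a, b), 1.0)
  # iou 0.5 and dot 0.5 -> 4
  a2 <- detection(0, "dog", 0.5, 0.5, 0, 0, 10, 20)
  b2 <- detection(1, "dog", 0.5, 0.5, 0, 0, 10, 10)
  expect_equal(iou(a2, b2), 0.5)
  expect_equal(pair_distance(a2, b2), 4.0)
  # disjoint boxes can never match
  c2 <- det_row(1, "dog", 50, 50, 60, 60)
  expect_identical(pair_distance(a, c2), Inf)
})

test_that("match_consecutive pairs obvious candidates and reports unmatched", {
  a <- det_row(0, "dog", 100, 100, 160, 140)
  b <- det_row(1, "dog", 103, 101, 163, 141)
  m <- match_consecutive(a, b)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$idx_t, m$idx_t1), c(1, 1))

  two_t <- rbind(det_row(0, "dog", 100, 100, 160, 140),
                 det_row(0, "person", 300, 100, 340, 220))
  two_t1 <- rbind(det_row(1, "person", 302, 104, 342, 224),
                  det_row(1, "dog", 98, 99, 158, 139))
  m2 <- match_consecutive(two_t, two_t1)
  expect_equal(nrow(m2), 2)
  expect_equal(m2$idx_t1[m2$idx_t == 1], 2)  # dog with dog
  expect_equal(m2$idx_t1[m2$idx_t == 2], 1)  # person with person

  m3 <- match_consecutive(two_t, pupwatch:::empty_detections())
  expect_equal(nrow(m3), 0)
  expect_equal(attr(m3, "unmatched_t"), 1:2)
})

test_that("matching agrees with the exhaustive min-cost oracle on small instances", {
  set.seed(42)
  n_diff <- 0
  for (trial in 1:300) {
    inst <- random_match_instance()
    greedy <- match_consecutive(inst$t, inst$t1)
    oracle <- exhaustive_match(inst$t, inst$t1)
    same <- nrow(greedy) == nrow(oracle) &&
      all(greedy$idx_t == oracle$idx_t) &&
      all(greedy$idx_t1 == oracle$idx_t1)
    if (!same) n_diff <- n_diff + 1
  }
  expect_equal(n_diff, 0)
})

test_that("build_tubelets partitions detections and splits on gaps", {
  tr <- constant_velocity_truth(8)
  det <- simulate_detections(tr, seed = 1)
  tb <- build_tubelets(det)
  expect_equal(max(tb$tubelet_id), 1)
  expect_equal(nrow(tb), 8)
  expect_true(all(diff(tb$frame) == 1))

  det_gap <- det[!(det$frame %in% 3:4), ]
  tb2 <- build_tubelets(det_gap)
  expect_equal(max(tb2$tubelet_id), 2)
  # partition: every detection in exactly one tubelet
  expect_equal(nrow(tb2), nrow(det_gap))
  expect_equal(anyDuplicated(tb2[, c("frame", "xmin")]), 0)
})

test_that("two separated dogs produce two tubelets matching a nearest-IoU oracle", {
  set.seed(7)
  frames <- 0:9
  d1 <- do.call(rbind, lapply(frames, function(f)
    det_row(f, "dog", 50 + 2 * f, 50, 110 + 2 * f, 100)))
  d2 <- do.call(rbind, lapply(frames, function(f)
    det_row(f, "dog", 300, 300 + 3 * f, 360, 350 + 3 * f)))
  det <- rbind(d1, d2)
  det <- det[order(det$frame), ]
  tb <- build_tubelets(det)
  expect_equal(max(tb$tubelet_id), 2)
  # oracle: frame-by-frame nearest-IoU chaining from each frame-0 box
  for (id in 1:2) {
    entries <- tb[tb$tubelet_id == id, ]
    for (i in seq_len(nrow(entries) - 1)) {
      cur <- entries[i, ]
      cand <- det[det$frame == cur$frame + 1, ]
      best <- which.max(iou(cand, cur[rep(1, nrow(cand)), ]))
      expect_equal(entries$xmin[i + 1], cand$xmin[best])
    }
  }
})

test_that("interpolate_gap is coordinate-wise linear with nearer-anchor scores", {
  e <- dplyr::mutate(det_row(5, "dog", 0, 0, 10, 10),
                     tubelet_id = 1L, provenance = "detected")
  s <- dplyr::mutate(det_row(7, "dog", 20, 0, 30, 10),
                     tubelet_id = 1L, provenance = "detected")
  mid <- interpolate_gap(e, s)
  expect_equal(nrow(mid), 1)
  expect_equal(unlist(mid[, c("xmin", "ymin", "xmax", "ymax")]),
               c(xmin = 10, ymin = 0, xmax = 20, ymax = 10))
  expect_equal(mid$provenance, "interpolated")

  # stationary box: constant interpolation
  s2 <- dplyr::mutate(det_row(4, "dog", 0, 0, 10, 10),
                      tubelet_id = 1L, provenance = "detected")
  e2 <- dplyr::mutate(det_row(0, "dog", 0, 0, 10, 10),
                      tubelet_id = 1L, provenance = "detected")
  mid2 <- interpolate_gap(e2, s2)
  expect_equal(nrow(mid2), 3)
  expect_true(all(mid2$xmin == 0 & mid2$xmax == 10))

  # three-step diagonal
  e3 <- dplyr::mutate(det_row(0, "dog", 0, 0, 10, 10),
                      tubelet_id = 1L, provenance = "detected")
  s3 <- dplyr::mutate(det_row(3, "dog", 30, 30, 40, 40),
                      tubelet_id = 1L, provenance = "detected")
  mid3 <- interpolate_gap(e3, s3)
  expect_equal(mid3$xmin, c(10, 20))
  expect_equal(mid3$ymax, c(20, 30))

  # score vectors come from the nearer anchor, ties from the earlier one
  e4 <- dplyr::mutate(detection(0, "dog", 0.9, 0.1, 0, 0, 10, 10),
                      tubelet_id = 1L, provenance = "detected")
  s4 <- dplyr::mutate(detection(4, "dog", 0.7, 0.3, 4, 0, 14, 10),
                      tubelet_id = 1L, provenance = "detected")
  mid4 <- interpolate_gap(e4, s4)
  expect_equal(mid4$score_dog, c(0.9, 0.9, 0.7))

  expect_error(interpolate_gap(e, dplyr::mutate(s, frame = 6L)), "no gap")
})

test_that("interpolated boxes stay inside their anchors' envelope", {
  set.seed(3)
  for (i in 1:25) {
    e <- dplyr::mutate(det_row(0, "dog", runif(1, 0, 100), runif(1, 0, 100),
                               runif(1, 150, 250), runif(1, 150, 250)),
                       tubelet_id = 1L, provenance = "detected")
    s <- dplyr::mutate(det_row(sample(2:12, 1), "dog",
                               runif(1, 0, 100), runif(1, 0, 100),
                               runif(1, 150, 250), runif(1, 150, 250)),
                       tubelet_id = 1L, provenance = "detected")
    mid <- interpolate_gap(e, s)
    for (col in c("xmin", "ymin", "xmax", "ymax")) {
      lo <- min(e[[col]], s[[col]]); hi <- max(e[[col]], s[[col]])
      expect_true(all(mid[[col]] >= lo - 1e-12 & mid[[col]] <= hi + 1e-12))
    }
  }
})

test_that("link_tubelets bridges gaps strictly shorter than k and preserves detections", {
  tr <- constant_velocity_truth(60)
  det <- simulate_detections(tr, seed = 5)

  # qualifying gap of 2 frames
  d1 <- det[!(det$frame %in% 20:21), ]
  lk1 <- link_tubelets(build_tubelets(d1), k = 15)
  expect_equal(max(lk1$tubelet_id), 1)
  expect_true(all(diff(lk1$frame) == 1))

  # gap of exactly k frames is not bridged (strict rule)
  d2 <- det[!(det$frame %in% 20:34), ]  # 15 missing frames
  lk2 <- link_tubelets(build_tubelets(d2), k = 15)
  expect_equal(max(lk2$tubelet_id), 2)
  # one frame fewer missing: bridged
  d3 <- det[!(det$frame %in% 20:33), ]  # 14 missing frames
  lk3 <- link_tubelets(build_tubelets(d3), k = 15)
  expect_equal(max(lk3$tubelet_id), 1)

  # conservation: detected entries never modified or deleted
  detected <- lk3[lk3$provenance == "detected",
                  c("frame", "xmin", "ymin", "xmax", "ymax")]
  expect_equal(as.data.frame(detected[order(detected$frame), ]),
               as.data.frame(d3[order(d3$frame),
                                c("frame", "xmin", "ymin", "xmax", "ymax")]))
})

test_that("a chain of three fragments merges into the exhaustively optimal tubelet", {
  tr <- constant_velocity_truth(90)
  det <- simulate_detections(tr, seed = 9)
  d <- det[!(det$frame %in% c(25:30, 60:66)), ]
  tb <- build_tubelets(d)
  expect_equal(max(tb$tubelet_id), 3)
  lk <- link_tubelets(tb, k = 15)
  expect_equal(max(lk$tubelet_id), 1)
  expect_equal(nrow(lk), 90)
  # exhaustive pairing oracle on this instance: the only feasible
  # pairing set linking all three fragments is (T1,T2), (T2,T3)
  recon <- lk[lk$provenance == "interpolated", ]
  gt <- tr[tr$frame %in% recon$frame, ]
  expect_true(all(iou(recon, gt) > 0.999))
})

test_that("cross-class tubelets are never linked", {
  dog <- do.call(rbind, lapply(0:4, function(f)
    det_row(f, "dog", 100, 100, 160, 140)))
  person <- do.call(rbind, lapply(10:14, function(f)
    det_row(f, "person", 102, 101, 162, 141)))
  tb <- build_tubelets(rbind(dog, person))
  lk <- link_tubelets(tb, k = 15)
  expect_equal(max(lk$tubelet_id), 2)
  expect_false(any(lk$provenance == "interpolated"))
})

test_that("deleting short interior runs reconstructs every box nearly exactly", {
  tr <- constant_velocity_truth(300)
  det <- simulate_detections(tr, seed = 2)
  set.seed(21)
  deleted <- unlist(lapply(c(30, 80, 140, 200, 260), function(s)
    s:(s + sample(1:13, 1))))
  d <- det[!(det$frame %in% deleted), ]
  lk <- link_tubelets(build_tubelets(d), k = 15)
  expect_equal(sort(lk$frame), 0:299)
  recon <- lk[lk$frame %in% deleted, ]
  gt <- tr[tr$frame %in% deleted, ]
  expect_true(all(iou(recon[order(recon$frame), ], gt[order(gt$frame), ]) >= 0.99))
})
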