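test_that("episodes merge runs of identical labels with exact durations", {
  log <- units_log(c("barking", "barking", "barking", "idle"))
  eps <- episodes_from_log(log, fps = 21)
  expect_equal(eps$label, c("barking", "idle"))
  expect_equal(eps$start_frame, c(0L, 24L))
  expect_equal(eps$end_frame, c(23L, 31L))
  expect_equal(eps$duration_s, c(24 / 21, 8 / 21))

  expect_equal(nrow(episodes_from_log(log[0, ], fps = 21)), 0)

  # alternating labels: one episode per unit
  alt <- units_log(rep(c("walking", "idle"), 5))
  expect_equal(nrow(episodes_from_log(alt, fps = 21)), 10)

  # a temporal gap always splits, even with equal labels
  gap <- units_log(c("idle", "idle"))
  gap$start_frame[2] <- gap$start_frame[2] + 8L
  gap$end_frame[2] <- gap$end_frame[2] + 8L
  expect_equal(nrow(episodes_from_log(gap, fps = 21)), 2)

  overlapping <- units_log(c("idle", "idle"))
  overlapping$start_frame[2] <- 4L
  expect_error(episodes_from_log(overlapping, fps = 21), "overlapping")
})

test_that("episode round-trip reproduces the unit log exactly", {
  set.seed(19)
  for (i in 1:50) {
    labs <- sample(behavior_labels(), sample(1:40, 1), replace = TRUE)
    log <- units_log(labs)
    # random gaps between some units
    if (nrow(log) > 3) {
      cut <- sort(sample(2:nrow(log), 2))
      shift <- c(rep(0L, cut[1] - 1),
                 rep(8L, cut[2] - cut[1]),
                 rep(24L, nrow(log) - cut[2] + 1))
      log$start_frame <- log$start_frame + shift
      log$end_frame <- log$end_frame + shift
    }
    eps <- episodes_from_log(log, fps = 21)
    # flatten back to 8-frame units
    flat <- do.call(rbind, lapply(seq_len(nrow(eps)), function(e) {
      starts <- seq.int(eps$start_frame[e], eps$end_frame[e], by = 8L)
      data.frame(start_frame = starts, end_frame = starts + 7L,
                 label = eps$label[e])
    }))
    expect_equal(flat, as.data.frame(log[, c("start_frame", "end_frame", "label")]))
  }
})

test_that("welfare thresholds flag exactly above the configured limits", {
  # 1.2 cumulative barking minutes: flagged (threshold > 1 min)
  eps_bark <- episodes_from_log(units_log(rep("barking", 189)), fps = 21)
  ws <- welfare_state(eps_bark)
  expect_equal(ws$value[ws$behavior == "barking"], 1.2)
  expect_true(ws$flagged[ws$behavior == "barking"])

  # 4 distinct wall-bouncing episodes: flagged (> 3 times)
  labs <- rep(c("wall_bouncing", "idle"), 4)
  ws2 <- welfare_state(episodes_from_log(units_log(labs), fps = 21))
  expect_equal(ws2$value[ws2$behavior == "wall_bouncing"], 4)
  expect_true(ws2$flagged[ws2$behavior == "wall_bouncing"])

  # 2 minutes of grooming: not flagged (> 5 min)
  eps_groom <- episodes_from_log(units_log(rep("grooming", 315)), fps = 21)
  ws3 <- welfare_state(eps_groom)
  expect_equal(ws3$value[ws3$behavior == "grooming"], 2)
  expect_false(ws3$flagged[ws3$behavior == "grooming"])

  # exactly at threshold: not flagged (strictly greater)
  eps_at <- tibble::tibble(label = "barking", start_frame = 0L,
                           end_frame = 1259L, duration_s = 60)
  ws4 <- welfare_state(eps_at)
  expect_false(ws4$flagged[ws4$behavior == "barking"])
})

test_that("welfare flags are monotone in duration and count", {
  set.seed(29)
  for (i in 1:20) {
    n1 <- sample(1:200, 1)
    eps1 <- episodes_from_log(units_log(rep("barking", n1)), fps = 21)
    eps2 <- episodes_from_log(units_log(rep("barking", n1 + sample(1:100, 1))),
                              fps = 21)
    f1 <- welfare_state(eps1)$flagged[1]
    f2 <- welfare_state(eps2)$flagged[1]
    expect_true(!f1 || f2)
  }
})

test_that("alerts fire once at the threshold crossing", {
  eps <- episodes_from_log(units_log(rep("barking", 200)), fps = 21)
  al <- welfare_alerts(eps, fps = 21)
  expect_equal(nrow(al), 1)
  expect_equal(al$behavior, "barking")
  # crossing happens when cumulative barking passes 1 min = frame 1260
  expect_equal(al$frame, 1260L)

  # below threshold: no alert
  eps2 <- episodes_from_log(units_log(rep("barking", 100)), fps = 21)
  expect_equal(nrow(welfare_alerts(eps2, fps = 21)), 0)

  # count-based alert fires at the start of the 4th episode
  labs <- rep(c("wall_bouncing", "idle"), 5)
  eps3 <- episodes_from_log(units_log(labs), fps = 21)
  al3 <- welfare_alerts(eps3, fps = 21)
  expect_equal(al3$behavior, "wall_bouncing")
  expect_equal(al3$frame, eps3$start_frame[eps3$label == "wall_bouncing"][4])
})

test_that("heatmap spreads each record uniformly and conserves mass", {
  # box covering exactly 4 cells of an 8x8 grid over a 80x80 image
  loc <- tibble::tibble(frame = 0:9, timestamp_s = (0:9) / 21,
                        xmin = 10, ymin = 10, xmax = 30, ymax = 30)
  hm <- occupancy_heatmap(loc, 80, 80, grid_w = 8, grid_h = 8)
  expect_equal(sum(hm > 0), 4)
  expect_equal(unname(hm[2, 2]), 2.5)
  expect_equal(sum(hm), 10)

  empty <- loc[0, ]
  expect_true(all(occupancy_heatmap(empty, 80, 80, 8, 8) == 0))

  set.seed(37)
  loc2 <- tibble::tibble(frame = 0:99, timestamp_s = (0:99) / 21,
                         xmin = runif(100, 0, 300), ymin = runif(100, 0, 300),
                         xmax = NA, ymax = NA)
  loc2$xmax <- loc2$xmin + runif(100, 5, 80)
  loc2$ymax <- loc2$ymin + runif(100, 5, 80)
  hm2 <- occupancy_heatmap(loc2, 400, 400, 16, 16)
  expect_equal(sum(hm2), 100, tolerance = 1e-6)
  expect_true(all(hm2 >= 0))
})

test_that("trajectory centroids, markers and color indices are correct", {
  loc <- tibble::tibble(frame = 0L, timestamp_s = 0,
                        xmin = 0, ymin = 0, xmax = 10, ymax = 10)
  tr <- trajectory(loc)
  expect_equal(c(tr$x, tr$y), c(5, 5))
  expect_equal(tr$marker, "start")  # single record: start == end point

  loc3 <- tibble::tibble(frame = 0:2, timestamp_s = 0:2,
                         xmin = c(0, 10, 20), ymin = 0,
                         xmax = c(10, 20, 30), ymax = 10)
  tr3 <- trajectory(loc3)
  expect_equal(tr3$color_index, c(0, 0.5, 1))
  expect_equal(tr3$marker, c("start", NA, "end"))
  expect_true(all(diff(tr3$timestamp_s) > 0))
})

test_that("nested proportions sum to one at both levels and aggregate by category", {
  one <- episodes_from_log(units_log(rep("walking", 4)), fps = 21)
  p1 <- proportions(one)
  expect_equal(p1$fraction[p1$level == "category"], 1)
  expect_equal(p1$name[p1$level == "category"], "active")
  expect_equal(p1$fraction[p1$level == "behavior"], 1)

  two <- episodes_from_log(units_log(c(rep("walking", 3), rep("lying_down", 3))),
                           fps = 21)
  p2 <- proportions(two)
  expect_equal(sort(p2$fraction[p2$level == "category"]), c(0.5, 0.5))

  # 30 s barking, 60 s idle, 30 s walking
  eps <- tibble::tibble(label = c("barking", "idle", "walking"),
                        start_frame = c(0L, 630L, 1890L),
                        end_frame = c(629L, 1889L, 2519L),
                        duration_s = c(30, 60, 30))
  p3 <- proportions(eps)
  beh <- p3[p3$level == "behavior", ]
  expect_equal(beh$fraction[beh$name == "barking"], 0.25)
  expect_equal(beh$fraction[beh$name == "idle"], 0.5)
  expect_equal(beh$fraction[beh$name == "walking"], 0.25)
  cat_ <- p3[p3$level == "category", ]
  expect_equal(cat_$fraction[cat_$name == "active"], 0.5)
  # inner fractions aggregate exactly to their category's outer fraction
  agg <- tapply(beh$fraction, beh$category, sum)
  expect_equal(unname(agg[names(agg) == "active"]),
               cat_$fraction[cat_$name == "active"])
  expect_equal(sum(cat_$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(beh$fraction), 1, tolerance = 1e-9)

  expect_error(proportions(eps[0, ]), "zero total duration")
})

test_that("timeline lanes group static behaviors below active ones", {
  eps <- tibble::tibble(label = c("walking", "sleeping"),
                        start_frame = c(0L, 168L), end_frame = c(167L, 335L),
                        duration_s = c(8, 8))
  tl <- timeline(eps, fps = 21)
  lanes <- attr(tl, "lanes")
  expect_equal(nrow(lanes), 12)
  n_active <- sum(behavior_categories() == "active")
  expect_true(all(lanes$lane[lanes$category == "active"] <= n_active))
  expect_true(all(lanes$lane[lanes$category == "static"] > n_active))
  # spans in minutes
  expect_equal(tl$start_min, c(0, 8 / 60))
  expect_equal(tl$end_min, c(8 / 60, 16 / 60))
  # spans within one lane never overlap
  expect_true(all(tl$end_min >= tl$start_min))
})

test_that("summary figure builders return ggplot objects", {
  log <- units_log(c(rep("walking", 4), rep("barking", 4), rep("idle", 2)))
  loc <- tibble::tibble(frame = 0:9, timestamp_s = (0:9) / 21,
                        xmin = 100, ymin = 100, xmax = 200, ymax = 180)
  s <- summarize_session(log, loc)
  expect_s3_class(plot_gauges(s$welfare), "ggplot")
  expect_s3_class(plot_heatmap(s$heatmap), "ggplot")
  expect_s3_class(plot_trajectory(s$trajectory), "ggplot")
  expect_s3_class(plot_doughnut(s$proportions), "ggplot")
  expect_s3_class(plot_timeline(s$timeline), "ggplot")
  expect_s3_class(ggplot2::autoplot(s$heatmap), "ggplot")
  expect_equal(nrow(tidy(s)), nrow(s$episodes))
  expect_equal(glance(s)$n_episodes, nrow(s$episodes))
})
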