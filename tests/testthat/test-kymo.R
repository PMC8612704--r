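test_that("motility classification uses strict net displacement > 5 um", {
  expect_equal(classify_motility(c(0, 3, 6))$label, "mobile")
  expect_equal(classify_motility(c(0, 2, 5))$label, "stationary")  # boundary
  expect_equal(classify_motility(c(2, 2, 2))$label, "stationary")
  expect_equal(classify_motility(c(2, 2, 2))$net_displacement, 0)
  # net displacement is endpoint-to-endpoint, not path length
  expect_equal(classify_motility(c(0, 4, 0))$label, "stationary")
  expect_error(classify_motility(3), "at least 2")
})

test_that("raising the threshold never converts stationary to mobile", {
  set.seed(9)
  for (i in 1:200) {
    pos <- cumsum(rnorm(20, 0, 1))
    lab <- vapply(c(1, 3, 5, 8), function(th)
      classify_motility(pos, th)$label, character(1))
    # labels along increasing thresholds may only switch mobile -> stationary
    m <- lab == "mobile"
    expect_true(all(diff(m) <= 0))
  }
})

test_that("bout summaries count mobile tracks and flag degenerate bouts", {
  tracks <- do.call(rbind, lapply(1:20, function(j) {
    d <- if (j <= 6) 6 else 1
    data.frame(track_id = j, frame = c(1, 60), position_um = c(10, 10 + d))
  }))
  s <- summarize_bout(tracks)
  expect_equal(s$n_tracks, 20)
  expect_equal(s$n_mobile, 6)
  expect_equal(s$mobile_fraction, 0.30)
  s0 <- summarize_bout(tracks[0, ])
  expect_true(s0$degenerate)
  expect_equal(s0$mobile_fraction, 0)
})

test_that("mobile fraction is invariant to relabeling and direction reversal", {
  set.seed(21)
  p <- noise_free_params(crisis = 4.2)
  sch <- sample_event_schedule(p, "a")
  b <- simulate_kymograph_bouts(sch, p, bout_times = 0.5)[[1]]
  s1 <- summarize_bout(b)
  t2 <- b$tracks
  t2$track_id <- max(t2$track_id) + 1 - t2$track_id        # relabel
  expect_equal(summarize_bout(t2)$mobile_fraction, s1$mobile_fraction)
  t3 <- b$tracks
  t3$position_um <- -t3$position_um                        # reverse direction
  expect_equal(summarize_bout(t3)$mobile_fraction, s1$mobile_fraction)
})

test_that("arrest time is the first sustained all-stationary bout", {
  s <- data.frame(bout_start = 0:4, n_tracks = 20,
                  n_mobile = c(6, 4, 2, 0, 0),
                  mobile_fraction = c(.3, .2, .1, 0, 0), degenerate = FALSE)
  expect_equal(arrest_time(s), 3)
  s$n_mobile <- c(6, 4, 2, 1, 1)
  expect_true(is.na(arrest_time(s)))
  # a single zero-mobile fluke followed by movement is not an arrest
  s$n_mobile <- c(6, 0, 2, 0, 0)
  expect_equal(arrest_time(s), 3)
  expect_error(arrest_time(s[0, ]), "no bout")
})

test_that("simulated bouts: baseline fraction, collective arrest, constant count", {
  p <- noise_free_params(crisis = 4.5)
  set.seed(31)
  sch <- sample_event_schedule(p, "a")
  bt <- bout_schedule(sch, p)
  bouts <- simulate_kymograph_bouts(sch, p, bt)
  ss <- summarize_bouts(bouts)
  expect_equal(ss$n_mobile[ss$bout_start < 0], 6)           # 20 x 0.3
  expect_true(all(ss$n_tracks == 20))                       # count unchanged
  expect_true(all(ss$n_mobile[ss$bout_start >= sch$t_mito_stop] == 0))
  arr <- arrest_time(ss)
  expect_lte(abs(arr - sch$t_mito_stop), p$bout[["spacing_min"]] / 60 + 1e-9)
})

test_that("arrest-time estimates are unbiased to within one bout interval", {
  p <- cascade_params()
  set.seed(41)
  err <- replicate(100, {
    sch <- sample_event_schedule(p, "a")
    bouts <- simulate_kymograph_bouts(sch, p, bout_schedule(sch, p),
                                      positions = FALSE)
    arrest_time(summarize_bouts(bouts)) - sch$t_mito_stop
  })
  expect_lt(abs(mean(err)), p$bout[["spacing_min"]] / 60)
})

test_that("bouts after fragmentation are empty and flagged", {
  p <- noise_free_params(crisis = 4)
  set.seed(51)
  sch <- sample_event_schedule(p, "a")
  b <- simulate_kymograph_bouts(sch, p, sch$t_fragmentation + 0.5)[[1]]
  expect_true(b$post_fragmentation)
  expect_equal(nrow(b$tracks), 0)
  expect_error(simulate_kymograph_bouts(sch, p, c(5, 3)), "sorted")
})

test_that("track extraction recovers simulated tracks from rendered kymographs", {
  p <- noise_free_params(crisis = 5)
  set.seed(61)
  sch <- sample_event_schedule(p, "a")
  b <- simulate_kymograph_bouts(sch, p, bout_times = 0.2, positions = TRUE)[[1]]
  # single well-isolated mobile track
  one <- b$tracks[b$tracks$track_id == 1, ]
  img <- render_kymograph(list_one <- structure(
    list(bout_start = b$bout_start, frame_interval_s = b$frame_interval_s,
         n_frames = b$n_frames, tracks = one, truth = b$truth[1, ],
         post_fragmentation = FALSE), class = "kymo_bout"))
  tr <- extract_tracks(img, pixel_size_um = 0.3, frame_interval_s = 5)
  expect_equal(length(unique(tr$track_id)), 1)
  got <- tr$position_um[order(tr$frame)]
  want <- one$position_um[order(one$frame)][tr$frame]
  expect_lt(max(abs(got - want)), 0.3)  # within one pixel
  # blank image yields no tracks
  expect_equal(nrow(extract_tracks(matrix(0, 60, 300), 0.3, 5)), 0)
})

test_that("two well-separated tracks are linked without identity swaps", {
  n_frames <- 60
  tA <- 10 + 0.1 * (seq_len(n_frames) - 1)    # drifts right
  tB <- 70 - 0.1 * (seq_len(n_frames) - 1)    # drifts left, 60 um away
  tracks <- rbind(data.frame(track_id = 1, frame = 1:n_frames, position_um = tA),
                  data.frame(track_id = 2, frame = 1:n_frames, position_um = tB))
  b <- structure(list(bout_start = 0, frame_interval_s = 5, n_frames = n_frames,
                      tracks = tracks,
                      truth = data.frame(track_id = 1:2, mobile = c(TRUE, TRUE)),
                      post_fragmentation = FALSE), class = "kymo_bout")
  tr <- extract_tracks(render_kymograph(b), 0.3, 5)
  expect_equal(length(unique(tr$track_id)), 2)
  for (id in unique(tr$track_id)) {
    pos <- tr$position_um[tr$track_id == id]
    # each recovered track stays on one side: no swap ever crosses the gap
    expect_true(all(pos < 40) || all(pos > 40))
    expect_equal(nrow(tr[tr$track_id == id, ]), n_frames)
  }
})

test_that("render-and-extract recovers ground-truth motility labels", {
  # a resolvable field: tracks re-spaced 25 um apart before rendering, as in
  # kymographs where individual mitochondria can be distinguished at all
  p <- noise_free_params(crisis = 5)
  p$motility$jitter_sd_um <- 0.3  # default realistic jitter
  set.seed(71)
  agree <- total <- 0
  for (r in 1:10) {
    sch <- sample_event_schedule(p, "a")
    b <- simulate_kymograph_bouts(sch, p, bout_times = 0.2,
                                  positions = TRUE)[[1]]
    for (j in unique(b$tracks$track_id)) {
      i <- b$tracks$track_id == j
      x1 <- b$tracks$position_um[i][which.min(b$tracks$frame[i])]
      b$tracks$position_um[i] <- b$tracks$position_um[i] - x1 + 25 * j
    }
    got <- summarize_bout(extract_tracks(render_kymograph(b,
      width_um = 25 * (max(b$tracks$track_id) + 1) + 20), 0.3, 5))
    # compare recovered mobile count against ground truth
    agree <- agree + min(got$n_mobile, sum(b$truth$mobile)) +
      min(got$n_tracks - got$n_mobile, sum(!b$truth$mobile))
    total <- total + nrow(b$truth)
  }
  expect_gte(agree / total, 0.99)
})
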