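test_that("delta_t: mean, SEM, pairwise exclusion and antisymmetry", {
  calls <- data.frame(t_mito_stop = c(4.0, 4.5), t_ca_onset = c(4.40, 4.94))
  d <- delta_t(calls, "mito_stop", "ca_onset")
  expect_equal(d$mean, 0.42)
  expect_equal(d$sem, 0.02)
  expect_equal(d$n, 2)
  # identity pair
  d0 <- delta_t(calls, "ca_onset", "ca_onset")
  expect_true(all(d0$delta_t == 0))
  # antisymmetry
  expect_equal(delta_t(calls, "ca_onset", "mito_stop")$mean, -d$mean)
  # axons missing an event are excluded pairwise and counted
  calls2 <- rbind(calls, data.frame(t_mito_stop = 5, t_ca_onset = NA))
  d2 <- delta_t(calls2, "mito_stop", "ca_onset")
  expect_equal(d2$n, 2); expect_equal(d2$n_excluded, 1)
  calls3 <- data.frame(t_mito_stop = c(1, 2), t_ca_onset = c(NA, NA))
  expect_error(delta_t(calls3, "mito_stop", "ca_onset"), "no axon")
})

test_that("ordering fraction reproduces the 5-of-7 strict-before split", {
  # five axons one 10-min frame apart, two in the same frame
  te <- c(3.00, 3.20, 3.40, 3.60, 3.80, 4.00, 4.20)
  tl <- te + c(rep(10 / 60, 5), rep(0.05, 2))
  calls <- data.frame(t_tmrm_drop = te, t_ca_onset = tl)
  o <- ordering_fraction(calls, "tmrm_drop", "ca_onset", 10)
  expect_equal(o$n_strict_before, 5)
  expect_equal(o$n_same_frame, 2)
  expect_equal(o$n_after, 0)
  expect_equal(o$fraction_strict, 5 / 7, tolerance = 1e-12)
  # all differences far above a frame: all strict
  calls2 <- data.frame(t_tmrm_drop = te, t_ca_onset = te + 1)
  expect_equal(ordering_fraction(calls2, "tmrm_drop", "ca_onset", 10)$fraction_strict, 1)
  # exact ties: all same-frame
  calls3 <- data.frame(t_tmrm_drop = te, t_ca_onset = te)
  o3 <- ordering_fraction(calls3, "tmrm_drop", "ca_onset", 10)
  expect_equal(o3$fraction_strict, 0)
  expect_equal(o3$n_same_frame, 7)
  # invariant under a constant time shift
  calls4 <- data.frame(t_tmrm_drop = te + 2.5, t_ca_onset = tl + 2.5)
  o4 <- ordering_fraction(calls4, "tmrm_drop", "ca_onset", 10)
  expect_equal(o4$n_strict_before, o$n_strict_before)
  expect_equal(o4$n_same_frame, o$n_same_frame)
})

test_that("linear fit: exact line, hand-computed OLS, degenerate inputs", {
  f <- linear_fit(1:10, 2 * (1:10) + 1)
  expect_equal(f$r_squared, 1)
  expect_equal(f$slope, 2)
  g <- linear_fit(c(1, 2, 3), c(1, 2, 2))
  expect_equal(g$slope, 0.5)
  expect_equal(g$r_squared, 0.75)
  expect_error(linear_fit(c(1, 1, 1), 1:3), "constant")
  h <- linear_fit(1:5, rep(3, 5))
  expect_equal(h$r_squared, 0)
  expect_equal(h$flag, "constant response")
  expect_error(linear_fit(1:2, 1:2), "at least 3")
})

test_that("R^2 is invariant under affine rescaling of x and y", {
  set.seed(14)
  x <- rnorm(20); y <- 1.5 * x + rnorm(20, 0, 0.5)
  r <- linear_fit(x, y)$r_squared
  expect_equal(linear_fit(3 * x - 7, y)$r_squared, r)
  expect_equal(linear_fit(x, -0.2 * y + 11)$r_squared, r)
})

test_that("shuffled-response regressions have the known null mean R^2", {
  set.seed(15)
  n <- 10
  x <- rnorm(n); y <- 2 * x + rnorm(n)
  r2 <- replicate(1000, linear_fit(x, sample(y))$r_squared)
  # under the null E[R^2] = 1/(n-1)
  expect_lt(abs(mean(r2) - 1 / (n - 1)), 0.02)
})

test_that("ATP-motility analysis pairs declines and counts violations", {
  ax <- data.frame(perceval_decline_pct = c(60, 40, 20, 70, 50, 30, 65, 45, 25),
                   motility_drop_pct = c(30, 20, 10, 35, 25, 15, 32, 22, 12),
                   time_to_arrest_h = c(0.5, 1.5, 2.5, 0.3, 1.0, 2.0, 0.4, 1.2, 2.2))
  am <- atp_motility_analysis(ax)
  expect_equal(am$n_violation, 0)
  expect_gt(am$fit_stall$r_squared, 0.99)         # exactly coupled here
  expect_lt(am$fit_time_to_arrest$slope, 0)       # more ATP loss, sooner arrest
  ax$motility_drop_pct[1] <- 90
  expect_equal(atp_motility_analysis(ax)$n_violation, 1)
  expect_error(atp_motility_analysis(data.frame(a = 1)), "missing column")
})

test_that("noise-free coupling gives perfect regressions and zero violations", {
  p <- noise_free_params(crisis = 4.6)
  # spread crisis times deterministically by varying the (degenerate) support
  rows <- lapply(c(4.0, 4.4, 4.8, 5.2, 5.6, 6.0, 6.4, 6.8, 7.2), function(cr) {
    p2 <- noise_free_params(crisis = cr)
    set.seed(round(100 * cr))
    sch <- sample_event_schedule(p2, paste0("a", cr))
    co <- list(traces = simulate_traces(sch, p2, channels = "PercevalHR",
                                        t_end = 3.6),
               bouts = structure(list(simulate_kymograph_bouts(sch, p2,
                 bout_schedule(sch, p2), positions = FALSE)),
                 names = sch$axon_id))
    co$traces$axon_id <- sch$axon_id
    analyze_cohort(co)
  })
  calls <- do.call(rbind, rows)
  am <- atp_motility_analysis(calls)
  expect_equal(am$n_violation, 0)
  # not exactly 1 even without noise: the mobile fraction is quantized in
  # 1/6 steps and the decline-vs-time relation is logistic, not linear
  expect_gt(am$fit_time_to_arrest$r_squared, 0.75)
  expect_gt(am$fit_stall$r_squared, 0.8)
})

test_that("cohort report assembles statistics and handles event-free cohorts", {
  p <- cascade_params()
  co <- generate_cohort(4, p, seed = 31, protocol = "calcium_tmrm")
  calls <- analyze_cohort(co)
  rep1 <- cohort_report(calls)
  expect_false(is.null(rep1$delta_t$tmrm_to_ca))
  expect_true(is.null(rep1$delta_t$ca_to_ps))     # channel not acquired
  expect_false(is.null(rep1$ordering))
  # determinism: same calls, same report
  expect_identical(rep1, cohort_report(calls))
  # event-free control: statistics are not applicable, not zero
  ko <- generate_cohort(4, p, seed = 32, protocol = "calcium_tmrm",
                        injured = FALSE)
  repko <- cohort_report(analyze_cohort(ko))
  expect_true(is.null(repko$delta_t$tmrm_to_ca))
  expect_error(cohort_report(calls[0, ]), "empty")
})
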