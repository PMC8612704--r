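test_that("parameter invariants are enforced", {
  expect_error(cascade_params(offset_ca_to_ps = c(mean = 0.5, sd = -1)), "sd")
  expect_error(cascade_params(crisis_time = c(mean = 5, sd = 1, min = 9, max = 4)),
               "min")
  expect_error(cascade_params(cadences_min = c(GCaMP6 = 0, TMRM = 10,
                                               PercevalHR = 5, mRuby3 = 10,
                                               AnnexinV = 10)), "cadence")
  expect_error(cascade_params(frame_noise_cv = -0.1), "frame_noise_cv")
  expect_error(cascade_params(atp = list(tau = 0.5, tau_sd = 0,
                                         arrest_level = 1.2, onset_level = 0.9)),
               "arrest_level")
  expect_equal(unname(cascade_params()$frame_noise_cv), 0.10)
})

test_that("the deterministic cascade reproduces the configured offsets", {
  s <- sample_event_schedule(noise_free_params(crisis = 4), "d1")
  expect_equal(s$t_mito_stop, 4.0)
  expect_equal(s$t_ca_onset, 4.42)
  expect_equal(s$t_ps_exposure, 4.93)
  expect_equal(s$t_degeneration, 4.42 + 100 / 60, tolerance = 1e-12)
  expect_lt(s$t_atp_onset, s$t_mito_stop)
  expect_lte(s$t_tmrm_drop, s$t_ca_onset)
  expect_gte(s$t_tmrm_drop, s$t_mito_stop)
})

test_that("zero offsets give a degenerate but valid schedule with equal times", {
  p <- noise_free_params(crisis = 5, tau = 0)
  p$offset_mito_stop_to_ca["mean"] <- 0
  p$offset_tmrm_to_ca_min["mean"] <- 0
  p$offset_ca_to_ps["mean"] <- 0
  p$offset_ca_to_degeneration["mean"] <- 0
  p$fragmentation_delay["mean"] <- 0
  s <- sample_event_schedule(p, "z")
  times <- unlist(s[c("t_atp_onset", "t_mito_stop", "t_tmrm_drop", "t_ca_onset",
                      "t_ps_exposure", "t_degeneration", "t_fragmentation")])
  expect_true(all(times == 5))
  expect_silent(validate_schedule(s))
})

test_that("every sampled schedule satisfies the cascade ordering", {
  p <- cascade_params()
  set.seed(101)
  for (i in 1:10000) {
    s <- sample_event_schedule(p, "a")
    expect_true(s$t_atp_onset <= s$t_mito_stop &&
                s$t_mito_stop <= s$t_tmrm_drop &&
                s$t_tmrm_drop <= s$t_ca_onset &&
                s$t_ca_onset <= s$t_ps_exposure &&
                s$t_ps_exposure <= s$t_degeneration &&
                s$t_degeneration <= s$t_fragmentation)
  }
})

test_that("sampled offsets recover their configured means (Monte-Carlo)", {
  p <- cascade_params()
  set.seed(202)
  dca <- replicate(10000, {
    s <- sample_event_schedule(p, "a")
    s$t_ca_onset - s$t_mito_stop
  })
  se <- sd(dca) / sqrt(length(dca))
  expect_lt(abs(mean(dca) - p$offset_mito_stop_to_ca[["mean"]]), 3 * se + 1e-9)
})

test_that("frame noise has the configured coefficient of variation", {
  p <- cascade_params()  # cv = 0.10
  sch <- sample_event_schedule(p, "a", injured = FALSE)  # event-free
  set.seed(33)
  tr <- simulate_traces(sch, p, channels = "GCaMP6",
                        cadences_min = c(GCaMP6 = 0.05), t_end = 8)
  x <- tr$intensity
  expect_gte(length(x), 10000)
  cv_emp <- sd(x) / mean(x)
  expect_lt(abs(cv_emp - 0.10) / 0.10, 0.2)
})

test_that("noise-free traces round-trip through every detector within one frame", {
  p <- noise_free_params(crisis = 4.7)
  s <- sample_event_schedule(p, "rt")
  tr <- simulate_traces(s, p)
  calls <- call_axon_events(tr)
  cad <- p$cadences_min / 60
  expect_lte(calls$t_ca_onset - s$t_ca_onset, cad[["GCaMP6"]] + 1e-9)
  expect_gte(calls$t_ca_onset, s$t_ca_onset - 1e-9)
  expect_lte(calls$t_tmrm_drop - s$t_tmrm_drop, cad[["TMRM"]] + 1e-9)
  expect_gte(calls$t_tmrm_drop, s$t_tmrm_drop - 1e-9)
  expect_lte(calls$t_ps_exposure - s$t_ps_exposure, cad[["AnnexinV"]] + 1e-9)
  expect_lte(calls$t_degeneration - s$t_degeneration, cad[["mRuby3"]] + 1e-9)
  expect_gte(calls$ca_fold, 2)
})

test_that("CCCP-mode ATP forcing produces a ~70% PercevalHR decline", {
  p <- noise_free_params()
  s <- sample_event_schedule(p, "cccp")
  tr <- simulate_traces(s, p, channels = "PercevalHR", t_end = 2.2, cccp = TRUE)
  b <- compute_baseline(tr$time_h, tr$intensity)
  at2 <- tr$intensity[max(which(tr$time_h <= 2))]
  expect_equal(100 * (1 - at2 / b), 70, tolerance = 0.02)
})

test_that("uninjured control axons almost never trigger the calcium detector", {
  p <- cascade_params()  # cv = 0.10
  set.seed(44)
  sch <- sample_event_schedule(p, "ctrl", injured = FALSE)
  fp <- 0
  for (i in 1:1000) {
    tr <- simulate_traces(sch, p, channels = "GCaMP6", t_end = 10)
    b <- compute_baseline(tr$time_h, tr$intensity)
    if (!is.na(detect_calcium_onset(tr$time_h, tr$intensity, b)$time))
      fp <- fp + 1
  }
  expect_lte(fp / 1000, 0.05)
})

test_that("cohorts are reproducible and respect the ordering invariant", {
  p <- cascade_params()
  co1 <- generate_cohort(5, p, seed = 99, protocol = "calcium_annexin")
  co2 <- generate_cohort(5, p, seed = 99, protocol = "calcium_annexin")
  expect_identical(co1$traces, co2$traces)
  expect_identical(co1$schedules, co2$schedules)
  co3 <- generate_cohort(5, p, seed = 100, protocol = "calcium_annexin")
  expect_false(identical(co1$traces, co3$traces))
  co22 <- generate_cohort(22, p, seed = 7, protocol = "calcium_annexin")
  expect_equal(nrow(co22$schedules), 22)
  expect_silent(validate_schedule(co22$schedules))
  expect_error(generate_cohort(0, p, seed = 1), "n must be")
})

test_that("cohort calcium-onset spread covers the observed range in most cohorts", {
  # under the default crisis distribution the n = 22 onset spread reaches
  # below 4.5 h and above 8 h in roughly three quarters of cohorts
  # (Monte-Carlo estimate 0.77); assert a supported lower bound
  p <- cascade_params()
  set.seed(55)
  hits <- replicate(200, {
    ca <- replicate(22, sample_event_schedule(p, "a")$t_ca_onset)
    min(ca) < 4.5 && max(ca) > 8
  })
  expect_gte(mean(hits), 0.70 - 3 * sqrt(0.77 * 0.23 / 200))
})
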