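test_that("z-scoring matches its definition against the baseline", {
  lfp <- lfp_signal(c(rep(2, 100), rep(2, 50), 7), fs = 10)
  baseline <- interval_tbl(0, 10)
  # constant trace within baseline -> degenerate
  expect_error(zscore_trace(lfp, baseline),
               class = "preictal_degenerate_baseline")

  withr::with_seed(81, x <- rnorm(1000))
  lfp <- lfp_signal(c(x, mean(x) + 5 * sd(x)), fs = 100)
  zt <- zscore_trace(lfp, interval_tbl(0, 10))
  expect_equal(zt$z[1001], 5, tolerance = 1e-12)
  # samples equal to the baseline mean -> z = 0
  lfp0 <- lfp_signal(c(x, mean(x)), fs = 100)
  zt0 <- zscore_trace(lfp0, interval_tbl(0, 10))
  expect_equal(zt0$z[1001], 0, tolerance = 1e-12)
})

test_that("Gaussian baseline rarely exceeds |z| > 5", {
  # tail probability 2*pnorm(-5) ~ 5.7e-7: expect none in 2e5 samples
  withr::with_seed(82, lfp <- lfp_signal(rnorm(2e5), fs = 1000))
  zt <- zscore_trace(lfp, interval_tbl(0, 200))
  expect_lte(mean(abs(zt$z) > 5), 1e-4)
})

test_that("onset detection finds the amplitude step and respects the search bound", {
  sess <- simulate_session(step_lfp_config(seed = 83))
  baseline <- interval_tbl(0, 120)
  det <- detect_ictal_onset(sess$lfp, baseline, 120)
  expect_true(det$detected)
  expect_lt(abs(det$onset_s - 300), 0.05)
  expect_gt(det$z_at_onset, 5)

  # never exceeding ~4 SD -> no onset
  withr::with_seed(84, quiet <- lfp_signal(rnorm(60000), fs = 1000))
  det <- detect_ictal_onset(quiet, interval_tbl(0, 30), 30)
  expect_false(det$detected)
  expect_true(is.na(det$onset_s))

  # crossing before injection only -> not detected (search starts at injection)
  withr::with_seed(85, {
    x <- rnorm(60000)
    x[10000:10200] <- 50
  })
  lfp <- lfp_signal(x, fs = 1000)
  det <- detect_ictal_onset(lfp, interval_tbl(0, 5), injection_time_s = 30)
  expect_false(det$detected)
})

test_that("onset error stays within the sustained-crossing window across seeds", {
  errs <- vapply(1:10, function(i) {
    sess <- simulate_session(step_lfp_config(seed = 860 + i))
    det <- detect_ictal_onset(sess$lfp, interval_tbl(0, 120), 120)
    det$onset_s - 300
  }, numeric(1))
  expect_true(all(errs >= 0))
  expect_true(all(errs <= 0.060))
})

test_that("preictal quartiles are equal half-open intervals", {
  p <- partition_preictal(0, 400)
  expect_equal(p$start_s, c(0, 100, 200, 300))
  expect_equal(p$end_s, c(100, 200, 300, 400))

  p <- partition_preictal(100, 101)
  expect_equal(p$end_s - p$start_s, rep(0.25, 4))

  expect_error(partition_preictal(400, 400),
               class = "preictal_invalid_parameter")

  # property: equal quartiles covering [injection, onset) for random pairs
  withr::with_seed(87, {
    for (i in 1:25) {
      inj <- runif(1, 0, 500)
      on <- inj + runif(1, 0.1, 2000)
      p <- partition_preictal(inj, on)
      expect_equal(p$start_s[1], inj)
      expect_equal(p$end_s[4], on)
      expect_equal(diff(p$start_s), rep((on - inj) / 4, 3), tolerance = 1e-9)
      expect_equal(p$start_s[-1], p$end_s[-4])
    }
  })
})

test_that("ictal partition is four exact 15 s quarters within the recording", {
  p <- partition_ictal(400, recording_end_s = 600)
  expect_equal(p$start_s[1], 400)
  expect_equal(p$end_s[1], 415)
  expect_equal(p$end_s - p$start_s, rep(15, 4))
  expect_equal(p$start_s[-1], p$end_s[-4])
  expect_error(partition_ictal(400, recording_end_s = 430),
               class = "preictal_truncated_ictal")
})

test_that("pulse-epoch exclusion subtracts guard windows from periods", {
  periods <- interval_tbl(0, 100, name = "P1")

  # no pulses: full period
  masked <- exclude_pulse_epochs(periods, tibble::tibble(
    onset_s = numeric(0), duration_s = numeric(0)), guard_s = 1)
  expect_equal(masked$effective_duration_s, 100)

  # one 5 ms pulse + 1 s total guard -> 98.995 s effective
  masked <- exclude_pulse_epochs(
    periods, tibble::tibble(onset_s = 50, duration_s = 0.005), guard_s = 1)
  expect_equal(masked$effective_duration_s, 98.995)
  expect_equal(nrow(masked$mask[[1]]), 2)

  # period fully covered -> zero effective duration, NaN rate downstream
  masked <- exclude_pulse_epochs(
    interval_tbl(10, 11, name = "P1"),
    tibble::tibble(onset_s = 10, duration_s = 1), guard_s = 1)
  expect_equal(masked$effective_duration_s, 0)
  expect_true(is.nan(mean_firing_rate(c(10.2, 10.5), masked$mask[[1]],
                                      masked$effective_duration_s)))
})

test_that("quiescence masking thresholds the wheel trace", {
  # all-zero speed: one interval covering the recording
  wheel <- tibble::tibble(time_s = seq(0, 99.9, 0.1), speed = 0)
  q <- mask_quiescence(wheel, threshold = 1, recording_end_s = 100)
  expect_equal(nrow(q), 1)
  expect_equal(c(q$start_s, q$end_s), c(0, 100))

  # speed always above threshold: empty set
  wheel$speed <- 5
  q <- mask_quiescence(wheel, threshold = 1, recording_end_s = 100)
  expect_equal(nrow(q), 0)

  # square wave: alternating intervals at the low phases
  wheel$speed <- rep(c(rep(0, 100), rep(5, 100)), 5)
  q <- mask_quiescence(wheel, threshold = 1, recording_end_s = 100)
  expect_equal(nrow(q), 5)
  expect_equal(q$start_s, seq(0, 80, by = 20))
  expect_equal(q$end_s - q$start_s, rep(10, 5))

  # absent wheel data: identity mask with a warning
  expect_warning(q <- mask_quiescence(NULL, recording_end_s = 100),
                 "no wheel data")
  expect_equal(c(q$start_s, q$end_s), c(0, 100))
})
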