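test_that("pulse spike probability counts responses in the 2-15 ms window", {
  pulses <- tibble::tibble(onset_s = seq(1, 40, by = 1), duration_s = 0.005,
                           intensity = rep(c(1, 2), 20))
  # a spike 5 ms after every pulse -> probability 1 at both intensities
  tbl <- pulse_spike_probability(pulses$onset_s + 0.005, pulses)
  expect_equal(tbl$probability, c(1, 1))
  # silent unit -> 0
  tbl <- pulse_spike_probability(numeric(0), pulses)
  expect_equal(tbl$probability, c(0, 0))
  # spikes outside the window do not count
  tbl <- pulse_spike_probability(pulses$onset_s + 0.0005, pulses)
  expect_equal(tbl$probability, c(0, 0))
  # Bernoulli p = 0.5 with 400 pulses: within 3 binomial SE
  pulses4 <- tibble::tibble(onset_s = seq(1, 400, by = 1) * 0.5 + 1,
                            duration_s = 0.005, intensity = 1)
  withr::with_seed(111, {
    hit <- runif(400) < 0.5
    spikes <- pulses4$onset_s[hit] + 0.004
  })
  tbl <- pulse_spike_probability(spikes, pulses4)
  expect_lt(abs(tbl$probability - 0.5), 3 * sqrt(0.25 / 400))
})

test_that("sigmoid fit recovers noiseless parameters and degrades gracefully", {
  iv <- seq(1, 10, length.out = 8)
  tbl <- tibble::tibble(intensity = iv,
                        probability = sigmoid_response(iv, 0, 1, 5, 1))
  fit <- fit_sigmoid(tbl, seed = 7)
  expect_lt(fit$l1_error, 1e-3)
  expect_equal(fit$Rmax, 1 / (1 + exp(-5)), tolerance = 0.01)
  expect_equal(fit$c, 5, tolerance = 0.05)
  expect_equal(fit$slope, 1, tolerance = 0.05)

  # flat data: fitted curve ~ 0.3 everywhere
  flat <- tibble::tibble(intensity = iv, probability = 0.3)
  ffit <- fit_sigmoid(flat, seed = 8)
  pred <- sigmoid_response(iv, ffit$B, ffit$S, ffit$c, ffit$A)
  expect_true(all(abs(pred - 0.3) < 0.02))

  expect_error(fit_sigmoid(tbl[1:3, ]),
               class = "preictal_underdetermined_fit")
})

test_that("sigmoid fit is deterministic and improves with restarts", {
  tbl <- simulate_opto_responses(0.05, 0.9, 5, 1, seq(0.5, 10, length.out = 8),
                                 n_pulses = 100, seed = 112)
  f1 <- fit_sigmoid(tbl, seed = 3)
  f2 <- fit_sigmoid(tbl, seed = 3)
  expect_identical(tidy(f1), tidy(f2))
  # more restarts can only lower (or keep) the best L1 error
  few <- fit_sigmoid(tbl, n_restarts = 4, seed = 3)
  expect_lte(f1$l1_error, few$l1_error + 1e-12)
})

test_that("intensity-level classification picks near-50% and maximal levels", {
  tbl <- tibble::tibble(intensity = c(1, 2, 4, 8),
                        probability = c(0.1, 0.48, 0.9, 0.95))
  lev <- classify_intensity_levels(tbl)
  expect_equal(lev$medium, 2)
  expect_equal(lev$high, 8)

  # exact 0.5 present -> that level
  tbl$probability <- c(0.2, 0.5, 0.8, 0.9)
  expect_equal(classify_intensity_levels(tbl)$medium, 2)

  # all equal -> ambiguous, max for both, with warning
  tbl$probability <- rep(0.4, 4)
  expect_warning(lev <- classify_intensity_levels(tbl), "ambiguous")
  expect_equal(lev$medium, 8)
  expect_equal(lev$high, 8)
})

test_that("medium level of a dense sigmoid ladder lands near 50% probability", {
  iv <- seq(0.5, 10, length.out = 16)
  tbl <- simulate_opto_responses(0, 1, 5, 1, iv, n_pulses = 500, seed = 113)
  lev <- classify_intensity_levels(tbl)
  p_at_medium <- tbl$probability[tbl$intensity == lev$medium]
  expect_lt(abs(p_at_medium - 0.5), 0.05)
  expect_lt(abs(lev$medium - 5), 1)
})

test_that("modulation index reproduces its closed-form cases", {
  pulses <- tibble::tibble(onset_s = c(100, 200, 300, 400),
                           duration_s = 0.005, intensity = 5)
  # 2 spikes in each 200 ms pre window -> FR_pre = 10 Hz (pooled)
  pre <- as.vector(outer(-c(0.15, 0.05), pulses$onset_s, "+"))

  # equal rates: 1 spike per 50 ms in both windows -> y = 0
  eq_post <- as.vector(outer(0.025, pulses$onset_s, "+")) # 1 / 0.05 s = 20 Hz
  eq_pre <- as.vector(outer(-seq(0.025, 0.175, by = 0.05), pulses$onset_s, "+"))
  m <- modulation_index(sort(c(eq_pre, eq_post)), pulses)
  expect_equal(m$fr_pre, 20)   # 4 spikes / 0.2 s
  expect_equal(m$fr_post, 20)  # 1 spike / 0.05 s
  expect_equal(m$y, 0)

  # full suppression: no post spikes -> y = -1
  m <- modulation_index(sort(pre), pulses)
  expect_equal(m$fr_post, 0)
  expect_equal(m$y, -1)

  # FR_pre = 10 Hz, FR_post = 5 Hz -> y = -1/3
  post_one <- 100.025  # 1 spike pooled over 4 x 50 ms = 5 Hz
  m <- modulation_index(sort(c(pre, post_one)), pulses)
  expect_equal(m$fr_pre, 10)
  expect_equal(m$fr_post, 5)
  expect_equal(m$y, -1 / 3)

  # antisymmetry under exchanging the two rates
  y_of <- function(a, b) (b - a) / (b + a)
  expect_equal(y_of(10, 5), -y_of(5, 10))

  # both silent -> NaN; empty pulse table -> error
  m <- modulation_index(numeric(0), pulses)
  expect_true(is.nan(m$y))
  expect_error(modulation_index(1:3, pulses[0, ]),
               class = "preictal_invalid_input")
})

test_that("median modulation decreases monotonically with suppression depth", {
  depths <- c(0, 0.25, 0.5, 0.75, 1)
  med_y <- vapply(depths, function(d) {
    ys <- vapply(1:6, function(s) {
      cfg <- tiny_config(seed = 120 + round(100 * d) + s)
      cfg$opto$suppression_depth <- d
      cfg$cell_profiles$baseline_rate[cfg$cell_profiles$cell_type == "RS"] <- 12
      sess <- simulate_session(cfg)
      rs_i <- which(sess$units$cell_type == "RS")
      mean(vapply(rs_i, function(i) {
        modulation_index(sess$units$spike_times[[i]], sess$pulses)$y
      }, numeric(1)))
    }, numeric(1))
    median(ys)
  }, numeric(1))
  expect_equal(cor(med_y, depths, method = "spearman"), -1)
})
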