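test_that("spike phases are constant at sinusoid peaks and flip by pi at troughs", {
  f <- 10  # peaks/troughs land exactly on the 1 kHz sample grid
  lfp <- sinusoid_lfp(f, amplitude = 50, fs = 1000, duration_s = 30)
  peaks <- (1 / (4 * f)) + (5:100) / f        # maxima of sin(2*pi*f*t)
  troughs <- (3 / (4 * f)) + (5:100) / f      # minima
  ph_peak <- spike_phases(lfp, peaks, f)
  ph_trough <- spike_phases(lfp, troughs, f)
  expect_lt(diff(range(ph_peak)), 1e-6)
  d <- (ph_peak[1] - ph_trough[1]) %% (2 * pi)
  expect_equal(min(abs(c(d - pi, d + pi, d - 3 * pi))), 0, tolerance = 1e-6)
  # spikes too close to the edges are dropped and counted
  ph <- spike_phases(lfp, c(0.01, peaks[1]), f)
  expect_equal(attr(ph, "n_dropped"), 1)
  expect_error(spike_phases(lfp, peaks, 600),
               class = "preictal_invalid_parameter")
})

test_that("PPC matches exact values and the pairwise oracle", {
  expect_equal(ppc(rep(0.7, 5)), 1)
  expect_equal(ppc(c(0, pi)), -1)
  expect_true(is.nan(ppc(0.2)))
  # O(n) identity equals the O(n^2) pairwise definition to 1e-12
  withr::with_seed(101, {
    for (i in 1:20) {
      n <- sample(2:200, 1)
      phases <- runif(n, -pi, pi)
      expect_equal(ppc(phases), ppc_pairwise(phases), tolerance = 1e-12)
    }
  })
})

test_that("PPC of von Mises phases matches the squared mean resultant length", {
  ph <- rvonmises(10000, mu = 1, kappa = 1, seed = 102)
  expect_equal(ppc(ph), (besselI(1, 1) / besselI(1, 0))^2, tolerance = 0.05)
})

test_that("PPC is unbiased by spike count and centred at zero for uniform phases", {
  withr::with_seed(103, {
    ppc_50 <- vapply(1:200, function(i) ppc(runif(50, -pi, pi)), numeric(1))
    ppc_500 <- vapply(1:200, function(i) ppc(runif(500, -pi, pi)), numeric(1))
  })
  se_50 <- sd(ppc_50) / sqrt(200)
  se_500 <- sd(ppc_500) / sqrt(200)
  # mean zero for uniform phases
  expect_lt(abs(mean(ppc_50)), 3 * se_50)
  expect_lt(abs(mean(ppc_500)), 3 * se_500)
  # equal expectation at both counts (joint CI)
  expect_lt(abs(mean(ppc_50) - mean(ppc_500)),
            3 * sqrt(se_50^2 + se_500^2))
})

test_that("SFC spectrum peaks in the locked band and is flat without locking", {
  profiles <- default_cell_profiles(1, 0, 0)
  profiles$baseline_rate <- 20
  cfg <- simulation_config(
    seed = 104, duration_s = 400, injection_time_s = 300,
    true_onset_s = 330, cell_profiles = profiles,
    lfp_components = tibble::tibble(frequency = 24, amplitude = 60),
    noise_sd = 8, opto = NULL
  )
  sess <- simulate_session(cfg)
  spikes <- sess$units$spike_times[[1]]
  spikes <- spikes[spikes > 5 & spikes < 295]
  freqs <- seq(12, 40, by = 4)
  spec <- sfc_spectrum(sess$lfp, spikes, freqs, max_spikes = 400, seed = 1)
  expect_s3_class(spec, "ppc_spectrum")
  expect_equal(spec$frequency[which.max(spec$ppc)], 24)
  expect_gt(sfc_band_summary(spec, c(20, 28)),
            sfc_band_summary(spec, c(32, 40)) + 0.02)

  # kappa = 0: no locking, band PPC ~ 0
  profiles$kappa_vm <- 0
  cfg0 <- simulation_config(
    seed = 105, duration_s = 400, injection_time_s = 300,
    true_onset_s = 330, cell_profiles = profiles,
    lfp_components = tibble::tibble(frequency = 24, amplitude = 60),
    noise_sd = 8, opto = NULL
  )
  sess0 <- simulate_session(cfg0)
  spikes0 <- sess0$units$spike_times[[1]]
  spikes0 <- spikes0[spikes0 > 5 & spikes0 < 295]
  spec0 <- sfc_spectrum(sess0$lfp, spikes0, 24, max_spikes = 2000, seed = 1)
  expect_lt(abs(spec0$ppc), 0.02)
})

test_that("band power concentrates on the stimulus frequency and scales quadratically", {
  lfp <- sinusoid_lfp(24, amplitude = 10, fs = 1000, duration_s = 20)
  p_in <- band_power(lfp, c(20, 28))
  p_out <- band_power(lfp, c(40, 48))
  expect_gt(p_in, 100 * p_out)

  expect_equal(band_power(lfp_signal(rep(0, 5000), fs = 1000), c(20, 28)), 0)

  lfp2 <- sinusoid_lfp(24, amplitude = 20, fs = 1000, duration_s = 20)
  expect_equal(band_power(lfp2, c(20, 28)) / p_in, 4, tolerance = 1e-8)

  expect_true(is.nan(band_power(lfp_signal(rnorm(100), fs = 1000), c(20, 28))))
})

test_that("spectrogram shows a stationary ridge, the ictal step, and unit normalisation", {
  fs <- 250
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  gain <- ifelse(t >= 20, 10, 1)
  withr::with_seed(106, {
    x <- (20 * sin(2 * pi * 24 * t) + rnorm(length(t), sd = 2)) * gain
  })
  lfp <- lfp_signal(x, fs = fs)
  freqs <- seq(8, 40, by = 4)
  sg <- lfp_spectrogram(lfp, freqs, time_step_s = 0.2)

  # normalisation: sum of 10^power over all bins is 1
  expect_equal(sum(10^sg$power), 1, tolerance = 1e-9)

  # ridge at 24 Hz in the stationary pre-step half
  pre <- sg$time_s > 2 & sg$time_s < 18
  ridge <- freqs[which.max(rowMeans(10^sg$power[, pre]))]
  expect_equal(ridge, 24)

  # amplitude step x10 -> ~100x power at the component frequency
  post <- sg$time_s > 22 & sg$time_s < 38
  f24 <- which(freqs == 24)
  ratio <- mean(10^sg$power[f24, post]) / mean(10^sg$power[f24, pre])
  expect_equal(ratio, 100, tolerance = 0.1)
})
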