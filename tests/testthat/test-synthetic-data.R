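test_that("renewal trains have the expected count and gamma-renewal LV", {
  # Poisson count: 10 Hz x 100 s within 3 SD of 1000
  st <- simulate_renewal_train(10, shape = 1, duration = 100, seed = 11)
  expect_lt(abs(length(st) - 1000), 3 * sqrt(1000))
  expect_false(is.unsorted(st))
  expect_true(all(st >= 0 & st < 100))

  # LV of gamma-renewal trains matches 3/(2*shape+1) within 2% at >= 1e4 ISIs
  for (shape in c(0.5, 1, 2, 4)) {
    st <- simulate_renewal_train(100, shape = shape, duration = 420,
                                 seed = 100 + shape * 10)
    isis <- diff(st)
    expect_gte(length(isis), 1e4)
    expect_equal(local_variation(isis), 3 / (2 * shape + 1),
                 tolerance = 0.02)
  }
})

test_that("renewal train rejects non-positive parameters", {
  expect_error(simulate_renewal_train(0, 1, 10), class = "preictal_invalid_parameter")
  expect_error(simulate_renewal_train(10, -1, 10), class = "preictal_invalid_parameter")
  expect_error(simulate_renewal_train(10, 1, 0), class = "preictal_invalid_parameter")
})

test_that("opto response simulation follows the sigmoid", {
  # midpoint: p(c) = B + S/2
  tbl <- simulate_opto_responses(0, 1, 5, 1, intensities = 5,
                                 n_pulses = 4000, seed = 3)
  expect_equal(tbl$probability, 0.5, tolerance = 3 * sqrt(0.25 / 4000) / 0.5)

  # saturation: p(10) = 1/(1+e^-5) = 0.9933
  tbl <- simulate_opto_responses(0, 1, 5, 1, intensities = 10,
                                 n_pulses = 1e4, seed = 4)
  expect_equal(tbl$probability, 1 / (1 + exp(-5)), tolerance = 0.01)

  # flat curve: S = 0 -> proportion ~ B everywhere
  tbl <- simulate_opto_responses(0.3, 0, 5, 1, intensities = c(1, 5, 9),
                                 n_pulses = 2000, seed = 5)
  expect_true(all(abs(tbl$probability - 0.3) < 3 * sqrt(0.3 * 0.7 / 2000)))

  expect_error(simulate_opto_responses(0, 1, 5, 1, numeric(0), 10),
               class = "preictal_invalid_parameter")
})

test_that("sessions are bit-identical given the same config", {
  cfg <- tiny_config(seed = 21)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$units$spike_times, s2$units$spike_times)
  expect_identical(s1$lfp$samples, s2$lfp$samples)
  expect_identical(s1$pulses, s2$pulses)
})

test_that("ictal gain scales the noise-only LFP SD by the configured factor", {
  cfg <- simulation_config(
    seed = 8, duration_s = 400, injection_time_s = 100, true_onset_s = 200,
    cell_profiles = default_cell_profiles(0, 0, 0),
    lfp_components = tibble::tibble(frequency = numeric(0), amplitude = numeric(0)),
    noise_sd = 10, ictal_gain = 10, opto = NULL
  )
  sess <- simulate_session(cfg)
  t <- seq(0, cfg$duration_s - 1 / cfg$lfp_fs, by = 1 / cfg$lfp_fs)
  sd_pre <- sd(sess$lfp$samples[t < 200])
  sd_post <- sd(sess$lfp$samples[t >= 200])
  expect_equal(sd_post / sd_pre, 10, tolerance = 0.05)
})

test_that("per-period empirical rates track the configured multipliers", {
  profiles <- default_cell_profiles(n_pv = 1, n_sst = 1, n_rs = 1)
  cfg <- simulation_config(seed = 31, duration_s = 900,
                           injection_time_s = 200, true_onset_s = 800,
                           cell_profiles = profiles, opto = NULL)
  sess <- simulate_session(cfg)
  periods <- dplyr::bind_rows(
    interval_tbl(0, 200, name = "baseline"),
    partition_preictal(200, 800)
  )
  for (i in seq_len(nrow(profiles))) {
    spikes <- sess$units$spike_times[[i]]
    mult <- c(baseline = 1, profiles$multipliers[[i]])
    for (j in seq_len(nrow(periods))) {
      p <- periods[j, ]
      expected <- profiles$baseline_rate[i] * mult[[p$name]]
      dur <- p$end_s - p$start_s
      observed <- sum(spikes >= p$start_s & spikes < p$end_s) / dur
      se <- sqrt(expected / dur)
      expect_lt(abs(observed - expected), 4 * se)
    }
  }
})

test_that("von Mises thinning produces the analytic PPC at the locked band", {
  for (kappa in c(0, 1, 4)) {
    profiles <- default_cell_profiles(n_pv = 1, n_sst = 0, n_rs = 0)
    profiles$kappa_vm <- kappa
    profiles$baseline_rate <- 40
    cfg <- simulation_config(seed = 41 + kappa, duration_s = 400,
                             injection_time_s = 300, true_onset_s = 330,
                             cell_profiles = profiles, opto = NULL)
    sess <- simulate_session(cfg)
    spikes <- sess$units$spike_times[[1]]
    spikes <- spikes[spikes < 290]
    # phase of the locked 24 Hz component at spike times
    phases <- (2 * pi * 24 * spikes) %% (2 * pi)
    expected <- (besselI(kappa, 1) / besselI(kappa, 0))^2
    n <- length(phases)
    expect_gt(n, 3000)
    # simulation error: PPC SE ~ 2*R*sd(cos)/sqrt(n); use a generous bound
    expect_equal(ppc(phases), expected, tolerance = 0.02 + 3 / sqrt(n))
  }
})

test_that("tagged units respond within 2-15 ms and full RS suppression silences the window", {
  cfg <- tiny_config(seed = 51)
  cfg$opto$suppression_depth <- 1
  sess <- simulate_session(cfg)
  # tagged unit: evoked spikes in the 2-15 ms window at high intensity
  tagged_i <- which(sess$units$tagged)[1]
  spikes <- sess$units$spike_times[[tagged_i]]
  high <- sess$pulses[sess$pulses$intensity == 10, ]
  prob <- pulse_spike_probability(spikes, high)
  expect_gt(prob$probability, 0.5)
  # RS with depth 1: no spikes in any suppression window
  for (i in which(sess$units$cell_type == "RS")) {
    rs_spikes <- sess$units$spike_times[[i]]
    win <- interval_tbl(sess$pulses$onset_s, sess$pulses$onset_s + 0.05)
    expect_equal(sum(preictal:::in_intervals(rs_spikes, win)), 0)
  }
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(injection_time_s = 400, true_onset_s = 300),
               class = "preictal_invalid_parameter")
  expect_error(simulation_config(ictal_gain = 0.5),
               class = "preictal_invalid_parameter")
  bad <- default_cell_profiles(1, 0, 0)
  bad$shape <- 0.01
  expect_error(simulation_config(cell_profiles = bad),
               class = "preictal_invalid_parameter")
  expect_error(
    simulation_config(opto = list(intensities = c(2, 1), n_per_level = 5,
                                  pulse_duration_s = 0.005,
                                  pulse_interval_s = 0.5, start_s = 10,
                                  suppression_depth = 0.5,
                                  suppression_window_s = 0.05)),
    class = "preictal_invalid_parameter"
  )
})
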