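# Independent oracles and small fixtures used across the suite.

# O(n^2) pairwise-definition PPC: mean cosine of all pairwise phase
# differences. Kept deliberately naive and separate from the package's
# O(n) identity implementation.
ppc_pairwise <- function(phases) {
  n <- length(phases)
  if (n < 2) return(NaN)
  s <- 0
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      s <- s + cos(phases[j] - phases[k])
    }
  }
  2 / (n * (n - 1)) * s
}

# Brute-force two-sided exact binomial p (doubled smaller tail, capped),
# summing the full outcome distribution term by term.
binom_two_sided_bruteforce <- function(k, n, p0 = 0.5) {
  probs <- vapply(0:n, function(x) dbinom(x, n, p0), numeric(1))
  lower <- sum(probs[seq_len(k + 1)])
  upper <- sum(probs[(k + 1):(n + 1)])
  min(1, 2 * min(lower, upper))
}

# Pure sinusoidal LFP fixture.
sinusoid_lfp <- function(frequency, amplitude = 1, fs = 1000,
                         duration_s = 10, phase = 0) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  lfp_signal(amplitude * sin(2 * pi * frequency * t + phase), fs = fs)
}

# Analytic biphasic template with no rebound: after the trough the
# normalised waveform is exactly -exp(-dt / tau_ms).
exp_decay_template <- function(tau_ms, fs = 40000, duration_ms = 2.5,
                               trough_ms = 0.6) {
  waveform_template(cell_type = NULL, fs = fs, duration_ms = duration_ms,
                    trough_ms = trough_ms, tau_ms = tau_ms,
                    rebound_amp = 0, rebound_ms = 0, rebound_sd_ms = 1)
}

# Small, fast session configuration for IO/pipeline plumbing tests.
tiny_config <- function(seed = 1L, wheel = FALSE, opto = TRUE) {
  simulation_config(
    seed = seed, duration_s = 260, injection_time_s = 60,
    true_onset_s = 160,
    cell_profiles = default_cell_profiles(n_pv = 2, n_sst = 1, n_rs = 2),
    lfp_components = tibble::tibble(frequency = 24, amplitude = 60),
    noise_sd = 8,
    opto = if (opto) {
      list(intensities = c(1, 2, 3, 5, 8, 10), n_per_level = 8,
           pulse_duration_s = 0.005, pulse_interval_s = 0.5, start_s = 5,
           suppression_depth = 0.8, suppression_window_s = 0.05)
    },
    wheel = wheel
  )
}

# Step-change LFP session used by the onset-detection checks: 24 Hz
# sinusoid + Gaussian noise, all sample amplitudes scaled by `gain` from
# `onset_s` onward.
step_lfp_config <- function(seed, duration_s = 600, injection_time_s = 120,
                            onset_s = 300, gain = 10) {
  simulation_config(
    seed = seed, duration_s = duration_s,
    injection_time_s = injection_time_s, true_onset_s = onset_s,
    cell_profiles = default_cell_profiles(0, 0, 0)[0, ],
    lfp_components = tibble::tibble(frequency = 24, amplitude = 60),
    noise_sd = 8, ictal_gain = gain, opto = NULL
  )
}
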