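# Synthetic-session generator: gamma-renewal spike trains with per-period
# rate multipliers, sinusoid + Gaussian-noise LFP with an ictal amplitude
# step, von Mises phase locking by thinning, optogenetically "tagged" units
# with sigmoid pulse responses, and pulse-triggered suppression of
# regular-spiking (RS) units. Ground truth travels with the session so the
# analysis stages can be validated against it.

#' Simulate a gamma-renewal spike train
#'
#' Inter-spike intervals are drawn i.i.d. from a gamma distribution with
#' shape `shape` and mean `1/rate`, so `shape = 1` gives a homogeneous
#' Poisson train, `shape > 1` more regular firing and `shape < 1` burstier
#' firing. The closed-form local variation of such a train is
#' `3 / (2 * shape + 1)`.
#'
#' @param rate Mean firing rate in Hz (> 0).
#' @param shape Gamma shape parameter (> 0).
#' @param duration Train duration in seconds (> 0).
#' @param seed Optional integer seed.
#' @param refractory_s Optional hard refractory period in seconds: a dead
#'   time added to every drawn interval (the rate is not re-adjusted).
#' @return Sorted numeric vector of spike times in `[0, duration)`.
#' @export
#' @examples
#' st <- simulate_renewal_train(10, shape = 1, duration = 60, seed = 1)
#' length(st) / 60 # close to 10 Hz
simulate_renewal_train <- function(rate, shape, duration, seed = NULL,
                                   refractory_s = 0) {
  check_positive(rate, "rate")
  check_positive(shape, "shape")
  check_positive(duration, "duration")
  stopifnot(refractory_s >= 0)
  with_seed_if(seed, {
    mean_isi <- 1 / rate + refractory_s
    times <- numeric(0)
    t_last <- 0
    repeat {
      n_more <- ceiling((duration - t_last) / mean_isi +
                          4 * sqrt(max(1, (duration - t_last) / mean_isi)) + 10)
      isis <- rgamma(n_more, shape = shape, rate = shape * rate) + refractory_s
      new_times <- t_last + cumsum(isis)
      times <- c(times, new_times)
      t_last <- times[length(times)]
      if (t_last >= duration) break
    }
    times[times < duration]
  })
}

#' Simulate binomial pulse-response counts from a sigmoid input-output curve
#'
#' For each laser intensity `I` the spike probability is
#' `p(I) = B + S / (1 + exp(-(I - c) / A))`, clipped to `[0, 1]`, and the
#' number of pulses with an evoked spike is drawn as
#' `Binomial(n_pulses, p(I))`.
#'
#' @param B,S,c,A Sigmoid parameters: baseline offset, scale, half-maximum
#'   intensity (mW/mm^2) and width (mW/mm^2; the slope is `1/A`).
#' @param intensities Numeric vector of tested intensities (non-empty).
#' @param n_pulses Pulses delivered per intensity level.
#' @param seed Optional integer seed.
#' @return Tibble with columns `intensity`, `n_pulses`, `n_spikes`,
#'   `probability` (= `n_spikes / n_pulses`).
#' @export
#' @examples
#' simulate_opto_responses(0, 1, 5, 1, intensities = 1:8, n_pulses = 100, seed = 1)
simulate_opto_responses <- function(B, S, c, A, intensities, n_pulses,
                                    seed = NULL) {
  if (length(intensities) == 0) {
    abort("intensities must be non-empty", class = "preictal_invalid_parameter")
  }
  check_positive(A, "A")
  check_positive(n_pulses, "n_pulses")
  p <- sigmoid_response(intensities, B = B, S = S, c = c, A = A)
  with_seed_if(seed, {
    k <- rbinom(length(intensities), size = n_pulses, prob = p)
    tibble::tibble(
      intensity = as.numeric(intensities),
      n_pulses = as.integer(n_pulses),
      n_spikes = as.integer(k),
      probability = k / n_pulses
    )
  })
}

#' Parameterised mean spike waveform templates
#'
#' Analytic extracellular waveform: a Gaussian rise into the trough followed
#' by an exponential repolarisation with time constant `tau_ms`, plus a
#' Gaussian rebound peak. Narrow-spiking templates (fast `tau_ms`) recover
#' well above the `-0.35` repolarisation threshold at 0.9 ms after the
#' trough; the broad RS template stays below it.
#'
#' @param cell_type One of `"PV"`, `"SST"`, `"RS"`, or `NULL` to pass the
#'   shape parameters explicitly.
#' @param fs Sampling rate of the template in Hz.
#' @param duration_ms Template length in ms.
#' @param trough_ms Time of the trough from template start, ms.
#' @param tau_ms Repolarisation time constant, ms.
#' @param rise_sd_ms Gaussian SD of the depolarising rise, ms.
#' @param rebound_amp,rebound_ms,rebound_sd_ms Rebound peak amplitude
#'   (relative to unit trough), latency after the trough (ms) and width (ms).
#' @param amplitude_uv Peak-to-trough scaling in microvolts.
#' @return Numeric vector of sampled voltages.
#' @export
waveform_template <- function(cell_type = c("PV", "SST", "RS"), fs = 32000,
                              duration_ms = 2.5, trough_ms = 0.6,
                              tau_ms = NULL, rise_sd_ms = 0.1,
                              rebound_amp = NULL, rebound_ms = NULL,
                              rebound_sd_ms = NULL, amplitude_uv = 1) {
  if (!is.null(cell_type)) {
    cell_type <- match.arg(cell_type)
    par <- switch(cell_type,
      PV  = list(tau = 0.22, ra = 0.35, rm = 0.35, rs = 0.15),
      SST = list(tau = 0.40, ra = 0.30, rm = 0.60, rs = 0.15),
      RS  = list(tau = 1.30, ra = 0.15, rm = 1.20, rs = 0.35)
    )
    tau_ms <- tau_ms %||% par$tau
    rebound_amp <- rebound_amp %||% par$ra
    rebound_ms <- rebound_ms %||% par$rm
    rebound_sd_ms <- rebound_sd_ms %||% par$rs
  }
  check_positive(fs, "fs")
  check_positive(tau_ms, "tau_ms")
  t_ms <- seq(0, duration_ms, by = 1000 / fs)
  dt <- t_ms - trough_ms
  trough <- ifelse(dt <= 0,
                   -exp(-dt^2 / (2 * rise_sd_ms^2)),
                   -exp(-dt / tau_ms))
  rebound <- (rebound_amp %||% 0) *
    exp(-(dt - (rebound_ms %||% 0))^2 / (2 * (rebound_sd_ms %||% 1)^2))
  (trough + rebound) * amplitude_uv
}

#' Default cell profiles for the synthetic session
#'
#' Eighteen units emulating the three CA1 classes and their preictal
#' trajectories: tagged PV cells with a late preictal surge, tagged SST
#' cells with an early plateau, and untagged broad-waveform RS cells with a
#' gradual ramp. Per-period rate multipliers are relative to baseline and
#' apply to the four preictal quartiles `P1`-`P4` and the four 15 s ictal
#' sub-periods `I1`-`I4`.
#'
#' @param n_pv,n_sst,n_rs Number of units of each class.
#' @return Tibble with one row per unit: `unit_id`, `cell_type`,
#'   `baseline_rate`, `shape`, `kappa_vm`, `locked_band`, `tagged`,
#'   sigmoid truth `B`, `S`, `c`, `A`, `amplitude_uv`, and a `multipliers`
#'   list-column (named numeric over P1-P4, I1-I4).
#' @export
default_cell_profiles <- function(n_pv = 6, n_sst = 4, n_rs = 8) {
  mult <- function(...) list(c(...))
  pv <- tibble::tibble(
    cell_type = "PV", baseline_rate = 14, shape = 1, kappa_vm = 1,
    locked_band = 24, tagged = TRUE, B = 0.05, S = 0.9, c = 5, A = 1,
    amplitude_uv = 60,
    multipliers = mult(P1 = 1.2, P2 = 1.5, P3 = 2, P4 = 4,
                       I1 = 4, I2 = 3, I3 = 2, I4 = 1.5)
  )
  sst <- tibble::tibble(
    cell_type = "SST", baseline_rate = 8, shape = 1, kappa_vm = 0.5,
    locked_band = 24, tagged = TRUE, B = 0.05, S = 0.85, c = 6, A = 1.5,
    amplitude_uv = 55,
    multipliers = mult(P1 = 1.8, P2 = 2, P3 = 2, P4 = 2,
                       I1 = 2, I2 = 1.8, I3 = 1.5, I4 = 1.2)
  )
  rs <- tibble::tibble(
    cell_type = "RS", baseline_rate = 3, shape = 1, kappa_vm = 0,
    locked_band = NA_real_, tagged = FALSE,
    B = NA_real_, S = NA_real_, c = NA_real_, A = NA_real_,
    amplitude_uv = 80,
    multipliers = mult(P1 = 1.2, P2 = 1.5, P3 = 1.8, P4 = 2.2,
                       I1 = 2.5, I2 = 2.5, I3 = 2, I4 = 2)
  )
  profiles <- dplyr::bind_rows(
    pv[rep(1, n_pv), ], sst[rep(1, n_sst), ], rs[rep(1, n_rs), ]
  )
  profiles$unit_id <- sprintf("u%02d", seq_len(nrow(profiles)))
  dplyr::relocate(profiles, "unit_id")
}

#' Build and validate a simulation configuration
#'
#' The configuration fixes the study conditions the generator emulates: a
#' baseline period, a chemoconvulsant injection, a preictal build-up and an
#' ictal amplitude surge in the LFP, with optogenetic pulse trains delivered
#' during baseline.
#'
#' @param seed Integer seed; the session is fully reproducible given the
#'   config (the seed is part of it).
#' @param duration_s Recording length (s).
#' @param lfp_fs LFP sampling rate (Hz).
#' @param injection_time_s Chemoconvulsant injection time (s).
#' @param true_onset_s Ground-truth ictal onset (s); must satisfy
#'   `injection_time_s < true_onset_s` and `true_onset_s + 60 <= duration_s`
#'   for a full ictal hour of quarters.
#' @param cell_profiles Tibble as from [default_cell_profiles()]; may have
#'   zero rows for an LFP-only session.
#' @param lfp_components Tibble/data frame with columns `frequency` (Hz) and
#'   `amplitude` (uV): sinusoidal LFP components.
#' @param noise_sd Gaussian LFP noise SD (uV).
#' @param ictal_gain Multiplier (> 1) applied to all LFP sample amplitudes
#'   from `true_onset_s` onward.
#' @param opto List of pulse-train settings: `intensities` (strictly
#'   increasing ladder, mW/mm^2), `n_per_level`, `pulse_duration_s`,
#'   `pulse_interval_s`, `start_s` (pulses are delivered during baseline),
#'   `suppression_depth` in `[0, 1]` and `suppression_window_s` for RS
#'   inhibition. `NULL` disables pulses.
#' @param wheel If `TRUE`, simulate a wheel-speed trace with locomotion bouts.
#' @return A validated list with class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1L,
                              duration_s = 600,
                              lfp_fs = 1000,
                              injection_time_s = 120,
                              true_onset_s = 420,
                              cell_profiles = default_cell_profiles(),
                              lfp_components = tibble::tibble(
                                frequency = c(6, 24),
                                amplitude = c(40, 25)
                              ),
                              noise_sd = 10,
                              ictal_gain = 10,
                              opto = list(
                                intensities = c(0.5, 1, 2, 3, 4, 5, 7, 10),
                                n_per_level = 25,
                                pulse_duration_s = 0.005,
                                pulse_interval_s = 0.5,
                                start_s = 10,
                                suppression_depth = 0.8,
                                suppression_window_s = 0.05
                              ),
                              wheel = FALSE) {
  check_positive(duration_s, "duration_s")
  check_positive(lfp_fs, "lfp_fs")
  if (!(injection_time_s < true_onset_s && true_onset_s < duration_s)) {
    abort("need injection_time_s < true_onset_s < duration_s",
          class = "preictal_invalid_parameter")
  }
  if (ictal_gain <= 1) {
    abort("ictal_gain must be > 1", class = "preictal_invalid_parameter")
  }
  if (nrow(cell_profiles) > 0) {
    if (any(cell_profiles$baseline_rate < 0)) {
      abort("all rates must be >= 0", class = "preictal_invalid_parameter")
    }
    if (any(cell_profiles$shape < 0.1)) {
      abort("gamma shape must be >= 0.1", class = "preictal_invalid_parameter")
    }
    if (any(cell_profiles$kappa_vm < 0)) {
      abort("kappa_vm must be >= 0", class = "preictal_invalid_parameter")
    }
  }
  if (!is.null(opto)) {
    iv <- opto$intensities
    if (length(iv) == 0 || any(diff(iv) <= 0)) {
      abort("opto intensity ladder must be strictly increasing",
            class = "preictal_invalid_parameter")
    }
    if (opto$suppression_depth < 0 || opto$suppression_depth > 1) {
      abort("suppression_depth must be in [0, 1]",
            class = "preictal_invalid_parameter")
    }
    n_pulses <- length(iv) * opto$n_per_level
    last_pulse <- opto$start_s + (n_pulses - 1) * opto$pulse_interval_s +
      opto$pulse_duration_s
    if (last_pulse >= injection_time_s) {
      abort("opto pulse train must end before injection_time_s",
            class = "preictal_invalid_parameter")
    }
  }
  structure(
    list(
      seed = as.integer(seed), duration_s = duration_s, lfp_fs = lfp_fs,
      injection_time_s = injection_time_s, true_onset_s = true_onset_s,
      cell_profiles = cell_profiles,
      lfp_components = tibble::as_tibble(lfp_components),
      noise_sd = noise_sd, ictal_gain = ictal_gain, opto = opto,
      wheel = isTRUE(wheel), waveform_fs = 32000
    ),
    class = "simulation_config"
  )
}

# Period layout used by the generator: baseline, four preictal quartiles,
# four 15 s ictal quarters, and the remainder of the recording.
simulation_periods <- function(config) {
  inj <- config$injection_time_s
  on <- config$true_onset_s
  q <- inj + (on - inj) * 0:4 / 4
  ict_end <- min(on + 60, config$duration_s)
  ict <- seq(on, ict_end, by = 15)
  starts <- c(0, q[1:4], ict[-length(ict)])
  ends <- c(inj, q[2:5], ict[-1])
  names <- c("baseline", paste0("P", 1:4),
             paste0("I", seq_len(length(ict) - 1)))
  tail_start <- ends[length(ends)]
  if (tail_start < config$duration_s) {
    starts <- c(starts, tail_start)
    ends <- c(ends, config$duration_s)
    names <- c(names, "post")
  }
  interval_tbl(starts, ends, name = names)
}

#' Simulate a full recording session
#'
#' Draws every unit's spike train as a piecewise-constant-rate gamma-renewal
#' process following its per-period multipliers; thins spikes of
#' phase-locked units by von Mises acceptance on the instantaneous phase of
#' their locked LFP component (candidate rates are pre-scaled so the mean
#' rate is preserved); builds the LFP as a sum of sinusoids plus Gaussian
#' noise with all amplitudes multiplied by `ictal_gain` from the true onset;
#' adds short-latency (3 ms +/- 0.3 ms jitter) pulse-evoked spikes to tagged
#' units with probability given by their true sigmoid; and suppresses RS
#' firing by `suppression_depth` in the window after each pulse.
#'
#' @param config A [simulation_config()].
#' @return An object of class `ephys_session`: a list with `units` (tibble:
#'   `unit_id`, `cell_type`, `tagged`, `spike_times` list-column, `waveform`
#'   list-column), `lfp` ([lfp_signal()]), `pulses` (tibble `onset_s`,
#'   `duration_s`, `intensity`), `injection_time_s`, `duration_s`,
#'   `waveform_fs`, optional `wheel`, and `truth` (the config).
#' @export
#' @examples
#' cfg <- simulation_config(seed = 42, duration_s = 200, injection_time_s = 60,
#'                          true_onset_s = 130, cell_profiles = default_cell_profiles(1, 1, 2),
#'                          opto = NULL)
#' sess <- simulate_session(cfg)
#' sess$units
simulate_session <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, {
    periods <- simulation_periods(config)
    pulses <- simulate_pulse_table(config)
    units <- simulate_units(config, periods, pulses)
    lfp <- simulate_lfp(config)
    wheel <- if (config$wheel) simulate_wheel(config) else NULL
    new_ephys_session(
      units = units, lfp = lfp, pulses = pulses,
      injection_time_s = config$injection_time_s,
      duration_s = config$duration_s, waveform_fs = config$waveform_fs,
      wheel = wheel, truth = config
    )
  })
}

# Regular pulse train in baseline, cycling through the intensity ladder so
# every level is spread across the train.
simulate_pulse_table <- function(config) {
  opto <- config$opto
  if (is.null(opto)) {
    return(tibble::tibble(onset_s = numeric(0), duration_s = numeric(0),
                          intensity = numeric(0)))
  }
  n <- length(opto$intensities) * opto$n_per_level
  tibble::tibble(
    onset_s = opto$start_s + (seq_len(n) - 1) * opto$pulse_interval_s,
    duration_s = opto$pulse_duration_s,
    intensity = rep(opto$intensities, times = opto$n_per_level)
  )
}

simulate_units <- function(config, periods, pulses) {
  profiles <- config$cell_profiles
  if (nrow(profiles) == 0) {
    return(tibble::tibble(
      unit_id = character(0), cell_type = character(0), tagged = logical(0),
      spike_times = list(), waveform = list()
    ))
  }
  opto <- config$opto
  rows <- purrr::map(seq_len(nrow(profiles)), function(i) {
    pr <- profiles[i, ]
    mult <- pr$multipliers[[1]]
    spikes <- purrr::pmap(periods, function(name, start_s, end_s) {
      m <- if (name %in% names(mult)) mult[[name]] else 1
      rate <- pr$baseline_rate * m
      dur <- end_s - start_s
      if (rate <= 0 || dur <= 0) return(numeric(0))
      locked <- !is.na(pr$locked_band) && pr$kappa_vm > 0
      gen_rate <- if (locked) {
        rate * exp(pr$kappa_vm) / besselI(pr$kappa_vm, 0)
      } else {
        rate
      }
      st <- start_s + simulate_renewal_train(gen_rate, pr$shape, dur)
      if (locked) {
        phase <- 2 * pi * pr$locked_band * st
        keep <- runif(length(st)) < exp(pr$kappa_vm * (cos(phase) - 1))
        st <- st[keep]
      }
      st
    })
    spikes <- sort(unlist(spikes))
    if (nrow(pulses) > 0) {
      if (isTRUE(pr$tagged)) {
        p_evoked <- sigmoid_response(pulses$intensity, pr$B, pr$S, pr$c, pr$A)
        hit <- runif(nrow(pulses)) < p_evoked
        evoked <- pulses$onset_s[hit] + 0.003 +
          rnorm(sum(hit), mean = 0, sd = 0.0003)
        spikes <- sort(c(spikes, evoked))
      } else if (pr$cell_type == "RS" && !is.null(opto) &&
                 opto$suppression_depth > 0) {
        win <- interval_tbl(pulses$onset_s,
                            pulses$onset_s + opto$suppression_window_s)
        in_win <- in_intervals(spikes, win)
        drop <- in_win & (runif(length(spikes)) < opto$suppression_depth)
        spikes <- spikes[!drop]
      }
    }
    spikes <- spikes[spikes >= 0 & spikes < config$duration_s]
    tibble::tibble(
      unit_id = pr$unit_id, cell_type = pr$cell_type,
      tagged = isTRUE(pr$tagged),
      spike_times = list(spikes),
      waveform = list(waveform_template(pr$cell_type, fs = config$waveform_fs,
                                        amplitude_uv = pr$amplitude_uv))
    )
  })
  dplyr::bind_rows(rows)
}

# Sum-of-sinusoids + white noise LFP; the whole trace (components and noise)
# is scaled by ictal_gain from true_onset_s onward.
simulate_lfp <- function(config) {
  n <- round(config$duration_s * config$lfp_fs)
  t <- (seq_len(n) - 1) / config$lfp_fs
  x <- rnorm(n, sd = config$noise_sd)
  comps <- config$lfp_components
  for (i in seq_len(nrow(comps))) {
    x <- x + comps$amplitude[i] * sin(2 * pi * comps$frequency[i] * t)
  }
  gain <- ifelse(t >= config$true_onset_s, config$ictal_gain, 1)
  lfp_signal(x * gain, fs = config$lfp_fs)
}

# Alternating locomotion/quiescence bouts (exponential durations) sampled at
# 10 Hz; speed is bout indicator times a positive running speed plus jitter.
simulate_wheel <- function(config) {
  fs <- 10
  t <- seq(0, config$duration_s - 1 / fs, by = 1 / fs)
  state <- logical(length(t))
  i <- 1
  moving <- FALSE
  while (i <= length(t)) {
    dur <- rexp(1, rate = if (moving) 1 / 10 else 1 / 30)
    j <- min(length(t), i + round(dur * fs))
    state[i:j] <- moving
    moving <- !moving
    i <- j + 1
  }
  speed <- ifelse(state, pmax(0, rnorm(length(t), 8, 2)),
                  abs(rnorm(length(t), 0, 0.2)))
  tibble::tibble(time_s = t, speed = speed)
}

#' Construct an LFP signal
#'
#' @param samples Numeric vector of voltages (uV).
#' @param fs Sampling rate (Hz, > 0).
#' @param start_s Time of the first sample (s).
#' @return List with class `lfp_signal`: `samples`, `fs`, `start_s`.
#' @export
lfp_signal <- function(samples, fs, start_s = 0) {
  check_positive(fs, "fs")
  structure(list(samples = as.numeric(samples), fs = fs, start_s = start_s),
            class = "lfp_signal")
}

#' @export
print.lfp_signal <- function(x, ...) {
  cat(sprintf("<lfp_signal: %d samples @ %g Hz (%.1f s)>\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

# Sample times of an LFP signal.
lfp_times <- function(lfp) {
  lfp$start_s + (seq_along(lfp$samples) - 1) / lfp$fs
}

new_ephys_session <- function(units, lfp, pulses, injection_time_s,
                              duration_s, waveform_fs, wheel = NULL,
                              truth = NULL) {
  bad <- purrr::map_lgl(units$spike_times, function(st) {
    length(st) > 0 && (is.unsorted(st) || st[1] < 0 ||
                         st[length(st)] > duration_s)
  })
  if (any(bad)) {
    abort("spike times must be sorted and within [0, duration]",
          class = "preictal_validation_error")
  }
  if (nrow(pulses) > 0 &&
      (min(pulses$onset_s) < 0 || max(pulses$onset_s) >= duration_s)) {
    abort("pulse onsets must lie within the recording",
          class = "preictal_validation_error")
  }
  structure(
    list(units = units, lfp = lfp, pulses = pulses,
         injection_time_s = injection_time_s, duration_s = duration_s,
         waveform_fs = waveform_fs, wheel = wheel, truth = truth),
    class = "ephys_session"
  )
}

#' @export
print.ephys_session <- function(x, ...) {
  cat(sprintf(
    "<ephys_session: %d units, %.0f s, injection at %.0f s, %d pulses>\n",
    nrow(x$units), x$duration_s, x$injection_time_s, nrow(x$pulses)))
  invisible(x)
}
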