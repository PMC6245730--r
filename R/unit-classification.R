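# Waveform feature extraction, regular-spiking (RS) classification,
# optogenetic tagging, and spike-train quality control.

#' Waveform features of a mean spike waveform
#'
#' The waveform is normalised to `[-1, +1]` by its maximum absolute value;
#' the trough is the minimum, the peak the subsequent maximum. The
#' repolarisation feature is the normalised voltage 0.9 ms after the trough
#' (linear interpolation between samples), the basis of broad/narrow
#' classification.
#'
#' @param waveform Numeric vector of sampled voltages.
#' @param waveform_fs Sampling rate of the waveform (Hz).
#' @param repolarization_ms Read-out delay after the trough (default 0.9 ms).
#' @return One-row tibble: `peak_to_trough_ms`, `amplitude`
#'   (peak-to-trough, in the waveform's voltage units), `repolarization_0p9`.
#' @export
waveform_features <- function(waveform, waveform_fs,
                              repolarization_ms = 0.9) {
  check_positive(waveform_fs, "waveform_fs")
  n <- length(waveform)
  trough_i <- which.min(waveform)
  t_ms <- (seq_len(n) - 1) / waveform_fs * 1000
  if (t_ms[n] - t_ms[trough_i] < repolarization_ms) {
    abort("waveform window too short: need >= 0.9 ms after the trough",
          class = "preictal_insufficient_window")
  }
  norm <- waveform / max(abs(waveform))
  repol <- approx(t_ms, norm, xout = t_ms[trough_i] + repolarization_ms)$y
  after <- waveform[trough_i:n]
  peak_i <- trough_i - 1 + which.max(after)
  tibble::tibble(
    peak_to_trough_ms = t_ms[peak_i] - t_ms[trough_i],
    amplitude = waveform[peak_i] - waveform[trough_i],
    repolarization_0p9 = repol
  )
}

#' Classify a unit as regular-spiking (RS) or not
#'
#' RS (putative excitatory) cells are untagged units with a broad waveform,
#' defined as a repolarisation value at 0.9 ms strictly below -0.35 on the
#' normalised waveform. Light-driven (tagged) units are never RS.
#'
#' @param features One-row tibble from [waveform_features()].
#' @param is_tagged Logical: did the unit pass optogenetic tagging?
#' @param threshold Repolarisation threshold (default -0.35).
#' @return `"RS"` or `"non-RS"`.
#' @export
classify_rs <- function(features, is_tagged, threshold = -0.35) {
  if (!is_tagged && features$repolarization_0p9 < threshold) "RS" else "non-RS"
}

#' Identify an optotagged unit from its pulse-triggered responses
#'
#' Tagging relies on the short latency and low jitter of directly evoked
#' spikes. For each tagging pulse the first spike in the response window is
#' collected; the unit is tagged when the median first-spike latency and
#' its SD (jitter) are small, the evoked probability is high, and that
#' probability significantly exceeds the chance rate implied by the unit's
#' own baseline firing (one-sided binomial test).
#'
#' @param spikes Spike times (s).
#' @param pulses Pulse tibble (`onset_s`, `duration_s`, ...); tagging pulses
#'   are expected to lie in the baseline period.
#' @param response_window Two-element window after pulse onset (s); default
#'   1-10 ms.
#' @param latency_max_ms,jitter_max_ms,p_min Tagging thresholds: maximum
#'   median latency, maximum latency SD, minimum evoked probability.
#' @param chance_alpha Significance level of the chance-rate guard.
#' @param baseline_rate_hz Optional known baseline rate; when `NULL` it is
#'   estimated from the spike train outside 20 ms post-pulse windows.
#' @return One-row tibble: `n_pulses`, `evoked_probability`,
#'   `median_latency_ms`, `latency_jitter_ms`, `chance_probability`,
#'   `chance_p_value`, `is_tagged`.
#' @export
identify_tagged_unit <- function(spikes, pulses,
                                 response_window = c(0.001, 0.010),
                                 latency_max_ms = 6, jitter_max_ms = 1.5,
                                 p_min = 0.3, chance_alpha = 0.05,
                                 baseline_rate_hz = NULL) {
  if (nrow(pulses) == 0) {
    abort("no tagging pulses", class = "preictal_invalid_input")
  }
  w <- diff(response_window)
  lat_ms <- purrr::map_dbl(pulses$onset_s, function(on) {
    hit <- spikes[spikes >= on + response_window[1] &
                    spikes < on + response_window[2]]
    if (length(hit) == 0) NA_real_ else (hit[1] - on) * 1000
  })
  n_evoked <- sum(!is.na(lat_ms))
  p_evoked <- n_evoked / nrow(pulses)
  med_lat <- if (n_evoked > 0) median(lat_ms, na.rm = TRUE) else NA_real_
  jitter <- if (n_evoked > 1) sd(lat_ms, na.rm = TRUE) else NA_real_
  if (is.null(baseline_rate_hz)) {
    excl <- interval_tbl(pulses$onset_s, pulses$onset_s + 0.020)
    span <- interval_subtract(
      interval_tbl(0, max(c(spikes, pulses$onset_s + 1))), excl)
    baseline_rate_hz <- sum(in_intervals(spikes, span)) /
      max(interval_duration(span), .Machine$double.eps)
  }
  p_chance <- 1 - exp(-baseline_rate_hz * w)
  p_val <- pbinom(n_evoked - 1, nrow(pulses), min(p_chance, 1),
                  lower.tail = FALSE)
  tagged <- n_evoked > 0 &&
    !is.na(med_lat) && med_lat <= latency_max_ms &&
    !is.na(jitter) && jitter <= jitter_max_ms &&
    p_evoked >= p_min && p_val < chance_alpha
  tibble::tibble(
    n_pulses = nrow(pulses), evoked_probability = p_evoked,
    median_latency_ms = med_lat, latency_jitter_ms = jitter,
    chance_probability = p_chance, chance_p_value = p_val,
    is_tagged = tagged
  )
}

#' Refractory-period contamination of a spike train
#'
#' Fraction of inter-spike intervals shorter than the refractory period; a
#' proxy for sorting contamination. Well-isolated units should stay at or
#' below 0.1% at 1.5 ms.
#'
#' @param spikes Spike times (s).
#' @param refractory_ms Refractory bound (default 1.5 ms).
#' @return Fraction in `[0, 1]`; `NaN` with a warning for < 2 spikes.
#' @export
isi_contamination <- function(spikes, refractory_ms = 1.5) {
  if (length(spikes) < 2) {
    warn("fewer than 2 spikes: contamination undefined")
    return(NaN)
  }
  isis <- diff(sort(spikes))
  mean(isis < refractory_ms / 1000)
}

#' Was a unit tracked long enough for ictal analysis?
#'
#' Ictal spiking analyses use only units whose activity could be resolved
#' for at least 60 s after onset.
#'
#' @param tracked_until_s Last time the unit was still isolated (s).
#' @param onset_s Ictal onset (s).
#' @param min_ictal_s Required tracking span after onset (default 60 s).
#' @return Logical.
#' @export
check_ictal_trackability <- function(tracked_until_s, onset_s,
                                     min_ictal_s = 60) {
  tracked_until_s - onset_s >= min_ictal_s
}

#' Classify all units of a session
#'
#' Runs waveform feature extraction, optotagging against baseline pulses,
#' RS classification and ISI quality control for every unit. Tagging is
#' assessed on the highest-intensity pulses only (light power is calibrated
#' so evoked probability approaches 1 there; weaker ladder pulses would
#' dilute the evoked-latency statistics with spontaneous spikes). Untagged
#' narrow-waveform units are labelled `"unidentified-narrow"` and should be
#' excluded from RS-specific analyses.
#'
#' @param session An `ephys_session`.
#' @param ... Passed to [identify_tagged_unit()].
#' @return Tibble: `unit_id`, waveform features, tagging statistics,
#'   `contamination`, `label` in
#'   `{"tagged", "RS", "unidentified-narrow"}`.
#' @export
classify_units <- function(session, ...) {
  tagging_pulses <- session$pulses
  if (nrow(tagging_pulses) > 0 && "intensity" %in% names(tagging_pulses) &&
      !all(is.na(tagging_pulses$intensity))) {
    tagging_pulses <-
      tagging_pulses[tagging_pulses$intensity ==
                       max(tagging_pulses$intensity, na.rm = TRUE), ]
  }
  purrr::map(seq_len(nrow(session$units)), function(i) {
    u <- session$units[i, ]
    feats <- waveform_features(u$waveform[[1]], session$waveform_fs)
    tag <- if (nrow(tagging_pulses) > 0) {
      identify_tagged_unit(u$spike_times[[1]], tagging_pulses, ...)
    } else {
      tibble::tibble(n_pulses = 0L, evoked_probability = NA_real_,
                     median_latency_ms = NA_real_, latency_jitter_ms = NA_real_,
                     chance_probability = NA_real_, chance_p_value = NA_real_,
                     is_tagged = FALSE)
    }
    rs <- classify_rs(feats, tag$is_tagged)
    label <- if (tag$is_tagged) "tagged" else if (rs == "RS") "RS" else "unidentified-narrow"
    dplyr::bind_cols(
      tibble::tibble(unit_id = u$unit_id), feats, tag,
      tibble::tibble(
        contamination = suppressWarnings(isi_contamination(u$spike_times[[1]])),
        label = label
      )
    )
  }) |>
    dplyr::bind_rows()
}
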