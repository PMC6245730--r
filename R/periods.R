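# Ictal-onset detection from the LFP and partitioning of the recording into
# the analysis periods: baseline, four equal preictal quartiles spanning
# injection -> onset, and four 15 s ictal sub-periods.

#' Z-score an LFP trace against a baseline interval
#'
#' Per-sample `z = (x - mean_baseline) / sd_baseline`, computed on the raw
#' samples (no filtering or envelope).
#'
#' @param lfp An [lfp_signal()].
#' @param baseline Interval tibble (one row) within the recording.
#' @return Tibble with columns `time_s`, `z`.
#' @export
zscore_trace <- function(lfp, baseline) {
  stopifnot(inherits(lfp, "lfp_signal"), nrow(baseline) >= 1)
  t <- lfp_times(lfp)
  base <- lfp$samples[in_intervals(t, baseline)]
  if (length(base) < 2) {
    abort("baseline interval contains fewer than 2 samples",
          class = "preictal_degenerate_baseline")
  }
  s <- sd(base)
  if (s == 0) {
    abort("baseline SD is zero; cannot z-score",
          class = "preictal_degenerate_baseline")
  }
  tibble::tibble(time_s = t, z = (lfp$samples - mean(base)) / s)
}

#' Detect ictal onset from the z-scored LFP
#'
#' Onset is the first time after the injection at which `|z|` exceeds
#' `z_threshold` for at least `min_duration_ms` consecutive samples. The
#' sustained-crossing requirement rejects single-sample noise excursions.
#'
#' @param lfp An [lfp_signal()].
#' @param baseline Baseline interval tibble used for the z-score.
#' @param injection_time_s Search starts at this time.
#' @param z_threshold Absolute z-score threshold (default 5).
#' @param min_duration_ms Minimum sustained crossing (default 10 ms).
#' @return One-row tibble: `onset_s` (NA if never crossed), `z_at_onset`,
#'   `detected` (logical).
#' @export
detect_ictal_onset <- function(lfp, baseline, injection_time_s,
                               z_threshold = 5, min_duration_ms = 10) {
  zt <- zscore_trace(lfp, baseline)
  post <- zt$time_s > injection_time_s
  over <- abs(zt$z) > z_threshold & post
  min_run <- max(1L, round(min_duration_ms / 1000 * lfp$fs))
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(r$values & r$lengths >= min_run)
  if (length(ok) == 0) {
    return(tibble::tibble(onset_s = NA_real_, z_at_onset = NA_real_,
                          detected = FALSE))
  }
  i <- starts[ok[1]]
  tibble::tibble(onset_s = zt$time_s[i], z_at_onset = abs(zt$z[i]),
                 detected = TRUE)
}

#' Partition the preictal period into four equal quartiles
#'
#' Seizure latency varies across animals, so the injection-to-onset span is
#' divided into four equal half-open intervals `P1`-`P4`.
#'
#' @param injection_s,onset_s Injection and detected onset times (s),
#'   `injection_s < onset_s`.
#' @return Interval tibble with rows `P1`-`P4`.
#' @export
#' @examples
#' partition_preictal(0, 400)
partition_preictal <- function(injection_s, onset_s) {
  if (!(onset_s > injection_s)) {
    abort("onset must be after injection", class = "preictal_invalid_parameter")
  }
  edges <- injection_s + (onset_s - injection_s) * 0:4 / 4
  interval_tbl(edges[1:4], edges[2:5], name = paste0("P", 1:4))
}

#' Partition the first 60 s of the seizure into four 15 s sub-periods
#'
#' @param onset_s Ictal onset (s).
#' @param recording_end_s End of the recording (s); the full 60 s must fit.
#' @return Interval tibble with rows `I1`-`I4`, each exactly 15 s.
#' @export
partition_ictal <- function(onset_s, recording_end_s = Inf) {
  if (onset_s + 60 > recording_end_s) {
    abort("recording ends before the 60 s ictal period is complete",
          class = "preictal_truncated_ictal")
  }
  starts <- onset_s + 15 * 0:3
  interval_tbl(starts, starts + 15, name = paste0("I", 1:4))
}

#' Remove laser-pulse epochs from analysis periods
#'
#' Spontaneous-activity metrics must not include light-evoked activity, so
#' a guard window around every pulse is cut out of each period and the
#' effective duration is reduced accordingly. The removed window per pulse
#' is `[onset - guard_s/2, onset + duration + guard_s/2)`, i.e. the total
#' removed time per isolated pulse is `duration + guard_s`.
#'
#' @param periods Interval tibble with a `name` column.
#' @param pulses Pulse tibble (`onset_s`, `duration_s`, ...).
#' @param guard_s Total guard time added around each pulse (s).
#' @return Tibble with one row per period: `name`, `start_s`, `end_s`,
#'   `effective_duration_s`, and a `mask` list-column of kept sub-intervals.
#' @export
exclude_pulse_epochs <- function(periods, pulses, guard_s = 1) {
  remove <- if (nrow(pulses) == 0) {
    interval_tbl(numeric(0), numeric(0))
  } else {
    interval_tbl(pulses$onset_s - guard_s / 2,
                 pulses$onset_s + pulses$duration_s + guard_s / 2)
  }
  masks <- purrr::map(seq_len(nrow(periods)), function(i) {
    interval_subtract(periods[i, c("start_s", "end_s")], remove)
  })
  tibble::tibble(
    name = periods$name,
    start_s = periods$start_s,
    end_s = periods$end_s,
    effective_duration_s = purrr::map_dbl(masks, interval_duration),
    mask = masks
  )
}

#' Quiescence intervals from a wheel-speed trace
#'
#' Simple speed-threshold mask: maximal intervals over which the sampled
#' wheel speed stays below `threshold`. This is a deliberate stand-in for
#' change-point-based locomotion segmentation, which is out of scope.
#'
#' @param wheel Tibble with columns `time_s`, `speed`, or `NULL`.
#' @param threshold Speed threshold (same units as `speed`).
#' @param recording_end_s Used to close the final interval.
#' @return Interval tibble of quiescent periods. With `wheel = NULL`, one
#'   interval covering the whole recording is returned with a warning.
#' @export
mask_quiescence <- function(wheel, threshold = 1, recording_end_s = NULL) {
  if (is.null(wheel) || nrow(wheel) == 0) {
    warn("no wheel data: treating the entire recording as quiescent")
    end_s <- recording_end_s %||% Inf
    return(interval_tbl(0, end_s))
  }
  quiet <- wheel$speed < threshold
  if (!any(quiet)) return(interval_tbl(numeric(0), numeric(0)))
  dt <- if (nrow(wheel) > 1) median(diff(wheel$time_s)) else 0
  end_default <- wheel$time_s[nrow(wheel)] + dt
  r <- rle(quiet)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1
  keep <- which(r$values)
  start_s <- wheel$time_s[starts_i[keep]]
  end_s <- purrr::map_dbl(ends_i[keep], function(j) {
    if (j < nrow(wheel)) wheel$time_s[j + 1] else recording_end_s %||% end_default
  })
  interval_tbl(start_s, end_s)
}

#' Assemble the full period set for a session
#'
#' Runs onset detection against the pre-injection baseline, partitions the
#' preictal and ictal spans, and removes pulse epochs from every period.
#'
#' @param session An `ephys_session`.
#' @param z_threshold,min_duration_ms Onset-detection settings.
#' @param guard_s Pulse guard passed to [exclude_pulse_epochs()].
#' @return List of class `period_set`: `periods` (masked period tibble
#'   including `baseline`), `onset_s`, `injection_time_s`, `z_threshold`,
#'   `detection` (the [detect_ictal_onset()] row).
#' @export
build_period_set <- function(session, z_threshold = 5, min_duration_ms = 10,
                             guard_s = 1) {
  stopifnot(inherits(session, "ephys_session"))
  baseline <- interval_tbl(0, session$injection_time_s, name = "baseline")
  det <- detect_ictal_onset(session$lfp, baseline, session$injection_time_s,
                            z_threshold = z_threshold,
                            min_duration_ms = min_duration_ms)
  if (!det$detected) {
    abort("no ictal onset detected; cannot build period set",
          class = "preictal_no_onset")
  }
  periods <- dplyr::bind_rows(
    baseline,
    partition_preictal(session$injection_time_s, det$onset_s),
    partition_ictal(det$onset_s, recording_end_s = session$duration_s)
  )
  masked <- exclude_pulse_epochs(periods, session$pulses, guard_s = guard_s)
  structure(
    list(periods = masked, onset_s = det$onset_s,
         injection_time_s = session$injection_time_s,
         z_threshold = z_threshold, detection = det),
    class = "period_set"
  )
}

#' @export
print.period_set <- function(x, ...) {
  cat(sprintf("<period_set: onset %.3f s, injection %.1f s>\n",
              x$onset_s, x$injection_time_s))
  print(x$periods[, c("name", "start_s", "end_s", "effective_duration_s")])
  invisible(x)
}
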