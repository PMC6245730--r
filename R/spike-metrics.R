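# Firing-rate trajectories and temporal-patterning statistics per unit and
# per analysis period.

#' Mean firing rate within a (possibly masked) period
#'
#' Number of spikes falling inside the period's mask divided by the
#' effective duration.
#'
#' @param spikes Numeric vector of spike times (s).
#' @param mask Interval tibble of the kept sub-intervals of the period.
#' @param effective_duration_s Total mask duration; defaults to the mask's.
#' @return Rate in Hz; `NaN` when the effective duration is zero.
#' @export
mean_firing_rate <- function(spikes, mask,
                             effective_duration_s = interval_duration(mask)) {
  if (effective_duration_s <= 0) return(NaN)
  sum(in_intervals(spikes, mask)) / effective_duration_s
}

#' Coefficient of local variation (LV) of inter-spike intervals
#'
#' `LV = 3/(n-1) * sum_i ((ISI_i - ISI_{i+1}) / (ISI_i + ISI_{i+1}))^2`
#' over the `n` intervals of a train. LV is 1 for Poisson firing, below 1
#' for regular firing and above 1 for bursty/irregular firing, and is
#' robust to slow rate changes. For a gamma-renewal train with shape
#' `kappa`, `E[LV] = 3 / (2 * kappa + 1)`.
#'
#' @param isis Numeric vector of inter-spike intervals (any time unit).
#' @return LV; `NaN` with fewer than 2 ISIs.
#' @export
#' @examples
#' local_variation(diff(simulate_renewal_train(20, 1, 100, seed = 1))) # ~1
local_variation <- function(isis) {
  n <- length(isis)
  if (n < 2) return(NaN)
  d <- (isis[-n] - isis[-1]) / (isis[-n] + isis[-1])
  3 / (n - 1) * sum(d^2)
}

#' Log-ratio of short to long inter-spike intervals
#'
#' `log10` of the fraction of ISIs in `[2, 10)` ms over the fraction in
#' `[10, 100)` ms — a burstiness index: positive values indicate a
#' preponderance of short, burst-like intervals.
#'
#' @param isis ISIs in seconds.
#' @param short_ms,long_ms Band edges in ms (half-open bands
#'   `[short_ms[1], short_ms[2])` and `[long_ms[1], long_ms[2])`).
#' @return log10 ratio; `NaN` with a warning when either band is empty.
#' @export
isi_log_ratio <- function(isis, short_ms = c(2, 10), long_ms = c(10, 100)) {
  ms <- isis * 1000
  n_short <- sum(ms >= short_ms[1] & ms < short_ms[2])
  n_long <- sum(ms >= long_ms[1] & ms < long_ms[2])
  if (n_short == 0 || n_long == 0) {
    warn("empty ISI band; log ratio undefined")
    return(NaN)
  }
  log10(n_short / n_long)
}

#' Per-period change in firing rate relative to baseline
#'
#' Units whose baseline rate is below `min_baseline_hz` are excluded
#' (low-rate units make per-period changes unreliable). The change is the
#' difference in Hz by default; a normalised ratio
#' `(rate - baseline) / baseline` is also available.
#'
#' @param rates Tibble in long format with columns `unit_id`, `period`,
#'   `rate` and one `baseline` row per unit (`period == "baseline"`).
#' @param min_baseline_hz Baseline inclusion threshold (default 0.1 Hz).
#' @param method `"difference"` (Hz) or `"ratio"` (dimensionless).
#' @return Tibble `unit_id`, `period`, `rate`, `baseline_rate`, `change`,
#'   with excluded units dropped.
#' @export
rate_change_vs_baseline <- function(rates, min_baseline_hz = 0.1,
                                    method = c("difference", "ratio")) {
  method <- match.arg(method)
  base <- rates |>
    dplyr::filter(.data$period == "baseline") |>
    dplyr::select("unit_id", baseline_rate = "rate")
  out <- rates |>
    dplyr::filter(.data$period != "baseline") |>
    dplyr::inner_join(base, by = "unit_id") |>
    dplyr::filter(.data$baseline_rate >= min_baseline_hz)
  out$change <- switch(method,
    difference = out$rate - out$baseline_rate,
    ratio = (out$rate - out$baseline_rate) / out$baseline_rate
  )
  out
}

# ISIs within one masked period: intervals are formed only between
# consecutive spikes inside the same kept sub-interval, so no ISI spans a
# period boundary or an excised pulse epoch.
period_isis <- function(spikes, mask) {
  unlist(purrr::pmap(mask[, c("start_s", "end_s")], function(start_s, end_s) {
    s <- spikes[spikes >= start_s & spikes < end_s]
    if (length(s) < 2) numeric(0) else diff(s)
  }))
}

#' Per-unit, per-period spike metrics for a session
#'
#' Computes the mean firing rate, LV and ISI log-ratio for every unit in
#' every analysis period (pulse epochs excluded via the period masks).
#'
#' @param session An `ephys_session`.
#' @param period_set A [build_period_set()] result.
#' @return Long tibble: `unit_id`, `cell_type`, `period`, `rate`, `lv`,
#'   `isi_log_ratio`, `n_spikes`, `effective_duration_s`.
#' @export
spike_metrics <- function(session, period_set) {
  periods <- period_set$periods
  grid <- tidyr::expand_grid(
    unit_i = seq_len(nrow(session$units)),
    period_i = seq_len(nrow(periods))
  )
  purrr::pmap(grid, function(unit_i, period_i) {
    u <- session$units[unit_i, ]
    p <- periods[period_i, ]
    spikes <- u$spike_times[[1]]
    mask <- p$mask[[1]]
    isis <- period_isis(spikes, mask)
    tibble::tibble(
      unit_id = u$unit_id, cell_type = u$cell_type, period = p$name,
      rate = mean_firing_rate(spikes, mask, p$effective_duration_s),
      lv = local_variation(isis),
      isi_log_ratio = suppressWarnings(isi_log_ratio(isis)),
      n_spikes = sum(in_intervals(spikes, mask)),
      effective_duration_s = p$effective_duration_s
    )
  }) |>
    dplyr::bind_rows()
}
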