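# End-to-end orchestration: onset detection -> periods -> unit
# classification -> per-period metrics -> spike-field coherence -> opto
# input-output fits -> RS modulation -> group statistics.

#' Run the full analysis pipeline on a session
#'
#' @param session An `ephys_session`.
#' @param stages Character vector of stages to run; `"rates"` and the
#'   period/unit bookkeeping always run.
#' @param z_threshold,min_duration_ms,guard_s Onset/period settings (see
#'   [build_period_set()]).
#' @param sfc_band,sfc_step Band and frequency step for the per-period
#'   spike-field coherence summary.
#' @param sfc_max_spikes Per-period spike cap for PPC (PPC is unbiased by
#'   spike count; capping bounds run time).
#' @param seed Seed for subsampling and fit restarts.
#' @return Object of class `ictal_analysis`: list of tibbles (`unit_table`,
#'   `periods`, `metrics`, `rate_changes`, `sfc`, `opto_fits`,
#'   `intensity_levels`, `modulation`, `contrasts`, `fraction_tests`) plus
#'   `onset_s` and the settings used.
#' @export
analyze_session <- function(session,
                            stages = c("rates", "sfc", "opto",
                                       "modulation", "stats"),
                            z_threshold = 5, min_duration_ms = 10,
                            guard_s = 1, sfc_band = c(20, 28), sfc_step = 2,
                            sfc_max_spikes = 200, seed = 1L) {
  period_set <- build_period_set(session, z_threshold = z_threshold,
                                 min_duration_ms = min_duration_ms,
                                 guard_s = guard_s)
  unit_table <- classify_units(session)
  metrics <- spike_metrics(session, period_set)
  out <- list(
    onset_s = period_set$onset_s,
    detection = period_set$detection,
    periods = period_set$periods[, c("name", "start_s", "end_s",
                                     "effective_duration_s")],
    unit_table = unit_table,
    metrics = metrics,
    settings = list(z_threshold = z_threshold,
                    min_duration_ms = min_duration_ms, guard_s = guard_s,
                    sfc_band = sfc_band, sfc_step = sfc_step,
                    sfc_max_spikes = sfc_max_spikes, seed = seed)
  )
  if ("rates" %in% stages) {
    rates <- metrics[, c("unit_id", "cell_type", "period", "rate")]
    out$rate_changes <- rate_change_vs_baseline(rates)
  }
  if ("sfc" %in% stages) {
    out$sfc <- sfc_by_period(session, period_set, band = sfc_band,
                             step = sfc_step, max_spikes = sfc_max_spikes,
                             seed = seed)
  }
  if ("opto" %in% stages && nrow(session$pulses) > 0) {
    opto <- opto_stage(session, unit_table, seed = seed)
    out$opto_fits <- opto$fits
    out$intensity_levels <- opto$levels
    if ("modulation" %in% stages) {
      out$modulation <- modulation_stage(session, unit_table, opto$levels)
    }
  }
  if ("stats" %in% stages) {
    out$contrasts <- dplyr::bind_rows(
      dplyr::mutate(period_contrasts(metrics, "rate"), metric = "rate"),
      dplyr::mutate(period_contrasts(metrics, "lv"), metric = "lv")
    )
    out$fraction_tests <- fraction_stage(metrics)
  }
  structure(out, class = "ictal_analysis")
}

# Mean PPC in the coherence band per unit and period (baseline + preictal).
sfc_by_period <- function(session, period_set, band = c(20, 28), step = 2,
                          max_spikes = 200, seed = 1L) {
  freqs <- seq(band[1], band[2], by = step)
  periods <- period_set$periods
  periods <- periods[periods$name %in% c("baseline", paste0("P", 1:4)), ]
  grid <- tidyr::expand_grid(unit_i = seq_len(nrow(session$units)),
                             period_i = seq_len(nrow(periods)))
  purrr::pmap(grid, function(unit_i, period_i) {
    u <- session$units[unit_i, ]
    p <- periods[period_i, ]
    spikes <- u$spike_times[[1]]
    spikes <- spikes[in_intervals(spikes, p$mask[[1]])]
    spec <- sfc_spectrum(session$lfp, spikes, freqs,
                         max_spikes = max_spikes, seed = seed)
    tibble::tibble(
      unit_id = u$unit_id, cell_type = u$cell_type, period = p$name,
      band_ppc = sfc_band_summary(spec, band),
      n_spikes = min(length(spikes), max_spikes)
    )
  }) |>
    dplyr::bind_rows()
}

# Sigmoid input-output fit per tagged unit; intensity levels from the
# average response curve of the tagged population (the "simultaneously
# driven" cells).
opto_stage <- function(session, unit_table, seed = 1L) {
  tagged_ids <- unit_table$unit_id[unit_table$is_tagged]
  tagged <- session$units[session$units$unit_id %in% tagged_ids, ]
  if (nrow(tagged) == 0) {
    return(list(fits = tibble::tibble(), levels = NULL))
  }
  prob_tables <- purrr::map(tagged$spike_times, pulse_spike_probability,
                            pulses = session$pulses)
  fits <- purrr::map2(tagged$unit_id, prob_tables, function(id, tbl) {
    fit <- fit_sigmoid(tbl, seed = seed)
    dplyr::bind_cols(tibble::tibble(unit_id = id),
                     tidyr::pivot_wider(tidy(fit), names_from = "term",
                                        values_from = "estimate"),
                     glance(fit))
  }) |>
    dplyr::bind_rows()
  mean_curve <- dplyr::bind_rows(prob_tables) |>
    dplyr::summarise(probability = mean(.data$probability),
                     .by = "intensity")
  levels <- classify_intensity_levels(mean_curve)
  list(fits = fits, levels = levels)
}

# Pulse-triggered RS modulation at the medium and high intensity levels.
modulation_stage <- function(session, unit_table, levels) {
  if (is.null(levels)) return(tibble::tibble())
  rs_ids <- unit_table$unit_id[unit_table$label == "RS"]
  rs <- session$units[session$units$unit_id %in% rs_ids, ]
  classes <- tibble::tibble(
    intensity_class = c("medium", "high"),
    intensity = c(levels$medium, levels$high)
  )
  grid <- tidyr::expand_grid(unit_i = seq_len(nrow(rs)),
                             class_i = seq_len(nrow(classes)))
  purrr::pmap(grid, function(unit_i, class_i) {
    u <- rs[unit_i, ]
    cl <- classes[class_i, ]
    pulses <- session$pulses[session$pulses$intensity == cl$intensity, ]
    dplyr::bind_cols(
      tibble::tibble(unit_id = u$unit_id,
                     intensity_class = cl$intensity_class,
                     intensity = cl$intensity),
      modulation_index(u$spike_times[[1]], pulses)
    )
  }) |>
    dplyr::bind_rows()
}

# Fraction-of-cells-increasing tests per cell type: last preictal period
# vs the first and vs the third.
fraction_stage <- function(metrics) {
  wide <- metrics |>
    dplyr::select("unit_id", "cell_type", "period", "rate") |>
    tidyr::pivot_wider(names_from = "period", values_from = "rate")
  purrr::map(split(wide, wide$cell_type), function(d) {
    purrr::map(c("P1", "P3"), function(ref) {
      if (!all(c(ref, "P4") %in% names(d))) return(NULL)
      res <- fraction_increased(d[[ref]], d$P4)
      dplyr::bind_cols(
        tibble::tibble(cell_type = d$cell_type[1],
                       contrast = paste0("P4_vs_", ref)),
        res
      )
    }) |>
      purrr::compact() |>
      dplyr::bind_rows()
  }) |>
    dplyr::bind_rows()
}

#' @export
print.ictal_analysis <- function(x, ...) {
  cat(sprintf("<ictal_analysis: onset %.3f s, %d units>\n",
              x$onset_s, nrow(x$unit_table)))
  cat("tables:", paste(names(x)[purrr::map_lgl(x, is.data.frame)],
                       collapse = ", "), "\n")
  invisible(x)
}

#' One-row summary of a session analysis
#' @param x An `ictal_analysis`.
#' @param ... Unused.
#' @return Tibble: `onset_s`, `z_at_onset`, `n_units`, `n_tagged`, `n_rs`,
#'   `n_pulses_analyzed`.
#' @method glance ictal_analysis
#' @export
glance.ictal_analysis <- function(x, ...) {
  tibble::tibble(
    onset_s = x$onset_s,
    z_at_onset = x$detection$z_at_onset,
    n_units = nrow(x$unit_table),
    n_tagged = sum(x$unit_table$is_tagged),
    n_rs = sum(x$unit_table$label == "RS"),
    n_pulses_analyzed = if (is.null(x$modulation)) 0L else
      sum(x$modulation$n_pulses[!duplicated(x$modulation$intensity_class)])
  )
}

#' Long tidy table of all per-unit, per-period metrics
#' @param x An `ictal_analysis`.
#' @param ... Unused.
#' @return Long tibble: `unit_id`, `cell_type`, `period`, `metric`, `value`.
#' @method tidy ictal_analysis
#' @export
tidy.ictal_analysis <- function(x, ...) {
  x$metrics |>
    tidyr::pivot_longer(cols = c("rate", "lv", "isi_log_ratio"),
                        names_to = "metric", values_to = "value") |>
    dplyr::select("unit_id", "cell_type", "period", "metric", "value")
}

# Tables of an analysis suitable for write_results().
analysis_tables <- function(analysis) {
  keep <- purrr::keep(unclass(analysis), is.data.frame)
  keep$detection <- NULL
  keep
}

#' Write an analysis to a results directory
#'
#' Thin wrapper around [write_results()] that serialises every table of an
#' [analyze_session()] result and echoes the settings (thresholds, seed)
#' into the manifest.
#'
#' @param analysis An `ictal_analysis`.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_analysis <- function(analysis, path) {
  write_results(analysis_tables(analysis), path,
                config = c(analysis$settings, list(onset_s = analysis$onset_s)))
}
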