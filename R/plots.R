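# ggplot2 figure methods for the package's result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_hline geom_boxplot facet_wrap labs scale_fill_viridis_c
#'   stat_summary theme_minimal
NULL

#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance

#' Plot a spike-field coherence spectrum
#' @param object A `ppc_spectrum` from [sfc_spectrum()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ppc_spectrum
#' @export
autoplot.ppc_spectrum <- function(object, ...) {
  ggplot(object, aes(x = .data$frequency, y = .data$ppc)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    geom_line() +
    geom_point() +
    labs(x = "Frequency (Hz)", y = "PPC",
         title = "Spike-field coherence (pairwise phase consistency)") +
    theme_minimal()
}

#' Plot a sigmoid input-output fit over its data
#' @param object A `sigmoid_fit` from [fit_sigmoid()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sigmoid_fit
#' @export
autoplot.sigmoid_fit <- function(object, ...) {
  rng <- range(object$data$intensity)
  curve <- tibble::tibble(
    intensity = seq(rng[1], rng[2], length.out = 200),
    probability = sigmoid_response(seq(rng[1], rng[2], length.out = 200),
                                   object$B, object$S, object$c, object$A)
  )
  ggplot(object$data, aes(x = .data$intensity, y = .data$probability)) +
    geom_line(data = curve, colour = "steelblue") +
    geom_point() +
    labs(x = expression("Laser intensity (mW/mm"^2 * ")"),
         y = "Spike probability",
         title = sprintf("Sigmoid fit: c50 = %.2f, slope = %.2f, Rmax = %.2f",
                         object$c, object$slope, object$Rmax)) +
    theme_minimal()
}

#' Plot an LFP spectrogram
#' @param object An `lfp_spectrogram` from [lfp_spectrogram()].
#' @param ... Unused.
#' @return A ggplot (tile heat map of normalised log10 power).
#' @method autoplot lfp_spectrogram
#' @export
autoplot.lfp_spectrogram <- function(object, ...) {
  df <- tidyr::expand_grid(frequency = object$frequency,
                           time_s = object$time_s)
  df$power <- as.vector(t(object$power))
  ggplot(df, aes(x = .data$time_s, y = .data$frequency,
                 fill = .data$power)) +
    geom_tile() +
    scale_fill_viridis_c(name = "log10 power") +
    labs(x = "Time (s)", y = "Frequency (Hz)") +
    theme_minimal()
}

#' Per-period firing-rate change trajectories by cell type
#'
#' Mean change in firing rate versus baseline over the preictal (and ictal)
#' periods, one line per cell type, with per-unit points.
#'
#' @param metrics Long tibble from [spike_metrics()] (or
#'   `analysis$metrics`).
#' @param periods Which periods to show (default preictal quartiles).
#' @return A ggplot.
#' @export
plot_rate_trajectories <- function(metrics, periods = paste0("P", 1:4)) {
  rates <- metrics[, c("unit_id", "cell_type", "period", "rate")]
  changes <- rate_change_vs_baseline(rates)
  changes <- changes[changes$period %in% periods, ]
  changes$period <- factor(changes$period, levels = periods)
  ggplot(changes, aes(x = .data$period, y = .data$change,
                      colour = .data$cell_type, group = .data$cell_type)) +
    geom_point(alpha = 0.4, position = ggplot2::position_dodge(0.3)) +
    stat_summary(fun = mean, geom = "line") +
    stat_summary(fun = mean, geom = "point", size = 3) +
    labs(x = "Preictal period", y = "Rate change vs baseline (Hz)",
         colour = "Cell type") +
    theme_minimal()
}

#' Pulse-triggered modulation of RS firing by intensity class
#' @param modulation Modulation tibble from [analyze_session()].
#' @return A ggplot.
#' @export
plot_modulation <- function(modulation) {
  ggplot(modulation, aes(x = .data$intensity_class, y = .data$y)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    geom_boxplot(width = 0.4, outlier.shape = NA) +
    geom_point(position = ggplot2::position_jitter(width = 0.08)) +
    labs(x = "Pulse intensity class",
         y = expression(y == (FR[post] - FR[pre]) / (FR[post] + FR[pre]))) +
    theme_minimal()
}
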