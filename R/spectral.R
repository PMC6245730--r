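# Spike-field coherence via pairwise phase consistency (PPC), LFP band
# power, and wavelet-style spectrograms. All spectral estimates use
# Hanning-tapered windows whose length is a fixed number of cycles of the
# target frequency (default 7), so spectral smoothing is proportional to
# frequency.

hanning_taper <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

#' Spike-LFP phases at one frequency
#'
#' For every spike, a Hanning-tapered LFP segment of `cycles / frequency`
#' seconds centred on the spike is Fourier-transformed at the target
#' frequency and the phase is the argument of that coefficient. Spikes
#' whose window does not fit inside the recording are dropped.
#'
#' @param lfp An [lfp_signal()].
#' @param spikes Spike times (s).
#' @param frequency Target frequency (Hz), below Nyquist.
#' @param cycles Window length in cycles of `frequency` (default 7).
#' @return Numeric vector of phases (radians) with attribute `n_dropped`.
#' @export
spike_phases <- function(lfp, spikes, frequency, cycles = 7) {
  stopifnot(inherits(lfp, "lfp_signal"))
  if (frequency >= lfp$fs / 2) {
    abort("frequency must be below Nyquist", class = "preictal_invalid_parameter")
  }
  n_win <- max(3L, round(cycles / frequency * lfp$fs))
  half <- (n_win - 1) / 2
  centers <- round((spikes - lfp$start_s) * lfp$fs) + 1
  first <- centers - floor(half)
  ok <- first >= 1 & (first + n_win - 1) <= length(lfp$samples)
  taper <- hanning_taper(n_win)
  osc <- exp(-1i * 2 * pi * frequency * (seq_len(n_win) - 1) / lfp$fs)
  kernel <- taper * osc
  phases <- purrr::map_dbl(first[ok], function(i) {
    Arg(sum(lfp$samples[i:(i + n_win - 1)] * kernel))
  })
  attr(phases, "n_dropped") <- sum(!ok)
  phases
}

#' Pairwise phase consistency (PPC)
#'
#' The mean cosine of the phase differences over all spike pairs:
#' `PPC = 2/(n(n-1)) * sum_{j<k} cos(theta_j - theta_k)`. Unlike the
#' resultant-length statistic, its expectation does not depend on the
#' number of spikes. Computed via the O(n) identity
#' `(|sum e^{i theta}|^2 - n) / (n (n - 1))`, which is algebraically equal
#' to the pairwise sum.
#'
#' @param phases Phases in radians (n >= 2).
#' @return PPC in `[-1, 1]`; `NaN` for fewer than 2 phases.
#' @export
#' @examples
#' ppc(c(0, 0, 0)) # 1
#' ppc(c(0, pi)) # -1
ppc <- function(phases) {
  n <- length(phases)
  if (n < 2) return(NaN)
  (Mod(sum(exp(1i * phases)))^2 - n) / (n * (n - 1))
}

#' Spike-field coherence spectrum
#'
#' PPC as a function of frequency, with an optional cap on the number of
#' spikes used (PPC is unbiased by spike count, so subsampling changes only
#' the variance).
#'
#' @param lfp An [lfp_signal()].
#' @param spikes Spike times (s).
#' @param frequencies Frequency grid (Hz), all below Nyquist.
#' @param cycles Window length in cycles (default 7).
#' @param max_spikes Optional cap; spikes are subsampled deterministically
#'   given `seed` when exceeded.
#' @param seed Seed for the subsampling draw.
#' @return Tibble of class `ppc_spectrum`: `frequency`, `ppc`, `n_spikes`.
#' @export
sfc_spectrum <- function(lfp, spikes, frequencies, cycles = 7,
                         max_spikes = NULL, seed = NULL) {
  if (any(frequencies >= lfp$fs / 2)) {
    abort("frequencies must be below Nyquist",
          class = "preictal_invalid_parameter")
  }
  if (!is.null(max_spikes) && length(spikes) > max_spikes) {
    spikes <- with_seed_if(seed %||% 1L,
                           sort(sample(spikes, max_spikes)))
  }
  rows <- purrr::map(frequencies, function(f) {
    ph <- spike_phases(lfp, spikes, f, cycles = cycles)
    tibble::tibble(frequency = f, ppc = ppc(ph), n_spikes = length(ph))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ppc_spectrum", class(out))
  out
}

#' Mean PPC over a frequency band
#'
#' Unweighted mean of the PPC across the spectrum bins inside the band.
#' The band is closed (`[lo, hi]`), so the canonical 20-28 Hz summary
#' includes both edge frequencies.
#'
#' @param spectrum A [sfc_spectrum()] result.
#' @param band Two-element band in Hz (default `c(20, 28)`).
#' @return Mean PPC over in-band frequencies (`NaN` when none).
#' @export
sfc_band_summary <- function(spectrum, band = c(20, 28)) {
  sel <- spectrum$frequency >= band[1] & spectrum$frequency <= band[2]
  if (!any(sel)) return(NaN)
  mean(spectrum$ppc[sel])
}

#' LFP power in a frequency band
#'
#' The signal is split into non-overlapping segments (default 1 s), each is
#' Hanning-tapered and Fourier-transformed, power is averaged over the DFT
#' bins inside the band (edges inclusive), and then over segments.
#'
#' @param lfp An [lfp_signal()].
#' @param band Two-element band in Hz (default `c(20, 28)`).
#' @param segment_s Segment length in seconds (default 1).
#' @return Mean band power (uV^2-scale, unnormalised); `NaN` when the
#'   recording is shorter than one segment.
#' @export
band_power <- function(lfp, band = c(20, 28), segment_s = 1) {
  n_seg_len <- round(segment_s * lfp$fs)
  n_seg <- floor(length(lfp$samples) / n_seg_len)
  if (n_seg < 1) return(NaN)
  taper <- hanning_taper(n_seg_len)
  freqs <- (seq_len(n_seg_len) - 1) * lfp$fs / n_seg_len
  sel <- freqs >= band[1] & freqs <= band[2]
  if (!any(sel)) {
    abort("band contains no DFT bins at this segment length",
          class = "preictal_invalid_parameter")
  }
  seg_power <- purrr::map_dbl(seq_len(n_seg), function(k) {
    x <- lfp$samples[((k - 1) * n_seg_len + 1):(k * n_seg_len)]
    mean(Mod(fft(taper * x))[sel]^2)
  })
  mean(seg_power)
}

#' Time-frequency spectrogram of the LFP
#'
#' Convolution of the signal with complex oscillations tapered by a Hanning
#' window of 7 cycles per frequency (a wavelet-style transform with
#' frequency-proportional bandwidth). Power is normalised by the summed
#' power over all returned time-frequency bins and reported as base-10 log,
#' so `sum(10^power) == 1`.
#'
#' @param lfp An [lfp_signal()].
#' @param frequencies Frequency grid (Hz), below Nyquist.
#' @param cycles Cycles per frequency (default 7).
#' @param time_step_s Optional decimation step of the time axis (s);
#'   default keeps every sample.
#' @return List of class `lfp_spectrogram`: `time_s`, `frequency`, `power`
#'   (frequency x time matrix of normalised log10 power).
#' @export
lfp_spectrogram <- function(lfp, frequencies, cycles = 7, time_step_s = NULL) {
  if (any(frequencies >= lfp$fs / 2)) {
    abort("frequencies must be below Nyquist",
          class = "preictal_invalid_parameter")
  }
  n <- length(lfp$samples)
  t <- lfp_times(lfp)
  keep <- if (is.null(time_step_s)) {
    seq_len(n)
  } else {
    seq(1, n, by = max(1, round(time_step_s * lfp$fs)))
  }
  power <- matrix(NA_real_, nrow = length(frequencies), ncol = length(keep))
  for (fi in seq_along(frequencies)) {
    f <- frequencies[fi]
    n_win <- max(3L, round(cycles / f * lfp$fs))
    taper <- hanning_taper(n_win)
    kern <- taper * exp(1i * 2 * pi * f * (seq_len(n_win) - 1) / lfp$fs)
    kern <- kern / sum(taper)
    L <- stats::nextn(n + n_win - 1, 2)
    conv <- fft(fft(c(lfp$samples, rep(0, L - n))) *
                  fft(c(kern, rep(0, L - n_win))), inverse = TRUE) / L
    centre <- conv[seq_len(n) + floor((n_win - 1) / 2)]
    power[fi, ] <- Mod(centre[keep])^2
  }
  power <- power / sum(power)
  structure(
    list(time_s = t[keep], frequency = frequencies, power = log10(power)),
    class = "lfp_spectrogram"
  )
}

#' @export
print.lfp_spectrogram <- function(x, ...) {
  cat(sprintf("<lfp_spectrogram: %d frequencies x %d time bins>\n",
              length(x$frequency), length(x$time_s)))
  invisible(x)
}
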