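# Input-output characterisation of light-driven interneurons (sigmoid fit
# of spike probability vs laser intensity, minimising the L1 norm over 64
# random restarts) and pulse-triggered suppression of RS cells.

#' Sigmoid input-output curve
#'
#' `p(I) = B + S / (1 + exp(-(I - c) / A))`, clipped to `[0, 1]`: `B` is
#' the baseline offset, `S` the scale, `c` the half-maximum intensity
#' (c50) and `1/A` the slope.
#'
#' @param intensity Laser intensity (mW/mm^2), vectorised.
#' @param B,S,c,A Curve parameters (`A > 0`).
#' @return Spike probability in `[0, 1]`.
#' @export
sigmoid_response <- function(intensity, B, S, c, A) {
  pmin(1, pmax(0, B + S / (1 + exp(-(intensity - c) / A))))
}

#' Empirical spike probability per pulse intensity
#'
#' Fraction of pulses followed by at least one spike in the response window
#' (default 2-15 ms after pulse onset), per tested intensity.
#'
#' @param spikes Spike times (s).
#' @param pulses Pulse tibble (`onset_s`, `intensity`, ...).
#' @param window Response window after onset (s), half-open.
#' @return Tibble: `intensity`, `n_pulses`, `n_responses`, `probability`.
#' @export
pulse_spike_probability <- function(spikes, pulses,
                                    window = c(0.002, 0.015)) {
  if (nrow(pulses) == 0) {
    abort("no pulses", class = "preictal_invalid_input")
  }
  hit <- purrr::map_lgl(pulses$onset_s, function(on) {
    any(spikes >= on + window[1] & spikes < on + window[2])
  })
  tibble::tibble(intensity = pulses$intensity, hit = hit) |>
    dplyr::summarise(
      n_pulses = dplyr::n(),
      n_responses = sum(.data$hit),
      probability = mean(.data$hit),
      .by = "intensity"
    ) |>
    dplyr::arrange(.data$intensity)
}

#' Fit the sigmoid input-output curve by L1 minimisation
#'
#' Minimises the sum of absolute deviations between the clipped sigmoid and
#' the observed per-intensity probabilities with derivative-free
#' Nelder-Mead search, restarted from 64 random initialisations (`B` in
#' `[0, 0.5]`, `S` in `[0, 1]`, `c` spanning the tested range, `A` in
#' `[0.01, range]`); the restart with the lowest L1 error wins, ties going
#' to the first found. `Rmax` is the fitted probability at the maximum
#' tested intensity and the slope is `1/A`.
#'
#' @param prob_table Tibble from [pulse_spike_probability()] (columns
#'   `intensity`, `probability`), with >= 4 distinct intensities.
#' @param n_restarts Number of random initialisations (default 64).
#' @param seed Seed for the restart draws (default 1).
#' @return Object of class `sigmoid_fit`: list with `B`, `S`, `c`, `A`,
#'   `slope`, `Rmax`, `l1_error`, `n_restarts_used`, `data`.
#' @export
#' @examples
#' tbl <- tibble::tibble(intensity = 1:8,
#'                       probability = sigmoid_response(1:8, 0, 1, 5, 1))
#' fit <- fit_sigmoid(tbl)
#' tidy(fit)
fit_sigmoid <- function(prob_table, n_restarts = 64, seed = 1L) {
  iv <- prob_table$intensity
  pv <- prob_table$probability
  if (length(unique(iv)) < 4) {
    abort("need >= 4 distinct intensities to fit the sigmoid",
          class = "preictal_underdetermined_fit")
  }
  rng <- range(iv)
  span <- max(rng[2] - rng[1], .Machine$double.eps)
  objective <- function(par) {
    if (par[4] <= 0) return(1e6 + abs(par[4]))
    sum(abs(sigmoid_response(iv, par[1], par[2], par[3], par[4]) - pv))
  }
  best <- NULL
  with_seed_if(seed, {
    starts <- matrix(
      c(runif(n_restarts, 0, 0.5), runif(n_restarts, 0, 1),
        runif(n_restarts, rng[1], rng[2]), runif(n_restarts, 0.01, span)),
      ncol = 4
    )
    for (k in seq_len(n_restarts)) {
      fit <- optim(starts[k, ], objective, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  })
  par <- best$par
  structure(
    list(
      B = par[1], S = par[2], c = par[3], A = par[4],
      slope = 1 / par[4],
      Rmax = sigmoid_response(rng[2], par[1], par[2], par[3], par[4]),
      l1_error = best$value, n_restarts_used = n_restarts,
      data = tibble::as_tibble(prob_table)
    ),
    class = "sigmoid_fit"
  )
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "<sigmoid_fit: B=%.3f S=%.3f c50=%.3f A=%.3f (slope %.3f), Rmax=%.3f, L1=%.4f>\n",
    x$B, x$S, x$c, x$A, x$slope, x$Rmax, x$l1_error))
  invisible(x)
}

#' Tidy a sigmoid input-output fit
#' @param x A `sigmoid_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`).
#' @method tidy sigmoid_fit
#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble::tibble(
    term = c("B", "S", "c", "A", "slope", "Rmax"),
    estimate = c(x$B, x$S, x$c, x$A, x$slope, x$Rmax)
  )
}

#' One-row summary of a sigmoid input-output fit
#' @param x A `sigmoid_fit`.
#' @param ... Unused.
#' @return Tibble: `l1_error`, `n_restarts_used`, `n_levels`.
#' @method glance sigmoid_fit
#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble::tibble(l1_error = x$l1_error, n_restarts_used = x$n_restarts_used,
                 n_levels = nrow(x$data))
}

#' Select medium- and high-intensity pulse levels
#'
#' The medium level is the tested intensity whose driven-cell spike
#' probability is nearest 0.5 (ties to the lower intensity); the high level
#' is the intensity with the maximum probability (ties to the largest
#' intensity). When all probabilities are equal the choice is ambiguous: a
#' warning is raised and the maximum intensity is returned for both.
#'
#' @param prob_table Tibble from [pulse_spike_probability()].
#' @return One-row tibble: `medium`, `high` (intensities).
#' @export
classify_intensity_levels <- function(prob_table) {
  iv <- prob_table$intensity
  pv <- prob_table$probability
  if (length(unique(pv)) == 1) {
    warn("all spike probabilities equal: intensity levels ambiguous")
    return(tibble::tibble(medium = max(iv), high = max(iv)))
  }
  medium <- iv[which.min(abs(pv - 0.5))]
  pmax_ <- max(pv)
  high <- max(iv[pv == pmax_])
  tibble::tibble(medium = medium, high = high)
}

#' Pulse-triggered modulation of RS firing
#'
#' Compares the firing rate in the 50 ms after pulse onset (`fr_post`) with
#' the rate in the 200 ms before (`fr_pre`), pooling spikes across pulses,
#' and reports `y = (fr_post - fr_pre) / (fr_post + fr_pre)`: -1 for full
#' suppression, 0 for no change, +1 for firing only after pulses.
#'
#' @param spikes Spike times (s).
#' @param pulses Pulse tibble (`onset_s`, ...), typically one intensity
#'   class at a time.
#' @param pre_window_s,post_window_s Window lengths (s); defaults 0.2 and
#'   0.05.
#' @param pooled Pool spikes across pulses (default) or average per-pulse
#'   modulation rates.
#' @return One-row tibble: `fr_pre`, `fr_post`, `y`, `n_pulses`. `y` is
#'   `NaN` when both rates are zero.
#' @export
modulation_index <- function(spikes, pulses, pre_window_s = 0.2,
                             post_window_s = 0.05, pooled = TRUE) {
  if (nrow(pulses) == 0) {
    abort("no pulses", class = "preictal_invalid_input")
  }
  pre_n <- purrr::map_int(pulses$onset_s, function(on) {
    sum(spikes >= on - pre_window_s & spikes < on)
  })
  post_n <- purrr::map_int(pulses$onset_s, function(on) {
    sum(spikes >= on & spikes < on + post_window_s)
  })
  if (pooled) {
    fr_pre <- sum(pre_n) / (nrow(pulses) * pre_window_s)
    fr_post <- sum(post_n) / (nrow(pulses) * post_window_s)
  } else {
    fr_pre <- mean(pre_n / pre_window_s)
    fr_post <- mean(post_n / post_window_s)
  }
  y <- if (fr_pre == 0 && fr_post == 0) {
    NaN
  } else {
    (fr_post - fr_pre) / (fr_post + fr_pre)
  }
  tibble::tibble(fr_pre = fr_pre, fr_post = fr_post, y = y,
                 n_pulses = nrow(pulses))
}
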