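#' @importFrom rlang .data abort warn %||%
#' @importFrom stats rbinom rgamma rnorm runif rexp fft optim median sd
#'   quantile pbinom dbinom wilcox.test kruskal.test approx besselI rpois
#' @importFrom utils head tail
NULL

# All intervals in the package are half-open [start, end), in seconds from
# recording start.

#' Build an interval tibble
#'
#' Intervals are the package's unit of time bookkeeping: half-open
#' `[start_s, end_s)` windows in seconds from recording start.
#'
#' @param start_s,end_s Numeric vectors of equal length; `start_s <= end_s`.
#' @param name Optional character vector of interval labels.
#' @return A tibble with columns `name` (if given), `start_s`, `end_s`.
#' @export
#' @examples
#' interval_tbl(0, 120, name = "baseline")
interval_tbl <- function(start_s, end_s, name = NULL) {
  stopifnot(length(start_s) == length(end_s))
  if (any(end_s < start_s)) {
    abort("interval end_s must be >= start_s", class = "preictal_invalid_parameter")
  }
  out <- tibble::tibble(start_s = as.numeric(start_s), end_s = as.numeric(end_s))
  if (!is.null(name)) out <- tibble::add_column(out, name = name, .before = 1)
  out
}

#' Total duration covered by a set of disjoint intervals
#' @param intervals An interval tibble (columns `start_s`, `end_s`).
#' @return Total length in seconds.
#' @export
interval_duration <- function(intervals) {
  if (nrow(intervals) == 0) return(0)
  sum(intervals$end_s - intervals$start_s)
}

#' Subtract a set of intervals from another
#'
#' Removes every `[start_s, end_s)` window in `remove` from each interval in
#' `keep`, returning the remaining (possibly split) sub-intervals.
#'
#' @param keep,remove Interval tibbles.
#' @return An interval tibble of what remains of `keep`.
#' @export
interval_subtract <- function(keep, remove) {
  if (nrow(keep) == 0) return(interval_tbl(numeric(0), numeric(0)))
  if (nrow(remove) == 0) return(keep[, c("start_s", "end_s")])
  remove <- merge_intervals(remove)
  pieces <- purrr::pmap(keep[, c("start_s", "end_s")], function(start_s, end_s) {
    s <- start_s
    out_s <- numeric(0)
    out_e <- numeric(0)
    rel <- remove[remove$end_s > start_s & remove$start_s < end_s, , drop = FALSE]
    for (i in seq_len(nrow(rel))) {
      if (rel$start_s[i] > s) {
        out_s <- c(out_s, s)
        out_e <- c(out_e, rel$start_s[i])
      }
      s <- max(s, rel$end_s[i])
    }
    if (s < end_s) {
      out_s <- c(out_s, s)
      out_e <- c(out_e, end_s)
    }
    tibble::tibble(start_s = out_s, end_s = out_e)
  })
  dplyr::bind_rows(pieces)
}

# Merge overlapping/touching intervals into a disjoint sorted set.
merge_intervals <- function(intervals) {
  if (nrow(intervals) <= 1) return(intervals[, c("start_s", "end_s")])
  x <- dplyr::arrange(intervals[, c("start_s", "end_s")], .data$start_s)
  s <- x$start_s[1]; e <- x$end_s[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_len(nrow(x))[-1]) {
    if (x$start_s[i] <= e) {
      e <- max(e, x$end_s[i])
    } else {
      out_s <- c(out_s, s); out_e <- c(out_e, e)
      s <- x$start_s[i]; e <- x$end_s[i]
    }
  }
  tibble::tibble(start_s = c(out_s, s), end_s = c(out_e, e))
}

# TRUE for times falling inside any of the half-open intervals.
in_intervals <- function(times, intervals) {
  if (nrow(intervals) == 0) return(rep(FALSE, length(times)))
  hit <- rep(FALSE, length(times))
  for (i in seq_len(nrow(intervals))) {
    hit <- hit | (times >= intervals$start_s[i] & times < intervals$end_s[i])
  }
  hit
}

# Run thunk under a fixed RNG state when seed is given, untouched otherwise.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Draw from a von Mises distribution
#'
#' Rejection sampler: uniform proposals accepted with probability
#' `exp(kappa * (cos(theta - mu) - 1))`. Used for phase-locking calibration;
#' exact for any `kappa >= 0` (at `kappa = 0` the distribution is uniform).
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration (>= 0).
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1, seed = NULL) {
  stopifnot(kappa >= 0)
  with_seed_if(seed, {
    if (kappa == 0) {
      runif(n, -pi, pi)
    } else {
      out <- numeric(0)
      while (length(out) < n) {
        m <- ceiling((n - length(out)) * exp(kappa) / besselI(kappa, 0) * 1.1) + 16
        th <- runif(m, -pi, pi)
        keep <- runif(m) < exp(kappa * (cos(th - mu) - 1))
        out <- c(out, th[keep])
      }
      out[seq_len(n)]
    }
  })
}

# Internal parameter check helper.
check_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    abort(paste0(what, " must be a positive number"),
          class = "preictal_invalid_parameter")
  }
  invisible(x)
}
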