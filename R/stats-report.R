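# Group-level nonparametric testing: the fraction-of-cells binomial
# statistic, Wilcoxon/Kruskal-Wallis contrasts, and Bonferroni correction.

# Paired signed-rank test that treats the degenerate all-ties case (every
# difference zero) as evidence of no effect (p = 1) instead of NaN.
paired_signed_rank <- function(a, b) {
  if (all(a == b)) {
    return(list(statistic = c(V = 0), p.value = 1))
  }
  wilcox.test(a, b, paired = TRUE)
}

#' Fraction of cells increasing their rate between two periods
#'
#' Counts cells whose rate in period B exceeds their rate in period A (ties
#' count as non-increases) and tests the fraction against 0.5 with an exact
#' two-sided binomial test, defined as twice the smaller tail probability,
#' capped at 1.
#'
#' @param rate_a,rate_b Paired per-cell rates (Hz) in the two periods.
#' @return One-row tibble of class `fraction_test`: `n_cells`,
#'   `k_increased`, `percent`, `p_two_sided`.
#' @export
#' @examples
#' fraction_increased(rep(1, 18), c(rep(2, 17), 0.5)) # 94.4%, p < 0.001
fraction_increased <- function(rate_a, rate_b) {
  ok <- !is.na(rate_a) & !is.na(rate_b)
  rate_a <- rate_a[ok]; rate_b <- rate_b[ok]
  n <- length(rate_a)
  if (n == 0 || length(rate_b) != n) {
    abort("need >= 1 cell with rates in both periods",
          class = "preictal_invalid_input")
  }
  k <- sum(rate_b > rate_a)
  p <- min(1, 2 * min(pbinom(k, n, 0.5), pbinom(k - 1, n, 0.5, lower.tail = FALSE)))
  out <- tibble::tibble(n_cells = n, k_increased = k,
                        percent = 100 * k / n, p_two_sided = p)
  class(out) <- c("fraction_test", class(out))
  out
}

#' Nonparametric group contrasts on a long metric table
#'
#' For each metric, runs a paired Wilcoxon signed-rank test (two groups
#' with a blocking variable), an unpaired rank-sum test (two independent
#' groups), or a Kruskal-Wallis test (more than two groups). Exact p-values
#' are used where R's implementations provide them for small samples
#' without ties.
#'
#' @param data Long tibble of observations.
#' @param value Column name (string) holding the metric values.
#' @param group Column name of the grouping factor.
#' @param block Optional column name identifying paired observations (e.g.
#'   `unit_id`); when given with two groups, the test is paired.
#' @param metric Optional column name; when given, tests are run per metric
#'   level.
#' @return Tibble: `metric` (if any), `test`, `n`, `statistic`, `p_value`.
#'   Groups with fewer than 2 observations are skipped with a warning.
#' @export
group_tests <- function(data, value, group, block = NULL, metric = NULL) {
  split_by <- if (is.null(metric)) list(all = data) else split(data, data[[metric]])
  rows <- purrr::imap(split_by, function(d, met) {
    d <- d[!is.na(d[[value]]), ]
    counts <- table(d[[group]])
    if (any(counts < 2) || length(counts) < 2) {
      warn(sprintf("group with < 2 observations: test skipped (%s)", met))
      return(NULL)
    }
    g <- factor(d[[group]])
    v <- d[[value]]
    if (nlevels(g) == 2) {
      if (!is.null(block)) {
        wide <- tidyr::pivot_wider(
          d[, c(block, group, value)],
          names_from = dplyr::all_of(group),
          values_from = dplyr::all_of(value)
        )
        a <- wide[[levels(g)[1]]]
        b <- wide[[levels(g)[2]]]
        keep <- !is.na(a) & !is.na(b)
        ht <- paired_signed_rank(a[keep], b[keep])
        test <- "wilcoxon_signed_rank"
        n <- sum(keep)
      } else {
        ht <- wilcox.test(v ~ g)
        test <- "wilcoxon_rank_sum"
        n <- length(v)
      }
    } else {
      ht <- kruskal.test(v ~ g)
      test <- "kruskal_wallis"
      n <- length(v)
    }
    tibble::tibble(
      metric = if (is.null(metric)) NA_character_ else met,
      test = test, n = n,
      statistic = unname(ht$statistic), p_value = ht$p.value
    )
  })
  dplyr::bind_rows(purrr::compact(rows))
}

#' Bonferroni correction
#'
#' Adjusted p-values are `min(1, m * p)`; the corresponding per-test
#' significance threshold at family level `alpha` is `alpha / m` (e.g.
#' 0.0125 for four comparisons at 0.05).
#'
#' @param p Raw p-values in `[0, 1]`.
#' @param m Number of comparisons (default `length(p)`).
#' @param alpha Family-wise level used for the reported threshold.
#' @return Tibble: `p_raw`, `p_adjusted`, `threshold`, `significant`.
#' @export
bonferroni <- function(p, m = length(p), alpha = 0.05) {
  if (m < 1) abort("m must be >= 1", class = "preictal_invalid_input")
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]", class = "preictal_invalid_input")
  }
  tibble::tibble(
    p_raw = p,
    p_adjusted = pmin(1, m * p),
    threshold = alpha / m,
    significant = p < alpha / m
  )
}

#' Period-versus-baseline contrasts for a metrics table
#'
#' For each cell type and each preictal period, runs a paired signed-rank
#' test of the per-unit metric against its baseline value and applies a
#' Bonferroni correction over the four periods — the table mirrored in the
#' figure-legend convention `*p < 0.0125`.
#'
#' @param metrics Long tibble from [spike_metrics()].
#' @param value Metric column to contrast (default `"rate"`).
#' @param periods Periods to contrast against baseline.
#' @return Tibble: `cell_type`, `period`, `n`, `statistic`, `p_value`,
#'   `p_adjusted`, `significant`.
#' @export
period_contrasts <- function(metrics, value = "rate",
                             periods = paste0("P", 1:4)) {
  rows <- purrr::map(split(metrics, metrics$cell_type), function(d) {
    base <- d[d$period == "baseline", c("unit_id", value)]
    purrr::map(periods, function(p) {
      cur <- d[d$period == p, c("unit_id", value)]
      j <- dplyr::inner_join(base, cur, by = "unit_id",
                             suffix = c("_base", "_period"))
      j <- j[stats::complete.cases(j), ]
      if (nrow(j) < 2) {
        warn(sprintf("fewer than 2 paired units for %s in %s: skipped",
                     d$cell_type[1], p))
        return(NULL)
      }
      ht <- paired_signed_rank(j[[paste0(value, "_period")]],
                               j[[paste0(value, "_base")]])
      tibble::tibble(cell_type = d$cell_type[1], period = p, n = nrow(j),
                     statistic = unname(ht$statistic), p_value = ht$p.value)
    }) |>
      purrr::compact() |>
      dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  adj <- bonferroni(out$p_value, m = length(periods))
  out$p_adjusted <- adj$p_adjusted
  out$significant <- adj$significant
  out
}
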