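#' Mann-Whitney U test
#'
#' Two-sided rank-sum test of stochastic ordering between two samples.
#' The exact null distribution (by enumeration) is used when
#' `length(x) * length(y) <= 400` and the pooled sample is tie-free;
#' otherwise the normal approximation with midranks, tie correction and
#' continuity correction. Backed by [stats::wilcox.test()], whose `W`
#' statistic is the Mann-Whitney U for the first sample.
#'
#' @param x,y Numeric samples, each with at least 3 values.
#' @return One-row tibble: `U`, `p_value`, `method` (`"exact"` or
#'   `"normal_approx"`), `n_x`, `n_y`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort_data("empty sample")
  if (length(x) < 3 || length(y) < 3) {
    abort_data("each sample needs at least 3 values")
  }
  stop_if_not_finite(x, "x")
  stop_if_not_finite(y, "y")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) * length(y) <= 400) && !ties
  ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  tibble(U = unname(ht$statistic), p_value = ht$p.value,
         method = if (exact) "exact" else "normal_approx",
         n_x = length(x), n_y = length(y))
}

#' Pearson product-moment correlation
#'
#' @param x,y Equal-length numeric samples (>= 3 values, both with nonzero
#'   variance).
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) abort_param("x and y must have equal length")
  if (length(x) < 3) abort_data("need at least 3 paired values")
  stop_if_not_finite(x, "x")
  stop_if_not_finite(y, "y")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_param("zero variance: correlation undefined")
  }
  stats::cor(x, y, method = "pearson")
}

#' Per-group summary statistics
#'
#' Mean +/- SD (and SEM) per group, the summary form used for experimental
#' groups throughout.
#'
#' @param data A data frame in long format.
#' @param group,value Column names (tidy-eval) of the grouping variable and
#'   the measured value.
#' @return Tibble with one row per group: `n`, `mean`, `sd`, `sem`.
#' @examples
#' df <- tibble::tibble(g = rep(c("a", "b"), each = 4), v = c(1:4, 3:6))
#' group_summary(df, g, v)
#' @export
group_summary <- function(data, group, value) {
  data |>
    dplyr::group_by({{ group }}) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean({{ value }}),
                     sd = stats::sd({{ value }}),
                     sem = stats::sd({{ value }}) / sqrt(dplyr::n()),
                     .groups = "drop")
}

#' Fold change between two groups
#'
#' Ratio of group means, `a / b`.
#'
#' @param a,b Group means, or one-row summaries with a `mean` column (as
#'   returned by [group_summary()] rows or [ros_summary()]).
#' @return `mean(a) / mean(b)`.
#' @export
fold_change <- function(a, b) {
  ma <- if (is.data.frame(a)) a$mean[[1]] else as.numeric(a)[[1]]
  mb <- if (is.data.frame(b)) b$mean[[1]] else as.numeric(b)[[1]]
  if (!is.finite(mb) || mb == 0) abort_param("reference group mean is zero")
  ma / mb
}

#' Significance stars for a p value
#'
#' The conventional coding: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001,
#' `****` p < 0.0001, otherwise `ns`.
#'
#' @param p Probability in \[0, 1\] (vectorised).
#' @return Character vector of labels.
#' @export
star_code <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort_param("p must lie in [0, 1]")
  }
  dplyr::case_when(p < 1e-4 ~ "****",
                   p < 1e-3 ~ "***",
                   p < 1e-2 ~ "**",
                   p < 0.05 ~ "*",
                   TRUE ~ "ns")
}

#' Pairwise group comparisons
#'
#' Mann-Whitney tests, fold changes and significance stars for every pair
#' of groups in a long-format table.
#'
#' @inheritParams group_summary
#' @param bonferroni Apply Bonferroni correction over the pairs (off by
#'   default, matching per-comparison reporting).
#' @return Tibble with one row per group pair: `group_a`, `group_b`, `U`,
#'   `p_value`, `stars`, `fold_change`.
#' @export
pairwise_stats <- function(data, group, value, bonferroni = FALSE) {
  g <- dplyr::pull(data, {{ group }})
  v <- dplyr::pull(data, {{ value }})
  levels <- unique(g)
  if (length(levels) < 2) abort_data("need at least two groups")
  pairs <- utils::combn(as.character(levels), 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- v[g == pairs[1, i]]
    b <- v[g == pairs[2, i]]
    mw <- mann_whitney(a, b)
    tibble(group_a = pairs[1, i], group_b = pairs[2, i],
           U = mw$U, p_value = mw$p_value,
           fold_change = mean(a) / mean(b))
  })
  if (bonferroni) out$p_value <- pmin(1, out$p_value * nrow(out))
  out$stars <- star_code(out$p_value)
  out
}
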