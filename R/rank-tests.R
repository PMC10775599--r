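#' @include AllGenerics.R
NULL

#' Rank tests between treatment groups
#'
#' Two groups: Wilcoxon rank-sum test (exact permutation distribution when
#' both samples have fewer than 50 observations and no ties, otherwise the
#' normal approximation with tie and continuity correction — the
#' [stats::wilcox.test()] conventions). More than two groups: a global
#' Kruskal-Wallis test followed by all pairwise rank-sum tests with
#' Benjamini-Hochberg adjustment (configurable via `adjustMethod`).
#'
#' @param values numeric vector of measurements (long format).
#' @param groups factor/character of the same length assigning each value to
#'   a group; every group needs at least 2 observations.
#' @param adjustMethod multiple-testing correction for the pairwise tests
#'   (default `"BH"`; any [stats::p.adjust()] method).
#' @return data.frame with columns `comparison`, `test`, `statistic`,
#'   `p_value`, `p_adjusted`, `n1`, `n2` — one row per pairwise comparison,
#'   preceded by a `"kruskal"` row when more than two groups are compared.
#' @examples
#' rankTest(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
#' @export
rankTest <- function(values, groups, adjustMethod = "BH") {
  groups <- as.factor(as.character(groups))
  if (length(values) != length(groups)) {
    stop("'values' and 'groups' must have the same length")
  }
  n_per <- table(groups)
  if (any(n_per < 2L)) {
    stop(
      "every group needs at least 2 observations; too small: ",
      paste(names(n_per)[n_per < 2L], collapse = ", ")
    )
  }
  levs <- levels(groups)
  pair_row <- function(g1, g2) {
    x <- values[groups == g1]
    y <- values[groups == g2]
    wt <- suppressWarnings(stats::wilcox.test(x, y))
    data.frame(
      comparison = paste(g1, "vs", g2),
      test = "wilcoxon_rank_sum",
      statistic = unname(wt$statistic),
      p_value = wt$p.value,
      p_adjusted = NA_real_,
      n1 = length(x), n2 = length(y),
      stringsAsFactors = FALSE
    )
  }
  if (length(levs) == 2L) {
    out <- pair_row(levs[1], levs[2])
    out$p_adjusted <- out$p_value
    return(out)
  }
  kw <- stats::kruskal.test(values, groups)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  rows <- do.call(rbind, lapply(pairs, function(p) pair_row(p[1], p[2])))
  rows$p_adjusted <- stats::p.adjust(rows$p_value, method = adjustMethod)
  head_row <- data.frame(
    comparison = "all groups",
    test = "kruskal_wallis",
    statistic = unname(kw$statistic),
    p_value = kw$p.value,
    p_adjusted = kw$p.value,
    n1 = length(values), n2 = NA_integer_,
    stringsAsFactors = FALSE
  )
  rbind(head_row, rows)
}

#' Single-pass chi-squared outlier screen
#'
#' Tests the observation farthest from the sample mean with the statistic
#' `(x - mean)^2 / s^2` (sample variance, n-1 denominator) against the
#' chi-squared distribution with 1 degree of freedom, and recommends removal
#' when p < `alpha`. At most one observation is flagged per call and the test
#' is never iterated internally; when the two extremes are equidistant from
#' the mean the candidate is the one with the larger absolute value.
#'
#' @param values numeric vector, length >= 3, non-zero variance.
#' @param alpha removal threshold on the p-value (default 0.05).
#' @return list with elements `candidate` (the tested value), `index`,
#'   `statistic`, `p`, `removed` (logical), and `values` (the input with the
#'   candidate dropped when `removed`, unchanged otherwise).
#' @examples
#' chisqOutlier(c(1, 2, 3, 100))$candidate  # 100
#' @export
chisqOutlier <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop("at least 3 observations are required")
  v <- stats::var(values)
  if (v == 0) stop("zero variance: outlier test undefined")
  m <- mean(values)
  dev <- abs(values - m)
  cand <- which(dev == max(dev))
  if (length(cand) > 1L) {
    cand <- cand[which.max(abs(values[cand]))]
  }
  stat <- (values[cand] - m)^2 / v
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  removed <- p < alpha
  list(
    candidate = values[cand],
    index = cand,
    statistic = stat,
    p = p,
    removed = removed,
    values = if (removed) values[-cand] else values
  )
}
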