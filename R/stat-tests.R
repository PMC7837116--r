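test_result <- function(statistic, p_value, alternative, method, n) {
  structure(list(statistic = unname(statistic),
                 p_value = unname(p_value),
                 alternative = alternative, method = method, n = n),
            class = "circuitdiff_test")
}

#' @export
print.circuitdiff_test <- function(x, ...) {
  cat(x$method, " (", x$alternative, "): statistic = ",
      format(x$statistic), ", p = ", format(x$p_value), "\n", sep = "")
  invisible(x)
}

#' Chi-square test for proportions
#'
#' Pearson chi-square on a k x 2 count table (typically the 2x2 table of
#' from-seed versus other input counts in two volumes, or responder
#' versus non-responder counts in two behavior groups), with (k - 1)
#' degrees of freedom. The Yates continuity correction (2x2 only) is off
#' by default.
#'
#' @param table k x 2 matrix of counts.
#' @param continuity apply the Yates correction (default FALSE).
#' @return a test result with `statistic`, `p_value`, `method`, `n`.
#' @export
chi_square_proportions <- function(table, continuity = FALSE) {
  table <- as.matrix(table)
  if (ncol(table) != 2 || nrow(table) < 2)
    stop("need a k x 2 table with k >= 2")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal: expected counts are zero")
  res <- suppressWarnings(stats::chisq.test(table, correct = continuity))
  test_result(res$statistic, res$p.value, "two_sided",
              paste0("chi-square test for proportions",
                     if (continuity) " (Yates-corrected)"),
              n = rowSums(table))
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum (Mann-Whitney) test with midranks for ties. The p value is
#' exact by enumeration when the combined sample size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction is used. `alternative = "greater"` tests whether
#' `x` tends to be larger than `y`.
#'
#' @param x,y numeric samples.
#' @param alternative `"two_sided"`, `"greater"`, or `"less"`.
#' @param exact override the exact-vs-approximate choice.
#' @return a test result (statistic is the Mann-Whitney U of `x`).
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two_sided", "greater",
                                              "less"),
                              exact = NULL) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact)) exact <- (length(x) + length(y) <= 12) && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = sub("two_sided", "two.sided",
                                               alternative),
                       exact = exact, correct = TRUE))
  test_result(res$statistic, res$p.value, alternative,
              paste0("Wilcoxon rank-sum test (",
                     if (exact) "exact" else "normal approximation", ")"),
              n = c(length(x), length(y)))
}

#' One- and two-sample t tests
#'
#' One-sample t versus `mu` (e.g. exploration-area ratios against 100%)
#' or two-sample Welch t (unpooled variances) on group means. Degenerate
#' zero-variance inputs use the convention p = 1 for a zero effect and
#' p = 0 (flagged in the method string) for a nonzero one.
#'
#' @param x numeric sample.
#' @param y second sample, or NULL for the one-sample test.
#' @param mu null value for the one-sample test (default 0).
#' @param alternative `"two_sided"`, `"greater"`, or `"less"`.
#' @param var_equal pool variances in the two-sample test (default FALSE,
#'   i.e. Welch).
#' @return a test result.
#' @export
t_test <- function(x, y = NULL, mu = 0,
                   alternative = c("two_sided", "greater", "less"),
                   var_equal = FALSE) {
  alternative <- match.arg(alternative)
  degenerate <- if (is.null(y)) stats::sd(x) == 0 else
    stats::sd(x) == 0 && stats::sd(y) == 0
  if (isTRUE(degenerate)) {
    effect <- if (is.null(y)) mean(x) - mu else mean(x) - mean(y)
    if (effect == 0)
      return(test_result(0, 1, alternative, "t test (zero variance)",
                         n = c(length(x), length(y))))
    return(test_result(sign(effect) * Inf, 0, alternative,
                       "t test (zero variance, nonzero effect: flagged)",
                       n = c(length(x), length(y))))
  }
  res <- stats::t.test(x, y, mu = mu,
                       alternative = sub("two_sided", "two.sided",
                                         alternative),
                       var.equal = var_equal)
  test_result(res$statistic, res$p.value, alternative, res$method,
              n = c(length(x), length(y)))
}

#' 95% confidence interval for a proportion
#'
#' Closed-form Wilson score interval (default) or Wald interval.
#'
#' @param successes,n counts, `0 <= successes <= n`, `n > 0`.
#' @param method `"wilson"` or `"wald"`.
#' @param conf confidence level (default 0.95).
#' @return numeric `c(lo, hi)`.
#' @export
proportion_ci <- function(successes, n, method = c("wilson", "wald"),
                          conf = 0.95) {
  method <- match.arg(method)
  stopifnot(n > 0, successes >= 0, successes <= n)
  p <- successes / n
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    return(c(lo = max(0, p - half), hi = min(1, p + half)))
  }
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(lo = max(0, center - half), hi = min(1, center + half))
}
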