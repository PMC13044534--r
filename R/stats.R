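#' Statistical comparisons for cohort summaries
#'
#' The comparison toolkit used across the pipeline: unpaired two-tailed
#' Mann-Whitney tests for non-normal per-sample summaries, Wilcoxon
#' signed-rank tests for matched pairs, two-way ANOVA for class-by-site
#' designs, and Sidak / Bonferroni multiplicity adjustment. Significance is
#' defined as two-sided p < 0.05 throughout.
#'
#' @name stats-report
NULL

.tme_test <- function(statistic, p_value, method, exact, n,
                      degenerate = FALSE) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 method = method, exact = exact, n = n,
                 adjustment = "none", degenerate = degenerate),
            class = "tme_test")
}

#' Unpaired two-tailed Mann-Whitney test
#'
#' Reports the U statistic (number of (a, b) pairs with a ranked above b)
#' and the two-sided p value: exact enumeration when the combined sample
#' size is at most 12 and there are no ties, otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param a,b Non-empty numeric samples.
#' @return A `tme_test` (statistic, p_value, method, exact flag, sizes).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value  # exact: 0.1
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 12) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  .tme_test(wt$statistic, wt$p.value, "mann_whitney", exact,
            c(n_a = length(a), n_b = length(b)))
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped; if none remain the test is degenerate and
#' p = 1 is reported with a flag. Exact enumeration of the 2^n sign
#' patterns when n <= 15 and the absolute differences are tie-free,
#' otherwise the normal approximation with continuity correction.
#'
#' @param paired_diffs Vector of matched-pair differences.
#' @return A `tme_test` with the signed-rank statistic.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3))$p_value  # exact: 0.25
#' @export
wilcoxon_signed_rank <- function(paired_diffs) {
  d <- paired_diffs[!is.na(paired_diffs)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(.tme_test(NA_real_, 1, "wilcoxon_signed_rank", FALSE,
                     c(n = 0), degenerate = TRUE))
  }
  ties <- anyDuplicated(abs(d)) > 0
  exact <- n <= 15 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = exact, correct = TRUE))
  .tme_test(wt$statistic, wt$p.value, "wilcoxon_signed_rank", exact, c(n = n))
}

#' Two-way ANOVA with type-II sums of squares
#'
#' Fits `values ~ factor_a * factor_b` and reports the F statistic and p
#' value for each main effect and the interaction. Type-II sums of squares
#' are used because per-sample class percentages are unbalanced across
#' sites. A response with zero variance is flagged degenerate (all sums of
#' squares vanish and no test is meaningful).
#'
#' @param values Numeric response.
#' @param factor_a,factor_b Grouping labels (each with >= 2 levels).
#' @return Data frame: effect, df, F, p_value; attribute `degenerate`.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  fa <- factor(factor_a); fb <- factor(factor_b)
  if (nlevels(fa) < 2 || nlevels(fb) < 2) {
    stop("each factor needs at least 2 levels")
  }
  if (stats::var(values) == 0) {
    out <- data.frame(effect = c("factor_a", "factor_b", "interaction"),
                      df = NA_integer_, F = NA_real_, p_value = NA_real_,
                      stringsAsFactors = FALSE)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  fit <- stats::lm(values ~ fa * fb)
  tab <- car::Anova(fit, type = 2)
  eff <- rownames(tab)
  pick <- function(name) which(eff == name)
  out <- data.frame(
    effect = c("factor_a", "factor_b", "interaction"),
    df = tab$Df[c(pick("fa"), pick("fb"), pick("fa:fb"))],
    F = tab$`F value`[c(pick("fa"), pick("fb"), pick("fa:fb"))],
    p_value = tab$`Pr(>F)`[c(pick("fa"), pick("fb"), pick("fa:fb"))],
    stringsAsFactors = FALSE
  )
  attr(out, "degenerate") <- FALSE
  out
}

#' Sidak or Bonferroni p-value adjustment
#'
#' Sidak: `1 - (1 - p)^m`; Bonferroni: `min(1, m * p)`, with `m` the number
#' of comparisons (default: the length of the vector). Sidak is uniformly
#' no larger than Bonferroni.
#'
#' @param p_values Raw p values in `[0, 1]`.
#' @param method `"sidak"` or `"bonferroni"`.
#' @param m Number of comparisons.
#' @return Adjusted p values.
#' @export
adjust_p <- function(p_values, method = c("sidak", "bonferroni"),
                     m = length(p_values)) {
  method <- match.arg(method)
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p values must lie in [0, 1]")
  }
  switch(method,
         sidak = 1 - (1 - p_values)^m,
         bonferroni = pmin(1, m * p_values))
}
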