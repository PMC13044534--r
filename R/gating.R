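#' Adaptive thresholding primitives
#'
#' Low-level building blocks for per-image, per-marker positivity gates:
#' the arcsinh intensity transform, the exact two-class k-means threshold,
#' the median + 3 x MAD fallback for unimodal channels, the unimodality
#' test that selects between them, and control-based floor calibration.
#'
#' @name gating-primitives
NULL

# single quantile convention used everywhere: linear interpolation between
# closest order statistics (type 7)
quantile7 <- function(x, p) stats::quantile(x, p, type = 7, names = FALSE)

#' Arcsinh intensity transform
#'
#' `asinh(x / cofactor)`: approximately linear near zero and logarithmic for
#' large values, compressing high signals. Cofactor 150 is the package-wide
#' default for immunofluorescence intensities.
#'
#' @param x Non-negative intensities.
#' @param cofactor Positive scale parameter (default 150).
#' @return Transformed intensities; strictly increasing in `x`.
#' @examples
#' arcsinh_transform(150, 150)  # asinh(1) = log(1 + sqrt(2))
#' @export
arcsinh_transform <- function(x, cofactor = 150) {
  if (!is.numeric(cofactor) || length(cofactor) != 1 || cofactor <= 0) {
    stop("cofactor must be a single positive number")
  }
  asinh(x / cofactor)
}

# optimal contiguous split of a sorted 1-D sample into two classes,
# minimizing total within-class sum of squares (prefix-sum scan).
# Returns split index k (left class = first k sorted values), the two class
# means, and the pooled within-class SD.
.best_split <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  k <- seq_len(n - 1)
  ss_left <- cs2[k] - cs[k]^2 / k
  ss_right <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  wss <- ss_left + ss_right
  kb <- which.min(wss)
  m1 <- cs[kb] / kb
  m2 <- (cs[n] - cs[kb]) / (n - kb)
  list(k = kb, n = n, m1 = m1, m2 = m2,
       wss = wss[kb], pooled_sd = sqrt(wss[kb] / n),
       min_frac = min(kb, n - kb) / n)
}

#' Two-class k-means threshold for a 1-D intensity vector
#'
#' Computes the global two-class k-means solution. In one dimension the
#' optimal two-cluster assignment is a contiguous split of the sorted
#' values, so the within-class sum of squares is minimized exactly by
#' scanning all n-1 candidate cut points; the returned threshold is the
#' midpoint of the two cluster means, which reproduces nearest-center
#' classification. Solving the 1-D problem exactly (rather than by Lloyd
#' iteration) removes any dependence on initialization.
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @return Threshold (numeric scalar).
#' @examples
#' kmeans_threshold(c(0, 0, 0, 10, 10, 10))  # 5
#' @export
kmeans_threshold <- function(values) {
  values <- values[!is.na(values)]
  if (length(unique(values)) < 2) {
    stop(degenerate_error("all intensity values identical; no two-class split exists"))
  }
  sp <- .best_split(values)
  (sp$m1 + sp$m2) / 2
}

degenerate_error <- function(msg) {
  structure(class = c("tmequant_degenerate", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Median + 3 x MAD fallback threshold
#'
#' Robust threshold for unimodal channels: `median(x) + 3 * mad(x)` with the
#' MAD unscaled (no 1.4826 normality constant). Note the documented
#' weakness: with a majority of exact zeros the MAD collapses to 0 and the
#' threshold equals the median.
#'
#' @param values Non-empty numeric vector.
#' @return Threshold (numeric scalar).
#' @examples
#' mad_fallback_threshold(1:9)  # 5 + 3 * 2 = 11
#' @export
mad_fallback_threshold <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty intensity vector")
  med <- stats::median(values)
  med + 3 * stats::median(abs(values - med))
}

#' Test whether an intensity distribution should be treated as unimodal
#'
#' Splits the sample with the exact two-class k-means solution and declares
#' the distribution unimodal when the two cluster centers are not well
#' separated relative to the pooled within-cluster SD, or when the smaller
#' cluster holds less than `min_cluster_frac` of the cells. The default
#' separation constant 3.5 was set from the behavior of the split statistic
#' itself: the optimal split of a single Gaussian has a center separation of
#' about 2.65 pooled within-cluster SDs (2.8 for the right-skewed
#' asinh-transformed background model), while balanced or 10% two-component
#' mixtures separated by 4 component SDs measure 4.1 or more. A constant of
#' 3.5 therefore sends unimodal channels to the conservative MAD fallback
#' and resolvable mixtures to the k-means gate. Deterministic for fixed
#' input.
#'
#' @param values Numeric vector (intended for n >= 10).
#' @param separation Separation constant (default 3.5), in units of pooled
#'   within-cluster SD.
#' @param min_cluster_frac Minority-cluster fraction below which the split
#'   is considered spurious (default 0.01).
#' @return `TRUE` if the sample should be treated as unimodal.
#' @export
is_unimodal <- function(values, separation = 3.5, min_cluster_frac = 0.01) {
  values <- values[!is.na(values)]
  if (length(unique(values)) < 2) return(TRUE)
  sp <- .best_split(values)
  if (sp$min_frac < min_cluster_frac) return(TRUE)
  if (sp$pooled_sd == 0) return(FALSE)
  (sp$m2 - sp$m1) < separation * sp$pooled_sd
}

#' Floor-rule constructors
#'
#' A floor rule describes how a background floor is calibrated from
#' negative-control intensities: `floor_none()` disables flooring,
#' `floor_fixed_percentile(p)` uses the p-th percentile of the controls
#' (99.5 for the macrophage panel), and `floor_fpr_budget(budgets)` uses the
#' (1 - budget) quantile per marker so that the fraction of control cells
#' strictly above the floor cannot exceed the marker's false-positive-rate
#' budget.
#'
#' @param percentile Percentile in (0, 100].
#' @param budgets Named numeric vector of per-marker FPR budgets in (0, 1).
#' @return A floor-rule list used by [calibrate_floor()] and [panel_spec()].
#' @export
floor_none <- function() list(type = "none")

#' @rdname floor_none
#' @export
floor_fixed_percentile <- function(percentile = 99.5) {
  stopifnot(percentile > 0, percentile <= 100)
  list(type = "fixed_control_percentile", percentile = percentile)
}

#' @rdname floor_none
#' @export
floor_fpr_budget <- function(budgets) {
  if (is.null(names(budgets)) || any(budgets <= 0 | budgets >= 1)) {
    stop("budgets must be a named vector with values in (0, 1)")
  }
  list(type = "fpr_budget", budgets = budgets)
}

#' Calibrate a background floor from negative-control intensities
#'
#' Under the fixed-percentile rule the floor is the stated percentile of the
#' control values, using the package-wide interpolating quantile convention
#' (type 7). Under an FPR-budget rule the floor is the ceiling order
#' statistic `sorted(x)[ceiling((1 - budget) * n)]`: with this choice the
#' number of control values strictly above the floor is at most
#' `n * budget`, so the in-sample false-positive guarantee is exact for
#' every control size (an interpolated quantile can overshoot the budget by
#' a fractional count).
#'
#' @param control_values Non-empty numeric control intensities (same scale
#'   as the data to be gated, i.e. transformed if the panel transforms).
#' @param rule A floor rule (see [floor_none()]).
#' @param marker Marker id; required to look up a budget under the
#'   FPR-budget rule.
#' @return Floor value, or `NA_real_` for `floor_none()`.
#' @export
calibrate_floor <- function(control_values, rule, marker = NULL) {
  control_values <- control_values[!is.na(control_values)]
  if (!length(control_values)) stop("empty control intensity vector")
  switch(rule$type,
    none = NA_real_,
    fixed_control_percentile = quantile7(control_values, rule$percentile / 100),
    fpr_budget = {
      if (is.null(marker) || is.na(match(marker, names(rule$budgets)))) {
        stop("no FPR budget configured for marker: ",
             if (is.null(marker)) "<missing>" else marker)
      }
      xs <- sort(control_values)
      xs[ceiling((1 - rule$budgets[[marker]]) * length(xs))]
    },
    stop("unknown floor rule type: ", rule$type)
  )
}
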