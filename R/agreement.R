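# Method-agreement statistics: one-way intraclass correlation with a
# Fleiss-style qualitative label, Bland-Altman bias and limits of
# agreement, and Pearson correlation.

as_pairs <- function(pairs) {
  if (!all(c("value_a", "value_b") %in% names(pairs))) {
    stop("pairs must have columns value_a and value_b")
  }
  pairs <- pairs[stats::complete.cases(pairs[c("value_a", "value_b")]), ]
  pairs
}

#' One-way random-effects intraclass correlation (single measure)
#'
#' Each subject is measured twice (two timepoints or two observers); the
#' one-way ANOVA decomposition gives between-subject (MSB) and
#' within-subject (MSW) mean squares, and
#' `ICC = (MSB - MSW) / (MSB + (k - 1) * MSW)` with `k = 2`. Variance
#' components are `sigma2_between = (MSB - MSW) / k` and
#' `sigma2_error = MSW`; the p-value is from the F test `MSB / MSW`
#' against the null of no subject effect.
#'
#' @param pairs a [paired_set()] or data frame with columns `value_a`,
#'   `value_b` (one row per subject).
#' @return An object of class `icc_result`: list with `icc`, `ms_between`,
#'   `ms_within`, `variance_between`, `variance_error`, `f`, `df1`, `df2`,
#'   `p_value`, `label` (see [classify_icc()]), `n_subjects`, `k`.
#' @export
icc_oneway <- function(pairs) {
  pairs <- as_pairs(pairs)
  n <- nrow(pairs)
  if (n < 2L) stop("need at least 2 subjects")
  k <- 2L
  x <- cbind(pairs$value_a, pairs$value_b)
  grand <- mean(x)
  subj_means <- rowMeans(x)
  ssb <- k * sum((subj_means - grand)^2)
  ssw <- sum((x - subj_means)^2)
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  if (msb == 0 && msw == 0) {
    stop("zero total variance: ICC is undefined for constant data")
  }
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  f <- if (msw > 0) msb / msw else Inf
  p <- stats::pf(f, n - 1, n * (k - 1), lower.tail = FALSE)
  structure(
    list(icc = icc, ms_between = msb, ms_within = msw,
         variance_between = (msb - msw) / k, variance_error = msw,
         f = f, df1 = n - 1L, df2 = n * (k - 1L), p_value = p,
         label = classify_icc(icc), n_subjects = n, k = k),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "One-way random-effects ICC (single measure), %d subjects x %d\n",
    x$n_subjects, x$k))
  cat(sprintf("  ICC = %.4f (%s); F(%d, %d) = %.3f, p = %.3g\n",
              x$icc, x$label, x$df1, x$df2, x$f, x$p_value))
  cat(sprintf("  variance components: between = %.4f, error = %.4f\n",
              x$variance_between, x$variance_error))
  invisible(x)
}

#' Two-way absolute-agreement ICC (single measure), optional alternative
#'
#' ICC(A,1) from the two-way crossed decomposition with a rater effect;
#' offered as a sensitivity alternative to [icc_oneway()].
#'
#' @inheritParams icc_oneway
#' @return List with `icc`, mean squares, and the Fleiss-style `label`.
#' @export
icc_twoway_agreement <- function(pairs) {
  pairs <- as_pairs(pairs)
  n <- nrow(pairs)
  if (n < 2L) stop("need at least 2 subjects")
  k <- 2L
  x <- cbind(pairs$value_a, pairs$value_b)
  grand <- mean(x)
  msr <- k * sum((rowMeans(x) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(x) - grand)^2) / (k - 1)
  sse <- sum((x - outer(rowMeans(x), rep(1, k)) -
                outer(rep(1, n), colMeans(x)) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  list(icc = icc, ms_rows = msr, ms_cols = msc, ms_error = mse,
       label = classify_icc(icc))
}

#' Qualitative label for an ICC value (Fleiss-style cutpoints)
#'
#' `icc > 0.75` is `"excellent"`, `0.40 <= icc <= 0.75` is `"good"`, and
#' `icc < 0.40` is `"poor"`; both boundary values fall in `"good"`.
#'
#' @param icc a finite ICC value.
#' @return `"excellent"`, `"good"`, or `"poor"` (vectorized).
#' @export
classify_icc <- function(icc) {
  stopifnot(is.numeric(icc), all(is.finite(icc)))
  ifelse(icc > 0.75, "excellent", ifelse(icc >= 0.40, "good", "poor"))
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as `value_b - value_a` (by convention DC - MC, or
#' T2 - T1). The bias is the mean difference, and the limits of agreement
#' are `bias +/- multiplier * SD` of the differences (sample SD, n - 1
#' denominator). Coverage is the percentage of differences inside the
#' limits, boundary points counted as inside.
#'
#' @param pairs a [paired_set()] or data frame with `value_a`, `value_b`.
#' @param multiplier the limits' half-width in SD units (default 1.96, the
#'   normal-theory 95% content).
#' @return An object of class `bland_altman_result`: list with `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `coverage` (percent), `multiplier`,
#'   `n`, `sign_convention`, and the per-pair `differences` and `means`.
#' @export
bland_altman <- function(pairs, multiplier = 1.96) {
  pairs <- as_pairs(pairs)
  n <- nrow(pairs)
  if (n < 2L) stop("need at least 2 pairs")
  d <- pairs$value_b - pairs$value_a
  m <- (pairs$value_a + pairs$value_b) / 2
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  loa_low <- bias - multiplier * sd_diff
  loa_high <- bias + multiplier * sd_diff
  coverage <- 100 * mean(d >= loa_low & d <= loa_high)
  structure(
    list(bias = bias, sd_diff = sd_diff, loa_low = loa_low,
         loa_high = loa_high, coverage = coverage, multiplier = multiplier,
         n = n, sign_convention = "B - A", differences = d, means = m),
    class = "bland_altman_result"
  )
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (%s, n = %d): bias = %.3f, SD = %.3f\n  LoA [%.3f, %.3f] (x %.2f), coverage = %.1f%%\n",
    x$sign_convention, x$n, x$bias, x$sd_diff, x$loa_low, x$loa_high,
    x$multiplier, x$coverage))
  invisible(x)
}

#' Pearson correlation, plain or difference-versus-mean
#'
#' `mode = "plain"` is the ordinary product-moment correlation of `x` and
#' `y`. `mode = "diff_vs_mean"` correlates the paired differences
#' `y - x` with the paired means `(x + y) / 2` — the proportional-bias
#' check that accompanies a Bland-Altman plot, whose value is near zero
#' when the bias does not drift with magnitude.
#'
#' @param x,y numeric vectors of equal length (>= 3), each with nonzero
#'   variance.
#' @param mode `"plain"` or `"diff_vs_mean"`.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y, mode = c("plain", "diff_vs_mean")) {
  mode <- match.arg(mode)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (mode == "diff_vs_mean") {
    d <- y - x
    m <- (x + y) / 2
    if (stats::sd(d) == 0 || stats::sd(m) == 0) {
      stop("zero variance in differences or means")
    }
    return(stats::cor(d, m))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  stats::cor(x, y)
}

#' Bland-Altman plot
#'
#' Scatter of paired differences against paired means with the bias and
#' limits-of-agreement lines.
#'
#' @param ba a [bland_altman()] result.
#' @param title optional plot title.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(ba, title = NULL) {
  stopifnot(inherits(ba, "bland_altman_result"))
  df <- data.frame(pair_mean = ba$means, pair_diff = ba$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = pair_mean, y = pair_diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ba$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of methods (%)",
                  y = sprintf("Difference (%s, %%)", ba$sign_convention),
                  title = title) +
    ggplot2::theme_minimal()
}
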