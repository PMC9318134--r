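# Lesion-comparison statistics: D'Agostino-Pearson omnibus normality,
# Mann-Whitney PI-vs-PD per marker, and Wilcoxon signed-rank MC-vs-DC.

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness (D'Agostino 1970) and kurtosis
#' (Anscombe & Glynn 1983) into `K2 = Z1^2 + Z2^2`, referred to a
#' chi-square distribution with 2 degrees of freedom. Requires `n >= 8`;
#' the kurtosis normalization is unstable below that.
#'
#' @param x numeric vector, `n >= 8`, nonzero variance.
#' @return List with `k2`, `p_value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson requires n >= 8; use a larger sample")
  if (stats::sd(x) == 0) stop("zero variance: normality test undefined")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)

  # skewness: D'Agostino (1970) Z transform of g1
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Anscombe & Glynn (1983) Z transform of b2
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sqrt_b1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_b1 * (2 / sqrt_b1 + sqrt(1 + 4 / sqrt_b1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(k2 = k2, p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact p-value (full enumeration of the rank distribution) when the
#' pooled sample has at most 12 tie-free observations; otherwise the
#' normal approximation with tie and continuity corrections. The path
#' taken is reported in `method`.
#'
#' @param group_a,group_b numeric vectors, each non-empty.
#' @return List with `u` (U statistic of `group_a`, i.e. the number of
#'   (a, b) pairs with a > b, ties counted 1/2), `p_value`, and `method`.
#' @export
mann_whitney <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- (length(group_a) + length(group_b) <= 12) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  list(u = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal_approx")
}

#' Two-sided Wilcoxon signed-rank test
#'
#' Differences are `paired_b - paired_a`; zero differences are excluded
#' (the classical Wilcoxon convention) and their count reported. When at
#' most 15 nonzero differences remain, the p-value is exact: all `2^n`
#' sign assignments are enumerated on the observed (mid)ranks, so tied
#' absolute differences are handled exactly too. Larger samples use the
#' normal approximation with continuity correction.
#'
#' @param paired_a,paired_b paired numeric vectors of equal length.
#' @return List with `w` (sum of positive-difference ranks), `p_value`,
#'   `method`, `n_used` (nonzero differences), `n_zero` (excluded).
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  stopifnot(length(paired_a) == length(paired_b))
  d <- paired_b - paired_a
  n_zero <- sum(d == 0)
  d_nz <- d[d != 0]
  n <- length(d_nz)
  if (!n) {
    stop("all paired differences are zero: signed-rank test undefined")
  }
  r <- rank(abs(d_nz))
  w <- sum(r[d_nz > 0])
  if (n <= 15) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n),
                                   KEEP.OUT.ATTRS = FALSE))
    ws <- as.vector(signs %*% r)
    eps <- 1e-9
    p_le <- mean(ws <= w + eps)
    p_ge <- mean(ws >= w - eps)
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(w = w, p_value = p, method = "exact",
                n_used = n, n_zero = n_zero))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(paired_b, paired_a, paired = TRUE,
                       alternative = "two.sided", exact = FALSE,
                       correct = TRUE)
  )
  list(w = unname(wt$statistic), p_value = wt$p.value,
       method = "normal_approx", n_used = n, n_zero = n_zero)
}

#' Per-marker cohort comparison (PI vs PD, and MC vs DC)
#'
#' Aggregates field values to one mean per patient per marker per method,
#' then for every marker runs (a) the two-sided Mann-Whitney test of PI
#' versus PD patients within each method, and (b) the Wilcoxon signed-rank
#' test of MC versus DC across all patients. The D'Agostino-Pearson
#' normality statistic is reported per marker and method (pooled groups)
#' for information only — the group comparison is non-parametric
#' regardless, and no multiple-testing correction is applied across
#' markers.
#'
#' @param cohort a [generate_cohort()]-style data frame with columns
#'   `patient_id`, `group`, `marker`, `method`, `field_id`, `value`.
#' @param alpha significance level (default 0.05).
#' @param level `"patient"` (default: test patient means of the fields) or
#'   `"field"` (test raw field values; ignores within-patient clustering —
#'   labeled accordingly in the output).
#' @return A data frame of class `cohort_comparison`, one row per test:
#'   columns `marker`, `method`, `comparison`, `test_name`, `statistic`,
#'   `p_value`, `significant`, `note`; attribute `alpha`.
#' @export
compare_cohort <- function(cohort, alpha = 0.05,
                           level = c("patient", "field")) {
  level <- match.arg(level)
  need <- c("patient_id", "group", "marker", "method", "value")
  if (!all(need %in% names(cohort))) {
    stop("cohort must have columns ", paste(need, collapse = ", "))
  }
  if (length(unique(cohort$group)) < 2L) {
    stop("both PI and PD groups must be present")
  }
  agg <- if (level == "patient") {
    stats::aggregate(value ~ patient_id + group + marker + method,
                     data = cohort, FUN = mean)
  } else {
    cohort[c("patient_id", "group", "marker", "method", "value")]
  }
  markers <- unique(agg$marker)
  methods <- unique(agg$method)
  rows <- list()
  add_row <- function(marker, method, comparison, test_name, statistic,
                      p_value, note = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      marker = marker, method = method, comparison = comparison,
      test_name = test_name, statistic = statistic, p_value = p_value,
      significant = is.finite(p_value) && p_value < alpha, note = note
    )
  }
  for (m in markers) {
    for (meth in methods) {
      v <- agg[agg$marker == m & agg$method == meth, ]
      if (nrow(v) >= 8) {
        dp <- dagostino_pearson(v$value)
        add_row(m, meth, "normality", "dagostino_pearson", dp$k2, dp$p_value)
      }
      mw <- mann_whitney(v$value[v$group == "PI"], v$value[v$group == "PD"])
      add_row(m, meth, "PI_vs_PD", "mann_whitney", mw$u, mw$p_value,
              mw$method)
    }
    if (all(c("MC", "DC") %in% methods)) {
      mcv <- agg[agg$marker == m & agg$method == "MC", ]
      dcv <- agg[agg$marker == m & agg$method == "DC", ]
      dcv <- dcv[match(mcv$patient_id, dcv$patient_id), ]
      res <- tryCatch(
        wilcoxon_signed_rank(mcv$value, dcv$value),
        error = function(e) NULL
      )
      if (is.null(res)) {
        add_row(m, "MC_vs_DC", "MC_vs_DC", "wilcoxon_signed_rank",
                NA_real_, NA_real_, "degenerate: all differences zero")
      } else {
        add_row(m, "MC_vs_DC", "MC_vs_DC", "wilcoxon_signed_rank",
                res$w, res$p_value, res$method)
      }
    }
  }
  out <- do.call(rbind, rows)
  structure(out, alpha = alpha, level = level,
            class = c("cohort_comparison", "data.frame"))
}
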