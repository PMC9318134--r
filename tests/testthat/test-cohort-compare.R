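test_that("the normality statistic behaves on known shapes and guards bad input", {
  expect_error(dagostino_pearson(rnorm(5)), "n >= 8")
  expect_error(dagostino_pearson(rep(3.3, 20)), "zero variance")

  # frozen oracle values (independent reference implementation of the
  # transformed-moment omnibus test)
  x1 <- c(2.3, 4.1, 3.3, 5.8, 1.2, 6.6, 4.9, 3.7, 2.8, 5.1, 4.4, 3.0)
  r1 <- dagostino_pearson(x1)
  expect_equal(r1$k2, 0.006086414407406985, tolerance = 1e-12)
  expect_equal(r1$p_value, 0.9969614186576642, tolerance = 1e-12)
  expect_equal(r1$z_skew, 0.03733451273856353, tolerance = 1e-10)
  expect_equal(r1$z_kurt, -0.06850217927906398, tolerance = 1e-10)

  r2 <- dagostino_pearson((1:20)^2)
  expect_equal(r2$k2, 2.514697432414396, tolerance = 1e-12)
  expect_equal(r2$p_value, 0.28440707165007806, tolerance = 1e-12)
})

test_that("the normality test holds its size and detects skew", {
  set.seed(17)
  rej_null <- mean(vapply(1:500, function(i) {
    dagostino_pearson(rnorm(1000))$p_value < 0.05
  }, NA))
  expect_gte(rej_null, 0.03)
  expect_lte(rej_null, 0.07)

  rej_skew <- mean(vapply(1:500, function(i) {
    dagostino_pearson(rexp(200))$p_value < 0.05
  }, NA))
  expect_gte(rej_skew, 0.90)
})

test_that("Mann-Whitney matches exhaustive enumeration on small tie-free samples", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_equal(r$p_value, 0.1)   # 2/C(6,3) = 2/20
  expect_equal(r$method, "exact")

  set.seed(23)
  for (i in 1:15) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    a <- round(runif(na, 0, 50), 3); b <- round(runif(nb, 0, 50), 3)
    got <- mann_whitney(a, b)
    expect_equal(got$p_value, mw_enumeration_oracle(a, b),
                 tolerance = 1e-12)
    # U identity
    expect_equal(got$u + mann_whitney(b, a)$u, na * nb)
  }

  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("signed-rank matches sign-flip enumeration and handles zeros", {
  a <- c(1, 2, 3, 4, 5, 6)
  r <- wilcoxon_signed_rank(a, a + 2)
  expect_equal(r$w, 21)
  expect_equal(r$p_value, 2 / 2^6)
  expect_equal(r$method, "exact")

  set.seed(29)
  for (i in 1:15) {
    n <- sample(5:9, 1)
    x <- runif(n, 0, 30); y <- x + rnorm(n, 0, 2)
    got <- wilcoxon_signed_rank(x, y)
    expect_equal(got$p_value, sr_enumeration_oracle(x, y), tolerance = 1e-12)
    # antisymmetry of the two-sided p
    expect_equal(wilcoxon_signed_rank(y, x)$p_value, got$p_value)
  }

  expect_error(wilcoxon_signed_rank(a, a), "zero")
  # zero differences are excluded, not counted
  rz <- wilcoxon_signed_rank(c(1, 2, 3, 4), c(1, 3, 4, 5))
  expect_equal(rz$n_zero, 1)
  expect_equal(rz$n_used, 3)
})

test_that("exact and approximate p-values agree closely on tie-free small samples", {
  set.seed(37)
  for (i in 1:10) {
    a <- runif(6, 0, 40); b <- runif(6, 0, 40)
    exact_p <- mann_whitney(a, b)$p_value
    approx_p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    )
    expect_lt(abs(exact_p - approx_p), 0.05)

    x <- runif(10, 0, 40); y <- x + rnorm(10, 0, 3)
    exact_sr <- wilcoxon_signed_rank(x, y)$p_value
    approx_sr <- suppressWarnings(
      stats::wilcox.test(y, x, paired = TRUE, exact = FALSE,
                         correct = TRUE)$p.value
    )
    expect_lt(abs(exact_sr - approx_sr), 0.05)
  }
})

test_that("both rank tests hold their size at n = 11 per group", {
  set.seed(41)
  n_sim <- 2000
  rej_mw <- rej_sr <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    a <- rnorm(11, 10, 2); b <- rnorm(11, 10, 2)
    rej_mw[i] <- mann_whitney(a, b)$p_value < 0.05
    x <- rnorm(11, 10, 2); y <- x + rnorm(11, 0, 1)
    rej_sr[i] <- wilcoxon_signed_rank(x, y)$p_value < 0.05
  }
  expect_gte(mean(rej_mw), 0.03); expect_lte(mean(rej_mw), 0.07)
  expect_gte(mean(rej_sr), 0.03); expect_lte(mean(rej_sr), 0.07)
})

test_that("cohort comparison flags injected effects and reports degeneracies", {
  co <- generate_cohort(n_per_group = 11, seed = 3)
  res <- compare_cohort(co)
  expect_s3_class(res, "cohort_comparison")
  expect_identical(res, compare_cohort(co))  # deterministic

  pi_pd <- res[res$comparison == "PI_vs_PD", ]
  expect_equal(nrow(pi_pd), 14)  # 7 markers x 2 methods
  for (meth in c("MC", "DC")) {
    sig <- pi_pd$marker[pi_pd$method == meth & pi_pd$significant]
    expect_setequal(sig, c("CD68", "CD138"))
  }
  # signed-rank MC vs DC present for every marker
  expect_equal(sum(res$comparison == "MC_vs_DC"), 7)
  # normality reported, never used as a gate
  expect_equal(sum(res$comparison == "normality"), 14)

  # identical method columns -> degenerate signed-rank surfaced per marker
  co2 <- co
  mc_rows <- co2$method == "MC"
  key <- paste(co2$patient_id, co2$marker, co2$field_id)
  co2$value[mc_rows] <- co2$value[!mc_rows][match(key[mc_rows], key[!mc_rows])]
  res2 <- compare_cohort(co2)
  degen <- res2[res2$comparison == "MC_vs_DC", ]
  expect_true(all(is.na(degen$p_value)))
  expect_true(all(grepl("degenerate", degen$note)))

  expect_error(compare_cohort(co[co$group == "PI", ]), "group")
})

test_that("null cohorts produce false positives at roughly the nominal rate", {
  set.seed(53)
  n_rep <- 60
  fp <- vapply(seq_len(n_rep), function(i) {
    co <- generate_cohort(n_per_group = 11, marker_effects = numeric(0),
                          seed = 5000 + i)
    res <- compare_cohort(co)
    sum(res$significant[res$comparison == "PI_vs_PD" & res$method == "MC"])
  }, 0)
  # expected false positives per run ~ 7 * 0.05 = 0.35
  expect_lt(abs(mean(fp) - 0.35), 0.25)
})
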