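# Independent statistical oracles used by both the unit and the
# acceptance suites. Each is a from-scratch implementation (explicit sums
# or exhaustive enumeration) sharing no code with the package.

# One-way ANOVA ICC via stats::aov mean squares.
icc_anova_oracle <- function(a, b) {
  n <- length(a); k <- 2
  x <- c(a, b)
  subj <- factor(rep(seq_len(n), 2))
  fit <- stats::aov(x ~ subj)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  (ms[1] - ms[2]) / (ms[1] + (k - 1) * ms[2])
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments.
mw_enumeration_oracle <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_stat <- function(ai) {
    av <- pooled[ai]; bv <- pooled[-ai]
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  obs <- u_stat(seq_len(na))
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2, u_stat)
  mu <- na * (length(pooled) - na) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# Exact two-sided signed-rank p by enumerating all sign assignments.
sr_enumeration_oracle <- function(a, b) {
  d <- (b - a)[b - a != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  min(1, 2 * min(mean(ws <= obs + 1e-9), mean(ws >= obs - 1e-9)))
}
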