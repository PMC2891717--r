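# Shared fixtures and independent oracles.

# High-dose arm of the packaged field experiment: 2500 exposed, all 124
# survivors genotyped, 133 of 2376 dead genotyped.
field_experiment <- function() {
  tail_experiment(alive = genotype_counts(27, 52, 45),
                  dead_sampled = genotype_counts(72, 51, 10),
                  n_exposed = 2500,
                  dose_label = "120 ug/vial")
}

# Two-sided Fisher p by explicit hypergeometric enumeration over every
# table with the observed margins (independent of stats::fisher.test).
fisher_enum_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  if (m1 == 0 || m2 == 0 || n1 == 0 || (b + d) == 0) return(1.0)
  k <- max(0, n1 - m2):min(n1, m1)
  pr <- dhyper(k, m1, m2, n1)
  sum(pr[pr <= dhyper(a, m1, m2, n1) * (1 + 1e-7)])
}

# Exact conditional null for the trend statistic on a 2x3 table: enumerate
# all survivor allocations with fixed margins, weight by the multivariate
# hypergeometric, accumulate P(chi2 >= observed).
trend_exact_oracle <- function(alive, dead, scores = c(0, 1, 2)) {
  n <- alive + dead; N <- sum(n); R <- sum(alive)
  obs <- cochran_armitage_trend(alive, dead, scores)$chi2
  p <- 0
  for (a0 in 0:min(R, n[1])) for (a1 in 0:min(R - a0, n[2])) {
    a2 <- R - a0 - a1
    if (a2 < 0 || a2 > n[3]) next
    pr <- exp(lchoose(n[1], a0) + lchoose(n[2], a1) + lchoose(n[3], a2) -
              lchoose(N, R))
    chi2 <- tryCatch(
      cochran_armitage_trend(c(a0, a1, a2), n - c(a0, a1, a2), scores)$chi2,
      error = function(e) 0)
    if (chi2 >= obs - 1e-9) p <- p + pr
  }
  p
}

# Average allelic effect as the slope of the HWE-weighted least-squares
# regression of genotypic value (0, a(1+k), 2a) on allele count.
alpha_regression_oracle <- function(a, k, p) {
  g <- c(0, a * (1 + k), 2 * a)
  x <- 0:2
  w <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  unname(coef(lm(g ~ x, weights = w))[2])
}

# Additive variance as the HWE-weighted variance of breeding values
# alpha * (copy number), enumerated over the three classes.
sigma2A_enum_oracle <- function(p, alpha) {
  x <- 0:2
  w <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  mu <- sum(w * alpha * x)
  sum(w * (alpha * x - mu)^2)
}

# Analytic genotype survivorships for an additive liability locus with
# liability-scale h2 at incidence K: liability = alpha_l * x + e.
liability_truth <- function(h2, K, p) {
  q <- 1 - p; w <- c(q^2, 2 * p * q, p^2)
  alpha_l <- sqrt(h2 / (2 * p * q))
  sig_e <- sqrt(1 - h2)
  Kf <- function(t) sum(w * (1 - pnorm((t - (0:2) * alpha_l) / sig_e)))
  t0 <- uniroot(function(t) Kf(t) - K, c(-10, 10))$root
  list(alpha_l = alpha_l, sig_e = sig_e, threshold = t0,
       S = 1 - pnorm((t0 - (0:2) * alpha_l) / sig_e))
}
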