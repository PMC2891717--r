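test_that("two informative dose groups are inverted exactly", {
  # qnorm(0.0228) = -1.999, qnorm(0.9772) = +1.999: the saturated fit
  # passes through both empirical probits.
  tab <- bioassay_table(c(1, 100), c(10000, 10000), c(228, 9772))
  fit <- fit_probit(tab)
  expect_true(fit$converged)
  expect_equal(fit$intercept, qnorm(0.0228), tolerance = 1e-4)
  expect_equal(fit$slope, (qnorm(0.9772) - qnorm(0.0228)) / 2,
               tolerance = 1e-4)
})

test_that("fit recovers generating parameters within 3 SE on simulated data", {
  truth <- c(-3, 2)
  tab <- simulate_bioassay(truth[1], truth[2],
                           doses = 10^seq(0.8, 2.2, length.out = 5),
                           n_per_dose = 1000, seed = 101)
  fit <- fit_probit(tab)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$intercept - truth[1]) / se[1], 3)
  expect_lt(abs(fit$slope - truth[2]) / se[2], 3)
})

test_that("fitted likelihood dominates a coarse parameter grid", {
  tab <- bioassay_table(c(2, 8, 30, 120), rep(50, 4), c(4, 17, 32, 48))
  fit <- fit_probit(tab)
  ll <- function(b0, b1) {
    pr <- pmin(pmax(pnorm(b0 + b1 * log10(tab$dose)), 1e-12), 1 - 1e-12)
    sum(dbinom(tab$n_dead, tab$n_exposed, pr, log = TRUE))
  }
  grid <- expand.grid(b0 = seq(-4, 1, by = 0.1), b1 = seq(0.1, 4, by = 0.1))
  best_grid <- max(mapply(ll, grid$b0, grid$b1))
  expect_gte(fit$loglik + 1e-8, best_grid)
  # and the analytic loglik at the fitted parameters matches the fit's
  expect_equal(ll(fit$intercept, fit$slope), fit$loglik, tolerance = 1e-6)
})

test_that("natural-response fit collapses to the 2-parameter fit on c = 0 data", {
  tab <- simulate_bioassay(-3, 2, doses = 10^seq(0.8, 2.2, length.out = 6),
                           n_per_dose = 2000, seed = 7)
  plain <- fit_probit(tab)
  nr <- fit_probit(tab, use_natural_response = TRUE)
  expect_true(nr$converged)
  expect_lt(nr$natural_response, 0.01)
  expect_equal(nr$intercept, plain$intercept, tolerance = 0.05)
  expect_equal(nr$slope, plain$slope, tolerance = 0.05)
})

test_that("natural-response fit picks up background mortality from controls", {
  set.seed(31)
  doses <- 10^seq(0.8, 2.2, length.out = 5)
  pr <- 0.1 + 0.9 * pnorm(-3 + 2 * log10(doses))
  dead <- rbinom(5, 3000, pr)
  tab <- bioassay_table(c(0, doses), rep(3000, 6),
                        c(rbinom(1, 3000, 0.1), dead))
  fit <- fit_probit(tab, use_natural_response = TRUE)
  expect_true(fit$converged)
  expect_equal(fit$natural_response, 0.1, tolerance = 0.03)
  expect_equal(fit$slope, 2, tolerance = 0.25)
})

test_that("degenerate designs raise informative errors", {
  expect_error(fit_probit(bioassay_table(c(10, 10), c(50, 50), c(10, 20))),
               "distinct positive doses")
  expect_error(fit_probit(bioassay_table(c(1, 10, 100), rep(50, 3),
                                         c(0, 0, 0))),
               "all-alive or all-dead")
  # 0% / 100% groups only: slope diverges
  expect_error(fit_probit(bioassay_table(c(1, 10, 100), rep(50, 3),
                                         c(0, 0, 50))),
               "complete separation")
})

test_that("predicted mortality is non-decreasing in dose for positive slope", {
  tab <- simulate_bioassay(-2.5, 1.5, doses = c(2, 10, 40, 120),
                           n_per_dose = 500, seed = 5)
  fit <- fit_probit(tab)
  doses <- 10^seq(-1, 3, length.out = 50)
  expect_true(all(diff(predict_mortality(fit, doses)) >= 0))
})

test_that("LC quantiles follow the closed form and the LC95/LC5 identity", {
  fit <- fit_probit(bioassay_table(c(1, 100), c(10000, 10000),
                                   c(228, 9772)))
  expect_equal(estimate_lc(fit, 0.5)$dose, 10, tolerance = 1e-3)
  expect_equal(estimate_lc(fit, 0.0228)$dose, 1, tolerance = 1e-3)
  ratio <- estimate_lc(fit, 0.95)$dose / estimate_lc(fit, 0.05)$dose
  expect_equal(ratio, 10^(2 * qnorm(0.95) / fit$slope), tolerance = 1e-8)
})

test_that("delta and Fieller intervals bracket the estimate and agree at large n", {
  tab <- simulate_bioassay(-3, 2, doses = 10^seq(0.8, 2.2, length.out = 6),
                           n_per_dose = 5000, seed = 13)
  fit <- fit_probit(tab)
  for (m in c("delta", "fieller")) {
    lc <- estimate_lc(fit, 0.5, method = m)
    expect_lte(lc$ci_low, lc$dose)
    expect_gte(lc$ci_high, lc$dose)
  }
  d <- estimate_lc(fit, 0.5, method = "delta")
  f <- estimate_lc(fit, 0.5, method = "fieller")
  expect_equal(d$ci_low, f$ci_low, tolerance = 0.01)
  expect_equal(d$ci_high, f$ci_high, tolerance = 0.01)
})

test_that("LC estimation refuses unusable fits", {
  tab <- simulate_bioassay(-3, 2, doses = 10^seq(0.8, 2.2, length.out = 5),
                           n_per_dose = 200, seed = 3)
  fit <- fit_probit(tab)
  neg <- fit; neg$slope <- -1
  expect_error(estimate_lc(neg, 0.5), "slope")
  unconv <- fit; unconv$converged <- FALSE
  expect_error(estimate_lc(unconv, 0.5), "converge")
})

test_that("LC recovery over replicate simulations is unbiased", {
  # generating LC50 = 10^(3/2); mean estimate over 200 replicates
  set.seed(2024)
  lc50 <- replicate(200, {
    tab <- simulate_bioassay(-3, 2,
                             doses = 10^seq(0.85, 2.15, length.out = 5),
                             n_per_dose = 250)
    estimate_lc(fit_probit(tab), 0.5)$dose
  })
  expect_equal(mean(lc50), 10^1.5, tolerance = 0.02)
})

test_that("group LC50 comparison: symmetry, scaling, and the textbook t", {
  a <- c(1.2, 1.9, 1.4, 2.2)
  expect_equal(compare_lc50_groups(a, a)$fold_change, 1.0)
  expect_equal(compare_lc50_groups(a, a)$p, 0.5)
  expect_equal(compare_lc50_groups(a, 2 * a)$fold_change, 2.0)

  set.seed(9)
  b <- exp(rnorm(5, 1, 0.3)); cc <- exp(rnorm(6, 1.4, 0.5))
  got <- compare_lc50_groups(b, cc)
  # direct Welch formula on the logs
  la <- log10(b); lb <- log10(cc)
  se <- sqrt(var(lb) / length(lb) + var(la) / length(la))
  tstat <- (mean(lb) - mean(la)) / se
  df <- se^4 / ((var(lb) / length(lb))^2 / (length(lb) - 1) +
                (var(la) / length(la))^2 / (length(la) - 1))
  expect_equal(got$t, tstat, tolerance = 1e-10)
  expect_equal(got$p, pt(tstat, df, lower.tail = FALSE), tolerance = 1e-10)

  expect_error(compare_lc50_groups(1, c(1, 2)), "at least 2")
  expect_error(compare_lc50_groups(c(1, -2), c(1, 2)), "positive")
})
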