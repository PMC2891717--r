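test_that("dead-count scaling conserves totals and handles edge cases", {
  expect_equal(as.integer(scale_dead_counts(genotype_counts(72, 51, 10),
                                            2376)),
               c(1286L, 911L, 179L))
  expect_equal(as.integer(scale_dead_counts(genotype_counts(5, 5, 5), 15)),
               c(5L, 5L, 5L))
  expect_equal(as.integer(scale_dead_counts(genotype_counts(10, 0, 0), 100)),
               c(100L, 0L, 0L))
  expect_error(scale_dead_counts(genotype_counts(0, 0, 0), 10),
               "empty dead sample")
})

test_that("dead-count scaling is exact-total and scale-equivariant", {
  set.seed(42)
  for (i in 1:50) {
    smp <- genotype_counts(sample(0:40, 1), sample(0:40, 1),
                           sample(1:40, 1))
    tot <- sum(smp) + sample(0:2000, 1)
    out <- scale_dead_counts(smp, tot)
    expect_identical(sum(out), as.integer(tot))
    expect_true(all(out >= 0))
    # doubling both sample and total doubles the allocation up to the
    # one-unit discreteness of any exact-total apportionment
    dbl <- scale_dead_counts(genotype_counts(2 * smp[1], 2 * smp[2],
                                             2 * smp[3]), 2 * tot)
    expect_identical(sum(dbl), as.integer(2 * tot))
    expect_true(all(abs(as.integer(dbl) - 2L * as.integer(out)) <= 1L))
  }
})

test_that("genotype survivorship divides alive by class totals", {
  S <- genotype_survivorship(genotype_counts(27, 52, 45),
                             genotype_counts(1286, 911, 179))
  expect_equal(unname(round(S, 4)), c(0.0206, 0.0540, 0.2009))
  expect_equal(unname(genotype_survivorship(genotype_counts(5, 5, 5),
                                            genotype_counts(0, 0, 0))),
               c(1, 1, 1))
  expect_equal(unname(genotype_survivorship(genotype_counts(0, 0, 0),
                                            genotype_counts(3, 3, 3))),
               c(0, 0, 0))
  expect_error(genotype_survivorship(genotype_counts(1, 0, 1),
                                     genotype_counts(1, 0, 1)),
               "c1")
})

test_that("trend test matches the field data, the base-R reference, and nulls", {
  alive <- genotype_counts(27, 52, 45); dead <- genotype_counts(72, 51, 10)
  tt <- cochran_armitage_trend(alive, dead)
  expect_equal(round(tt$chi2), 42)
  expect_lt(tt$p, 1e-9)
  # independent reference: stats::prop.trend.test is the same statistic
  ref <- prop.trend.test(as.integer(alive),
                         as.integer(alive) + as.integer(dead), 0:2)
  expect_equal(tt$chi2, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(tt$p, ref$p.value, tolerance = 1e-10)
  # finite-sample variant shrinks the statistic by (N-1)/N
  fs <- cochran_armitage_trend(alive, dead, finite_sample = TRUE)
  N <- sum(as.integer(alive)) + sum(as.integer(dead))
  expect_equal(fs$chi2, tt$chi2 * (N - 1) / N, tolerance = 1e-12)
  # proportional rows: no trend
  expect_equal(cochran_armitage_trend(genotype_counts(10, 20, 30),
                                      genotype_counts(5, 10, 15))$chi2, 0)
  expect_error(cochran_armitage_trend(genotype_counts(5, 5, 5),
                                      genotype_counts(0, 0, 0)),
               "one outcome")
})

test_that("trend statistic is invariant under affine score changes", {
  set.seed(7)
  for (i in 1:25) {
    a <- genotype_counts(sample(1:30, 1), sample(1:30, 1), sample(1:30, 1))
    d <- genotype_counts(sample(1:30, 1), sample(1:30, 1), sample(1:30, 1))
    base <- cochran_armitage_trend(a, d, scores = c(0, 1, 2))$chi2
    shifted <- cochran_armitage_trend(a, d, scores = 3 - 1.7 * c(0, 1, 2))$chi2
    expect_equal(shifted, base, tolerance = 1e-9)
  }
})

test_that("asymptotic trend p is close to the exact conditional null on tiny tables", {
  tables <- list(list(a = c(1, 2, 3), d = c(3, 2, 1)),
                 list(a = c(0, 2, 4), d = c(4, 1, 1)),
                 list(a = c(2, 2, 2), d = c(2, 2, 2)))
  for (tb in tables) {
    p_asym <- cochran_armitage_trend(tb$a, tb$d)$p
    p_exact <- trend_exact_oracle(tb$a, tb$d)
    # at total n = 12 the conditional null is coarsely discrete, so the
    # chi-square approximation is only expected to be loosely calibrated
    expect_lt(abs(p_asym - p_exact), 0.2)
  }
})

test_that("trend test holds its nominal type-I error under a simulated null", {
  set.seed(515)
  n_sim <- 2000
  rejections <- 0L
  cfg_p <- 0.3
  for (i in seq_len(n_sim)) {
    g <- simulate_genotypes(cfg_p, 400)
    alive <- runif(400) < 0.25            # survival independent of genotype
    a <- c(sum(g == 0 & alive), sum(g == 1 & alive), sum(g == 2 & alive))
    d <- c(sum(g == 0 & !alive), sum(g == 1 & !alive), sum(g == 2 & !alive))
    p <- tryCatch(cochran_armitage_trend(a, d)$p, error = function(e) 1)
    if (p < 0.05) rejections <- rejections + 1L
  }
  # binomial SE at 0.05 over 2000 sims is ~0.005; allow 4 SE
  expect_lt(abs(rejections / n_sim - 0.05), 0.02)
})

test_that("fisher_exact agrees with hand enumeration and handles degeneracy", {
  expect_equal(fisher_exact(1, 1, 1, 1), 1.0)
  expect_equal(fisher_exact(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact(3, 1, 1, 3), fisher_enum_oracle(3, 1, 1, 3),
               tolerance = 1e-12)
  expect_message(p0 <- fisher_exact(0, 0, 3, 5), "zero margin")
  expect_equal(p0, 1.0)
  set.seed(88)
  suppressMessages(
    for (i in 1:200) {
      x <- as.integer(rmultinom(1, sample(4:30, 1), runif(4, 0.05, 1)))
      expect_equal(fisher_exact(x[1], x[2], x[3], x[4]),
                   fisher_enum_oracle(x[1], x[2], x[3], x[4]),
                   tolerance = 1e-12)
    }
  )
})

test_that("homozygote odds ratio matches direct arithmetic", {
  or <- homozygote_odds_ratio(genotype_counts(27, 52, 45),
                              genotype_counts(1286, 911, 179))
  expect_equal(round(or), 12)
  expect_equal(or, (45 / 179) / (27 / 1286), tolerance = 1e-12)
  expect_equal(homozygote_odds_ratio(genotype_counts(10, 1, 10),
                                     genotype_counts(10, 1, 10)), 1.0)
  # 2-copy odds 10/10 against 0-copy odds 5/20
  expect_equal(homozygote_odds_ratio(genotype_counts(5, 3, 10),
                                     genotype_counts(20, 3, 10)), 4.0)
  expect_error(homozygote_odds_ratio(genotype_counts(0, 5, 5),
                                     genotype_counts(10, 5, 5)),
               "zero homozygote cell")
  expect_message(
    or_c <- homozygote_odds_ratio(genotype_counts(0, 5, 5),
                                  genotype_counts(10, 5, 5),
                                  continuity = TRUE),
    "Haldane")
  expect_equal(or_c, (5.5 / 5.5) / (0.5 / 10.5), tolerance = 1e-12)
})

test_that("allele frequency estimates and intervals behave at boundaries", {
  expect_equal(allele_frequency(genotype_counts(25, 50, 25))$frequency, 0.5)
  f <- allele_frequency(genotype_counts(27, 52, 45))
  expect_equal(f$frequency, 142 / 248, tolerance = 1e-12)
  expect_equal(f$n_alleles, 248L)
  expect_lte(f$ci_low, f$frequency); expect_gte(f$ci_high, f$frequency)
  b <- allele_frequency(genotype_counts(0, 0, 10))
  expect_equal(b$frequency, 1.0)
  expect_equal(b$ci_high, 1.0)
  w <- allele_frequency(genotype_counts(27, 52, 45), method = "wilson")
  expect_lt(w$ci_low, w$frequency); expect_gt(w$ci_high, w$frequency)
  # Wilson and Clopper-Pearson agree closely at n = 248
  expect_equal(w$ci_low, f$ci_low, tolerance = 0.01)
})

test_that("population frequency comparison is exact-test based", {
  expect_equal(compare_population_frequencies(10, 100, 10, 100), 1.0)
  expect_lt(compare_population_frequencies(40, 100, 10, 683), 1e-4)
  expect_equal(compare_population_frequencies(3, 4, 1, 4),
               fisher_enum_oracle(3, 1, 1, 3), tolerance = 1e-12)
})
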