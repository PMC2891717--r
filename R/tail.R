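#' Genotype counts by focal-allele copy number
#'
#' Counts of individuals carrying 0, 1 or 2 copies of the focal (resistant)
#' allele at a bi-allelic locus.
#'
#' @param c0,c1,c2 non-negative integer counts for the 0-, 1- and 2-copy
#'   classes.
#' @return Named integer vector of class `"genotype_counts"`.
#' @examples
#' genotype_counts(27, 52, 45)
#' @export
genotype_counts <- function(c0, c1, c2) {
  x <- c(c0 = c0, c1 = c1, c2 = c2)
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x)))
    stop("genotype counts must be non-negative integers")
  structure(as.integer(round(x)), names = c("c0", "c1", "c2"),
            class = "genotype_counts")
}

as_genotype_counts <- function(x) {
  if (inherits(x, "genotype_counts")) return(x)
  stopifnot(is.numeric(x), length(x) == 3)
  genotype_counts(x[1], x[2], x[3])
}

#' A selective-genotyping (extreme tails) exposure experiment
#'
#' Represents one exposure of `n_exposed` individuals at a discriminating
#' dose where every survivor is genotyped and only a subsample of the dead
#' is genotyped. Total dead is inferred as `n_exposed - sum(alive)`.
#'
#' @param alive [genotype_counts()] of all survivors.
#' @param dead_sampled [genotype_counts()] of the genotyped dead subsample.
#' @param n_exposed total individuals exposed.
#' @param dose_label free-text description of the dose.
#' @return Object of class `"tail_experiment"`: list with `alive`,
#'   `dead_sampled`, `n_exposed`, `total_dead`, `dose_label`.
#' @examples
#' tail_experiment(genotype_counts(27, 52, 45), genotype_counts(72, 51, 10),
#'                 n_exposed = 2500)
#' @export
tail_experiment <- function(alive, dead_sampled, n_exposed, dose_label = "") {
  alive <- as_genotype_counts(alive)
  dead_sampled <- as_genotype_counts(dead_sampled)
  stopifnot(length(n_exposed) == 1, n_exposed > 0,
            n_exposed == round(n_exposed))
  total_dead <- as.integer(n_exposed) - sum(alive)
  if (total_dead < 0)
    stop("more survivors than individuals exposed")
  if (sum(dead_sampled) > total_dead)
    stop("dead sample (", sum(dead_sampled), ") exceeds total dead (",
         total_dead, ")")
  structure(list(alive = alive, dead_sampled = dead_sampled,
                 n_exposed = as.integer(n_exposed),
                 total_dead = total_dead,
                 dose_label = as.character(dose_label)[1]),
            class = "tail_experiment")
}

#' @export
print.tail_experiment <- function(x, ...) {
  cat("Tail-genotyping experiment",
      if (nzchar(x$dose_label)) paste0(" (", x$dose_label, ")"), "\n",
      sep = "")
  cat("  exposed:", x$n_exposed, " total dead:", x$total_dead, "\n")
  m <- rbind(alive = unclass(x$alive), dead_sampled = unclass(x$dead_sampled))
  print(m)
  invisible(x)
}

#' Scale a genotyped dead subsample up to the total dead
#'
#' When only a fraction of the dead are genotyped, the per-genotype dead
#' counts are estimated by allocating the total dead proportionally to the
#' sampled shares. Integerisation uses largest-remainder (Hamilton)
#' rounding so the three estimated counts sum to the total exactly; ties in
#' the fractional remainders are broken toward the lower copy-number class.
#'
#' @param dead_sampled [genotype_counts()] of the genotyped dead.
#' @param total_dead total number of dead individuals (>= sample size).
#' @return A `"genotype_counts"` vector of estimated dead counts summing to
#'   `total_dead`.
#' @examples
#' scale_dead_counts(genotype_counts(72, 51, 10), 2376)  # 1286 911 179
#' @export
scale_dead_counts <- function(dead_sampled, total_dead) {
  dead_sampled <- as_genotype_counts(dead_sampled)
  n <- sum(dead_sampled)
  if (n == 0) stop("empty dead sample: genotype proportions undefined")
  stopifnot(total_dead >= n, total_dead == round(total_dead))
  raw <- as.numeric(dead_sampled) / n * total_dead
  base <- floor(raw)
  left <- as.integer(round(total_dead - sum(base)))
  if (left > 0) {
    take <- order(raw - base, seq_along(raw), decreasing = c(TRUE, FALSE),
                  method = "radix")[seq_len(left)]
    base[take] <- base[take] + 1
  }
  genotype_counts(base[1], base[2], base[3])
}

#' Per-genotype survivorship
#'
#' @param alive [genotype_counts()] of survivors.
#' @param dead [genotype_counts()] of dead (typically the scaled estimated
#'   totals from [scale_dead_counts()]).
#' @return Numeric vector `(S0, S1, S2)` of survival proportions
#'   `alive / (alive + dead)` per copy-number class.
#' @examples
#' genotype_survivorship(genotype_counts(27, 52, 45),
#'                       genotype_counts(1286, 911, 179))
#' @export
genotype_survivorship <- function(alive, dead) {
  alive <- as_genotype_counts(alive); dead <- as_genotype_counts(dead)
  tot <- as.numeric(alive) + as.numeric(dead)
  if (any(tot == 0))
    stop("no individuals in genotype class ",
         paste(names(alive)[tot == 0], collapse = ", "),
         ": survivorship undefined")
  setNames(as.numeric(alive) / tot, c("S0", "S1", "S2"))
}

#' Cochran-Armitage trend test for allele-dosage association
#'
#' Tests for a linear trend in the proportion surviving across ordered
#' genotype classes (copies of the focal allele), the standard single-locus
#' association test for an ordinal genotype. The statistic is
#' \eqn{T^2/\mathrm{Var}(T)} where \eqn{T} is the score-weighted excess of
#' survivors over its margin-fixed expectation; no continuity correction is
#' applied, and the statistic is referred to a chi-square distribution with
#' 1 degree of freedom.
#'
#' @param alive,dead [genotype_counts()] of the two outcome rows. For a
#'   subsampled-dead design, testing against the genotyped dead sample
#'   (not scaled totals) preserves the real sampling variance.
#' @param scores numeric scores for the three classes; default `c(0, 1, 2)`
#'   (focal-allele dosage). The statistic is invariant under affine
#'   transformations of the scores.
#' @param finite_sample multiply the variance by `N/(N-1)` (the
#'   finite-population variant); default `FALSE`.
#' @return Object of class `"trend_test"`: list with `chi2`, `df` (= 1), `p`.
#' @examples
#' cochran_armitage_trend(genotype_counts(27, 52, 45),
#'                        genotype_counts(72, 51, 10))
#' @export
cochran_armitage_trend <- function(alive, dead, scores = c(0, 1, 2),
                                   finite_sample = FALSE) {
  alive <- as_genotype_counts(alive); dead <- as_genotype_counts(dead)
  stopifnot(is.numeric(scores), length(scores) == 3)
  a <- as.numeric(alive); d <- as.numeric(dead)
  n <- a + d; N <- sum(n); R <- sum(a)
  if (sum(n > 0) < 2) stop("need at least two non-empty genotype classes")
  if (R == 0 || R == N)
    stop("all individuals share one outcome: trend test undefined")
  sbar <- sum(scores * n) / N
  T_ <- sum(scores * a) - R * sbar
  pbar <- R / N
  V <- pbar * (1 - pbar) * (sum(scores^2 * n) - N * sbar^2)
  if (finite_sample) V <- V * N / (N - 1)
  if (V <= 0) stop("zero trend variance: scores or margins degenerate")
  chi2 <- T_^2 / V
  structure(list(chi2 = chi2, df = 1L,
                 p = pchisq(chi2, df = 1, lower.tail = FALSE),
                 scores = scores, finite_sample = finite_sample),
            class = "trend_test")
}

#' @export
print.trend_test <- function(x, ...) {
  cat(sprintf("Cochran-Armitage trend test: chi2 = %.3f, df = 1, p = %.3g\n",
              x$chi2, x$p))
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value for independence in a 2x2 contingency table,
#' summing hypergeometric probabilities (margins fixed) of every table at
#' most as probable as the one observed.
#'
#' @param a,b,c,d cell counts, table rows `(a, b)` and `(c, d)`.
#' @return Two-sided p-value. A table with a zero margin carries no
#'   information about association; its p-value is defined as 1 (a message
#'   is emitted).
#' @examples
#' fisher_exact(3, 1, 1, 3)  # 34/70
#' @export
fisher_exact <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (any(x < 0) || any(x != round(x)))
    stop("cell counts must be non-negative integers")
  m <- matrix(as.integer(x), nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    message("fisher_exact: zero margin, p defined as 1")
    return(1.0)
  }
  fisher.test(m)$p.value
}

#' Odds ratio of survival for focal-allele homozygotes
#'
#' The odds of surviving for 2-copy homozygotes relative to 0-copy
#' homozygotes, `(alive2/dead2) / (alive0/dead0)`. Dead counts should be
#' the estimated totals ([scale_dead_counts()]) so the odds refer to the
#' whole exposed cohort rather than the genotyped subsample.
#'
#' @param alive [genotype_counts()] of survivors.
#' @param dead [genotype_counts()] of (estimated total) dead.
#' @param continuity apply the Haldane-Anscombe +0.5 correction to the four
#'   homozygote cells; default `FALSE`. Its use is always messaged.
#' @return The odds ratio (numeric).
#' @examples
#' homozygote_odds_ratio(genotype_counts(27, 52, 45),
#'                       genotype_counts(1286, 911, 179))  # ~12
#' @export
homozygote_odds_ratio <- function(alive, dead, continuity = FALSE) {
  alive <- as_genotype_counts(alive); dead <- as_genotype_counts(dead)
  cells <- c(alive[["c2"]], dead[["c2"]], alive[["c0"]], dead[["c0"]])
  if (any(cells == 0)) {
    if (!continuity)
      stop("zero homozygote cell: odds ratio undefined ",
           "(set continuity = TRUE for the Haldane-Anscombe correction)")
    message("homozygote_odds_ratio: Haldane-Anscombe +0.5 applied")
    cells <- cells + 0.5
  } else if (continuity) {
    message("homozygote_odds_ratio: Haldane-Anscombe +0.5 applied")
    cells <- cells + 0.5
  }
  (cells[1] / cells[2]) / (cells[3] / cells[4])
}

wilson_ci <- function(x, n, conf) {
  z <- qnorm(1 - (1 - conf) / 2)
  ph <- x / n
  centre <- (ph + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(max(0, centre - half), min(1, centre + half))
}

#' Focal-allele frequency with a binomial confidence interval
#'
#' Estimates the allele frequency `(c1 + 2 c2) / 2n` from genotype counts,
#' treating the `2n` allele copies as binomial draws. The default interval
#' is the exact Clopper-Pearson interval; Wilson's score interval is
#' available as an alternative.
#'
#' @param counts [genotype_counts()].
#' @param conf confidence level (default 0.95).
#' @param method `"clopper-pearson"` (default) or `"wilson"`.
#' @return Object of class `"freq_estimate"`: list with `frequency`,
#'   `n_alleles`, `ci_low`, `ci_high`, `conf`, `method`.
#' @examples
#' allele_frequency(genotype_counts(27, 52, 45))
#' @export
allele_frequency <- function(counts, conf = 0.95,
                             method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  counts <- as_genotype_counts(counts)
  if (sum(counts) == 0) stop("no genotyped individuals")
  n_alleles <- 2L * sum(counts)
  x <- counts[["c1"]] + 2L * counts[["c2"]]
  ci <- if (method == "clopper-pearson")
    as.numeric(binom.test(x, n_alleles, conf.level = conf)$conf.int)
  else wilson_ci(x, n_alleles, conf)
  structure(list(frequency = x / n_alleles, n_alleles = n_alleles,
                 ci_low = ci[1], ci_high = ci[2], conf = conf,
                 method = method),
            class = "freq_estimate")
}

#' @export
print.freq_estimate <- function(x, ...) {
  cat(sprintf("allele frequency %.4f (%d alleles; %g%% %s CI %.4f - %.4f)\n",
              x$frequency, x$n_alleles, 100 * x$conf, x$method,
              x$ci_low, x$ci_high))
  invisible(x)
}

#' Compare allele frequencies between two populations
#'
#' Exact two-sided test that two populations share an allele frequency,
#' via [fisher_exact()] on the 2x2 table of allele counts.
#'
#' @param count_a,total_a focal-allele count and total alleles surveyed in
#'   population A.
#' @param count_b,total_b the same for population B.
#' @return Two-sided p-value.
#' @examples
#' compare_population_frequencies(40, 100, 10, 683)  # p << 0.0001
#' @export
compare_population_frequencies <- function(count_a, total_a,
                                           count_b, total_b) {
  stopifnot(total_a > 0, total_b > 0,
            count_a <= total_a, count_b <= total_b)
  fisher_exact(count_a, total_a - count_a, count_b, total_b - count_b)
}
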