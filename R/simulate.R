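#' Simulation configuration for synthetic tail-genotyping cohorts
#'
#' Bundles the parameters of the generative model: a bi-allelic locus at
#' Hardy-Weinberg proportions with focal-allele frequency `p`, and probit
#' (liability) survival in which each genotype shifts the liability mean,
#' so individual g dies at dose d with probability
#' `pnorm(genotype_intercepts[g+1] + slope * log10(d))`.
#'
#' The defaults emulate the field association design the package targets:
#' five replicates of 500 flies at a discriminating high dose (120
#' micrograms per vial, near the population LC95) plus a low dose (2
#' micrograms, near the LC5), focal-allele frequency 0.28, and a
#' dead subsample of 133 genotyped. The default intercepts are chosen so
#' that genotype survivorships at the high dose are approximately 0.02,
#' 0.054 and 0.20 with a common slope of 2 probit units per log10
#' microgram -- the dose-response geometry of a strongly but incompletely
#' protective resistance allele.
#'
#' @param p focal allele frequency.
#' @param genotype_intercepts length-3 numeric, probit intercepts for the
#'   0-, 1- and 2-copy genotypes.
#' @param slope probit units per log10(microgram); positive.
#' @param doses numeric vector of positive doses; the last is used as the
#'   discriminating high dose by [simulate_tail_experiment()].
#' @param n_per_exposure flies per replicate exposure.
#' @param n_replicates number of replicate exposures.
#' @param dead_subsample number of dead to genotype, or `"all"`.
#' @param seed integer seed recorded in the config and used by the
#'   simulators; `NULL` leaves the RNG state untouched.
#' @return Object of class `"simulation_config"`.
#' @export
simulation_config <- function(p = 0.28,
                              genotype_intercepts = c(-2.12, -2.55, -3.32),
                              slope = 2,
                              doses = c(2, 120),
                              n_per_exposure = 500L,
                              n_replicates = 5L,
                              dead_subsample = 133L,
                              seed = NULL) {
  stopifnot(p >= 0, p <= 1, length(genotype_intercepts) == 3,
            slope > 0, all(doses > 0), n_per_exposure > 0,
            n_replicates > 0)
  if (!identical(dead_subsample, "all"))
    stopifnot(is.numeric(dead_subsample), dead_subsample > 0)
  structure(list(p = p, genotype_intercepts = genotype_intercepts,
                 slope = slope, doses = doses,
                 n_per_exposure = as.integer(n_per_exposure),
                 n_replicates = as.integer(n_replicates),
                 dead_subsample = dead_subsample,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "simulation_config")
}

#' Simulate genotypes at Hardy-Weinberg proportions
#'
#' @param p focal allele frequency in `[0, 1]`.
#' @param n number of individuals.
#' @param seed optional integer seed (set before drawing).
#' @return Integer vector of focal-allele copy numbers (0/1/2).
#' @examples
#' table(simulate_genotypes(0.28, 1000, seed = 1))
#' @export
simulate_genotypes <- function(p, n, seed = NULL) {
  stopifnot(p >= 0, p <= 1, n > 0)
  if (!is.null(seed)) set.seed(seed)
  q <- 1 - p
  sample(0:2, n, replace = TRUE, prob = c(q^2, 2 * p * q, p^2))
}

#' Simulate survival of a genotyped cohort at one dose
#'
#' Each individual dies independently with probability
#' `pnorm(intercepts[g+1] + slope * log10(dose))`.
#'
#' @param genotypes integer vector of copy numbers (0/1/2).
#' @param dose positive dose.
#' @param genotype_intercepts length-3 probit intercepts.
#' @param slope probit slope per log10 dose.
#' @param seed optional integer seed.
#' @return Logical vector, `TRUE` for survivors.
#' @export
simulate_survival <- function(genotypes, dose, genotype_intercepts, slope,
                              seed = NULL) {
  stopifnot(dose > 0, length(genotype_intercepts) == 3,
            all(genotypes %in% 0:2))
  if (!is.null(seed)) set.seed(seed)
  p_die <- pnorm(genotype_intercepts[genotypes + 1] + slope * log10(dose))
  runif(length(genotypes)) >= p_die
}

count_by_genotype <- function(genotypes) {
  genotype_counts(sum(genotypes == 0), sum(genotypes == 1),
                  sum(genotypes == 2))
}

#' Simulate a selective-genotyping tail experiment
#'
#' Exposes `n_replicates * n_per_exposure` Hardy-Weinberg individuals at a
#' discriminating dose, genotypes every survivor, and genotypes a random
#' subsample of the dead of the configured size -- the structure of an
#' extreme-tails association experiment.
#'
#' @param config a [simulation_config()].
#' @param dose exposure dose; defaults to the highest dose in the config.
#' @return A [tail_experiment()].
#' @examples
#' sim <- simulate_tail_experiment(simulation_config(seed = 42))
#' sim
#' @export
simulate_tail_experiment <- function(config, dose = max(config$doses)) {
  stopifnot(inherits(config, "simulation_config"), dose > 0)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_replicates * config$n_per_exposure
  g <- simulate_genotypes(config$p, n)
  alive <- simulate_survival(g, dose, config$genotype_intercepts,
                             config$slope)
  if (!any(alive))
    stop("no survivors at dose ", dose,
         ": choose a lower discriminating dose")
  dead_idx <- which(!alive)
  k <- if (identical(config$dead_subsample, "all")) length(dead_idx)
       else min(as.integer(config$dead_subsample), length(dead_idx))
  sampled <- if (k == length(dead_idx)) dead_idx
             else sample(dead_idx, k)
  tail_experiment(alive = count_by_genotype(g[alive]),
                  dead_sampled = count_by_genotype(g[sampled]),
                  n_exposed = n,
                  dose_label = paste0(format(dose), " ug/vial (simulated)"))
}

#' Simulate a dose-mortality bioassay
#'
#' Binomial deaths per dose group under the log10-dose probit law
#' `P(dead | d) = pnorm(beta0 + slope * log10(d))`, for validating
#' [fit_probit()] recovery.
#'
#' @param beta0 probit intercept.
#' @param slope probit slope per log10 dose; positive.
#' @param doses vector of positive doses.
#' @param n_per_dose flies exposed at each dose.
#' @param seed optional integer seed.
#' @param label label for the resulting table.
#' @return A [bioassay_table()].
#' @examples
#' simulate_bioassay(-3, 2, doses = 10^seq(1, 2, length.out = 5),
#'                   n_per_dose = 100, seed = 7)
#' @export
simulate_bioassay <- function(beta0, slope, doses, n_per_dose, seed = NULL,
                              label = "simulated") {
  stopifnot(slope > 0, all(doses > 0), n_per_dose > 0)
  if (!is.null(seed)) set.seed(seed)
  pr <- pnorm(beta0 + slope * log10(doses))
  dead <- rbinom(length(doses), n_per_dose, pr)
  bioassay_table(doses, rep(n_per_dose, length(doses)), dead, label = label)
}

#' Simulate a multi-population allele survey
#'
#' Draws binomial focal-allele counts for a set of populations with known
#' frequencies, emulating a geographic survey genotyping `n_flies`
#' individuals (2 alleles each) per site.
#'
#' @param frequencies per-population focal-allele frequencies in `[0, 1]`.
#' @param n_flies flies genotyped per population (recycled).
#' @param seed optional integer seed.
#' @return `data.frame` with columns `population`, `n_flies`, `n_alleles`,
#'   `count`, `frequency`.
#' @examples
#' simulate_allele_survey(c(0.3, 0.5, 0.8), n_flies = 40, seed = 3)
#' @export
simulate_allele_survey <- function(frequencies, n_flies, seed = NULL) {
  stopifnot(all(frequencies >= 0), all(frequencies <= 1), all(n_flies > 0))
  if (!is.null(seed)) set.seed(seed)
  n_flies <- rep_len(as.integer(n_flies), length(frequencies))
  n_alleles <- 2L * n_flies
  count <- rbinom(length(frequencies), n_alleles, frequencies)
  data.frame(population = seq_along(frequencies),
             n_flies = n_flies, n_alleles = n_alleles,
             count = count, frequency = count / n_alleles)
}
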