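#' Gene action (a, k) from genotype survivorships
#'
#' Genotypic values on the survivorship scale are anchored at the 0-copy
#' homozygote: the three genotypes take values \eqn{0}, \eqn{a(1+k)},
#' \eqn{2a}, where \eqn{a} is half the homozygote survivorship difference
#' and \eqn{k} the dominance coefficient (\eqn{k = 0} additive,
#' \eqn{k = 1} focal allele fully dominant, \eqn{k < 0} focal allele
#' recessive).
#'
#' @param S numeric vector `(S0, S1, S2)` of genotype survival
#'   probabilities, each in `[0, 1]` (see [genotype_survivorship()]).
#' @return Object of class `"gene_action"`: list with `a`, `k`,
#'   `two_a` (= 2a) and the input `S`.
#' @section Errors: `S2 == S0` makes `a = 0` and `k` undefined; this
#'   degenerate (null) locus raises an error here. The pipeline wrapper
#'   [locus_contribution()] instead reports a zero contribution.
#' @examples
#' S <- genotype_survivorship(genotype_counts(27, 52, 45),
#'                            genotype_counts(1286, 911, 179))
#' gene_action(S)  # a ~ 0.09, k ~ -0.63
#' @export
gene_action <- function(S) {
  stopifnot(is.numeric(S), length(S) == 3, all(S >= 0), all(S <= 1))
  if (S[3] == S[1])
    stop("S2 equals S0: a = 0 and the dominance coefficient k is undefined")
  a <- (S[3] - S[1]) / 2
  k <- (S[2] - S[1]) / a - 1
  structure(list(a = unname(a), k = unname(k), two_a = unname(2 * a),
                 S = unname(S)),
            class = "gene_action")
}

#' @export
print.gene_action <- function(x, ...) {
  cat(sprintf("gene action: a = %.4f (2a = %.4f), k = %.3f\n",
              x$a, x$two_a, x$k))
  invisible(x)
}

#' Average allelic effect of the focal allele
#'
#' The average effect of substituting the focal allele, i.e. the slope of
#' the least-squares regression of genotypic value on focal-allele count
#' under Hardy-Weinberg frequencies:
#' \deqn{\alpha = a\,[1 + k(q - p)],}
#' with \eqn{p} the focal-allele frequency and \eqn{q = 1 - p}.
#'
#' @param a half the homozygote difference (from [gene_action()]).
#' @param k dominance coefficient.
#' @param p focal allele frequency, in (0, 1).
#' @return The average allelic effect, in the units of the genotypic values
#'   (here survival-probability units).
#' @examples
#' average_effect(0.0902, -0.629, 0.28)  # ~0.065
#' @export
average_effect <- function(a, k, p) {
  stopifnot(is.numeric(a), is.numeric(k), is.numeric(p))
  if (p <= 0 || p >= 1)
    stop("allele frequency p must lie strictly between 0 and 1")
  a * (1 + k * ((1 - p) - p))
}

#' Additive genetic variance of a bi-allelic locus
#'
#' \deqn{\sigma^2_A = 2 p (1 - p)\,\alpha^2,}
#' the variance of breeding values contributed by the locus under
#' Hardy-Weinberg proportions.
#'
#' @param p focal allele frequency in `[0, 1]`.
#' @param alpha average allelic effect ([average_effect()]).
#' @return The additive variance (squared units of the genotypic values).
#' @examples
#' additive_variance(0.28, 0.0652)  # ~0.0017
#' @export
additive_variance <- function(p, alpha) {
  stopifnot(p >= 0, p <= 1)
  2 * p * (1 - p) * alpha^2
}

#' Expected incidence (population mean survival) under Hardy-Weinberg
#'
#' \deqn{K = q^2 S_0 + 2pq\,S_1 + p^2 S_2,} the population survival
#' fraction expected when genotypes are at Hardy-Weinberg proportions.
#' Serves as the incidence of the binary trait, whose phenotypic variance
#' is \eqn{K(1-K)}.
#'
#' @param S genotype survivorships `(S0, S1, S2)`.
#' @param p focal allele frequency in `[0, 1]`.
#' @return The expected incidence K.
#' @export
expected_incidence <- function(S, p) {
  stopifnot(is.numeric(S), length(S) == 3, p >= 0, p <= 1)
  q <- 1 - p
  unname(q^2 * S[1] + 2 * p * q * S[2] + p^2 * S[3])
}

#' Observed-scale heritability attributable to the locus
#'
#' For a binary (0/1 survival) trait with incidence K the phenotypic
#' variance is \eqn{K(1-K)}, so the locus explains
#' \deqn{h^2_{obs} = \sigma^2_A / [K(1-K)]}
#' of the observed-scale variance.
#'
#' @param sigma2_A additive variance ([additive_variance()]).
#' @param K incidence in (0, 1).
#' @return Observed-scale heritability (proportion).
#' @examples
#' observed_heritability(0.001714, 0.0482)  # ~0.037
#' @export
observed_heritability <- function(sigma2_A, K) {
  stopifnot(sigma2_A >= 0)
  if (K <= 0 || K >= 1) stop("incidence K must lie strictly in (0, 1)")
  sigma2_A / (K * (1 - K))
}

#' Liability-scale heritability (threshold-model transformation)
#'
#' Converts an observed-scale heritability of a binary trait to the
#' underlying continuous "liability" scale using the classical
#' threshold-model (Dempster-Lerner/Robertson) transformation:
#' \deqn{h^2_{liab} = h^2_{obs}\, K(1-K)/z^2,}
#' where K is the incidence and \eqn{z = \phi(\Phi^{-1}(K))} the standard
#' normal density at the liability threshold. The multiplier
#' \eqn{K(1-K)/z^2} exceeds 1 for all K and equals \eqn{\pi/2} at K = 0.5.
#'
#' @param h2_observed observed-scale heritability, >= 0.
#' @param K incidence in (0, 1).
#' @return List with `z` (normal density at the threshold), `multiplier`
#'   (`K(1-K)/z^2`) and `h2_liability`.
#' @examples
#' liability_heritability(0.037, 0.05)$h2_liability  # ~0.165
#' @export
liability_heritability <- function(h2_observed, K) {
  stopifnot(h2_observed >= 0)
  if (K <= 0 || K >= 1) stop("incidence K must lie strictly in (0, 1)")
  z <- dnorm(qnorm(K))
  mult <- K * (1 - K) / z^2
  list(z = z, multiplier = mult, h2_liability = h2_observed * mult)
}

#' Single-locus contribution chain for a tail-genotyping experiment
#'
#' Chains the full analysis on a [tail_experiment()]: scale the dead
#' subsample to the total dead, compute per-genotype survivorships, gene
#' action (a, k), the average allelic effect \eqn{\alpha}, the additive
#' variance \eqn{2pq\alpha^2}, the observed-scale heritability and the
#' liability-scale heritability.
#'
#' Two incidence conventions are provided. The default, `"consistent"`,
#' uses one incidence throughout -- the observed overall survival
#' `sum(alive)/n_exposed` -- and carries full precision through every
#' step. The `"reported"` convention mirrors how such chains are commonly
#' printed in the literature: the observed-scale denominator uses the
#' Hardy-Weinberg expected incidence [expected_incidence()], the
#' observed-scale heritability is rounded to 2 significant figures before
#' the threshold transformation, and the transformation itself uses the
#' nominal tail incidence of the design (0.05 at a nominal-LC95 dose).
#' Both conventions' liability heritabilities are always reported, with
#' the convention flags recorded in the result.
#'
#' A null locus (identical survivorship in the two homozygote classes) is
#' reported as a zero contribution with `k = NA` rather than an error.
#'
#' @param experiment a [tail_experiment()].
#' @param p focal allele frequency in (0, 1).
#' @param convention `"consistent"` (default) or `"reported"`; see Details.
#' @param K_incidence override for the observed-scale incidence
#'   (`"observed"`, `"hwe"`, or a number in (0, 1)).
#' @param liability_K override for the incidence used in the threshold
#'   transformation (number in (0, 1), or `NULL` to reuse `K_incidence`).
#' @param h2_sf round the observed-scale heritability to this many
#'   significant figures before the liability transformation (`NULL`:
#'   no rounding).
#' @return Object of class `"locus_contribution"`: list with `p`,
#'   `scaled_dead`, `S` (survivorships), `gene_action`, `alpha`,
#'   `sigma2_A`, `K` (incidence used, with `K_hwe` and `K_observed` also
#'   reported), `h2_observed`, `z`, `multiplier`, `h2_liability`,
#'   `h2_liability_consistent`, and `conventions`.
#' @examples
#' exp1 <- tail_experiment(genotype_counts(27, 52, 45),
#'                         genotype_counts(72, 51, 10), n_exposed = 2500)
#' locus_contribution(exp1, p = 0.28, convention = "reported")
#' @export
locus_contribution <- function(experiment, p,
                               convention = c("consistent", "reported"),
                               K_incidence = NULL, liability_K = NULL,
                               h2_sf = NULL) {
  convention <- match.arg(convention)
  stopifnot(inherits(experiment, "tail_experiment"))
  if (p <= 0 || p >= 1)
    stop("allele frequency p must lie strictly between 0 and 1")
  if (convention == "reported") {
    K_incidence <- K_incidence %||% "hwe"
    liability_K <- liability_K %||% 0.05
    h2_sf <- h2_sf %||% 2L
  } else {
    K_incidence <- K_incidence %||% "observed"
  }

  dead_est <- scale_dead_counts(experiment$dead_sampled,
                                experiment$total_dead)
  S <- genotype_survivorship(experiment$alive, dead_est)
  K_hwe <- expected_incidence(S, p)
  K_obs <- sum(experiment$alive) / experiment$n_exposed
  K <- if (is.numeric(K_incidence)) K_incidence
       else switch(K_incidence, hwe = K_hwe, observed = K_obs,
                   stop("unknown K_incidence"))

  null_locus <- S[["S2"]] == S[["S0"]]
  if (null_locus) {
    ga <- list(a = 0, k = NA_real_, two_a = 0, S = unname(S))
    class(ga) <- "gene_action"
    alpha <- 0
  } else {
    ga <- gene_action(S)
    alpha <- average_effect(ga$a, ga$k, p)
  }
  s2A <- additive_variance(p, alpha)
  h2_obs <- observed_heritability(s2A, K)

  h2_in <- if (is.null(h2_sf)) h2_obs else signif(h2_obs, h2_sf)
  K_liab <- liability_K %||% K
  liab <- liability_heritability(h2_in, K_liab)
  liab_consistent <- liability_heritability(h2_obs, K)

  structure(list(
    p = p, scaled_dead = dead_est, S = S, gene_action = ga,
    alpha = alpha, sigma2_A = s2A,
    K = K, K_hwe = K_hwe, K_observed = K_obs,
    h2_observed = h2_obs,
    z = liab$z, multiplier = liab$multiplier,
    h2_liability = liab$h2_liability,
    h2_liability_consistent = liab_consistent$h2_liability,
    conventions = list(convention = convention,
                       K_incidence = K_incidence,
                       liability_K = K_liab, h2_sf = h2_sf)),
    class = "locus_contribution")
}

#' @export
print.locus_contribution <- function(x, ...) {
  cat("Single-locus contribution (p =", format(x$p), ")\n")
  cat(sprintf("  survivorships S0/S1/S2: %.4f / %.4f / %.4f\n",
              x$S[1], x$S[2], x$S[3]))
  cat(sprintf("  2a = %.3f, k = %.3f, alpha = %.4f\n",
              x$gene_action$two_a, x$gene_action$k, x$alpha))
  cat(sprintf("  sigma2_A = %.5f,  K = %.4f (HWE %.4f, observed %.4f)\n",
              x$sigma2_A, x$K, x$K_hwe, x$K_observed))
  cat(sprintf("  h2 observed = %.4f;  h2 liability = %.4f (%s convention)\n",
              x$h2_observed, x$h2_liability, x$conventions$convention))
  if (x$conventions$convention != "consistent")
    cat(sprintf("  h2 liability, consistent convention = %.4f\n",
                x$h2_liability_consistent))
  invisible(x)
}
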