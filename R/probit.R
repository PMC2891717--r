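#' Construct a dose-mortality bioassay table
#'
#' A bioassay table holds quantal mortality data: one row per dose group with
#' the dose (micrograms per vial), the number of flies exposed and the number
#' dead at scoring. Zero-dose groups are permitted as controls; they only
#' enter the likelihood when natural-response (control-mortality) modelling
#' is switched on in [fit_probit()].
#'
#' @param dose numeric vector of doses (micrograms per vial), non-negative.
#' @param n_exposed integer vector, flies exposed per group (> 0).
#' @param n_dead integer vector, flies dead per group (0 <= n_dead <= n_exposed).
#' @param label free-text label (strain, sex, allele class).
#' @return A `data.frame` of class `"bioassay_table"` with columns
#'   `dose`, `n_exposed`, `n_dead` and a `label` attribute.
#' @examples
#' bioassay_table(dose = c(1, 3, 10, 30, 100),
#'                n_exposed = rep(60, 5),
#'                n_dead = c(2, 9, 28, 51, 59))
#' @export
bioassay_table <- function(dose, n_exposed, n_dead, label = "") {
  stopifnot(length(dose) == length(n_exposed),
            length(dose) == length(n_dead))
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("doses must be finite and non-negative")
  if (any(n_exposed <= 0) || any(n_exposed != round(n_exposed)))
    stop("n_exposed must be positive integers")
  if (any(n_dead < 0) || any(n_dead > n_exposed) || any(n_dead != round(n_dead)))
    stop("n_dead must be integers with 0 <= n_dead <= n_exposed")
  out <- data.frame(dose = as.numeric(dose),
                    n_exposed = as.integer(n_exposed),
                    n_dead = as.integer(n_dead))
  attr(out, "label") <- as.character(label)[1]
  class(out) <- c("bioassay_table", "data.frame")
  out
}

#' Convert a surface dose to a per-vial dose
#'
#' Exposure is sometimes reported per unit inner surface of the assay vial
#' rather than per vial. No single conversion constant is assumed: the vial
#' area must be supplied explicitly by the user.
#'
#' @param dose_ug_cm2 dose in micrograms per square centimetre.
#' @param vial_area_cm2 coated inner area of the vial in square centimetres.
#' @return Dose in micrograms per vial.
#' @export
ug_per_cm2_to_vial <- function(dose_ug_cm2, vial_area_cm2) {
  stopifnot(is.numeric(dose_ug_cm2), is.numeric(vial_area_cm2),
            vial_area_cm2 > 0)
  dose_ug_cm2 * vial_area_cm2
}

# Empirical-probit least squares starting values, with the
# (d + 0.5)/(n + 1) shrinkage so 0% and 100% groups stay finite.
probit_start <- function(tab) {
  pos <- tab$dose > 0
  x <- log10(tab$dose[pos])
  p <- (tab$n_dead[pos] + 0.5) / (tab$n_exposed[pos] + 1)
  fit <- lm(qnorm(p) ~ x)
  b <- coef(fit)
  c(beta0 = unname(b[1]), beta1 = unname(b[2]))
}

probit_loglik <- function(beta0, beta1, c0, tab) {
  eta <- beta0 + beta1 * log10(tab$dose)
  pr <- c0 + (1 - c0) * pnorm(eta)
  pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
  sum(dbinom(tab$n_dead, tab$n_exposed, pr, log = TRUE))
}

#' Fit a log10-dose probit mortality model by maximum likelihood
#'
#' Models the probability of death at dose \eqn{d} as
#' \deqn{P(\mathrm{dead} \mid d) = c + (1 - c)\,\Phi(\beta_0 + \beta_1 \log_{10} d),}
#' where \eqn{\Phi} is the standard normal distribution function and \eqn{c}
#' is an optional natural-response (dose-independent background mortality)
#' parameter, fixed at 0 by default. With \eqn{c = 0} the model is the
#' standard binomial GLM with probit link on log10 dose, fitted by
#' iteratively reweighted least squares; with natural response the full
#' three-parameter binomial likelihood is maximised numerically starting
#' from the empirical-probit least-squares solution.
#'
#' Zero-dose control groups are excluded from the likelihood unless
#' `use_natural_response = TRUE`, in which case they inform \eqn{c}.
#'
#' @param table a [bioassay_table()] (or data.frame with columns `dose`,
#'   `n_exposed`, `n_dead`).
#' @param use_natural_response logical; estimate the background-mortality
#'   parameter `c` (default `FALSE`).
#' @param maxit iteration cap for the optimiser.
#' @return An object of class `"probit_fit"`: a list with elements
#'   `intercept`, `slope`, `natural_response`, `vcov` (covariance of the
#'   fitted parameters from the inverse observed information), `loglik`,
#'   `converged`, and `data` (the positive-dose groups used).
#' @section Errors:
#'   Fewer than two distinct positive doses, all-dead or all-alive data, or
#'   data with fewer than two partially-killed dose groups (complete
#'   separation: the maximum-likelihood slope diverges) raise an error.
#'   Non-convergence within the iteration cap is flagged via `converged`,
#'   never silently ignored.
#' @examples
#' tab <- bioassay_table(c(1, 100), c(10000, 10000), c(228, 9772))
#' fit <- fit_probit(tab)
#' round(c(fit$intercept, fit$slope), 3)  # close to (-2, 2)
#' @seealso [estimate_lc()] for LC-quantile estimation from the fit.
#' @export
fit_probit <- function(table, use_natural_response = FALSE, maxit = 200L) {
  if (!inherits(table, "bioassay_table"))
    table <- bioassay_table(table$dose, table$n_exposed, table$n_dead)
  pos <- table[table$dose > 0, , drop = FALSE]
  if (length(unique(pos$dose)) < 2)
    stop("need at least 2 distinct positive doses to fit a probit model")
  if (sum(pos$n_dead) == 0 || sum(pos$n_dead) == sum(pos$n_exposed))
    stop("all-alive or all-dead data: dose-response slope is not estimable")
  # pool replicates at the same dose when checking informativeness
  pooled_dead <- tapply(pos$n_dead, pos$dose, sum)
  pooled_n <- tapply(pos$n_exposed, pos$dose, sum)
  informative <- sum(pooled_dead > 0 & pooled_dead < pooled_n)
  if (informative < 2)
    stop("complete separation: fewer than 2 dose groups with partial ",
         "mortality; the maximum-likelihood estimates diverge")

  if (!use_natural_response) {
    fit <- glm(cbind(n_dead, n_exposed - n_dead) ~ log10(dose),
               family = binomial(link = "probit"), data = pos,
               control = glm.control(epsilon = 1e-10, maxit = maxit))
    beta <- unname(coef(fit))
    out <- list(intercept = beta[1], slope = beta[2], natural_response = 0,
                vcov = unname(vcov(fit)), loglik = as.numeric(logLik(fit)),
                converged = isTRUE(fit$converged), data = pos)
  } else {
    st <- probit_start(pos)
    ctrl <- table[table$dose == 0, , drop = FALSE]
    c_start <- if (nrow(ctrl) > 0)
      max(sum(ctrl$n_dead) / sum(ctrl$n_exposed), 1e-4) else 1e-3
    nll <- function(par) {  # controls inform c when natural response is on
      c0 <- par[3]
      ll_ctrl <- if (nrow(ctrl) > 0)
        sum(dbinom(ctrl$n_dead, ctrl$n_exposed,
                   pmin(pmax(c0, 1e-12), 1 - 1e-12), log = TRUE)) else 0
      -(probit_loglik(par[1], par[2], c0, pos) + ll_ctrl)
    }
    opt <- optim(c(st, c0 = c_start), nll, method = "L-BFGS-B",
                 lower = c(-Inf, -Inf, 0), upper = c(Inf, Inf, 1 - 1e-9),
                 hessian = TRUE, control = list(maxit = maxit))
    vc <- tryCatch(solve(opt$hessian), error = function(e)
      matrix(NA_real_, 3, 3))
    out <- list(intercept = unname(opt$par[1]), slope = unname(opt$par[2]),
                natural_response = unname(opt$par[3]),
                vcov = vc, loglik = -opt$value,
                converged = opt$convergence == 0, data = pos)
  }
  if (out$converged && (!is.finite(out$slope) || out$slope == 0))
    stop("degenerate fit: slope is zero or non-finite")
  out$label <- attr(table, "label") %||% ""
  class(out) <- "probit_fit"
  out
}

#' @export
print.probit_fit <- function(x, ...) {
  cat("Log10-dose probit fit", if (nzchar(x$label)) paste0(" [", x$label, "]"),
      "\n", sep = "")
  cat(sprintf("  intercept %.4f  slope %.4f  natural response %.4f\n",
              x$intercept, x$slope, x$natural_response))
  cat(sprintf("  log-likelihood %.3f  converged: %s\n",
              x$loglik, x$converged))
  invisible(x)
}

#' Predict mortality probability at given doses
#'
#' @param object a `"probit_fit"`.
#' @param dose positive doses (micrograms per vial).
#' @param ... unused.
#' @return Vector of death probabilities.
#' @export
predict_mortality <- function(object, dose, ...) {
  stopifnot(inherits(object, "probit_fit"), all(dose > 0))
  c0 <- object$natural_response
  c0 + (1 - c0) * pnorm(object$intercept + object$slope * log10(dose))
}

#' Estimate an LC quantile (lethal concentration) from a probit fit
#'
#' The dose killing a fraction `quantile` of the population is
#' \deqn{\mathrm{LC}_q = 10^{(\Phi^{-1}(q) - \beta_0)/\beta_1}.}
#' Confidence limits are computed on the log10-dose scale by the delta
#' method (default) or by Fieller's theorem, then back-transformed. Under
#' natural-response fits the quantile refers to the dose-dependent
#' (Abbott-corrected) component of mortality, the usual toxicological
#' convention.
#'
#' @param fit a converged `"probit_fit"` with positive slope.
#' @param quantile target kill fraction in (0, 1), e.g. 0.5 for the LC50.
#' @param conf confidence level for the interval (default 0.95).
#' @param method `"delta"` (default) or `"fieller"`.
#' @return An object of class `"lc_estimate"`: list with `quantile`, `dose`,
#'   `ci_low`, `ci_high`, `conf`, `method`.
#' @examples
#' tab <- bioassay_table(c(1, 100), c(10000, 10000), c(228, 9772))
#' estimate_lc(fit_probit(tab), 0.5)$dose  # ~10
#' @export
estimate_lc <- function(fit, quantile, conf = 0.95,
                        method = c("delta", "fieller")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "probit_fit"),
            is.numeric(quantile), quantile > 0, quantile < 1)
  if (!isTRUE(fit$converged))
    stop("probit fit did not converge; LC estimate would be unreliable")
  if (fit$slope <= 0)
    stop("slope is not positive: LC quantile is undefined/unstable")
  z <- qnorm(quantile)
  b0 <- fit$intercept; b1 <- fit$slope
  m <- (z - b0) / b1                      # log10 dose at the quantile
  V <- fit$vcov[1:2, 1:2, drop = FALSE]
  tcrit <- qnorm(1 - (1 - conf) / 2)
  if (method == "delta") {
    grad <- c(-1 / b1, -(z - b0) / b1^2)
    se_m <- sqrt(drop(t(grad) %*% V %*% grad))
    lo <- m - tcrit * se_m; hi <- m + tcrit * se_m
  } else {
    # Fieller: solve (b0 + b1 m - z)^2 = t^2 (V11 + 2 V12 m + V22 m^2)
    A <- b1^2 - tcrit^2 * V[2, 2]
    B <- b1 * (b0 - z) - tcrit^2 * V[1, 2]
    C <- (b0 - z)^2 - tcrit^2 * V[1, 1]
    disc <- B^2 - A * C
    if (A <= 0 || disc < 0) {
      warning("Fieller interval is unbounded (slope not significantly ",
              "positive at this confidence level); returning NA limits")
      lo <- NA_real_; hi <- NA_real_
    } else {
      roots <- sort((-B + c(-1, 1) * sqrt(disc)) / A)
      lo <- roots[1]; hi <- roots[2]
    }
  }
  structure(list(quantile = quantile, dose = 10^m,
                 ci_low = 10^lo, ci_high = 10^hi,
                 conf = conf, method = method),
            class = "lc_estimate")
}

#' @export
print.lc_estimate <- function(x, ...) {
  cat(sprintf("LC%g = %.4g ug/vial  (%g%% CI %.4g - %.4g, %s method)\n",
              100 * x$quantile, x$dose, 100 * x$conf,
              x$ci_low, x$ci_high, x$method))
  invisible(x)
}

#' Compare LC50s between two groups of lines
#'
#' Resistance comparisons between allelic classes are made on replicate
#' line-level LC50s. LC50s are log-normally distributed to a good
#' approximation, so the comparison is a one-tailed Welch (unequal-variance)
#' two-sample t-test on log10(LC50), and the effect size is the ratio of
#' geometric means (fold-change of `group_b` over `group_a`).
#'
#' @param group_a,group_b numeric vectors of positive LC50s, length >= 2 each.
#' @param alternative direction of the one-tailed test; default `"greater"`
#'   tests whether `group_b` is more resistant than `group_a`.
#' @return List with `fold_change` (geometric-mean ratio b/a), `t`, `df`,
#'   `p`, `alternative`.
#' @examples
#' compare_lc50_groups(c(1, 2, 1.5), c(3, 4.5, 3.8))
#' @export
compare_lc50_groups <- function(group_a, group_b,
                                alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 LC50 values")
  if (any(group_a <= 0) || any(group_b <= 0))
    stop("LC50 values must be positive")
  la <- log10(group_a); lb <- log10(group_b)
  tt <- t.test(lb, la, alternative = alternative, var.equal = FALSE)
  list(fold_change = 10^(mean(lb) - mean(la)),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, alternative = alternative)
}
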