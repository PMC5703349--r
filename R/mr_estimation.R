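# Single-instrument Mendelian randomization arithmetic: the Wald ratio with
# its first-order delta-method standard error, allele harmonization for
# two-sample designs, the two-step mediated effect, and asymptotic power.

#' Wald-ratio instrumental-variable estimate
#'
#' The causal effect of the exposure on the outcome is estimated as the
#' ratio of the genotype-outcome coefficient to the genotype-exposure
#' coefficient.  Its standard error is the first-order delta-method
#' expression
#' `sqrt(se_go^2 / beta_ge^2 + beta_go^2 * se_ge^2 / beta_ge^4)`;
#' the covariance cross-term is zero in a two-sample design, where the two
#' coefficients come from independent samples, and is omitted.  The p-value
#' is two-sided normal on `z = ratio / se`.
#'
#' A weak-instrument flag is raised when `|beta_ge| / se_ge < 3` (roughly
#' F < 9); estimation proceeds, since rare-variant instruments legitimately
#' reach this state, but the flag is carried in the result.
#'
#' @param beta_go,se_go genotype-outcome coefficient and standard error.
#' @param beta_ge,se_ge genotype-exposure coefficient and standard error
#'   (`beta_ge` must be non-zero).
#' @param exposure,outcome,instrument optional labels carried through.
#' @return An object of class `iv_estimate`: `ratio` (outcome units per
#'   exposure unit), `se`, `z`, `p`, the input pairs, labels, and
#'   `weak_instrument`.
#' @export
wald_ratio <- function(beta_go, se_go, beta_ge, se_ge,
                       exposure = NA_character_, outcome = NA_character_,
                       instrument = NA_character_) {
  if (!is.finite(beta_ge) || beta_ge == 0)
    stop("degenerate instrument: genotype-exposure coefficient is zero")
  if (!is.finite(se_go) || se_go <= 0 || !is.finite(se_ge) || se_ge <= 0)
    stop("standard errors must be positive")
  ratio <- beta_go / beta_ge
  se <- sqrt(se_go^2 / beta_ge^2 + beta_go^2 * se_ge^2 / beta_ge^4)
  z <- ratio / se
  structure(list(exposure = exposure, outcome = outcome,
                 instrument = instrument,
                 ratio = ratio, se = se, z = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 beta_go = beta_go, se_go = se_go,
                 beta_ge = beta_ge, se_ge = se_ge,
                 weak_instrument = abs(beta_ge) / se_ge < 3),
            class = "iv_estimate")
}

#' @export
print.iv_estimate <- function(x, ...) {
  cat(sprintf("iv_estimate: %s -> %s via %s\n",
              x$exposure, x$outcome, x$instrument))
  cat(sprintf("  ratio %.4g (se %.3g), z = %.3g, p = %.3g%s\n",
              x$ratio, x$se, x$z, x$p,
              if (isTRUE(x$weak_instrument)) "  [weak instrument]" else ""))
  invisible(x)
}

#' Turn a list of IV estimates into a data frame
#'
#' @param estimates list of [wald_ratio()] results.
#' @return A data frame with one row per estimate.
#' @export
iv_table <- function(estimates) {
  do.call(rbind, lapply(estimates, function(e)
    data.frame(exposure = e$exposure, outcome = e$outcome,
               instrument = e$instrument, ratio = e$ratio, se = e$se,
               z = e$z, p = e$p, beta_go = e$beta_go, se_go = e$se_go,
               beta_ge = e$beta_ge, se_ge = e$se_ge,
               weak_instrument = e$weak_instrument,
               stringsAsFactors = FALSE)))
}

#' Harmonize a genotype-outcome / genotype-exposure pair to one effect allele
#'
#' If the two records use opposite effect alleles, the genotype-outcome beta
#' is sign-flipped so both refer to the exposure record's effect allele.
#'
#' @param go,ge one-row `summary_stats` records for the same variant.
#' @return A list with the (possibly flipped) `go`, the unchanged `ge` and a
#'   logical `flipped`.
#' @export
harmonize <- function(go, ge) {
  if (go$variant_id != ge$variant_id)
    stop("harmonize requires the same variant in both records")
  if (identical(go$effect_allele, ge$effect_allele)) {
    flipped <- FALSE
  } else if (identical(go$effect_allele, ge$other_allele) ||
             identical(go$other_allele, ge$effect_allele)) {
    go$beta <- -go$beta
    go$effect_allele <- ge$effect_allele
    go$other_allele <- ge$other_allele
    flipped <- TRUE
  } else {
    stop("irreconcilable effect alleles: ", go$effect_allele, " vs ",
         ge$effect_allele)
  }
  list(go = go, ge = ge, flipped = flipped)
}

#' Mediated effect from chained IV estimates
#'
#' Multiplies the step-2 estimate (outcome per methylation unit) by the
#' step-1 estimate (methylation per pg/ml of exposure) and by an exposure
#' increment, giving the outcome change per increment of exposure acting
#' through the CpG.
#'
#' @param step1 [wald_ratio()] estimate of exposure -> methylation; its
#'   `outcome` label names the CpG.
#' @param step2 [wald_ratio()] estimate of methylation -> outcome; its
#'   `exposure` label must name the same CpG.
#' @param increment exposure increment the effect is quoted per (default 10,
#'   i.e. IQ points per 10 pg/ml).
#' @return An object of class `mediated_effect` with `cpg_id`, `outcome`,
#'   `value` and `exposure_increment`.
#' @export
mediated_effect <- function(step1, step2, increment = 10) {
  if (!identical(step1$outcome, step2$exposure))
    stop("chaining error: step-1 outcome (", step1$outcome,
         ") does not match step-2 exposure (", step2$exposure, ")")
  structure(list(cpg_id = step2$exposure, outcome = step2$outcome,
                 value = step2$ratio * step1$ratio * increment,
                 exposure_increment = increment),
            class = "mediated_effect")
}

#' @export
print.mediated_effect <- function(x, ...) {
  cat(sprintf("mediated_effect: %.3g %s units per %g exposure units via %s\n",
              x$value, x$outcome, x$exposure_increment, x$cpg_id))
  invisible(x)
}

#' Asymptotic power of a two-sample MR analysis
#'
#' Standard large-sample approximation for a single-instrument design:
#' `power = Phi(|beta_std| * sqrt(n * r2) - z_(1 - alpha/2))`, where `r2` is
#' the fraction of exposure variance explained by the instrument and
#' `beta_std` the standardized causal effect.  At `beta_std = 0` this
#' returns `alpha / 2`, the one tail of the two-sided test.
#'
#' @param n outcome-sample size.
#' @param r2 instrument R-squared on the exposure, in (0, 1).
#' @param beta_std standardized causal effect.
#' @param alpha significance level, in (0, 1).
#' @return Power, a probability.
#' @export
mr_power <- function(n, r2, beta_std, alpha = 0.05) {
  if (n <= 0 || r2 <= 0 || r2 >= 1 || alpha <= 0 || alpha >= 1)
    stop("need n > 0, 0 < r2 < 1, 0 < alpha < 1")
  stats::pnorm(abs(beta_std) * sqrt(n * r2) - stats::qnorm(1 - alpha / 2))
}

#' Power of a single-predictor regression F-test
#'
#' Power of the 1-numerator-df F-test at effect size `f2` (Cohen's f-squared)
#' with noncentrality `f2 * (n - 2)`.
#'
#' @param f2 effect size, > 0.
#' @param n sample size (> 3).
#' @param alpha significance level.
#' @return Power, a probability.
#' @export
regression_power <- function(f2, n, alpha = 0.05) {
  if (f2 <= 0 || n <= 3 || alpha <= 0 || alpha > 1)
    stop("need f2 > 0, n > 3, 0 < alpha <= 1")
  if (alpha == 1) return(1)
  crit <- stats::qf(1 - alpha, 1, n - 2)
  stats::pf(crit, 1, n - 2, ncp = f2 * (n - 2), lower.tail = FALSE)
}
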