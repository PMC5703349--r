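# Synthetic cohorts with the causal structure the two-step analysis assumes:
#
#   maternal genotype --> maternal B12 --> child cord-blood methylation --> IQ
#
# plus a latent "socioeconomic" confounder feeding B12, methylation and IQ,
# and one cis-mQTL per instrumentable CpG.  Ground truth is recorded so
# estimator recovery can be tested.

#' Simulation parameters for a synthetic mother-child cohort
#'
#' Defaults describe a cohort in which a common maternal variant shifts
#' circulating vitamin B12 by 70.21 pg/ml per allele, a handful of CpGs
#' respond to B12, and two of those CpGs carry strong cis-mQTLs usable as
#' step-2 instruments.  Methylation is generated on the logit scale and
#' squashed through the logistic function centred at each CpG's baseline, so
#' beta-values stay in (0, 1) while remaining locally linear at small
#' effects.
#'
#' @param n_samples number of mother-child pairs (>= 10).
#' @param n_cpgs number of CpG sites on the array (responsive CpGs included).
#' @param instrument_maf minor-allele frequency of the maternal instrument;
#'   values down to 0.004 emulate a rare-variant instrument.
#' @param beta_gx genotype-to-exposure effect, pg/ml of B12 per allele.
#' @param b12_intercept baseline B12 in pg/ml.
#' @param responsive_cpg_effects named numeric: per-CpG effect of B12 on
#'   methylation, in proportion-methylated per pg/ml, evaluated at the CpG's
#'   baseline. Names become CpG ids; `NULL` simulates a fully null
#'   methylome (as do `NULL` `cis_snp_effects` and `theta_my`).
#' @param cis_snp_effects data frame (`cpg_id`, `variant_id`, `maf`, `beta`)
#'   giving one cis-mQTL per instrumentable CpG; `beta` is the
#'   proportion-methylated change per allele at the CpG baseline.
#' @param theta_my named numeric: effect of methylation on IQ, in IQ points
#'   per proportion methylated, for CpGs lying on the causal path.
#' @param conf_b12,conf_meth,conf_iq confounder loadings: pg/ml, logit units
#'   and IQ points per confounder SD.
#' @param sd_b12 residual SD of B12 in pg/ml (default gives instrument
#'   R-squared of about 0.05 at the default MAF).
#' @param sd_meth residual SD of methylation on the logit scale.
#' @param sd_iq residual SD of each IQ score (marginal IQ SD is close to 15
#'   once confounder and methylation contributions are added).
#' @param n_null_cis_snps number of effect-free SNPs placed inside each cis
#'   window, so instrument discovery has something to reject.
#' @param n_exposure sample size of the independent genotype-exposure panel
#'   used by [simulate_two_sample_panel()].
#' @param panel_maf instrument MAF in the exposure panel; defaults to
#'   `instrument_maf`, and setting it differently reproduces the
#'   allele-frequency mismatch of a trans-ancestry two-sample design.
#' @param seed integer RNG seed; one stream per cohort.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_samples = 2000,
                       n_cpgs = 200,
                       instrument_maf = 0.4,
                       beta_gx = 70.21,
                       b12_intercept = 300,
                       responsive_cpg_effects = c(cg_resp1 = -3.7e-4,
                                                  cg_resp2 = 5.5e-4,
                                                  cg_resp3 = 4.5e-4),
                       cis_snp_effects = data.frame(
                         cpg_id = c("cg_resp2", "cg_resp3"),
                         variant_id = c("rs_cis2", "rs_cis3"),
                         maf = c(0.43, 0.40),
                         beta = c(-0.26, -0.44),
                         stringsAsFactors = FALSE),
                       theta_my = c(cg_resp2 = 8, cg_resp3 = -6),
                       conf_b12 = 30,
                       conf_meth = 0.15,
                       conf_iq = 3,
                       sd_b12 = 210,
                       sd_meth = 0.15,
                       sd_iq = 14.7,
                       n_null_cis_snps = 2,
                       n_exposure = 3495,
                       panel_maf = NULL,
                       seed = 1L) {
  if (is.null(responsive_cpg_effects))
    responsive_cpg_effects <- stats::setNames(numeric(0), character(0))
  if (is.null(cis_snp_effects))
    cis_snp_effects <- data.frame(cpg_id = character(0),
                                  variant_id = character(0),
                                  maf = numeric(0), beta = numeric(0),
                                  stringsAsFactors = FALSE)
  if (is.null(theta_my))
    theta_my <- stats::setNames(numeric(0), character(0))
  if (n_samples < 10) stop("n_samples must be at least 10")
  if (instrument_maf <= 0 || instrument_maf > 0.5)
    stop("instrument_maf must lie in (0, 0.5]")
  if (any(c(sd_b12, sd_meth, sd_iq) <= 0)) stop("all noise SDs must be > 0")
  if (is.null(names(responsive_cpg_effects)) &&
      length(responsive_cpg_effects) > 0)
    stop("responsive_cpg_effects must be a named vector")
  if (n_cpgs < length(responsive_cpg_effects))
    stop("n_cpgs smaller than the number of responsive CpGs")
  if (nrow(cis_snp_effects) &&
      !all(cis_snp_effects$cpg_id %in% names(responsive_cpg_effects)))
    stop("cis_snp_effects refer to unknown CpGs")
  if (nrow(cis_snp_effects) &&
      any(cis_snp_effects$maf <= 0 | cis_snp_effects$maf > 0.5))
    stop("cis-SNP MAFs must lie in (0, 0.5]")
  if (length(theta_my) && !all(names(theta_my) %in%
                               names(responsive_cpg_effects)))
    stop("theta_my refers to unknown CpGs")
  if (is.null(panel_maf)) panel_maf <- instrument_maf
  structure(list(
    n_samples = as.integer(n_samples), n_cpgs = as.integer(n_cpgs),
    instrument_maf = instrument_maf, beta_gx = beta_gx,
    b12_intercept = b12_intercept,
    responsive_cpg_effects = responsive_cpg_effects,
    cis_snp_effects = cis_snp_effects, theta_my = theta_my,
    conf_b12 = conf_b12, conf_meth = conf_meth, conf_iq = conf_iq,
    sd_b12 = sd_b12, sd_meth = sd_meth, sd_iq = sd_iq,
    n_null_cis_snps = as.integer(n_null_cis_snps),
    n_exposure = as.integer(n_exposure), panel_maf = panel_maf,
    seed = as.integer(seed)), class = "sim_params")
}

#' Derive parameters for replicate r
#'
#' Replicate `r` of a simulation study uses `seed + r` on an otherwise
#' identical parameter set.
#'
#' @param params a [sim_params()] object.
#' @param r replicate index.
#' @return A `sim_params` object.
#' @export
replicate_params <- function(params, r) {
  params$seed <- params$seed + as.integer(r)
  params
}

# CpG/variant map for a parameter set: responsive CpGs sit on their own
# chromosomes with a cis window around them; filler CpGs cycle over the
# autosomes far from any simulated SNP.
.sim_map <- function(params) {
  resp <- names(params$responsive_cpg_effects)
  n_fill <- params$n_cpgs - length(resp)
  cpg_ids <- c(resp, sprintf("cg%07d", seq_len(n_fill)))
  resp_chr <- c("19", "22", "1", "3", "7", "11")[(seq_along(resp) - 1) %% 6 + 1]
  fill_chr <- as.character(rep_len(2:18, n_fill))
  ann <- data.frame(
    cpg_id = cpg_ids,
    chromosome = c(resp_chr, fill_chr),
    position = c(5e6 + 1e5 * seq_along(resp),
                 2e7 + 5e4 * seq_len(n_fill)),
    gene = c(sprintf("GENE_%s", toupper(resp)),
             rep("", n_fill)),
    stringsAsFactors = FALSE)
  # variants: maternal instrument plus child cis-SNPs (and null cis-SNPs)
  variants <- data.frame(variant_id = "rs_b12", chromosome = "19",
                         position = 49206674L, effect_allele = "T",
                         maf = params$instrument_maf,
                         beta_logit = 0, cpg_id = NA_character_,
                         stringsAsFactors = FALSE)
  for (k in seq_len(nrow(params$cis_snp_effects))) {
    ci <- params$cis_snp_effects[k, ]
    cpg <- ann[ann$cpg_id == ci$cpg_id, ]
    variants <- rbind(variants, data.frame(
      variant_id = ci$variant_id, chromosome = cpg$chromosome,
      position = cpg$position + 12345L, effect_allele = "C",
      maf = ci$maf, beta_logit = NA_real_, cpg_id = ci$cpg_id,
      stringsAsFactors = FALSE))
    if (params$n_null_cis_snps > 0) {
      for (d in seq_len(params$n_null_cis_snps)) {
        variants <- rbind(variants, data.frame(
          variant_id = sprintf("rs_null_%s_%d", ci$cpg_id, d),
          chromosome = cpg$chromosome,
          position = cpg$position + d * 200000L, effect_allele = "A",
          maf = 0.3, beta_logit = 0, cpg_id = NA_character_,
          stringsAsFactors = FALSE))
      }
    }
  }
  list(annotation = ann, variants = variants)
}

#' Simulate one cohort with recorded ground truth
#'
#' Genotypes are drawn under Hardy-Weinberg equilibrium at the stated MAFs;
#' B12 is linear in the maternal instrument dose plus confounding and noise;
#' methylation is a logistic-squashed linear predictor in centred B12, the
#' cis-SNP dose and the confounder; IQ scores are centred at 100 with
#' methylation and confounder contributions.  A fixed seed yields a
#' bit-identical cohort.
#'
#' @param params a [sim_params()] object.
#' @return A list with elements `cohort` (a [cohort_data()]) and `truth`
#'   (class `sim_truth`): the parameters plus, per responsive CpG, the
#'   realized average causal effect of B12 on the beta-value scale
#'   (`b12_effects`, proportion per pg/ml), the realized cis-mQTL effect per
#'   allele (`cis_effects`), the IQ effect per proportion methylated
#'   (`iq_effects`) and the implied mediated effect on IQ per 10 pg/ml of
#'   B12 (`mediated_per_10pg`).
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  map <- .sim_map(params)
  n <- params$n_samples
  if (n < nrow(map$variants) + 8)
    stop("n_samples too small for the requested model rank")
  set.seed(params$seed)
  ids <- sprintf("S%05d", seq_len(n))

  dos <- sapply(seq_len(nrow(map$variants)), function(k)
    stats::rbinom(n, 2L, map$variants$maf[k]))
  dos <- matrix(as.numeric(dos), nrow = n,
                dimnames = list(ids, map$variants$variant_id))
  geno <- genotype_matrix(dos, map$variants$effect_allele,
                          map$variants[, c("variant_id", "chromosome",
                                           "position")])

  conf <- stats::rnorm(n)
  b12 <- params$b12_intercept + params$beta_gx * dos[, "rs_b12"] +
    params$conf_b12 * conf + stats::rnorm(n, sd = params$sd_b12)
  mu_b12 <- params$b12_intercept + params$beta_gx * 2 * params$instrument_maf

  resp <- names(params$responsive_cpg_effects)
  n_fill <- params$n_cpgs - length(resp)
  b0 <- c(stats::setNames(rep(0.5, length(resp)), resp),
          stats::setNames(stats::runif(n_fill, 0.2, 0.8),
                          setdiff(map$annotation$cpg_id, resp)))
  betas <- matrix(NA_real_, n, params$n_cpgs,
                  dimnames = list(ids, map$annotation$cpg_id))
  avg_deriv <- stats::setNames(numeric(length(resp)), resp)
  cis_realized <- stats::setNames(rep(NA_real_, length(resp)), resp)
  for (j in map$annotation$cpg_id) {
    eta <- stats::qlogis(b0[j]) + params$conf_meth * conf +
      stats::rnorm(n, sd = params$sd_meth)
    if (j %in% resp) {
      s_j <- params$responsive_cpg_effects[j] / (b0[j] * (1 - b0[j]))
      eta <- eta + s_j * (b12 - mu_b12)
      ci <- params$cis_snp_effects[params$cis_snp_effects$cpg_id == j, ]
      if (nrow(ci)) {
        c_logit <- ci$beta / (b0[j] * (1 - b0[j]))
        eta <- eta + c_logit * (dos[, ci$variant_id] - 2 * ci$maf)
      }
    }
    bj <- stats::plogis(eta)
    betas[, j] <- bj
    if (j %in% resp) {
      # realized average marginal effects on the beta-value scale:
      # d beta / d x = slope_logit * beta * (1 - beta), cohort-averaged
      s_j <- params$responsive_cpg_effects[j] / (b0[j] * (1 - b0[j]))
      avg_deriv[j] <- s_j * mean(bj * (1 - bj))
      ci <- params$cis_snp_effects[params$cis_snp_effects$cpg_id == j, ]
      if (nrow(ci))
        cis_realized[j] <- ci$beta / (b0[j] * (1 - b0[j])) *
          mean(bj * (1 - bj))
    }
  }
  meth <- methylation_matrix(betas, map$annotation)

  theta <- stats::setNames(rep(0, length(resp)), resp)
  theta[names(params$theta_my)] <- params$theta_my
  iq_signal <- as.vector(betas[, resp, drop = FALSE] %*% theta -
                           sum(theta * b0[resp]))
  mk_iq <- function() 100 + iq_signal + params$conf_iq * conf +
    stats::rnorm(n, sd = params$sd_iq)

  pheno <- phenotype_table(data.frame(
    sample_id = ids,
    b12 = b12,
    iq_total = mk_iq(), iq_verbal = mk_iq(), iq_performance = mk_iq(),
    mat_age = 29 + stats::rnorm(n, sd = 4.5),
    mat_bmi = 23 + 1.5 * conf + stats::rnorm(n, sd = 3),
    mat_education = stats::rbinom(n, 1, stats::plogis(-1.4 + 0.5 * conf)),
    mat_smoking = stats::rbinom(n, 1, stats::plogis(-2 + 0.5 * conf)),
    parity = stats::rpois(n, 0.7),
    child_sex = stats::rbinom(n, 1, 0.5),
    age_testing = 8.6 + stats::rnorm(n, sd = 0.25),
    stringsAsFactors = FALSE))

  truth <- structure(list(
    params = params,
    instrument = "rs_b12",
    b12_effects = avg_deriv,
    cis_effects = cis_realized,
    iq_effects = theta,
    mediated_per_10pg = avg_deriv * theta * 10,
    baselines = b0), class = "sim_truth")
  list(cohort = cohort_data(geno, meth, pheno), truth = truth)
}

#' Serialize simulation ground truth
#'
#' Writes the `sim_truth` sidecar as YAML next to a generated cohort.
#'
#' @param truth a `sim_truth` object.
#' @param path output path.
#' @export
write_sim_truth <- function(truth, path) {
  p <- truth$params
  out <- list(
    seed = p$seed, n_samples = p$n_samples, n_cpgs = p$n_cpgs,
    instrument = truth$instrument,
    instrument_maf = p$instrument_maf, beta_gx = p$beta_gx,
    b12_effects = as.list(truth$b12_effects),
    iq_effects = as.list(truth$iq_effects),
    mediated_per_10pg = as.list(truth$mediated_per_10pg))
  yaml::write_yaml(out, path, precision = 12L)
  invisible(path)
}

#' Simulate a two-sample design: exposure panel plus analysis cohort
#'
#' The genotype-exposure association is estimated in an independent simulated
#' panel (sample size `n_exposure`, MAF `panel_maf`) and returned as a
#' summary statistic, mimicking the use of an external B12 GWAS; the
#' genotype-methylation arm is a full cohort from [simulate_cohort()].
#' Setting `panel_maf` far from `instrument_maf` reproduces the
#' allele-frequency mismatch that inflates two-sample IV uncertainty.
#'
#' @param params a [sim_params()] object.
#' @return A list with `exposure_stat` (one-row `summary_stats`), `cohort`
#'   and `truth`.
#' @export
simulate_two_sample_panel <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  sim <- simulate_cohort(params)
  set.seed(params$seed + 1000003L)
  m <- params$n_exposure
  dose <- stats::rbinom(m, 2L, params$panel_maf)
  if (stats::var(dose) == 0)
    stop("exposure panel has a monomorphic instrument; increase n_exposure")
  b12 <- params$b12_intercept + params$beta_gx * dose +
    stats::rnorm(m, sd = params$sd_b12)
  fit <- stats::lm.fit(cbind(1, dose), b12)
  rdf <- m - 2L
  sigma2 <- sum(fit$residuals^2) / rdf
  xx <- chol2inv(fit$qr$qr[1:2, 1:2, drop = FALSE])
  se <- sqrt(sigma2 * xx[2, 2])
  beta <- unname(fit$coefficients[2])
  pval <- 2 * stats::pt(-abs(beta / se), rdf)
  list(exposure_stat = summary_stat("rs_b12", "B12", "T",
                                    beta = beta, se = se, n = m, p = pval),
       cohort = sim$cohort, truth = sim$truth)
}
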