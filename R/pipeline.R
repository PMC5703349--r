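# Orchestration of the full two-step analysis: sample partitioning, the
# step-1 methylome scan plus exposure->methylation IV estimates, step-2
# cis-instrument discovery and methylation->outcome IV estimates, and the
# chained mediated effects, with TSV/YAML run artifacts.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  force(expr)
}

#' Pipeline configuration
#'
#' Collects every tunable of the two-step analysis with defaults matching
#' the package's synthetic cohorts.  The step-2 IV regression of IQ on the
#' cis instrument adjusts only for age at testing, while the conventional
#' observational regression of IQ on methylation uses the full covariate
#' list; the two covariate blocks are therefore separate fields.
#'
#' @param instrument variant id of the maternal (exposure) instrument.
#' @param step1_covariates covariate columns for the methylome scan.
#' @param mqtl_covariates covariate columns for cis-mQTL discovery.
#' @param iv_outcome_covariates covariates for the instrument-outcome
#'   regression of step 2 (default age at testing only).
#' @param observational_covariates covariates for the conventional
#'   methylation-outcome regression.
#' @param outcomes phenotype columns treated as outcomes.
#' @param fdr_cutoff BH q-value cutoff selecting step-1 hits.
#' @param top_k optional: select the k smallest-p CpGs instead of the FDR
#'   rule (stress-testing aid).
#' @param mqtl_window,mqtl_p_threshold,clump_r2 cis-instrument discovery
#'   settings (defaults: 1 Mb each side, 1e-7, 0.1).
#' @param instrument_allowlist optional variant ids the step-2 instrument
#'   may be chosen from (models availability of outcome-consortium data).
#' @param exposure_increment exposure increment the mediated effect is
#'   quoted per (default 10 pg/ml).
#' @param discovery_fraction fraction of samples assigned to the
#'   methylation (discovery) partition when no explicit ids are given;
#'   the default 0.15 mirrors a design where only a small arrayed subset
#'   of a large genotyped cohort has methylation data.
#' @param outlier_k IQR multiplier for methylation outlier trimming.
#' @param seed seed for the sample partition.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(instrument = "rs_b12",
                            step1_covariates = c("mat_age", "mat_bmi",
                                                 "mat_education",
                                                 "mat_smoking", "parity",
                                                 "child_sex"),
                            mqtl_covariates = character(),
                            iv_outcome_covariates = "age_testing",
                            observational_covariates = c("age_testing",
                                                         "mat_age",
                                                         "mat_bmi",
                                                         "mat_education",
                                                         "mat_smoking",
                                                         "parity"),
                            outcomes = c("iq_total", "iq_verbal",
                                         "iq_performance"),
                            fdr_cutoff = 0.05, top_k = NULL,
                            mqtl_window = 1e6, mqtl_p_threshold = 1e-7,
                            clump_r2 = 0.1, instrument_allowlist = NULL,
                            exposure_increment = 10,
                            discovery_fraction = 0.15,
                            outlier_k = 3, seed = 1L) {
  if (fdr_cutoff <= 0 || fdr_cutoff > 1) stop("fdr_cutoff must be in (0, 1]")
  if (discovery_fraction <= 0 || discovery_fraction >= 1)
    stop("discovery_fraction must be in (0, 1)")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Partition samples into discovery and outcome sets
#'
#' Discovery samples contribute methylation (step-1 scan, cis-mQTL
#' discovery, observational regressions); outcome samples contribute the
#' instrument-outcome regressions of step 2.  The sets are disjoint so
#' step-2 instruments are never evaluated against the outcome in the sample
#' that selected them.
#'
#' @param sample_ids character vector of all sample ids.
#' @param discovery_fraction fraction assigned to discovery.
#' @param seed partition seed.
#' @return A list with `discovery_ids` and `outcome_ids` (disjoint).
#' @export
sample_partition <- function(sample_ids, discovery_fraction = 0.15,
                             seed = 1L) {
  n_disc <- max(1L, round(length(sample_ids) * discovery_fraction))
  if (n_disc >= length(sample_ids))
    stop("discovery fraction leaves no outcome samples")
  disc <- .with_seed(seed, sort(sample(sample_ids, n_disc)))
  list(discovery_ids = disc,
       outcome_ids = setdiff(sample_ids, disc))
}

#' Step 1: methylome scan and exposure-methylation IV estimates
#'
#' Runs the scan on the discovery samples, selects CpGs at the FDR cutoff
#' (or the top k), and forms one Wald-ratio estimate per selected CpG by
#' pairing its genotype-methylation coefficient with the external
#' genotype-exposure summary statistic (allele-harmonized).
#'
#' @param cohort a [cohort_data()].
#' @param exposure_stat one-row `summary_stats` record for the instrument
#'   against the exposure.
#' @param config a [pipeline_config()].
#' @param discovery_ids samples to scan; default all samples with
#'   methylation.
#' @return A list with `scan` (a `scan_report`), `hits` (CpG ids), `iv`
#'   (named list of `iv_estimate`s), `iv_table` (data frame) and `status`
#'   ("ok" or "no hits").
#' @export
run_step1 <- function(cohort, exposure_stat, config = pipeline_config(),
                      discovery_ids = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (exposure_stat$variant_id != config$instrument)
    stop("exposure statistic is for ", exposure_stat$variant_id,
         ", config instrument is ", config$instrument)
  disc <- if (is.null(discovery_ids)) cohort$sample_ids else discovery_ids
  sub <- subset_cohort(cohort, disc)
  scan <- run_mwas(sub, config$instrument, config$step1_covariates,
                   outlier_k = config$outlier_k)
  res <- scan$results
  hits <- if (is.null(config$top_k)) {
    res$cpg_id[res$q_bh <= config$fdr_cutoff]
  } else {
    utils::head(res$cpg_id, config$top_k)
  }
  if (length(hits) == 0)
    return(list(scan = scan, hits = character(0), iv = list(),
                iv_table = NULL, status = "no hits"))
  allele <- unname(cohort$genotypes$effect_alleles[config$instrument])
  iv <- lapply(hits, function(cpg) {
    row <- res[res$cpg_id == cpg, ]
    go <- summary_stat(config$instrument, cpg, allele,
                       beta = row$beta, se = row$se, n = row$n, p = row$p)
    h <- harmonize(go, exposure_stat)
    wald_ratio(h$go$beta, h$go$se, h$ge$beta, h$ge$se,
               exposure = exposure_stat$trait, outcome = cpg,
               instrument = config$instrument)
  })
  names(iv) <- hits
  list(scan = scan, hits = hits, iv = iv, iv_table = iv_table(iv),
       status = "ok")
}

#' Step 2: cis-instrument discovery and methylation-outcome IV estimates
#'
#' For each step-1 hit: finds and clumps cis-mQTL instruments in the
#' discovery samples, regresses each outcome on the best instrument's dosage
#' in the outcome samples (discovery samples excluded, so instrument
#' selection cannot bias the outcome association), forms the Wald ratio with
#' the discovery-sample mQTL coefficient, fits the conventional
#' observational methylation-outcome regression on the discovery samples for
#' comparison, and chains the mediated effect.  A hit with no qualifying cis
#' instrument is reported as non-instrumentable and skipped.
#'
#' @param cohort a [cohort_data()].
#' @param hits CpG ids selected in step 1.
#' @param step1_iv named list of step-1 `iv_estimate`s (one per hit).
#' @param config a [pipeline_config()].
#' @param partition a [sample_partition()] list.
#' @return A list with `table` (one row per instrumentable CpG x outcome:
#'   instrument, SNP-outcome coefficient, observational coefficient, IV
#'   estimate, mediated effect), `instruments` (chosen cis-SNP per CpG) and
#'   `non_instrumentable` (CpG ids without a cis instrument).
#' @export
run_step2 <- function(cohort, hits, step1_iv, config = pipeline_config(),
                      partition) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(intersect(partition$discovery_ids, partition$outcome_ids)))
    stop("partition sets overlap")
  disc <- subset_cohort(cohort, partition$discovery_ids)
  outc <- subset_cohort(cohort, partition$outcome_ids,
                        drop_methylation = TRUE)
  ann <- disc$methylation$annotation
  rows <- list()
  instr_rows <- list()
  non_inst <- character(0)
  for (cpg in hits) {
    a <- ann[ann$cpg_id == cpg, ]
    if (nrow(a) == 0) { non_inst <- c(non_inst, cpg); next }
    meth_vec <- disc$methylation$betas[, cpg]
    covars <- if (length(config$mqtl_covariates))
      disc$phenotypes[, config$mqtl_covariates, drop = FALSE] else NULL
    cands <- find_cis_snps(a, disc$genotypes, meth_vec, covars,
                           window = config$mqtl_window,
                           p_threshold = config$mqtl_p_threshold,
                           cpg_id = cpg, outlier_k = config$outlier_k)
    if (!is.null(config$instrument_allowlist))
      cands <- cands[cands$variant_id %in% config$instrument_allowlist, ,
                     drop = FALSE]
    clumped <- ld_clump(cands, disc$genotypes, config$clump_r2)
    if (nrow(clumped) == 0) { non_inst <- c(non_inst, cpg); next }
    inst <- clumped[1, ]
    instr_rows[[cpg]] <- inst
    iv_covars <- if (length(config$iv_outcome_covariates))
      as.matrix(outc$phenotypes[, config$iv_outcome_covariates,
                                drop = FALSE]) else NULL
    obs_covars <- if (length(config$observational_covariates))
      as.matrix(disc$phenotypes[, config$observational_covariates,
                                drop = FALSE]) else NULL
    for (outcome in config$outcomes) {
      go <- .ols_dose(outc$phenotypes[[outcome]],
                      outc$genotypes$dosages[, inst$variant_id],
                      iv_covars, outlier_k = Inf)
      obs <- .ols_dose(disc$phenotypes[[outcome]], meth_vec, obs_covars,
                       outlier_k = Inf)
      step2 <- wald_ratio(go$beta, go$se, inst$beta, inst$se,
                          exposure = cpg, outcome = outcome,
                          instrument = inst$variant_id)
      med <- mediated_effect(step1_iv[[cpg]], step2,
                             config$exposure_increment)
      rows[[length(rows) + 1]] <- data.frame(
        cpg_id = cpg, gene = a$gene, chromosome = a$chromosome,
        position = a$position, outcome = outcome,
        instrument = inst$variant_id,
        beta_snp_outcome = go$beta, se_snp_outcome = go$se,
        p_snp_outcome = go$p, n_outcome = go$n,
        beta_obs = obs$beta, se_obs = obs$se, p_obs = obs$p, n_obs = obs$n,
        iv_ratio = step2$ratio, iv_se = step2$se, iv_p = step2$p,
        weak_instrument = step2$weak_instrument,
        mediated = med$value,
        exposure_increment = config$exposure_increment,
        stringsAsFactors = FALSE)
    }
  }
  list(table = if (length(rows)) do.call(rbind, rows) else NULL,
       instruments = if (length(instr_rows)) do.call(rbind, instr_rows)
                     else NULL,
       non_instrumentable = non_inst)
}

#' Run the full two-step analysis
#'
#' Partitions the cohort, runs step 1 then step 2, and (optionally) writes
#' the run artifacts: `scan.tsv`, `step1_iv.tsv`, `instruments.tsv`,
#' `step2_iv.tsv`, `mediated.tsv` and `run_summary.yaml`.  Deterministic
#' under a fixed config seed.  If a stage fails, the artifacts produced so
#' far are retained and the summary records the failing stage.
#'
#' @param cohort a [cohort_data()] with methylation.
#' @param exposure_stat the external genotype-exposure summary statistic.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param partition optional explicit [sample_partition()]; by default the
#'   samples are split with `config$discovery_fraction` and `config$seed`.
#' @return A list with `partition`, `step1`, `step2`, `summary` and
#'   `out_dir`.
#' @export
run_two_step <- function(cohort, exposure_stat, config = pipeline_config(),
                         out_dir = NULL, partition = NULL) {
  if (is.null(partition))
    partition <- sample_partition(cohort$sample_ids,
                                  config$discovery_fraction, config$seed)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  summary <- list(seed = config$seed,
                  n_samples = length(cohort$sample_ids),
                  n_discovery = length(partition$discovery_ids),
                  n_outcome = length(partition$outcome_ids),
                  failure_stage = NULL)
  emit <- function(df, file) {
    if (!is.null(out_dir) && !is.null(df))
      write_results(df, file.path(out_dir, file))
  }
  step1 <- tryCatch(
    run_step1(cohort, exposure_stat, config, partition$discovery_ids),
    error = function(e) e)
  if (inherits(step1, "error")) {
    summary$failure_stage <- "step1"
    summary$error <- conditionMessage(step1)
    if (!is.null(out_dir))
      yaml::write_yaml(summary, file.path(out_dir, "run_summary.yaml"))
    return(list(partition = partition, step1 = NULL, step2 = NULL,
                summary = summary, out_dir = out_dir))
  }
  emit(step1$scan$results, "scan.tsv")
  emit(step1$iv_table, "step1_iv.tsv")
  summary$lambda_gc <- step1$scan$lambda_gc
  summary$n_tested <- step1$scan$n_tested
  summary$n_excluded_probes <- step1$scan$n_excluded_probes
  summary$n_failed_fits <- step1$scan$n_failed
  summary$n_hits <- length(step1$hits)
  summary$status <- step1$status

  step2 <- NULL
  if (step1$status == "ok") {
    step2 <- tryCatch(
      run_step2(cohort, step1$hits, step1$iv, config, partition),
      error = function(e) e)
    if (inherits(step2, "error")) {
      summary$failure_stage <- "step2"
      summary$error <- conditionMessage(step2)
      step2 <- NULL
    } else {
      emit(step2$instruments, "instruments.tsv")
      emit(step2$table, "step2_iv.tsv")
      if (!is.null(step2$table))
        emit(step2$table[, c("cpg_id", "gene", "chromosome", "position",
                             "outcome", "mediated", "exposure_increment")],
             "mediated.tsv")
      summary$non_instrumentable <- as.list(step2$non_instrumentable)
      summary$n_instrumented <-
        length(step1$hits) - length(step2$non_instrumentable)
    }
  }
  if (!is.null(out_dir))
    yaml::write_yaml(summary, file.path(out_dir, "run_summary.yaml"))
  list(partition = partition, step1 = step1, step2 = step2,
       summary = summary, out_dir = out_dir)
}
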