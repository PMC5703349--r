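# Step 1: methylome-wide association scan of an instrument dosage against
# every retained CpG, with covariate adjustment, per-CpG outlier trimming,
# a genomic-inflation diagnostic and multiple-testing adjustment.

#' Remove sex-chromosome and poorly detected probes
#'
#' @param meth a [methylation_matrix()].
#' @param detection_p optional matrix of detection p-values aligned with
#'   `meth$betas` (same dimnames).
#' @param detection_threshold probes whose detection p exceeds this value are
#'   candidates for removal (default 0.05).
#' @param max_fail_frac a probe is dropped when the fraction of samples
#'   failing detection exceeds this; the default 0 drops a probe if any
#'   sample fails.
#' @return The filtered `methylation_matrix`, with attributes
#'   `n_excluded_sex` and `n_excluded_detection` recording exclusion counts.
#' @export
filter_probes <- function(meth, detection_p = NULL,
                          detection_threshold = 0.05, max_fail_frac = 0) {
  stopifnot(inherits(meth, "methylation_matrix"))
  keep <- !meth$annotation$sex_chromosome
  n_sex <- sum(!keep)
  n_det <- 0L
  if (!is.null(detection_p)) {
    if (!all(colnames(meth$betas) %in% colnames(detection_p)))
      stop("detection_p must cover every probe")
    dp <- detection_p[rownames(meth$betas), colnames(meth$betas),
                      drop = FALSE]
    fail_frac <- colMeans(dp > detection_threshold, na.rm = TRUE)
    det_keep <- fail_frac <= max_fail_frac
    n_det <- sum(keep & !det_keep)
    keep <- keep & det_keep
  }
  if (!any(keep)) stop("all probes removed by filtering")
  out <- methylation_matrix(meth$betas[, keep, drop = FALSE],
                            meth$annotation[keep, , drop = FALSE])
  attr(out, "n_excluded_sex") <- n_sex
  attr(out, "n_excluded_detection") <- n_det
  out
}

# Core covariate-adjusted OLS of a response on a dosage.  Returns the dose
# coefficient, its SE, a two-sided t-test p-value and the complete-case count.
.ols_dose <- function(y, dose, covars = NULL, outlier_k = 3) {
  X <- cbind(intercept = 1, dose = dose, covars)
  cc <- stats::complete.cases(X) & !is.na(y)
  if (is.finite(outlier_k)) {
    q <- stats::quantile(y[cc], c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    cc <- cc & y >= q[1] - outlier_k * iqr & y <= q[2] + outlier_k * iqr
    cc[is.na(cc)] <- FALSE
  }
  Xc <- X[cc, , drop = FALSE]
  yc <- y[cc]
  n <- length(yc)
  if (n < ncol(Xc) + 2) stop("too few complete cases after outlier removal")
  if (stats::var(Xc[, "dose"]) == 0)
    stop("degenerate instrument: dosage is constant")
  qr_x <- qr(Xc)
  if (qr_x$rank < ncol(Xc)) stop("rank-deficient design matrix")
  fit <- stats::lm.fit(Xc, yc)
  rdf <- n - qr_x$rank
  sigma2 <- sum(fit$residuals^2) / rdf
  R <- qr.R(qr_x)
  xtx_inv <- chol2inv(R)
  j <- which(colnames(Xc) == "dose")
  se <- sqrt(sigma2 * xtx_inv[j, j])
  beta <- unname(fit$coefficients["dose"])
  tval <- beta / se
  list(beta = beta, se = se, p = 2 * stats::pt(-abs(tval), rdf), n = n)
}

#' Per-CpG covariate-adjusted regression
#'
#' Ordinary least squares of methylation on allele dosage with covariates:
#' the coefficient measures the change in proportion methylated per
#' effect-allele count.  Samples whose beta-value lies more than
#' `outlier_k` interquartile ranges beyond the nearest quartile are dropped
#' before fitting (set `outlier_k = Inf` to disable); p-values use the t
#' distribution on the residual degrees of freedom.
#'
#' @param beta_vector per-sample methylation beta-values.
#' @param dose per-sample allele dosage.
#' @param covariates optional numeric matrix/data frame of adjustment
#'   columns.
#' @param outlier_k IQR multiplier for outlier trimming (default 3).
#' @return A list with `beta`, `se`, `p` and `n` (complete cases used).
#' @export
fit_cpg <- function(beta_vector, dose, covariates = NULL, outlier_k = 3) {
  if (!is.null(covariates)) {
    covariates <- as.matrix(as.data.frame(covariates))
    storage.mode(covariates) <- "double"
  }
  .ols_dose(beta_vector, dose, covariates, outlier_k)
}

#' Genomic inflation factor
#'
#' Lambda is the median of the 1-df chi-square statistics implied by the
#' p-values, divided by the null median `qchisq(0.5, 1)` (0.4549364); values
#' near 1 indicate a calibrated scan.
#'
#' @param p_values numeric vector of p-values in `(0, 1]`.
#' @return The inflation factor, a positive scalar.
#' @export
genomic_inflation <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) == 0) stop("no p-values supplied")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Benjamini-Hochberg q-values with an explicit test count
#'
#' Step-up FDR adjustment `q_(i) = min_(j >= i) p_(j) * n_tests / j`, capped
#' at 1 and mapped back to the input order.  `n_tests` may exceed the number
#' of p-values supplied, which is how a printed top-k table from a
#' methylome-wide scan is adjusted.
#'
#' @param p_values numeric p-values.
#' @param n_tests total number of tests performed (>= `length(p_values)`).
#' @return q-values in input order.
#' @export
adjust_bh <- function(p_values, n_tests = length(p_values)) {
  if (n_tests < length(p_values))
    stop("n_tests must be at least the number of p-values")
  if (length(p_values) == 0) return(numeric(0))
  stats::p.adjust(p_values, method = "BH", n = n_tests)
}

#' Bonferroni adjustment with an explicit test count
#'
#' @inheritParams adjust_bh
#' @return `min(1, p * n_tests)` per p-value.
#' @export
adjust_bonferroni <- function(p_values, n_tests = length(p_values)) {
  if (n_tests < length(p_values))
    stop("n_tests must be at least the number of p-values")
  pmin(1, p_values * n_tests)
}

#' Run the methylome-wide association scan
#'
#' Fits [fit_cpg()] for every retained probe against the chosen instrument
#' dosage, fills in BH q-values and Bonferroni-adjusted p-values using the
#' number of probes actually tested (overridable via `n_tests`), and reports
#' the genomic inflation factor.
#'
#' @param cohort a [cohort_data()] with methylation.
#' @param instrument variant id of the instrument dosage column.
#' @param covariate_names phenotype columns used as adjustment covariates.
#' @param detection_p,detection_threshold,max_fail_frac passed to
#'   [filter_probes()].
#' @param outlier_k passed to [fit_cpg()].
#' @param n_tests multiple-testing denominator; defaults to the number of
#'   probes tested.
#' @return A list of class `scan_report`: `results` (one row per CpG, sorted
#'   by p ascending), `lambda_gc`, `n_tested`, `n_excluded_probes`,
#'   `n_failed`.
#' @export
run_mwas <- function(cohort, instrument, covariate_names = character(),
                     detection_p = NULL, detection_threshold = 0.05,
                     max_fail_frac = 0, outlier_k = 3, n_tests = NULL) {
  stopifnot(inherits(cohort, "cohort_data"))
  if (is.null(cohort$methylation)) stop("cohort has no methylation data")
  if (!instrument %in% colnames(cohort$genotypes$dosages))
    stop("instrument ", instrument, " not present in genotypes")
  miss <- setdiff(covariate_names, names(cohort$phenotypes))
  if (length(miss))
    stop("covariates not in phenotypes: ", paste(miss, collapse = ", "))

  meth <- filter_probes(cohort$methylation, detection_p,
                        detection_threshold, max_fail_frac)
  n_excl <- attr(meth, "n_excluded_sex") + attr(meth, "n_excluded_detection")
  dose <- cohort$genotypes$dosages[, instrument]
  covars <- NULL
  if (length(covariate_names)) {
    covars <- as.matrix(cohort$phenotypes[, covariate_names, drop = FALSE])
    storage.mode(covars) <- "double"
  }

  cpgs <- colnames(meth$betas)
  rows <- vector("list", length(cpgs))
  failed <- character(0)
  for (i in seq_along(cpgs)) {
    fit <- tryCatch(.ols_dose(meth$betas[, i], dose, covars, outlier_k),
                    error = function(e) NULL)
    if (is.null(fit)) failed <- c(failed, cpgs[i]) else rows[[i]] <- fit
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) stop("every probe failed to fit")
  res <- data.frame(
    cpg_id = cpgs[keep],
    beta = vapply(rows[keep], `[[`, numeric(1), "beta"),
    se = vapply(rows[keep], `[[`, numeric(1), "se"),
    p = vapply(rows[keep], `[[`, numeric(1), "p"),
    n = vapply(rows[keep], `[[`, integer(1), "n"),
    stringsAsFactors = FALSE)
  m <- if (is.null(n_tests)) nrow(res) else n_tests
  res$q_bh <- adjust_bh(res$p, m)
  res$p_bonf <- adjust_bonferroni(res$p, m)
  ann <- meth$annotation[match(res$cpg_id, meth$annotation$cpg_id), ]
  res$chromosome <- ann$chromosome
  res$position <- ann$position
  res$gene <- ann$gene
  res <- res[order(res$p, res$cpg_id, method = "radix"), ]
  rownames(res) <- NULL
  structure(list(results = res,
                 lambda_gc = genomic_inflation(res$p),
                 n_tested = nrow(res),
                 n_excluded_probes = n_excl,
                 n_failed = length(failed),
                 failed_cpgs = failed),
            class = "scan_report")
}

#' @export
print.scan_report <- function(x, ...) {
  cat(sprintf(paste0("scan_report: %d CpGs tested, lambda = %.3f, ",
                     "%d probes excluded, %d failed fits\n"),
              x$n_tested, x$lambda_gc, x$n_excluded_probes, x$n_failed))
  top <- utils::head(x$results, 5)
  print(top, digits = 3)
  invisible(x)
}
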