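# Step 2 instrument discovery: cis-window mQTL search around a CpG and
# greedy LD clumping down to independent instruments.

#' Find cis-mQTL candidates for a CpG
#'
#' Regresses methylation at one CpG on the dosage of every same-chromosome
#' SNP within the cis window (covariate-adjusted, via the same OLS engine as
#' the methylome scan with the roles of SNP and CpG swapped) and keeps SNPs
#' passing the association threshold.
#'
#' @param cpg list or one-row data frame with `chromosome` and `position`
#'   of the CpG.
#' @param genotypes a [genotype_matrix()] for the discovery samples.
#' @param meth_vector per-sample methylation beta-values at the CpG, aligned
#'   with the genotype rows.
#' @param covariates optional adjustment columns.
#' @param window cis window in base pairs each side (default 1e6).
#' @param p_threshold association threshold (default 1e-7).
#' @param cpg_id label carried into the results.
#' @param outlier_k passed to the OLS engine.
#' @return A data frame of class `cis_candidates`, sorted by p ascending
#'   (ties: smaller `|distance|`, then variant id), with columns `cpg_id`,
#'   `variant_id`, `distance` (SNP minus CpG position), `beta`, `se`, `p`,
#'   `maf`, `n`.  Empty when no SNP qualifies — a CpG without a cis
#'   instrument is a reportable outcome, not an error.
#' @export
find_cis_snps <- function(cpg, genotypes, meth_vector, covariates = NULL,
                          window = 1e6, p_threshold = 1e-7,
                          cpg_id = NA_character_, outlier_k = 3) {
  pos <- genotypes$positions
  dist <- pos$position - as.integer(cpg$position)
  in_window <- pos$chromosome == as.character(cpg$chromosome) &
    abs(dist) <= window
  empty <- data.frame(cpg_id = character(0), variant_id = character(0),
                      distance = integer(0), beta = numeric(0),
                      se = numeric(0), p = numeric(0), maf = numeric(0),
                      n = integer(0), stringsAsFactors = FALSE)
  class(empty) <- c("cis_candidates", "data.frame")
  if (!any(in_window)) return(empty)
  if (!is.null(covariates)) {
    covariates <- as.matrix(as.data.frame(covariates))
    storage.mode(covariates) <- "double"
  }
  idx <- which(in_window)
  rows <- lapply(idx, function(k) {
    dose <- genotypes$dosages[, k]
    fit <- tryCatch(.ols_dose(meth_vector, dose, covariates, outlier_k),
                    error = function(e) NULL)
    if (is.null(fit) || fit$p >= p_threshold) return(NULL)
    af <- mean(dose, na.rm = TRUE) / 2
    data.frame(cpg_id = cpg_id, variant_id = pos$variant_id[k],
               distance = dist[k], beta = fit$beta, se = fit$se,
               p = fit$p, maf = min(af, 1 - af), n = fit$n,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$p, abs(out$distance), out$variant_id,
                   method = "radix"), ]
  rownames(out) <- NULL
  class(out) <- c("cis_candidates", "data.frame")
  out
}

#' Greedy LD clumping of cis-mQTL candidates
#'
#' Accepts the most significant candidate, removes every remaining candidate
#' whose squared dosage correlation with an accepted SNP exceeds the
#' threshold, and repeats.  LD is the squared Pearson correlation of dosages
#' in the analysis sample; no external reference panel is used.  Candidates
#' are ranked by p (ties: smaller `|distance|`, then variant id), so the
#' result does not depend on input row order.
#'
#' @param candidates a `cis_candidates` data frame (see [find_cis_snps()]).
#' @param genotypes the [genotype_matrix()] the LD is computed in.
#' @param r2_threshold squared-correlation threshold above which two SNPs
#'   are considered one clump (default 0.1).
#' @return The accepted subset, same columns as the input; every retained
#'   pair has pairwise r-squared at or below the threshold.
#' @export
ld_clump <- function(candidates, genotypes, r2_threshold = 0.1) {
  if (nrow(candidates) == 0) return(candidates)
  ord <- order(candidates$p, abs(candidates$distance),
               candidates$variant_id, method = "radix")
  candidates <- candidates[ord, , drop = FALSE]
  dos <- genotypes$dosages[, candidates$variant_id, drop = FALSE]
  sds <- apply(dos, 2, stats::sd, na.rm = TRUE)
  if (any(constant <- !is.finite(sds) | sds == 0)) {
    warning("dropping candidates with constant dosage: ",
            paste(candidates$variant_id[constant], collapse = ", "))
    candidates <- candidates[!constant, , drop = FALSE]
    dos <- dos[, !constant, drop = FALSE]
    if (nrow(candidates) == 0) return(candidates)
  }
  accepted <- integer(0)
  remaining <- seq_len(nrow(candidates))
  while (length(remaining)) {
    top <- remaining[1]
    accepted <- c(accepted, top)
    remaining <- remaining[-1]
    if (length(remaining)) {
      r2 <- stats::cor(dos[, top], dos[, remaining, drop = FALSE],
                       use = "pairwise.complete.obs")^2
      remaining <- remaining[is.na(r2) | r2 <= r2_threshold]
    }
  }
  out <- candidates[accepted, , drop = FALSE]
  rownames(out) <- NULL
  out
}
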