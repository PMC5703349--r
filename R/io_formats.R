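# Tabular input/output with schema validation.
#
# Every table is tab-separated UTF-8 with a single header row and "NA" for
# missing values.  Positions are 1-based; chromosome labels carry no "chr"
# prefix.  All readers return validated in-memory structures so downstream
# code never has to re-check invariants.

MISSING_DOSAGE_OK <- TRUE
BETA_EPS <- 1e-6

#' Construct a genotype dosage matrix
#'
#' @param dosages numeric matrix, samples in rows and variants in columns,
#'   holding expected minor-allele counts in `[0, 2]` (hard calls are simply
#'   dosages in `{0, 1, 2}`). `NA` marks missing genotypes.
#' @param effect_alleles character vector, one allele per variant; the allele
#'   whose count the dosage measures.
#' @param positions data frame with columns `variant_id`, `chromosome`
#'   (character, no "chr" prefix) and `position` (1-based integer).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, effect_alleles, positions) {
  if (!is.matrix(dosages) || !is.numeric(dosages))
    stop("dosages must be a numeric matrix")
  sample_ids <- rownames(dosages)
  variant_ids <- colnames(dosages)
  if (is.null(sample_ids) || is.null(variant_ids))
    stop("dosages must have sample row names and variant column names")
  if (anyDuplicated(sample_ids)) stop("duplicate sample_ids")
  if (anyDuplicated(variant_ids)) stop("duplicate variant_ids")
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop("dosages outside [0, 2]")
  if (length(effect_alleles) != ncol(dosages))
    stop("one effect allele per variant required")
  req <- c("variant_id", "chromosome", "position")
  if (!all(req %in% names(positions)))
    stop("positions needs columns variant_id, chromosome, position")
  if (!setequal(positions$variant_id, variant_ids) ||
      nrow(positions) != length(variant_ids))
    stop("positions must cover every variant exactly once")
  positions <- positions[match(variant_ids, positions$variant_id), req]
  positions$chromosome <- as.character(positions$chromosome)
  positions$position <- as.integer(positions$position)
  rownames(positions) <- NULL
  structure(
    list(dosages = dosages,
         effect_alleles = stats::setNames(as.character(effect_alleles),
                                          variant_ids),
         positions = positions),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Construct a methylation beta-value matrix
#'
#' Beta-values (proportion of methylated DNA molecules at a CpG) are clamped
#' into `(eps, 1 - eps)` so logit-scale arithmetic is always defined.
#'
#' @param betas numeric matrix, samples x CpGs, values in `[0, 1]`.
#' @param annotation data frame with columns `cpg_id`, `chromosome`,
#'   `position`, `gene`; a `sex_chromosome` flag is derived from the
#'   chromosome label (`X` or `Y`).
#' @param eps clamping margin, default `1e-6`.
#' @return An object of class `methylation_matrix`.
#' @export
methylation_matrix <- function(betas, annotation, eps = BETA_EPS) {
  if (!is.matrix(betas) || !is.numeric(betas))
    stop("betas must be a numeric matrix")
  if (is.null(rownames(betas)) || is.null(colnames(betas)))
    stop("betas must have sample row names and CpG column names")
  if (anyDuplicated(rownames(betas))) stop("duplicate sample_ids")
  if (anyDuplicated(colnames(betas))) stop("duplicate cpg_ids")
  rng <- range(betas, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("beta-values outside [0, 1]")
  betas[] <- pmin(pmax(betas, eps), 1 - eps)
  req <- c("cpg_id", "chromosome", "position", "gene")
  if (!all(req %in% names(annotation)))
    stop("annotation needs columns cpg_id, chromosome, position, gene")
  miss <- setdiff(colnames(betas), annotation$cpg_id)
  if (length(miss))
    stop("CpGs missing from annotation: ", paste(miss, collapse = ", "))
  annotation <- annotation[match(colnames(betas), annotation$cpg_id), req]
  annotation$chromosome <- as.character(annotation$chromosome)
  annotation$position <- as.integer(annotation$position)
  annotation$sex_chromosome <- annotation$chromosome %in% c("X", "Y")
  rownames(annotation) <- NULL
  structure(list(betas = betas, annotation = annotation),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("methylation_matrix: %d samples x %d CpGs (%d on sex chromosomes)\n",
              nrow(x$betas), ncol(x$betas), sum(x$annotation$sex_chromosome)))
  invisible(x)
}

#' Construct a phenotype/covariate table
#'
#' @param df data frame with a `sample_id` column plus numeric or categorical
#'   phenotype and covariate columns (exposure, IQ outcomes, maternal
#'   covariates, batch and cell-composition columns, ...).
#' @return The validated data frame, classed `phenotype_table`.
#' @export
phenotype_table <- function(df) {
  if (!"sample_id" %in% names(df)) stop("phenotypes need a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_ids")
  df$sample_id <- as.character(df$sample_id)
  rownames(df) <- NULL
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Bundle aligned cohort tables
#'
#' Intersects the three tables on `sample_id` and reorders each so row `i`
#' refers to the same mother-child pair everywhere.
#'
#' @param genotypes a [genotype_matrix()].
#' @param methylation a [methylation_matrix()], or `NULL` for samples without
#'   array data.
#' @param phenotypes a [phenotype_table()].
#' @return An object of class `cohort_data`.
#' @export
cohort_data <- function(genotypes, methylation, phenotypes) {
  ids <- intersect(rownames(genotypes$dosages), phenotypes$sample_id)
  if (!is.null(methylation)) ids <- intersect(ids, rownames(methylation$betas))
  if (length(ids) == 0) stop("no samples shared across tables")
  genotypes$dosages <- genotypes$dosages[ids, , drop = FALSE]
  if (!is.null(methylation))
    methylation$betas <- methylation$betas[ids, , drop = FALSE]
  phenotypes <- phenotypes[match(ids, phenotypes$sample_id), , drop = FALSE]
  rownames(phenotypes) <- NULL
  structure(list(genotypes = genotypes, methylation = methylation,
                 phenotypes = phenotypes, sample_ids = ids),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("cohort_data: %d samples, %d variants, %s CpGs\n",
              length(x$sample_ids), ncol(x$genotypes$dosages),
              if (is.null(x$methylation)) "no" else ncol(x$methylation$betas)))
  invisible(x)
}

#' Subset a cohort to a set of sample ids
#'
#' @param cohort a [cohort_data()] object.
#' @param ids sample ids to keep (order preserved).
#' @param drop_methylation drop the methylation table entirely, emulating
#'   samples genotyped but not arrayed.
#' @return A `cohort_data` restricted to `ids`.
#' @export
subset_cohort <- function(cohort, ids, drop_methylation = FALSE) {
  ids <- intersect(ids, cohort$sample_ids)
  if (length(ids) == 0) stop("no requested samples present in cohort")
  g <- cohort$genotypes
  g$dosages <- g$dosages[ids, , drop = FALSE]
  m <- cohort$methylation
  if (drop_methylation) m <- NULL
  else if (!is.null(m)) m$betas <- m$betas[ids, , drop = FALSE]
  ph <- cohort$phenotypes[match(ids, cohort$phenotypes$sample_id), ,
                          drop = FALSE]
  rownames(ph) <- NULL
  structure(list(genotypes = g, methylation = m, phenotypes = ph,
                 sample_ids = ids),
            class = "cohort_data")
}

# ---------------------------------------------------------------------------
# readers / writers

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", na.strings = "NA",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = NA)
}

.fmt_num <- function(x) {
  out <- ifelse(is.na(x), "NA", sprintf("%.10g", x))
  out
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], .fmt_num)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, na = "NA",
                       row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  invisible(ok)
}

#' Read a genotype dosage table
#'
#' Expects metadata columns `variant_id`, `chromosome`, `position`,
#' `effect_allele` followed by one numeric column per sample (variants in
#' rows).
#'
#' @param path path to a tab-separated file.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  df <- .read_tsv(path)
  meta <- c("variant_id", "chromosome", "position", "effect_allele")
  if (!all(meta %in% names(df)))
    stop("malformed genotype header: need columns ",
         paste(meta, collapse = ", "))
  sample_cols <- setdiff(names(df), meta)
  if (length(sample_cols) == 0) stop("no sample columns in ", path)
  dos <- t(as.matrix(df[, sample_cols, drop = FALSE]))
  if (!is.numeric(dos)) stop("non-numeric dosage values in ", path)
  colnames(dos) <- df$variant_id
  rownames(dos) <- sample_cols
  genotype_matrix(dos, df$effect_allele,
                  df[, c("variant_id", "chromosome", "position")])
}

#' Write a genotype dosage table
#'
#' @param geno a [genotype_matrix()].
#' @param path output path.
#' @export
write_genotypes <- function(geno, path) {
  df <- data.frame(variant_id = colnames(geno$dosages),
                   chromosome = geno$positions$chromosome,
                   position = geno$positions$position,
                   effect_allele = unname(geno$effect_alleles),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(t(geno$dosages)))
  .write_tsv(df, path)
}

#' Read a methylation beta-value matrix with its CpG annotation
#'
#' @param path beta matrix TSV: `cpg_id` column followed by one column per
#'   sample (CpGs in rows).
#' @param annotation_path annotation TSV with columns `cpg_id`, `chromosome`,
#'   `position`, `gene`.
#' @param eps clamping margin applied at load, see [methylation_matrix()].
#' @return A [methylation_matrix()].
#' @export
read_methylation <- function(path, annotation_path, eps = BETA_EPS) {
  df <- .read_tsv(path)
  if (names(df)[1] != "cpg_id")
    stop("malformed methylation header: first column must be cpg_id")
  ann <- .read_tsv(annotation_path)
  betas <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(betas) <- df$cpg_id
  methylation_matrix(betas, ann, eps = eps)
}

#' Write a methylation matrix and its annotation
#'
#' @param meth a [methylation_matrix()].
#' @param path beta matrix output path.
#' @param annotation_path annotation output path.
#' @export
write_methylation <- function(meth, path, annotation_path) {
  df <- data.frame(cpg_id = colnames(meth$betas), stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(t(meth$betas)))
  .write_tsv(df, path)
  .write_tsv(meth$annotation[, c("cpg_id", "chromosome", "position", "gene")],
             annotation_path)
}

#' Read a phenotype/covariate table
#'
#' @param path TSV with a `sample_id` column.
#' @return A [phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  phenotype_table(.read_tsv(path))
}

#' Write a phenotype table
#'
#' @param pheno a [phenotype_table()].
#' @param path output path.
#' @export
write_phenotypes <- function(pheno, path) {
  .write_tsv(as.data.frame(pheno), path)
}

#' Read GWAS-style summary statistics
#'
#' One row per (variant, trait) association, in the common summary-statistics
#' TSV dialect: `variant_id`, `trait`, `effect_allele`, `other_allele`,
#' `beta`, `se`, `n`, `p`.
#'
#' @param path path to the TSV.
#' @return A data frame of validated records, classed `summary_stats`.
#' @export
read_summary_stats <- function(path) {
  df <- .read_tsv(path)
  req <- c("variant_id", "trait", "effect_allele", "other_allele",
           "beta", "se", "n", "p")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("summary-statistics file missing columns: ",
         paste(miss, collapse = ", "))
  df <- df[, req]
  if (nrow(df)) {
    if (any(!is.finite(df$se) | df$se <= 0))
      stop("summary statistics must have se > 0")
    if (any(df$p < 0 | df$p > 1, na.rm = TRUE))
      stop("p-values must lie in [0, 1]")
  }
  class(df) <- c("summary_stats", "data.frame")
  df
}

#' Build a single summary-statistic record
#'
#' @param variant_id,trait,effect_allele,other_allele identifiers.
#' @param beta effect size in trait units per effect-allele count.
#' @param se positive standard error.
#' @param n sample size.
#' @param p association p-value.
#' @return A one-row `summary_stats` data frame.
#' @export
summary_stat <- function(variant_id, trait, effect_allele, beta, se, n,
                         p = NA_real_, other_allele = NA_character_) {
  if (!is.finite(se) || se <= 0) stop("se must be > 0")
  if (is.finite(p) && (p < 0 || p > 1)) stop("p must lie in [0, 1]")
  df <- data.frame(variant_id = variant_id, trait = trait,
                   effect_allele = effect_allele,
                   other_allele = other_allele,
                   beta = beta, se = se, n = as.integer(n), p = p,
                   stringsAsFactors = FALSE)
  class(df) <- c("summary_stats", "data.frame")
  df
}

#' Write result records deterministically
#'
#' Writes association-scan or IV-estimate tables with a fixed column order,
#' p-values in scientific notation, and rows ordered by (chromosome,
#' position) when those columns are present (otherwise by the first id
#' column).  Shuffling the input rows therefore never changes the bytes
#' written.
#'
#' @param records a data frame of homogeneous records (e.g. the `results`
#'   table of a scan report, or an IV-estimate table).
#' @param path output path.
#' @export
write_results <- function(records, path) {
  records <- as.data.frame(records)
  if (nrow(records)) {
    if (all(c("chromosome", "position") %in% names(records))) {
      ord <- order(records$chromosome, records$position,
                   records[[1]], method = "radix")
    } else {
      ord <- order(records[[1]], method = "radix")
    }
    records <- records[ord, , drop = FALSE]
  }
  pcols <- intersect(c("p", "q_bh", "p_bonf"), names(records))
  for (pc in pcols)
    records[[pc]] <- ifelse(is.na(records[[pc]]), "NA",
                            sprintf("%.6e", records[[pc]]))
  .write_tsv(records, path)
}
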