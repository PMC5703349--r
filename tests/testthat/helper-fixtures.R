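# Shared fixtures and independent oracles, all built in code.

std_covariates <- c("mat_age", "mat_bmi", "mat_education", "mat_smoking",
                    "parity", "child_sex")

# small hand-buildable genotype matrix
make_geno_fixture <- function(n = 3, variants = c("rs1", "rs2"),
                              chromosome = c("1", "1"),
                              position = c(1000L, 2000L),
                              dosages = NULL, seed = 1) {
  if (is.null(dosages)) {
    set.seed(seed)
    dosages <- matrix(sample(0:2, n * length(variants), replace = TRUE),
                      nrow = n)
  }
  dimnames(dosages) <- list(sprintf("S%03d", seq_len(n)), variants)
  genotype_matrix(dosages, rep("A", length(variants)),
                  data.frame(variant_id = variants, chromosome = chromosome,
                             position = position))
}

make_meth_fixture <- function(n = 3, cpgs = c("cg1", "cg2"),
                              chromosome = rep("1", length(cpgs)),
                              betas = NULL, seed = 1) {
  if (is.null(betas)) {
    set.seed(seed)
    betas <- matrix(runif(n * length(cpgs), 0.2, 0.8), nrow = n)
  }
  dimnames(betas) <- list(sprintf("S%03d", seq_len(n)), cpgs)
  methylation_matrix(betas,
                     data.frame(cpg_id = cpgs, chromosome = chromosome,
                                position = seq_along(cpgs) * 1000L,
                                gene = toupper(cpgs)))
}

# Exhaustive Benjamini-Hochberg oracle: q_(i) = min over j >= i of
# p_(j) * m / j, capped at 1, mapped back to input order.
bh_oracle <- function(p, m = length(p)) {
  k <- length(p)
  o <- order(p)
  q <- numeric(k)
  for (i in seq_len(k)) {
    js <- i:k
    q[o[i]] <- min(1, min(p[o][js] * m / js))
  }
  q
}

# Normal-equations OLS oracle for the dose coefficient.
ols_oracle <- function(y, dose, covars = NULL) {
  X <- cbind(1, dose, covars)
  xtx <- solve(t(X) %*% X)
  b <- xtx %*% t(X) %*% y
  res <- y - X %*% b
  rdf <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / rdf
  se <- sqrt(sigma2 * xtx[2, 2])
  list(beta = b[2], se = se, p = 2 * pt(-abs(b[2] / se), rdf))
}

# a null (no planted effect) parameter set for calibration runs
null_params <- function(n_samples, n_cpgs, seed, conf_meth = 0) {
  sim_params(n_samples = n_samples, n_cpgs = n_cpgs, seed = seed,
             conf_meth = conf_meth,
             responsive_cpg_effects = NULL, cis_snp_effects = NULL,
             theta_my = NULL)
}
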