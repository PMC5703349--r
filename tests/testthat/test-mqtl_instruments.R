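# Constructed genotype panels with known correlation structure plus
# simulated cohorts exercise the cis-window search and greedy clumping.

make_cis_panel <- function(n = 400, seed = 30) {
  set.seed(seed)
  base <- rbinom(n, 2, 0.4)
  jitter_copy <- function(frac) {
    d <- base
    idx <- sample(n, round(frac * n))
    d[idx] <- rbinom(length(idx), 2, 0.4)
    d
  }
  dos <- cbind(snp_a = base, snp_b = jitter_copy(0.05),
               snp_c = jitter_copy(0.05), snp_d = jitter_copy(0.05),
               snp_e = jitter_copy(0.05), snp_f = jitter_copy(0.05),
               snp_far = rbinom(n, 2, 0.3),
               snp_indep = rbinom(n, 2, 0.3))
  rownames(dos) <- sprintf("S%04d", seq_len(n))
  genotype_matrix(dos, rep("A", ncol(dos)),
                  data.frame(variant_id = colnames(dos),
                             chromosome = c(rep("5", 6), "5", "5"),
                             position = c(1e6 + (0:5) * 1e4,
                                          2.6e6, 1.4e6)))
}

test_that("cis search honours the window and threshold rules", {
  g <- make_cis_panel()
  set.seed(31)
  # methylation driven by snp_a; snp_far lies 1.5 Mb away
  y <- plogis(qlogis(0.5) - 0.8 * (g$dosages[, "snp_a"] - 0.8) +
                rnorm(400, sd = 0.3))
  cpg <- list(chromosome = "5", position = 1.1e6)
  cands <- find_cis_snps(cpg, g, y, cpg_id = "cg_t")
  expect_true("snp_a" %in% cands$variant_id)
  expect_false("snp_far" %in% cands$variant_id)  # outside the 1 Mb window
  expect_true(!is.unsorted(cands$p))
  expect_true(all(abs(cands$distance) <= 1e6))
  expect_true(all(cands$p < 1e-7))

  # a far SNP stays excluded no matter how associated it is
  y_far <- plogis(qlogis(0.5) - 0.8 * (g$dosages[, "snp_far"] - 0.6) +
                    rnorm(400, sd = 0.1))
  cands_far <- find_cis_snps(cpg, g, y_far, cpg_id = "cg_t")
  expect_false("snp_far" %in% cands_far$variant_id)

  # pure noise yields an empty candidate list, not an error
  null_cands <- find_cis_snps(cpg, g, runif(400, 0.4, 0.6), cpg_id = "cg_t")
  expect_equal(nrow(null_cands), 0L)

  # degenerate limits: infinite window + unit threshold = every SNP on the
  # chromosome
  all_cands <- find_cis_snps(cpg, g, y, window = Inf, p_threshold = 1,
                             cpg_id = "cg_t")
  expect_setequal(all_cands$variant_id, colnames(g$dosages))
})

test_that("greedy clumping keeps one representative per LD block", {
  g <- make_cis_panel()
  set.seed(32)
  y <- plogis(qlogis(0.5) - 0.8 * (g$dosages[, "snp_a"] - 0.8) +
                rnorm(400, sd = 0.3))
  cpg <- list(chromosome = "5", position = 1.1e6)
  cands <- find_cis_snps(cpg, g, y, p_threshold = 1, window = Inf,
                         cpg_id = "cg_t")
  block <- cands[cands$variant_id %in%
                   c("snp_a", "snp_b", "snp_c", "snp_d", "snp_e", "snp_f"), ]
  kept <- ld_clump(block, g, r2_threshold = 0.1)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$variant_id, block$variant_id[which.min(block$p)])

  # mutually uncorrelated candidates all survive
  indep <- cands[cands$variant_id %in% c("snp_a", "snp_indep", "snp_far"), ]
  expect_equal(nrow(ld_clump(indep, g, 0.1)), 3L)

  # the retained set satisfies the pairwise r-squared guarantee
  full <- ld_clump(cands, g, 0.1)
  if (nrow(full) > 1) {
    r2 <- cor(g$dosages[, full$variant_id])^2
    expect_true(all(r2[upper.tri(r2)] <= 0.1))
  }

  # input order cannot change the outcome
  shuffled <- cands[sample(nrow(cands)), ]
  expect_equal(ld_clump(shuffled, g, 0.1)$variant_id, full$variant_id)

  # perfectly correlated duplicate: lower p wins
  two <- cands[cands$variant_id %in% c("snp_a", "snp_b"), ]
  two$p[two$variant_id == "snp_a"] <- 1e-8
  two$p[two$variant_id == "snp_b"] <- 1e-10
  kept2 <- ld_clump(two, g, 0.1)
  expect_equal(nrow(kept2), 1L)
  expect_equal(kept2$variant_id, "snp_b")
})

test_that("constant-dosage candidates are dropped with a warning", {
  dos <- cbind(ok = rbinom(50, 2, 0.4), flat = rep(1, 50))
  rownames(dos) <- sprintf("S%02d", 1:50)
  g <- genotype_matrix(dos, c("A", "A"),
                       data.frame(variant_id = c("ok", "flat"),
                                  chromosome = "1", position = c(100L, 200L)))
  cands <- data.frame(cpg_id = "cg", variant_id = c("ok", "flat"),
                      distance = c(0L, 100L), beta = c(0.1, 0.1),
                      se = c(0.01, 0.01), p = c(1e-9, 1e-8),
                      maf = c(0.4, 0.5), n = 50L)
  expect_warning(kept <- ld_clump(cands, g, 0.1), "constant dosage")
  expect_equal(kept$variant_id, "ok")
})

test_that("a planted strong cis-mQTL is recovered below the mQTL threshold", {
  sim <- simulate_cohort(sim_params(n_samples = 2000, n_cpgs = 5, seed = 33))
  co <- sim$cohort
  ann <- co$methylation$annotation
  a3 <- ann[ann$cpg_id == "cg_resp3", ]
  cands <- find_cis_snps(a3, co$genotypes,
                         co$methylation$betas[, "cg_resp3"],
                         cpg_id = "cg_resp3")
  expect_true("rs_cis3" %in% cands$variant_id)
  expect_lt(cands$p[cands$variant_id == "rs_cis3"], 1e-7)
  # the planted effect is negative on the beta-value scale
  expect_lt(cands$beta[cands$variant_id == "rs_cis3"], 0)
})
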