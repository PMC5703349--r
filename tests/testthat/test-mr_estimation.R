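test_that("wald_ratio follows the ratio-estimator formulas", {
  # zero numerator collapses the delta-method SE to se_go / |beta_ge|
  iv <- wald_ratio(0, 0.3, -2, 0.1)
  expect_equal(iv$ratio, 0)
  expect_equal(iv$se, 0.3 / 2)
  expect_equal(iv$p, 1)

  # allele-coding invariance: flipping both coefficients changes nothing
  a <- wald_ratio(0.8, 0.2, 1.5, 0.1)
  b <- wald_ratio(-0.8, 0.2, -1.5, 0.1)
  expect_equal(a$ratio, b$ratio)
  expect_equal(a$se, b$se)
  expect_equal(a$p, b$p)

  expect_error(wald_ratio(1, 0.1, 0, 0.1), "degenerate")
  expect_error(wald_ratio(1, -0.1, 2, 0.1), "positive")
  expect_true(wald_ratio(1, 0.5, 1, 0.5)$weak_instrument)
  expect_false(wald_ratio(1, 0.5, 10, 0.5)$weak_instrument)
})

test_that("delta-method SE matches a parametric bootstrap for strong instruments", {
  boot_se <- function(bgo, sgo, bge, sge, B = 1e5, seed = 20) {
    set.seed(seed)
    sd(rnorm(B, bgo, sgo) / rnorm(B, bge, sge))
  }
  # very strong instrument: |beta_ge| / se_ge = 30
  iv <- wald_ratio(0.5, 0.1, 3, 0.1)
  expect_equal(iv$se, boot_se(0.5, 0.1, 3, 0.1), tolerance = 5e-3)
  # the external B12 statistic's strength (ratio ~ 12.7)
  iv2 <- wald_ratio(-0.259, 0.040, 70.21, 5.53)
  expect_equal(iv2$se, boot_se(-0.259, 0.040, 70.21, 5.53),
               tolerance = 1.5e-2)
})

test_that("harmonization aligns effect alleles by sign flips", {
  ge <- summary_stat("rs1", "B12", "T", 70, 5, 3000, other_allele = "A")
  go_same <- summary_stat("rs1", "cg1", "T", -0.2, 0.04, 600)
  expect_equal(harmonize(go_same, ge)$go$beta, -0.2)
  expect_false(harmonize(go_same, ge)$flipped)

  go_flip <- summary_stat("rs1", "cg1", "A", -0.2, 0.04, 600,
                          other_allele = "T")
  h <- harmonize(go_flip, ge)
  expect_equal(h$go$beta, 0.2)
  expect_true(h$flipped)
  # flipping twice is the identity
  h2 <- harmonize(h$go, ge)
  expect_equal(h2$go$beta, 0.2)
  expect_false(h2$flipped)

  go_bad <- summary_stat("rs1", "cg1", "G", 1, 0.1, 10, other_allele = "C")
  expect_error(harmonize(go_bad, ge), "irreconcilable")
  go_other <- summary_stat("rs2", "cg1", "T", 1, 0.1, 10)
  expect_error(harmonize(go_other, ge), "same variant")
})

test_that("mediated effects chain multiplicatively", {
  s1 <- wald_ratio(-0.259, 0.04, 70.21, 5.53, exposure = "B12",
                   outcome = "cg1")
  s2 <- wald_ratio(0.99, 0.39, -0.44, 0.04, exposure = "cg1",
                   outcome = "iq")
  m10 <- mediated_effect(s1, s2, 10)
  m1 <- mediated_effect(s1, s2, 1)
  expect_equal(m10$value, s1$ratio * s2$ratio * 10)
  expect_equal(m10$value, 10 * m1$value)
  # scaling associativity: mediated(s1, s2, c * inc) = c * mediated(s1, s2, inc)
  expect_equal(mediated_effect(s1, s2, 35)$value, 35 * m1$value)

  s2_wrong <- wald_ratio(1, 0.1, 1, 0.1, exposure = "cg_other",
                         outcome = "iq")
  expect_error(mediated_effect(s1, s2_wrong), "chaining")
  s2_zero <- wald_ratio(0, 0.1, 1, 0.1, exposure = "cg1", outcome = "iq")
  expect_equal(mediated_effect(s1, s2_zero)$value, 0)
})

test_that("MR power is the asymptotic normal approximation", {
  # null effect returns one tail of the two-sided test
  expect_equal(mr_power(100, 0.05, 0), 0.025, tolerance = 1e-10)
  # monotone in n, r2 and |beta|
  grid_n <- sapply(c(100, 400, 1600), mr_power, r2 = 0.05, beta_std = 0.3)
  grid_r2 <- sapply(c(0.01, 0.05, 0.2), function(r2)
    mr_power(500, r2, 0.3))
  grid_b <- sapply(c(0.1, 0.3, 0.6), function(b) mr_power(500, 0.05, b))
  expect_true(all(diff(grid_n) > 0))
  expect_true(all(diff(grid_r2) > 0))
  expect_true(all(diff(grid_b) > 0))
  expect_error(mr_power(100, 1.2, 0.3), "r2")
})

test_that("regression F-test power behaves over its grid", {
  expect_equal(regression_power(0.01, 641, alpha = 1), 1)
  grid_f <- sapply(c(0.005, 0.01, 0.05), regression_power, n = 641)
  grid_n <- sapply(c(100, 641, 2000), function(n)
    regression_power(0.01, n))
  expect_true(all(diff(grid_f) > 0))
  expect_true(all(diff(grid_n) > 0))
  expect_error(regression_power(-1, 100), "f2")
})

test_that("the two-sample Wald estimator keeps its nominal type-I error", {
  # null: no genotype -> methylation effect, alpha = 0.05
  base <- sim_params(n_samples = 500, n_cpgs = 1,
                     responsive_cpg_effects = c(cg_null = 0),
                     cis_snp_effects = NULL, theta_my = NULL, seed = 600)
  R <- 1000
  rej <- logical(R)
  for (r in seq_len(R)) {
    ts <- simulate_two_sample_panel(replicate_params(base, r))
    co <- ts$cohort
    f <- fit_cpg(co$methylation$betas[, "cg_null"],
                 co$genotypes$dosages[, "rs_b12"])
    iv <- wald_ratio(f$beta, f$se, ts$exposure_stat$beta,
                     ts$exposure_stat$se)
    rej[r] <- iv$p < 0.05
  }
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})
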