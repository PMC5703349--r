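test_that("probe filtering removes sex chromosomes and failed detections", {
  m <- make_meth_fixture(n = 4, cpgs = sprintf("cg%02d", 1:10),
                         chromosome = c("1", "X", "2", "3", "Y",
                                        "4", "5", "6", "7", "8"))
  f <- filter_probes(m)
  expect_equal(ncol(f$betas), 8L)
  expect_equal(attr(f, "n_excluded_sex"), 2L)
  expect_equal(attr(f, "n_excluded_detection"), 0L)

  # one probe fails detection in a single sample -> removed under the default
  dp <- matrix(0.001, nrow(m$betas), ncol(m$betas),
               dimnames = dimnames(m$betas))
  dp["S002", "cg03"] <- 0.2
  f2 <- filter_probes(m, detection_p = dp)
  expect_false("cg03" %in% colnames(f2$betas))
  expect_equal(attr(f2, "n_excluded_detection"), 1L)

  all_x <- make_meth_fixture(cpgs = c("cga", "cgb"),
                             chromosome = c("X", "X"))
  expect_error(filter_probes(all_x), "all probes removed")
})

test_that("fit_cpg matches the normal-equations oracle", {
  # hand-sized fixture: 6 points, one covariate
  dose <- c(0, 0, 1, 1, 2, 2)
  covar <- c(1.2, -0.5, 0.3, 0.9, -1.1, 0.2)
  y <- c(0.30, 0.32, 0.35, 0.36, 0.41, 0.40)
  got <- fit_cpg(y, dose, data.frame(cv = covar), outlier_k = Inf)
  want <- ols_oracle(y, dose, cbind(covar))
  expect_equal(got$beta, want$beta, tolerance = 1e-10)
  expect_equal(got$se, want$se, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  expect_equal(got$n, 6L)

  # 50 random small designs
  set.seed(42)
  for (i in 1:50) {
    n <- sample(8:20, 1)
    k <- sample(0:3, 1)
    dose <- rbinom(n, 2, 0.4)
    if (var(dose) == 0) dose[1] <- dose[1] + 1
    cv <- if (k > 0) matrix(rnorm(n * k), n) else NULL
    y <- 0.4 + 0.05 * dose + rnorm(n, sd = 0.1)
    got <- fit_cpg(y, dose, cv, outlier_k = Inf)
    want <- ols_oracle(y, dose, cv)
    expect_equal(got$beta, want$beta, tolerance = 1e-8)
    expect_equal(got$se, want$se, tolerance = 1e-8)
  }
})

test_that("fit_cpg recovers a planted effect and flags degenerate designs", {
  set.seed(13)
  n <- 2000
  dose <- rbinom(n, 2, 0.4)
  y <- 0.05 + 0.24 * dose + rnorm(n, sd = 0.25)
  f <- fit_cpg(y, dose)
  expect_lt(abs(f$beta - 0.24), 3 * f$se)

  # exact zero when the response is pure covariate signal
  cv <- rnorm(20)
  y0 <- 2 + 3 * cv
  d0 <- rbinom(20, 2, 0.5)
  if (var(d0) == 0) d0[1] <- d0[1] + 1
  f0 <- fit_cpg(y0, d0, data.frame(cv = cv), outlier_k = Inf)
  expect_equal(f0$beta, 0, tolerance = 1e-10)

  expect_error(fit_cpg(rnorm(20), rep(1, 20)), "degenerate")
  cv2 <- rnorm(20)
  expect_error(fit_cpg(rnorm(20), d0, data.frame(a = cv2, b = 2 * cv2),
                       outlier_k = Inf),
               "rank-deficient")
  expect_error(fit_cpg(rnorm(3), c(0, 1, 2)), "too few")
})

test_that("outlier trimming excludes extreme beta-values before fitting", {
  set.seed(14)
  n <- 100
  dose <- rbinom(n, 2, 0.4)
  y <- 0.5 + rnorm(n, sd = 0.01)
  y[1] <- 0.99  # far beyond 3 x IQR
  f <- fit_cpg(y, dose, outlier_k = 3)
  expect_equal(f$n, n - 1L)
  expect_equal(fit_cpg(y, dose, outlier_k = Inf)$n, n)
})

test_that("genomic inflation follows its definition and scaling", {
  expect_equal(genomic_inflation(c(0.5, 0.5, 0.5)), 1.0)
  set.seed(15)
  u <- runif(1e5)
  expect_gt(genomic_inflation(u), 0.98)
  expect_lt(genomic_inflation(u), 1.02)
  # doubling the chi-square statistics doubles lambda
  chi2 <- qchisq(u, 1, lower.tail = FALSE)
  p2 <- pchisq(2 * chi2, 1, lower.tail = FALSE)
  expect_equal(genomic_inflation(p2), 2, tolerance = 0.03)
  expect_error(genomic_inflation(numeric(0)), "no p-values")
  expect_error(genomic_inflation(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("BH adjustment equals the exhaustive oracle and stays monotone", {
  expect_equal(adjust_bh(0.03, 1), 0.03)
  expect_error(adjust_bh(c(0.1, 0.2), 1), "at least")
  set.seed(16)
  for (i in 1:20) {
    k <- sample(1:8, 1)
    p <- round(runif(k), 3)
    m <- k + sample(0:1000, 1)
    q <- adjust_bh(p, m)
    expect_equal(q, bh_oracle(p, m), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  # ties: a constant p-vector
  p <- rep(0.02, 5)
  expect_equal(adjust_bh(p, 10), bh_oracle(p, 10))
})

test_that("Bonferroni adjustment caps at one", {
  expect_equal(adjust_bonferroni(0.5, 10), 1.0)
  expect_equal(adjust_bonferroni(1e-4, 100), 0.01)
  expect_error(adjust_bonferroni(c(0.1, 0.2), 1), "at least")
})

test_that("run_mwas returns a complete, sorted scan report", {
  sim <- simulate_cohort(sim_params(n_samples = 300, n_cpgs = 12, seed = 17))
  scan <- run_mwas(sim$cohort, "rs_b12", std_covariates)
  res <- scan$results
  expect_equal(scan$n_tested, nrow(res))
  expect_true(!is.unsorted(res$p))
  expect_true(all(res$q_bh >= res$p - 1e-12))
  expect_true(all(res$p_bonf >= res$p - 1e-12))
  expect_true(all(res$n <= 300))
  expect_equal(res$q_bh, adjust_bh(res$p, scan$n_tested))
  expect_error(run_mwas(sim$cohort, "rs_missing", std_covariates),
               "not present")
})

test_that("a single-CpG scan has q and Bonferroni equal to p", {
  sim <- simulate_cohort(sim_params(n_samples = 100, n_cpgs = 1,
                                    responsive_cpg_effects = NULL,
                                    cis_snp_effects = NULL, theta_my = NULL,
                                    seed = 18))
  scan <- run_mwas(sim$cohort, "rs_b12", std_covariates)
  expect_equal(scan$results$q_bh, scan$results$p)
  expect_equal(scan$results$p_bonf, scan$results$p)
})

test_that("strongly responsive CpGs are exactly the FDR discoveries", {
  p <- sim_params(n_samples = 2000, n_cpgs = 500, seed = 19,
                  responsive_cpg_effects = c(cg_resp1 = -7.4e-4,
                                             cg_resp2 = 1.1e-3,
                                             cg_resp3 = 9e-4))
  scan <- run_mwas(simulate_cohort(p)$cohort, "rs_b12", std_covariates)
  hits <- scan$results$cpg_id[scan$results$q_bh <= 0.05]
  expect_setequal(hits, c("cg_resp1", "cg_resp2", "cg_resp3"))
  # and they dominate the ranking
  expect_setequal(scan$results$cpg_id[1:3], hits)
})
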