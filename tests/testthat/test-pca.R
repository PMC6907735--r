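# Eigenbasis of the phenotype covariance and PC-score regressions.

test_that("pc_weights returns a deterministic, orthonormal, reconstructing basis", {
  b <- pc_weights(diag(2))
  expect_equal(b$eigenvalues, c(1, 1))
  expect_equal(unname(b$weights), diag(2))

  b <- pc_weights(diag(c(2, 1)))
  expect_equal(b$eigenvalues, c(2, 1))
  expect_equal(unname(b$weights[, 1]), c(1, 0))

  set.seed(3)
  for (i in 1:5) {
    A <- crossprod(matrix(rnorm(25), 5))
    dimnames(A) <- list(letters[1:5], letters[1:5])
    b <- pc_weights(A)
    W <- b$weights
    expect_lt(max(abs(crossprod(W) - diag(5))), 1e-10)
    expect_lt(max(abs(W %*% (b$eigenvalues * t(W)) - A)), 1e-10 * max(abs(A)))
    expect_equal(sum(b$eigenvalues), sum(diag(A)), tolerance = 1e-10)
    expect_true(all(diff(b$eigenvalues) <= 1e-8 * max(b$eigenvalues)))
    # sign convention: dominant loading positive
    for (j in 1:5) {
      w <- W[, j]
      expect_gt(w[which.max(abs(w))], 0)
    }
  }
})

test_that("correlation-matrix PCA scales to unit diagonal first", {
  A <- matrix(c(4, 1, 1, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  b <- pc_weights(A, scaled = TRUE)
  expect_equal(sum(b$eigenvalues), 2, tolerance = 1e-12)
  expect_true(b$scaled)
})

test_that("centering shifts only the intercept; standardization rescales", {
  fx <- tiny_cohort(seed = 41L)
  sp <- model_spec("y1", snp = "snp0001", covariates = c("age", "sex"))
  f <- sslm(fx$panel, sp, mode = "exact")

  expect_equal(coef(center_coefficients(f, 0)), coef(f))
  fc <- center_coefficients(f, 2)
  expect_equal(coef(fc)[1], coef(f)[1] - 2, ignore_attr = TRUE)
  expect_equal(coef(fc)[-1], coef(f)[-1])
  expect_equal(fc$se, f$se)

  fs <- standardize_coefficients(f, 0, 1)
  expect_equal(coef(fs), coef(f))
  fs <- standardize_coefficients(f, 1, 2)
  expect_equal(coef(fs), (coef(f) - c(1, 0, 0, 0)) / 2)
  expect_equal(fs$se, f$se / 2)
  # slope inference is scale-invariant (the intercept's t does move with mu)
  expect_equal(fs$t[-1], f$t[-1])
  expect_equal(fs$p[-1], f$p[-1])
  expect_error(standardize_coefficients(f, 0, 0), "sigma")

  # oracle: raw OLS on the centered / standardized response
  mu <- fx$panel$variables$mean[fx$panel$variables$variable == "y1"]
  sdv <- sqrt(fx$panel$variables$variance[fx$panel$variables$variable == "y1"])
  ref_c <- lm_fit_reference(fx$raw, sp, center = TRUE)
  expect_equal(unname(coef(center_coefficients(f, mu))),
               unname(coef(ref_c)), tolerance = 1e-10)
  ref_s <- summary(lm_fit_reference(fx$raw, sp, center = TRUE, scale = TRUE))
  fs <- standardize_coefficients(f, mu, sdv)
  expect_equal(unname(coef(fs)), unname(ref_s$coefficients[, 1]),
               tolerance = 1e-10)
  expect_equal(unname(fs$se), unname(ref_s$coefficients[, 2]),
               tolerance = 1e-10)
})

test_that("a single-phenotype PCA degenerates to the centered fit", {
  fx <- tiny_cohort(seed = 42L)
  pf <- pc_fit(fx$panel, phenotypes = "y1", covariates = c("age", "sex"),
               snp = "snp0005", component = 1)
  expect_equal(unname(pf$basis$weights), matrix(1))
  direct <- sslm(fx$panel, model_spec("y1", snp = "snp0005",
                                      covariates = c("age", "sex")),
                 center = TRUE)
  expect_equal(coef(pf), coef(direct), tolerance = 1e-12)
})

test_that("PC-score fits match the raw-data PC regression oracle", {
  fx <- tiny_cohort(seed = 43L, n_subjects = 250L)
  for (j in 1:3) {
    for (scaled in c(FALSE, TRUE)) {
      pf <- pc_fit(fx$panel, covariates = c("age", "sex"), snp = "snp0009",
                   component = j, scaled = scaled, mode = "exact")
      sp <- model_spec(c("y1", "y2", "y3"),
                       weights = pf$basis$weights[, j],
                       snp = "snp0009", covariates = c("age", "sex"))
      ref <- summary(lm_fit_reference(fx$raw, sp, center = TRUE,
                                      scale = scaled))
      expect_rel_equal(unname(coef(pf))[-1],
                       unname(ref$coefficients[-1, 1]), 1e-10)
      expect_rel_equal(unname(pf$se), unname(ref$coefficients[, 2]), 1e-10)
    }
  }
  expect_error(pc_fit(fx$panel, covariates = "age", snp = "snp0001",
                      component = 9), "index error")
})

test_that("results are invariant to the stored sign of the weight vector", {
  fx <- tiny_cohort(seed = 44L)
  pf <- pc_fit(fx$panel, covariates = c("age", "sex"), snp = "snp0002",
               component = 2)
  w <- pf$basis$weights[, 2]
  flipped <- sslm(fx$panel, model_spec(c("y1", "y2", "y3"), weights = -w,
                                       snp = "snp0002",
                                       covariates = c("age", "sex")),
                  center = TRUE)
  expect_equal(coef(flipped), -coef(pf), tolerance = 1e-12)
  expect_equal(flipped$se, pf$se, tolerance = 1e-12)
  expect_equal(flipped$p, pf$p, tolerance = 1e-12)
})

test_that("PC fits with the slope-estimated covariance stay close to the oracle", {
  raw <- simulate_dataset(sim_config(n_subjects = 400L, n_snps = 6000L,
                                     seed = 45L))
  panel <- suppressWarnings(summarize_raw(raw, "exact"))
  est <- estimate_cov_panel(panel, phenotypes = panel$variables$variable)
  panel_est <- suppressWarnings(set_panel_cov(panel, est))

  snps <- sprintf("snp%04d", seq(20, 400, by = 20))
  pf1 <- pc_fit(panel_est, covariates = c("age", "sex"), snp = snps[1],
                component = 1)
  w <- pf1$basis$weights[, 1]
  got <- ss_scan(panel_est, c("y1", "y2", "y3"), weights = w,
                 covariates = c("age", "sex"), snps = snps, center = TRUE)
  want <- ols_scan(raw, c("y1", "y2", "y3"), weights = w,
                   covariates = c("age", "sex"), snps = snps, center = TRUE)
  g1 <- got[got$term == "genotype", ]
  g0 <- want[want$term == "genotype", ]
  expect_true(all(abs(g1$estimate - g0$estimate) < 0.05 * g0$se))
})
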