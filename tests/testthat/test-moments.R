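# Sufficient-statistic reconstruction: X'X, X'y, y'y from the release.

test_that("genotype moments follow Hardy-Weinberg unless released explicitly", {
  expect_equal(genotype_moments(0.5), c(mean = 1.0, variance = 0.5))
  expect_equal(genotype_moments(0.25), c(mean = 0.5, variance = 0.375))
  expect_equal(genotype_moments(0.3, 0.61, 0.44),
               c(mean = 0.61, variance = 0.44))
  expect_error(genotype_moments(1.2), "domain error")
  expect_error(genotype_moments(NA), "domain error")
})

test_that("build_xtx reproduces direct cross-products", {
  expect_equal(build_xtx(7, numeric(0), matrix(0, 0, 0)),
               matrix(7, dimnames = list("(Intercept)", "(Intercept)")))
  # data x = (0, 1, 2): mean 1, sample variance 1
  got <- build_xtx(3, c(x = 1), matrix(1, dimnames = list("x", "x")))
  expect_equal(unname(got), matrix(c(3, 3, 3, 5), 2))
  # random raw fixture vs brute force
  set.seed(1)
  X <- cbind(rnorm(25), rnorm(25), rpois(25, 3))
  got <- build_xtx(25, colMeans(X), cov(X))
  want <- crossprod(cbind(1, X))
  expect_rel_equal(unname(got), unname(want), 1e-10)
})

test_that("predictor cross-covariances match the raw sample quantities", {
  fx <- tiny_cohort(seed = 3L)
  panel <- fx$panel
  raw <- fx$raw

  # covariates only: submatrix of the panel covariance, unchanged
  sp <- model_spec("y1", covariates = c("age", "sex"))
  pc <- predictor_cross_cov(panel, sp)
  expect_equal(pc$cov, panel$cov[c("age", "sex"), c("age", "sex")])

  # genotype only: 1x1 genotype variance
  sp <- model_spec("y1", snp = "snp0002")
  pc <- predictor_cross_cov(panel, sp)
  expect_equal(unname(pc$cov[1, 1]), var(raw$genotypes[, "snp0002"]))

  # genotype + covariate: equals the raw cross-covariance matrix
  sp <- model_spec("y1", snp = "snp0002", covariates = "age")
  pc <- predictor_cross_cov(panel, sp)
  want <- cov(cbind(raw$genotypes[, "snp0002"], raw$age))
  expect_rel_equal(unname(pc$cov), unname(want), 1e-10)
  expect_equal(unname(pc$means),
               c(mean(raw$genotypes[, "snp0002"]), mean(raw$age)))
})

test_that("X'y and y'y reconstructions match raw sums, including combinations", {
  fx <- tiny_cohort(seed = 4L)

  # zero weights give the zero vector
  sp0 <- model_spec(c("y1", "y2"), weights = c(0, 0), snp = "snp0001",
                    covariates = "age")
  expect_equal(unname(build_xty(fx$panel, sp0)), rep(0, 3))

  sp <- model_spec(c("y1", "y2"), weights = c(1, -1), snp = "snp0001",
                   covariates = c("age", "sex"))
  want <- raw_suffstats(fx$raw, sp)
  expect_rel_equal(unname(build_xty(fx$panel, sp)), unname(want$xty), 1e-10)
  expect_rel_equal(build_yty(fx$panel, sp), want$yty, 1e-10)

  # single phenotype, centered, unit variance, n = 11: y'y = (n-1) var = 10
  vars <- data.frame(variable = "y", role = "phenotype", mean = 0, variance = 1)
  cm <- matrix(1, dimnames = list("y", "y"))
  snps <- data.frame(snp_id = "rs1", maf = 0.2, n = 11L,
                     geno_mean = 0.4, geno_var = 0.33)
  assoc <- data.frame(snp_id = "rs1", variable = "y", slope = 0,
                      intercept = 0)
  p <- summary_panel(vars, cm, snps, assoc)
  expect_equal(build_yty(p, model_spec("y")), 10)
})

test_that("full moment sets equal the raw-data oracle over random specs", {
  all_specs <- function() {
    ws <- round(rnorm(3), 2)
    list(
      model_spec("y1", snp = "snp0001", covariates = c("age", "sex")),
      model_spec(c("y1", "y2", "y3"), weights = ws,
                 snp = sample(sprintf("snp%04d", 1:20), 1),
                 covariates = sample(c("age", "sex"))),
      model_spec("y2", covariates = "age"),
      model_spec("y3", snp = "snp0007")
    )
  }
  for (n in c(50L, 400L)) {
    fx <- tiny_cohort(seed = n, n_subjects = n, n_snps = 20L)
    set.seed(n)
    for (sp in all_specs()) {
      m <- build_moments(fx$panel, sp, mode = "exact")
      want <- raw_suffstats(fx$raw, sp)
      expect_rel_equal(unname(m$xtx), unname(want$xtx), 1e-10)
      expect_rel_equal(unname(m$xty), unname(want$xty), 1e-10)
      expect_rel_equal(m$yty, want$yty, 1e-10)
      expect_identical(m$xtx[1, 1], as.numeric(fx$panel$n))
    }
  }
})

test_that("X'y and y'y are (bi)linear in the combination weights", {
  fx <- tiny_cohort(seed = 6L)
  set.seed(6)
  a <- rnorm(3); b <- rnorm(3); s <- runif(2, -2, 2)
  mk <- function(w) model_spec(c("y1", "y2", "y3"), weights = w,
                               snp = "snp0004", covariates = c("age", "sex"))
  xty <- function(w) build_xty(fx$panel, mk(w))
  expect_equal(xty(s[1] * a + s[2] * b), s[1] * xty(a) + s[2] * xty(b),
               tolerance = 1e-10)
  yty <- function(w, v) {
    # bilinear form via polarization of the quadratic y'y
    (build_yty(fx$panel, mk(w + v)) - build_yty(fx$panel, mk(w)) -
       build_yty(fx$panel, mk(v))) / 2
  }
  direct <- yty(a, b)
  expect_equal(yty(s[1] * a, b), s[1] * direct, tolerance = 1e-8)
})

test_that("X'X is invariant to predictor order up to permutation", {
  fx <- tiny_cohort(seed = 7L)
  m1 <- build_moments(fx$panel, model_spec("y1", snp = "snp0001",
                                           covariates = c("age", "sex")))
  m2 <- build_moments(fx$panel, model_spec("y1", snp = "snp0001",
                                           covariates = c("sex", "age")))
  perm <- match(colnames(m1$xtx), colnames(m2$xtx))
  expect_equal(m1$xtx, m2$xtx[perm, perm])
})

test_that("incomplete panels raise completeness errors naming the gap", {
  panel <- tiny_cohort(seed = 8L)$panel
  expect_error(build_moments(panel, model_spec("y1", snp = "nosuch")),
               "completeness error.*nosuch")
  expect_error(build_moments(panel, model_spec("zz", snp = "snp0001")),
               "completeness error.*zz")
  # drop one association record: the pair is named in the error
  p2 <- panel
  p2$assoc <- p2$assoc[!(p2$assoc$snp_id == "snp0001" &
                           p2$assoc$variable == "age"), ]
  expect_error(
    build_xty(p2, model_spec("y1", snp = "snp0001", covariates = "age")),
    "no association record.*snp0001.*age")
})
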