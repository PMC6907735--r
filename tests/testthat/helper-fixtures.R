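# Shared fixtures: small simulated cohorts and hand-built panels.

tiny_config <- function(n_subjects = 120L, n_snps = 30L, seed = 42L, ...) {
  sim_config(n_subjects = n_subjects, n_snps = n_snps, seed = seed,
             n_causal = min(10L, n_snps), ...)
}

tiny_cohort <- function(seed = 42L, n_subjects = 120L, n_snps = 30L, ...) {
  raw <- simulate_dataset(tiny_config(n_subjects, n_snps, seed, ...))
  panel <- suppressWarnings(summarize_raw(raw, mode = "exact"))
  list(raw = raw, panel = panel)
}

# a hand-built two-variable, two-SNP panel with known numbers
manual_panel <- function(n = 10L) {
  variables <- data.frame(
    variable = c("y", "age"), role = c("phenotype", "covariate"),
    mean = c(1.5, 40), variance = c(2, 25), stringsAsFactors = FALSE
  )
  cm <- matrix(c(2, 1.2, 1.2, 25), 2, 2,
               dimnames = list(c("y", "age"), c("y", "age")))
  snps <- data.frame(
    snp_id = c("rs1", "rs2"), maf = c(0.25, 0.4), n = n,
    geno_mean = c(0.5, NA), geno_var = c(0.37, NA), stringsAsFactors = FALSE
  )
  assoc <- data.frame(
    snp_id = rep(c("rs1", "rs2"), each = 2),
    variable = rep(c("y", "age"), 2),
    slope = c(0.3, -0.1, 0.2, 0.05),
    intercept = c(1.35, 40.05, 1.34, 39.96), stringsAsFactors = FALSE
  )
  summary_panel(variables, cm, snps, assoc, n = n)
}

# direct raw-data sufficient statistics, used as the independent oracle for
# the moment reconstruction (plain sums, no covariance identities)
raw_suffstats <- function(raw, spec, center = FALSE, scale = FALSE) {
  V <- cbind(raw$phenotypes, age = raw$age, sex = raw$sex)
  R <- V[, spec$response$variable, drop = FALSE]
  if (center || scale) R <- sweep(R, 2, colMeans(R))
  if (scale) R <- sweep(R, 2, apply(R, 2, sd), "/")
  y <- drop(R %*% spec$response$weight)
  X <- cbind(1, if (!is.null(spec$snp)) raw$genotypes[, spec$snp],
             if (length(spec$covariates)) V[, spec$covariates])
  list(xtx = crossprod(X), xty = drop(crossprod(X, y)), yty = sum(y^2))
}

# stats::lm reference fit (formula interface, independent of both package
# code paths)
lm_fit_reference <- function(raw, spec, center = FALSE, scale = FALSE) {
  V <- cbind(raw$phenotypes, age = raw$age, sex = raw$sex)
  R <- V[, spec$response$variable, drop = FALSE]
  if (center || scale) R <- sweep(R, 2, colMeans(R))
  if (scale) R <- sweep(R, 2, apply(R, 2, sd), "/")
  df <- data.frame(y = drop(R %*% spec$response$weight))
  if (!is.null(spec$snp)) df$g <- raw$genotypes[, spec$snp]
  for (v in spec$covariates) df[[v]] <- V[, v]
  stats::lm(y ~ ., data = df)
}

expect_rel_equal <- function(got, want, tol) {
  expect_lt(max(abs(got - want) / pmax(abs(want), 1e-12)), tol)
}
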