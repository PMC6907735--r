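#' Configure the synthetic biobank simulator
#'
#' Describes one simulated cohort: biallelic SNPs with allele frequencies
#' drawn from a truncated Beta distribution, genotypes binomial(2, maf)
#' (Hardy-Weinberg by construction), a Poisson age and Bernoulli sex, and
#' three quantitative phenotypes linearly driven by the first `n_causal`
#' SNPs plus age and sex, with jointly drawn residuals. Residuals carry a
#' full covariance matrix because the target inter-phenotype correlations
#' (one of them negative) cannot arise from shared causal markers alone.
#'
#' The default effect sizes and residual covariance are calibrated so the
#' realized phenotype correlations average about 0.30 (y1, y2), -0.08
#' (y1, y3) and 0.07 (y2, y3).
#'
#' @param n_subjects number of subjects (default 2000).
#' @param n_snps number of SNPs (default 2000; raise to biobank scale as
#'   compute allows).
#' @param n_causal number of causal SNPs, taken as the first columns
#'   (default 10).
#' @param maf_beta shape parameters of the Beta distribution of allele
#'   frequencies (default `c(2, 8)`).
#' @param maf_bounds truncation interval for allele frequencies (default
#'   `c(0.01, 0.5)`).
#' @param age_rate Poisson mean of age (default 50).
#' @param gamma 3 x `n_causal` matrix of phenotype-by-SNP effect sizes.
#' @param delta_age,kappa_sex length-3 age and sex effects.
#' @param residual_cov 3 x 3 positive definite residual covariance.
#' @param n_replicates replicate count used by [validate_method()]
#'   (default 20).
#' @param seed integer seed; every draw is reproducible from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 2000L, n_snps = 2000L, n_causal = 10L,
                       maf_beta = c(2, 8), maf_bounds = c(0.01, 0.5),
                       age_rate = 50,
                       gamma = NULL, delta_age = c(0.02, 0.015, 0.01),
                       kappa_sex = c(0.3, 0.2, -0.2),
                       residual_cov = NULL, n_replicates = 20L,
                       seed = 1L) {
  if (is.null(gamma))
    gamma <- rbind(rep(0.15, n_causal),
                   rep(0.12, n_causal),
                   rep(-0.10, n_causal))
  if (is.null(residual_cov))
    residual_cov <- matrix(c(1, 0.242, -0.036,
                             0.242, 1, 0.112,
                             -0.036, 0.112, 1), 3, 3)
  gamma <- as.matrix(gamma)
  residual_cov <- as.matrix(residual_cov)
  if (n_subjects <= 4L) stop("validation error: n_subjects too small")
  if (n_snps < n_causal) stop("validation error: n_snps < n_causal")
  if (maf_bounds[1] <= 0 || maf_bounds[2] > 0.5 ||
      maf_bounds[1] >= maf_bounds[2])
    stop("validation error: maf_bounds must lie within (0, 0.5]")
  if (!all(dim(gamma) == c(3L, n_causal)))
    stop("validation error: gamma must be 3 x n_causal")
  if (length(delta_age) != 3L || length(kappa_sex) != 3L)
    stop("validation error: delta_age and kappa_sex must have length 3")
  if (!all(dim(residual_cov) == c(3L, 3L)) ||
      max(abs(residual_cov - t(residual_cov))) > 1e-12 ||
      min(eigen(residual_cov, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("validation error: residual_cov must be 3 x 3 positive definite")
  structure(
    list(n_subjects = as.integer(n_subjects), n_snps = as.integer(n_snps),
         n_causal = as.integer(n_causal), maf_beta = maf_beta,
         maf_bounds = maf_bounds, age_rate = age_rate, gamma = gamma,
         delta_age = delta_age, kappa_sex = kappa_sex,
         residual_cov = residual_cov, n_replicates = as.integer(n_replicates),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

snp_names <- function(M) sprintf("snp%04d", seq_len(M))

#' Simulate one subject-level cohort
#'
#' Draws a complete subject-level dataset under the configuration: allele
#' frequencies Beta(`maf_beta`) truncated to `maf_bounds` (by rejection),
#' genotype dosages Binomial(2, maf), age Poisson, sex Bernoulli(0.5), and
#' phenotypes `y_h = sum_s gamma_hs g_s + delta_h age + kappa_h sex + e`
#' with residual rows drawn from a zero-mean Gaussian with covariance
#' `residual_cov`.
#'
#' @param config a [sim_config()].
#' @return An object of class `raw_dataset`: `genotypes` (n x M integer
#'   matrix, columns named `snp0001`, ...), `maf` (the drawn frequencies),
#'   `age`, `sex`, `phenotypes` (n x 3, columns `y1`, `y2`, `y3`),
#'   `true_cov` (population phenotype covariance implied by the config and
#'   the drawn frequencies), and the `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  M <- config$n_snps

  maf <- numeric(0)
  while (length(maf) < M) {
    cand <- stats::rbeta(M, config$maf_beta[1], config$maf_beta[2])
    cand <- cand[cand >= config$maf_bounds[1] & cand <= config$maf_bounds[2]]
    maf <- c(maf, cand)
  }
  maf <- maf[seq_len(M)]

  G <- matrix(stats::rbinom(n * M, 2L, rep(maf, each = n)), nrow = n)
  colnames(G) <- snp_names(M)
  names(maf) <- colnames(G)

  age <- stats::rpois(n, config$age_rate)
  sex <- stats::rbinom(n, 1L, 0.5)

  L <- chol(config$residual_cov)
  eps <- matrix(stats::rnorm(n * 3L), n, 3L) %*% L

  nc <- config$n_causal
  Y <- G[, seq_len(nc), drop = FALSE] %*% t(config$gamma) +
    outer(age, config$delta_age) + outer(sex, config$kappa_sex) + eps
  colnames(Y) <- c("y1", "y2", "y3")

  vg <- 2 * maf[seq_len(nc)] * (1 - maf[seq_len(nc)])
  true_cov <- config$gamma %*% (vg * t(config$gamma)) +
    config$age_rate * tcrossprod(config$delta_age) +
    0.25 * tcrossprod(config$kappa_sex) +
    config$residual_cov
  dimnames(true_cov) <- list(colnames(Y), colnames(Y))

  structure(
    list(genotypes = G, maf = maf, age = age, sex = sex, phenotypes = Y,
         true_cov = true_cov, config = config),
    class = "raw_dataset"
  )
}

#' @export
print.raw_dataset <- function(x, ...) {
  cat("simulated cohort: ", nrow(x$genotypes), " subjects x ",
      ncol(x$genotypes), " SNPs, 3 phenotypes + age + sex (seed ",
      x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Summarize a raw cohort into a release-style summary panel
#'
#' Produces exactly the statistics a biobank would release for the cohort:
#' per-(SNP, variable) simple-regression slope and intercept in closed form
#' (`slope = cov(v, g) / var(g)`, `intercept = mean(v) - slope * mean(g)`),
#' variable means/variances/covariances from the sample (n-1 denominator),
#' and genotype information. In `"exact"` mode the per-SNP sample genotype
#' mean and variance are included, permitting machine-precision downstream
#' reconstruction; in `"hwe"` mode only the sample allele frequency is
#' released and downstream analyses fall back on Hardy-Weinberg moments.
#' Monomorphic SNPs (zero genotype variance) are excluded with a warning.
#'
#' @param raw a [simulate_dataset()] result.
#' @param mode `"exact"` or `"hwe"`.
#' @return A validated [summary_panel()].
#' @export
summarize_raw <- function(raw, mode = c("exact", "hwe")) {
  mode <- match.arg(mode)
  stopifnot(inherits(raw, "raw_dataset"))
  G <- raw$genotypes
  n <- nrow(G)
  V <- cbind(raw$phenotypes, age = raw$age, sex = raw$sex)
  roles <- c("phenotype", "phenotype", "phenotype", "covariate", "covariate")

  gbar <- colMeans(G)
  gvar <- apply(G, 2L, stats::var)
  poly <- gvar > 0
  if (any(!poly)) {
    warning(sum(!poly), " monomorphic SNP(s) excluded from the panel")
    G <- G[, poly, drop = FALSE]
    gbar <- gbar[poly]
    gvar <- gvar[poly]
  }
  M <- ncol(G)

  vbar <- colMeans(V)
  vvar <- apply(V, 2L, stats::var)
  Vc <- sweep(V, 2L, vbar)
  Gc <- sweep(G, 2L, gbar)
  # cov(g, v) for every pair at once
  CGV <- crossprod(Gc, Vc) / (n - 1)
  slopes <- CGV / gvar
  intercepts <- sweep(-slopes * gbar, 2L, vbar, "+")

  assoc <- data.frame(
    snp_id = rep(colnames(G), times = ncol(V)),
    variable = rep(colnames(V), each = M),
    slope = as.vector(slopes),
    intercept = as.vector(intercepts),
    stringsAsFactors = FALSE
  )
  maf_hat <- gbar / 2
  snps <- data.frame(
    snp_id = colnames(G), maf = maf_hat, n = n,
    geno_mean = if (mode == "exact") gbar else NA_real_,
    geno_var = if (mode == "exact") gvar else NA_real_,
    stringsAsFactors = FALSE
  )
  variables <- data.frame(
    variable = colnames(V), role = roles, mean = vbar, variance = vvar,
    stringsAsFactors = FALSE
  )
  cov_v <- stats::cov(V)

  summary_panel(variables = variables, cov = cov_v, snps = snps,
                assoc = assoc, n = n)
}

#' Replace the released covariance block of a panel
#'
#' Substitutes entries of the panel covariance matrix for the variables
#' named in `cov` (e.g. a slope-correlation estimate from
#' [estimate_cov_panel()]), leaving the variable variances in place on the
#' diagonal so the panel stays self-consistent.
#'
#' @param panel a [summary_panel()].
#' @param cov covariance matrix whose dimnames are panel variables.
#' @return A new validated [summary_panel()].
#' @export
set_panel_cov <- function(panel, cov) {
  stopifnot(inherits(panel, "summary_panel"))
  cov <- as.matrix(cov)
  vars <- rownames(cov)
  miss <- setdiff(vars, rownames(panel$cov))
  if (length(miss))
    stop("completeness error: unknown variable(s): ", paste(miss, collapse = ", "))
  newcov <- panel$cov
  newcov[vars, vars] <- cov
  idx <- match(vars, panel$variables$variable)
  diag_target <- panel$variables$variance[idx]
  newcov[cbind(match(vars, rownames(newcov)), match(vars, rownames(newcov)))] <-
    diag_target
  summary_panel(panel$variables, newcov, panel$snps, panel$assoc, panel$n)
}

#' Subject-level OLS oracle
#'
#' Direct least-squares on the raw data for the same model a summary-based
#' fit describes: assembles the design (intercept, genotype, covariates) and
#' the weighted response combination, optionally centering (and
#' standardizing) the response variables by their sample moments, and fits
#' by QR ([stats::lm.fit]). This is the ground truth that every
#' summary-statistic reconstruction is judged against; it shares no code
#' with the moment-reconstruction path.
#'
#' @param raw a [simulate_dataset()] result.
#' @param spec a [model_spec()] naming `y1`/`y2`/`y3`/`age`/`sex` and a
#'   `snp_id` from the cohort.
#' @param center center each response variable at its sample mean before
#'   combining.
#' @param scale additionally divide each response variable by its sample
#'   standard deviation.
#' @return An `sslm`-classed fit (mode `"oracle"`).
#' @export
ols_oracle <- function(raw, spec, center = FALSE, scale = FALSE) {
  stopifnot(inherits(raw, "raw_dataset"), inherits(spec, "model_spec"))
  V <- cbind(raw$phenotypes, age = raw$age, sex = raw$sex)
  n <- nrow(V)

  rv <- spec$response$variable
  w <- spec$response$weight
  miss <- setdiff(c(rv, spec$covariates), colnames(V))
  if (length(miss))
    stop("completeness error: unknown variable(s): ", paste(miss, collapse = ", "))
  R <- V[, rv, drop = FALSE]
  if (center || scale) R <- sweep(R, 2L, colMeans(R))
  if (scale) R <- sweep(R, 2L, apply(R, 2L, stats::sd), "/")
  y <- drop(R %*% w)

  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(spec$snp)) {
    if (!(spec$snp %in% colnames(raw$genotypes)))
      stop("completeness error: unknown SNP: ", spec$snp)
    X <- cbind(X, raw$genotypes[, spec$snp, drop = FALSE])
  }
  if (length(spec$covariates))
    X <- cbind(X, V[, spec$covariates, drop = FALSE])

  qrx <- qr(X)
  if (qrx$rank < ncol(X))
    stop("singularity error: raw design is rank deficient")
  f <- stats::lm.fit(X, y)
  beta <- f$coefficients
  df <- n - ncol(X)
  if (df <= 0L) stop("degrees-of-freedom error: n - (p + 1) <= 0")
  sigma2 <- sum(f$residuals^2) / df
  XtXinv <- chol2inv(qr.R(qrx))
  se <- sqrt(pmax(sigma2 * diag(XtXinv), 0))
  names(se) <- colnames(X)
  new_sslm(beta, se, sigma2, df, n, colnames(X), spec, mode = "oracle")
}
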