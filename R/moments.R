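#' Genotype dosage moments from the allele frequency
#'
#' Returns the mean and variance of the additive genotype dosage (0/1/2).
#' When the release carries sample moments they are passed through unchanged
#' (exact mode); otherwise the Hardy-Weinberg values `2p` and `2p(1-p)` are
#' derived from the allele frequency `p`.
#'
#' @param maf allele frequency in (0, 1).
#' @param geno_mean,geno_var optional explicit sample moments (`NA`/`NULL`
#'   if not released).
#' @return Named numeric vector `c(mean = , variance = )`.
#' @export
genotype_moments <- function(maf, geno_mean = NULL, geno_var = NULL) {
  have_explicit <- !is.null(geno_mean) && !is.null(geno_var) &&
    !is.na(geno_mean) && !is.na(geno_var)
  if (have_explicit)
    return(c(mean = as.numeric(geno_mean), variance = as.numeric(geno_var)))
  if (is.null(maf) || is.na(maf) || maf <= 0 || maf >= 1)
    stop("domain error: maf must lie in (0, 1) when explicit genotype moments are absent")
  c(mean = 2 * maf, variance = 2 * maf * (1 - maf))
}

#' Specify a single-marker regression model
#'
#' Describes one multiple-regression model to be reconstructed from summary
#' statistics: a response that is a weighted linear combination of panel
#' variables, one optional genotype predictor, and further (non-genotype)
#' covariates. An intercept is always included. At most one genotype column
#' is allowed because marker-marker covariances (linkage disequilibrium) are
#' not part of the released summary set.
#'
#' @param response character vector of response variable names.
#' @param weights numeric combination weights, one per response variable
#'   (default all 1).
#' @param snp `snp_id` of the genotype predictor, or `NULL` for a
#'   covariates-only model.
#' @param covariates character vector of non-genotype predictor names.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(response, weights = NULL, snp = NULL,
                       covariates = character()) {
  response <- as.character(response)
  if (length(response) < 1L) stop("model spec needs at least one response term")
  if (is.null(weights)) weights <- rep(1, length(response))
  weights <- as.numeric(weights)
  if (length(weights) != length(response))
    stop("shape error: one weight per response variable required")
  if (any(!is.finite(weights))) stop("domain error: non-finite response weights")
  if (anyDuplicated(response))
    stop("integrity error: duplicated response variables")
  covariates <- as.character(covariates)
  if (anyDuplicated(covariates))
    stop("integrity error: duplicated predictors")
  if (!is.null(snp)) snp <- as.character(snp)
  structure(
    list(response = data.frame(variable = response, weight = weights,
                               stringsAsFactors = FALSE),
         snp = snp, covariates = covariates, include_intercept = TRUE),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  w <- x$response$weight
  lhs <- paste(ifelse(w == 1, x$response$variable,
                      paste0(fmt_num(w), "*", x$response$variable)),
               collapse = " + ")
  rhs <- paste(c(if (!is.null(x$snp)) paste0("g[", x$snp, "]"), x$covariates,
                 "1"), collapse = " + ")
  cat("model spec: ", lhs, " ~ ", rhs, "\n", sep = "")
  invisible(x)
}

fmt_num <- function(x) formatC(x, format = "g")

resolve_spec <- function(panel, spec) {
  vars <- panel$variables
  need <- union(spec$response$variable, spec$covariates)
  miss <- setdiff(need, vars$variable)
  if (length(miss))
    stop("completeness error: spec references unknown variable(s): ",
         paste(miss, collapse = ", "))
  if (!is.null(spec$snp) && !(spec$snp %in% panel$snps$snp_id))
    stop("completeness error: spec references unknown SNP: ", spec$snp)
  if (!is.null(spec$snp) && spec$snp %in% spec$covariates)
    stop("integrity error: genotype cannot also appear as a named covariate")
  invisible(TRUE)
}

# look up one slope b_{variable ~ snp}; error names the missing pair
assoc_slope <- function(panel, snp, variable) {
  i <- which(panel$assoc$snp_id == snp & panel$assoc$variable == variable)
  if (length(i) != 1L)
    stop("completeness error: no association record for (", snp, ", ",
         variable, ")")
  panel$assoc$slope[i]
}

panel_cov_entry <- function(panel, a, b) {
  if (!(a %in% rownames(panel$cov)) || !(b %in% rownames(panel$cov)))
    stop("completeness error: covariance missing for pair (", a, ", ", b, ")")
  panel$cov[a, b]
}

snp_moments <- function(panel, snp, mode) {
  i <- match(snp, panel$snps$snp_id)
  row <- panel$snps[i, ]
  if (mode == "hwe")
    return(genotype_moments(row$maf))
  gm <- genotype_moments(row$maf, row$geno_mean, row$geno_var)
  if (mode == "exact" && (is.na(row$geno_mean) || is.na(row$geno_var)))
    stop("completeness error: exact mode requires explicit genotype moments for ",
         snp)
  gm
}

#' Means and cross-covariances of a model's predictors
#'
#' Assembles the mean vector and sample covariance matrix of the non-intercept
#' predictor columns. Covariances between non-genotype predictors come
#' directly from the panel's covariance matrix. The genotype's covariance
#' with any other variable follows from the simple-regression identity
#' `cov(g, v) = b * var(g)`, where `b` is the released slope of `v ~ g`; its
#' variance comes from [genotype_moments()].
#'
#' @param panel a [summary_panel()].
#' @param spec a [model_spec()].
#' @param mode `"auto"` (explicit genotype moments when present, else HWE),
#'   `"exact"` (explicit moments required) or `"hwe"` (force MAF-derived
#'   moments).
#' @return List with `means` (named vector) and `cov` (matrix), predictors
#'   ordered genotype first, then covariates.
#' @export
predictor_cross_cov <- function(panel, spec, mode = c("auto", "exact", "hwe")) {
  mode <- match.arg(mode)
  resolve_spec(panel, spec)
  covs <- spec$covariates
  has_g <- !is.null(spec$snp)
  terms <- c(if (has_g) spec$snp, covs)
  p <- length(terms)
  means <- numeric(p)
  V <- matrix(0, p, p, dimnames = list(terms, terms))

  if (length(covs)) {
    idx <- match(covs, panel$variables$variable)
    cov_names <- covs
    for (a in cov_names) for (b in cov_names)
      V[a, b] <- panel_cov_entry(panel, a, b)
    means[match(covs, terms)] <- panel$variables$mean[idx]
  }
  if (has_g) {
    gm <- snp_moments(panel, spec$snp, mode)
    means[1L] <- gm[["mean"]]
    V[1L, 1L] <- gm[["variance"]]
    for (v in covs) {
      cgv <- assoc_slope(panel, spec$snp, v) * gm[["variance"]]
      V[spec$snp, v] <- V[v, spec$snp] <- cgv
    }
  }
  names(means) <- terms
  list(means = means, cov = V)
}

#' Reconstruct the cross-product matrix X'X from means and covariances
#'
#' Uses the identities `sum(x_k) = n * mean(x_k)` and
#' `sum(x_k x_l) = cov(x_k, x_l) * (n - 1) + n * mean(x_k) * mean(x_l)`
#' (sample covariances with the n-1 denominator) to rebuild the
#' `(p+1) x (p+1)` cross-product matrix of the design, intercept column
#' first.
#'
#' @param n sample size.
#' @param means mean vector of the p non-intercept predictors.
#' @param cov p x p sample covariance matrix of the predictors.
#' @return The `(p+1) x (p+1)` matrix `X'X`.
#' @export
build_xtx <- function(n, means, cov) {
  p <- length(means)
  cov <- as.matrix(cov)
  if (!all(dim(cov) == c(p, p)))
    stop("shape error: cov must be ", p, " x ", p)
  if (p && is.null(names(means))) names(means) <- paste0("x", seq_len(p))
  xtx <- matrix(0, p + 1L, p + 1L)
  xtx[1L, 1L] <- n
  if (p) {
    xtx[1L, -1L] <- n * means
    xtx[-1L, 1L] <- n * means
    xtx[-1L, -1L] <- cov * (n - 1) + n * tcrossprod(means)
  }
  nm <- c("(Intercept)", names(means))
  dimnames(xtx) <- list(nm, nm)
  xtx
}

response_stats <- function(panel, spec, center = FALSE) {
  rv <- spec$response$variable
  w <- spec$response$weight
  idx <- match(rv, panel$variables$variable)
  mu <- panel$variables$mean[idx]
  if (center) mu <- rep(0, length(mu))
  list(vars = rv, w = w, mu = mu)
}

#' Reconstruct X'y for a (combined) response
#'
#' The response is the weighted combination `y = sum_h c_h y_h` of panel
#' variables. Element 0 (the intercept row) is `n * sum_h c_h mean(y_h)`;
#' the element for predictor `x_k` is
#' `(sum_h c_h cov(x_k, y_h)) * (n - 1) + n * mean(x_k) * sum_h c_h mean(y_h)`,
#' with `cov(g, y_h)` taken from the released slope times the genotype
#' variance.
#'
#' @inheritParams predictor_cross_cov
#' @param center treat all response means as zero (used for
#'   principal-component scores of centered phenotypes).
#' @return Numeric vector of length p + 1, intercept element first.
#' @export
build_xty <- function(panel, spec, mode = c("auto", "exact", "hwe"),
                      center = FALSE) {
  mode <- match.arg(mode)
  resolve_spec(panel, spec)
  pc <- predictor_cross_cov(panel, spec, mode)
  rs <- response_stats(panel, spec, center)
  n <- panel$n
  ybar_c <- sum(rs$w * rs$mu)

  terms <- names(pc$means)
  xty <- numeric(length(terms) + 1L)
  xty[1L] <- n * ybar_c
  has_g <- !is.null(spec$snp)
  for (k in seq_along(terms)) {
    tk <- terms[k]
    if (has_g && k == 1L) {
      cxy <- sum(rs$w * vapply(rs$vars, function(v)
        assoc_slope(panel, spec$snp, v) * pc$cov[1L, 1L], numeric(1)))
    } else {
      cxy <- sum(rs$w * vapply(rs$vars, function(v)
        panel_cov_entry(panel, tk, v), numeric(1)))
    }
    xty[k + 1L] <- cxy * (n - 1) + n * pc$means[k] * ybar_c
  }
  names(xty) <- c("(Intercept)", terms)
  xty
}

#' Reconstruct y'y for a (combined) response
#'
#' For `y = sum_h c_h y_h`,
#' `y'y = sum_h sum_j c_h c_j (cov(y_h, y_j) * (n - 1) + mean(y_h) * mean(y_j) * n)`.
#'
#' @inheritParams build_xty
#' @return Scalar sum of squares of the combined response.
#' @export
build_yty <- function(panel, spec, center = FALSE) {
  resolve_spec(panel, spec)
  rs <- response_stats(panel, spec, center)
  n <- panel$n
  m <- length(rs$vars)
  S <- matrix(0, m, m)
  for (h in seq_len(m)) for (j in seq_len(m))
    S[h, j] <- panel_cov_entry(panel, rs$vars[h], rs$vars[j]) * (n - 1) +
      rs$mu[h] * rs$mu[j] * n
  val <- drop(crossprod(rs$w, S %*% rs$w))
  if (val < -1e-10 * max(abs(S)))
    stop("consistency error: reconstructed y'y is negative (", fmt_num(val),
         "); the panel contradicts itself")
  val
}

#' Reconstruct the full sufficient-statistic set of a model
#'
#' Composes [predictor_cross_cov()], [build_xtx()], [build_xty()] and
#' [build_yty()] into the complete sufficient statistics (`X'X`, `X'y`,
#' `y'y`, `n`, `p`) of the requested model, from which ordinary least
#' squares can be solved without subject-level data.
#'
#' @inheritParams build_xty
#' @return An object of class `moment_set` with elements `xtx`, `xty`,
#'   `yty`, `n`, `p` and `terms`.
#' @export
build_moments <- function(panel, spec, mode = c("auto", "exact", "hwe"),
                          center = FALSE) {
  mode <- match.arg(mode)
  resolve_spec(panel, spec)
  pc <- predictor_cross_cov(panel, spec, mode)
  xtx <- build_xtx(panel$n, pc$means, pc$cov)
  xty <- build_xty(panel, spec, mode, center)
  yty <- build_yty(panel, spec, center)
  structure(
    list(xtx = xtx, xty = xty, yty = yty, n = panel$n,
         p = length(pc$means), terms = colnames(xtx)),
    class = "moment_set"
  )
}

#' @export
print.moment_set <- function(x, ...) {
  cat("moment set: n = ", x$n, ", p = ", x$p,
      " predictor(s) + intercept\n", sep = "")
  cat("  y'y = ", fmt_num(x$yty), "\n", sep = "")
  print(x$xtx)
  invisible(x)
}
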