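#' Principal-component weights of a phenotype covariance matrix
#'
#' Eigendecomposition of the phenotype covariance matrix (or, with
#' `scaled = TRUE`, of the derived correlation matrix), yielding the weight
#' vectors that define principal-component scores of the centered (and
#' optionally standardized) phenotypes. Eigenvalues are returned in
#' descending order. Because an eigenvector and its negation span the same
#' component, each column is sign-fixed so that its largest-magnitude entry
#' is positive (ties broken by lowest index); equal eigenvalues are ordered
#' by the variable index of the dominant loading for reproducibility.
#'
#' @param cov symmetric positive semidefinite covariance matrix with
#'   variable dimnames. Slightly indefinite inputs (as arise from the
#'   slope-correlation estimate) are repaired via [repair_psd()] with a
#'   warning.
#' @param scaled perform the decomposition on the correlation matrix.
#' @return An object of class `pc_basis`: `eigenvalues`, `weights` (columns
#'   are components), `scaled`, `variable_names`.
#' @export
pc_weights <- function(cov, scaled = FALSE) {
  cov <- as.matrix(cov)
  if (is.null(rownames(cov)))
    dimnames(cov) <- list(paste0("v", seq_len(nrow(cov))),
                          paste0("v", seq_len(nrow(cov))))
  if (max(abs(cov - t(cov))) > 1e-12 * max(abs(cov), 1e-300))
    stop("domain error: covariance matrix must be symmetric")
  if (scaled) {
    s <- sqrt(diag(cov))
    if (any(s <= 0)) stop("domain error: zero variance; cannot scale")
    cov <- cov / tcrossprod(s)
    diag(cov) <- 1
  }
  e <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  tol <- 1e-8 * max(abs(e$values), 1e-300)
  if (min(e$values) < -sqrt(tol) * max(abs(e$values), 1)) {
    warning("covariance matrix is not positive semidefinite; repairing before PCA")
    cov <- repair_psd(cov)
    e <- eigen(cov, symmetric = TRUE)
  }
  lam <- pmax(e$values, 0)
  W <- e$vectors

  # deterministic sign: largest |loading| positive, first index on ties
  dom <- apply(W, 2L, function(w) which(abs(w) == max(abs(w)))[1L])
  flip <- W[cbind(dom, seq_len(ncol(W)))] < 0
  W[, flip] <- -W[, flip]

  # stable ordering of (numerically) tied eigenvalues by dominant loading index
  grp <- cumsum(c(TRUE, diff(lam) < -tol))
  ord <- order(grp, dom)
  lam <- lam[ord]
  W <- W[, ord, drop = FALSE]

  dimnames(W) <- list(rownames(cov), paste0("PC", seq_len(ncol(W))))
  structure(
    list(eigenvalues = lam, weights = W, scaled = scaled,
         variable_names = rownames(cov)),
    class = "pc_basis"
  )
}

#' @export
print.pc_basis <- function(x, ...) {
  pve <- x$eigenvalues / sum(x$eigenvalues)
  cat("principal-component basis over ", length(x$variable_names),
      " phenotype", if (length(x$variable_names) != 1) "s", sep = "")
  cat(if (x$scaled) " (correlation-matrix PCA)" else " (covariance-matrix PCA)",
      "\n", sep = "")
  tab <- rbind(eigenvalue = x$eigenvalues, `prop. variance` = pve)
  colnames(tab) <- colnames(x$weights)
  print(round(tab, 4))
  cat("\nweights:\n")
  print(round(x$weights, 4))
  invisible(x)
}

#' Re-express a fit for a centered response
#'
#' If a response is shifted by a constant `mu`, the same regression on the
#' centered response `y - mu` has the intercept reduced by `mu` and every
#' other coefficient, all standard errors, and the residual variance
#' unchanged.
#'
#' @param fit an `sslm` fit with an intercept term.
#' @param mu centering constant (the response mean).
#' @return A new `sslm` object describing the centered-response model.
#' @export
center_coefficients <- function(fit, mu) {
  stopifnot(inherits(fit, "sslm"))
  if (fit$terms[1L] != "(Intercept)")
    stop("fit has no intercept term to center")
  cf <- fit$coefficients
  cf[1L] <- cf[1L] - mu
  new_sslm(cf, fit$se, fit$sigma2, fit$df, fit$n, fit$terms, fit$spec,
           fit$mode, moments = fit$moments)
}

#' Re-express a fit for a standardized response
#'
#' If the response is standardized to `(y - mu) / sigma`, the intercept
#' becomes `(intercept - mu) / sigma`, every other coefficient and every
#' standard error is divided by `sigma`, and the residual variance by
#' `sigma^2`. Slope t statistics, p-values and degrees of freedom are
#' unchanged (standardization is a linear rescaling of the response); the
#' intercept's t statistic reflects the shift by `mu`, exactly as a raw-data
#' refit on the standardized response would.
#'
#' @param fit an `sslm` fit with an intercept term.
#' @param mu response mean.
#' @param sigma response standard deviation (> 0).
#' @return A new `sslm` object describing the standardized-response model.
#' @export
standardize_coefficients <- function(fit, mu, sigma) {
  stopifnot(inherits(fit, "sslm"))
  if (sigma <= 0) stop("domain error: sigma must be > 0")
  if (fit$terms[1L] != "(Intercept)")
    stop("fit has no intercept term to center")
  cf <- fit$coefficients
  cf[1L] <- cf[1L] - mu
  cf <- cf / sigma
  m <- fit$moments
  new_sslm(cf, fit$se / sigma, fit$sigma2 / sigma^2, fit$df, fit$n,
           fit$terms, fit$spec, fit$mode, moments = NULL)
}

#' Fit a principal-component score on a marker and covariates
#'
#' Derives the principal-component basis from the phenotype block of the
#' panel covariance (or a supplied covariance matrix, e.g. the
#' slope-correlation estimate), forms the component-`j` score of the
#' centered (optionally standardized) phenotypes as a weighted combination,
#' and fits `PC_j ~ SNP + covariates` entirely from summary statistics.
#' Centering makes all response mean terms vanish, so only the covariance
#' block of the release is needed for the response side.
#'
#' @param panel a [summary_panel()].
#' @param phenotypes phenotype names entering the PCA (default: all panel
#'   phenotypes).
#' @param covariates non-genotype predictor names.
#' @param snp `snp_id` of the genotype predictor (or `NULL`).
#' @param component 1-based component index (1 = largest eigenvalue).
#' @param scaled use correlation-matrix PCA of standardized phenotypes.
#' @param cov covariance matrix of the phenotypes to use in place of the
#'   panel's own block (e.g. from [estimate_cov_panel()]).
#' @param mode genotype-moment mode, as in [sslm()].
#' @return An `sslm` fit carrying the `pc_basis` used as `$basis`.
#' @export
pc_fit <- function(panel, phenotypes = NULL, covariates = character(),
                   snp = NULL, component = 1L, scaled = FALSE, cov = NULL,
                   mode = c("auto", "exact", "hwe")) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "summary_panel"))
  if (is.null(phenotypes))
    phenotypes <- panel$variables$variable[panel$variables$role == "phenotype"]
  m <- length(phenotypes)
  if (component < 1L || component > m)
    stop("index error: component must be in 1..", m)
  if (is.null(cov)) {
    miss <- setdiff(phenotypes, rownames(panel$cov))
    if (length(miss))
      stop("completeness error: covariance missing for ", paste(miss, collapse = ", "))
    cov <- panel$cov[phenotypes, phenotypes, drop = FALSE]
  } else {
    cov <- as.matrix(cov)[phenotypes, phenotypes, drop = FALSE]
  }
  basis <- pc_weights(cov, scaled = scaled)
  w <- basis$weights[, component]
  if (scaled) {
    sds <- sqrt(panel$variables$variance[match(phenotypes,
                                               panel$variables$variable)])
    w <- w / sds
  }
  spec <- model_spec(response = phenotypes, weights = w, snp = snp,
                     covariates = covariates)
  fit <- sslm(panel, spec, mode = mode, center = TRUE)
  fit$basis <- basis
  fit$component <- as.integer(component)
  fit
}
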