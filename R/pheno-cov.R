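#' Estimate a phenotype covariance matrix from effect-size correlations
#'
#' When the release omits the phenotype covariance matrix, the correlation
#' between two phenotypes can be approximated by the Pearson correlation of
#' their simple-regression slope vectors across many markers:
#' `cov(y_h, y_j) ~= cor(b_h, b_j) * sqrt(var(y_h) * var(y_j))`. The
#' approximation rests on most markers being null or weakly associated, so
#' that slope noise is driven by the phenotype residual correlation.
#'
#' @param slopes S x m numeric matrix of simple-regression slopes (one row
#'   per SNP, one named column per phenotype), S >= 3.
#' @param variances named vector of phenotype variances (> 0), in column
#'   order of `slopes`.
#' @return Symmetric covariance matrix with `variances` on the diagonal.
#' @export
estimate_cov <- function(slopes, variances) {
  slopes <- as.matrix(slopes)
  if (nrow(slopes) < 3L)
    stop("domain error: at least 3 SNPs required to correlate slopes")
  if (any(!is.finite(slopes))) stop("integrity error: non-finite slopes")
  m <- ncol(slopes)
  if (length(variances) != m)
    stop("shape error: one variance per slope column required")
  if (any(variances <= 0)) stop("domain error: variances must be > 0")
  sds <- apply(slopes, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(slopes)[sds == 0]
    stop("degenerate-column error: zero slope variance for ",
         paste(bad, collapse = ", "))
  }
  R <- stats::cor(slopes)
  s <- sqrt(as.numeric(variances))
  out <- R * tcrossprod(s)
  diag(out) <- as.numeric(variances)
  out <- (out + t(out)) / 2
  nm <- if (!is.null(names(variances))) names(variances) else colnames(slopes)
  dimnames(out) <- list(nm, nm)
  out
}

#' Extract a slope matrix and estimate the phenotype covariance from a panel
#'
#' Convenience wrapper around [estimate_cov()]: gathers the simple-regression
#' slopes of the requested phenotypes across all panel SNPs, optionally
#' drops SNPs whose single-marker |t| statistic exceeds a cutoff for any of
#' the phenotypes (strongly associated markers violate the null-marker
#' premise of the approximation), and returns the estimated covariance. The
#' single-marker t statistic is itself reconstructed from the release:
#' `t = b / SE(b)` with `SE(b)^2 = sigma2 / (var(g) (n - 1))` and
#' `sigma2 = ((var(y) - b^2 var(g)) (n - 1)) / (n - 2)`.
#'
#' @param panel a [summary_panel()].
#' @param phenotypes phenotype names to include (default: all variables with
#'   role `"phenotype"`).
#' @param max_abs_t drop SNPs with any single-marker `|t|` above this value
#'   (default `Inf`: use all SNPs).
#' @return Covariance matrix with attribute `"n_snps"`, the number of SNPs
#'   actually correlated.
#' @export
estimate_cov_panel <- function(panel, phenotypes = NULL, max_abs_t = Inf) {
  stopifnot(inherits(panel, "summary_panel"))
  if (is.null(phenotypes))
    phenotypes <- panel$variables$variable[panel$variables$role == "phenotype"]
  miss <- setdiff(phenotypes, panel$variables$variable)
  if (length(miss))
    stop("completeness error: unknown phenotype(s): ", paste(miss, collapse = ", "))

  a <- panel$assoc[panel$assoc$variable %in% phenotypes, ]
  snp_ids <- sort(unique(a$snp_id))
  B <- matrix(NA_real_, length(snp_ids), length(phenotypes),
              dimnames = list(snp_ids, phenotypes))
  B[cbind(match(a$snp_id, snp_ids), match(a$variable, phenotypes))] <- a$slope
  keep <- stats::complete.cases(B)
  B <- B[keep, , drop = FALSE]
  snp_ids <- snp_ids[keep]

  if (is.finite(max_abs_t)) {
    n <- panel$n
    gv <- vapply(snp_ids, function(s) snp_moments(panel, s, "auto")[["variance"]],
                 numeric(1))
    vy <- panel$variables$variance[match(phenotypes, panel$variables$variable)]
    tmax <- rep(0, length(snp_ids))
    for (j in seq_along(phenotypes)) {
      b <- B[, j]
      s2 <- pmax((vy[j] - b^2 * gv) * (n - 1), 0) / (n - 2)
      se <- sqrt(s2 / (gv * (n - 1)))
      tj <- ifelse(se > 0, abs(b) / se, Inf)
      tmax <- pmax(tmax, tj)
    }
    B <- B[tmax <= max_abs_t, , drop = FALSE]
  }

  v <- panel$variables$variance[match(phenotypes, panel$variables$variable)]
  names(v) <- phenotypes
  out <- estimate_cov(B, v)
  attr(out, "n_snps") <- nrow(B)
  out
}

#' Project a covariance matrix onto the positive semidefinite cone
#'
#' The slope-correlation estimate need not be positive semidefinite, but
#' eigendecomposition-based analyses require it. Eigenvalues below
#' `epsilon * max(eigenvalue)` are clipped up to that floor, the matrix is
#' reassembled, and its diagonal is rescaled back to the input variances.
#' Already-PSD matrices pass through unchanged.
#'
#' @param cov symmetric covariance matrix.
#' @param epsilon relative eigenvalue floor (default 1e-10).
#' @return Positive semidefinite matrix with the input diagonal.
#' @export
repair_psd <- function(cov, epsilon = 1e-10) {
  cov <- as.matrix(cov)
  if (max(abs(cov - t(cov))) > 1e-12 * max(abs(cov), 1e-300))
    stop("domain error: repair_psd requires a symmetric matrix")
  e <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  floor_val <- epsilon * max(e$values)
  if (all(e$values >= 0) || floor_val <= 0) return(cov)
  lam <- pmax(e$values, floor_val)
  out <- e$vectors %*% (lam * t(e$vectors))
  s <- sqrt(diag(cov) / diag(out))
  out <- out * tcrossprod(s)
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(cov)
  out
}
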