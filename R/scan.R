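#' Fit one model across many SNPs from summary statistics
#'
#' Runs the summary-statistic fit of [sslm()] once per SNP, holding the
#' response combination and covariates fixed, and collects all terms into a
#' long-format table. The genotype term is labelled `"genotype"` so results
#' are comparable across SNPs.
#'
#' @param panel a [summary_panel()].
#' @param response,weights,covariates model description as in [model_spec()].
#' @param snps SNP ids to fit (default: every SNP in the panel).
#' @param mode,center as in [sslm()].
#' @return data.frame with columns `snp_id`, `term`, `estimate`, `se`, `t`,
#'   `p`, `df`.
#' @export
ss_scan <- function(panel, response, weights = NULL, covariates = character(),
                    snps = NULL, mode = c("auto", "exact", "hwe"),
                    center = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "summary_panel"))
  if (is.null(snps)) snps <- panel$snps$snp_id
  out <- vector("list", length(snps))
  for (i in seq_along(snps)) {
    s <- snps[i]
    fit <- sslm(panel, model_spec(response, weights, snp = s,
                                  covariates = covariates),
                mode = mode, center = center)
    term <- fit$terms
    term[term == s] <- "genotype"
    out[[i]] <- data.frame(snp_id = s, term = term,
                           estimate = unname(fit$coefficients),
                           se = unname(fit$se), t = unname(fit$t),
                           p = unname(fit$p), df = fit$df,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Subject-level OLS scan (oracle) across many SNPs
#'
#' The raw-data counterpart of [ss_scan()]: for each SNP, assembles the
#' subject-level design and (combined, optionally centered/standardized)
#' response and fits by QR. Used as ground truth in validation.
#'
#' @param raw a [simulate_dataset()] result.
#' @inheritParams ss_scan
#' @param scale standardize each response variable by its sample standard
#'   deviation (after centering).
#' @return data.frame in the same shape as [ss_scan()].
#' @export
ols_scan <- function(raw, response, weights = NULL, covariates = character(),
                     snps = NULL, center = FALSE, scale = FALSE) {
  stopifnot(inherits(raw, "raw_dataset"))
  if (is.null(snps)) snps <- colnames(raw$genotypes)
  if (is.null(weights)) weights <- rep(1, length(response))
  V <- cbind(raw$phenotypes, age = raw$age, sex = raw$sex)
  n <- nrow(V)
  R <- V[, response, drop = FALSE]
  if (center || scale) R <- sweep(R, 2L, colMeans(R))
  if (scale) R <- sweep(R, 2L, apply(R, 2L, stats::sd), "/")
  y <- drop(R %*% weights)
  Xcov <- if (length(covariates)) V[, covariates, drop = FALSE] else NULL

  out <- vector("list", length(snps))
  for (i in seq_along(snps)) {
    s <- snps[i]
    X <- cbind(`(Intercept)` = rep(1, n), genotype = raw$genotypes[, s])
    if (!is.null(Xcov)) X <- cbind(X, Xcov)
    f <- stats::lm.fit(X, y)
    df <- n - ncol(X)
    sigma2 <- sum(f$residuals^2) / df
    XtXinv <- chol2inv(qr.R(f$qr))
    se <- sqrt(pmax(sigma2 * diag(XtXinv), 0))
    tt <- ifelse(se > 0, f$coefficients / se, 0)
    out[[i]] <- data.frame(snp_id = s, term = colnames(X),
                           estimate = unname(f$coefficients),
                           se = unname(se), t = unname(tt),
                           p = unname(2 * stats::pt(-abs(tt), df)), df = df,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
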