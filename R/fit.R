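#' Solve OLS coefficients from a moment set
#'
#' Solves the normal equations `(X'X) beta = X'y` by Cholesky factorization
#' of the symmetric system (no explicit inverse). The system is rejected when
#' the 2-norm condition number of `X'X` exceeds 1e12.
#'
#' @param m a `moment_set` from [build_moments()].
#' @return Named coefficient vector, intercept first.
#' @export
solve_coefficients <- function(m) {
  xtx <- m$xtx
  kap <- kappa(xtx, exact = TRUE)
  if (!is.finite(kap) || kap > 1e12)
    stop("singularity error: X'X is singular or ill-conditioned (condition number ",
         fmt_num(kap), ")")
  R <- chol(xtx)
  beta <- backsolve(R, forwardsolve(R, m$xty, upper.tri = TRUE, transpose = TRUE))
  resid <- max(abs(xtx %*% beta - m$xty))
  if (resid > 1e-8 * max(abs(m$xty), 1))
    stop("singularity error: normal-equation solve did not converge (residual ",
         fmt_num(resid), ")")
  names(beta) <- m$terms
  beta
}

#' Residual variance from a moment set and coefficients
#'
#' Computes the residual mean square `(y'y - beta' X'y) / (n - (p + 1))`.
#' Tiny negative values (within `1e-10 * y'y`) are rounding noise from a
#' rounded summary release and are clipped to zero; larger negatives mean
#' the panel contradicts itself and raise an error.
#'
#' @param m a `moment_set`.
#' @param beta coefficient vector from [solve_coefficients()].
#' @return Residual variance estimate (sigma-hat squared).
#' @export
residual_variance <- function(m, beta) {
  df <- m$n - (m$p + 1L)
  if (df <= 0L)
    stop("degrees-of-freedom error: n - (p + 1) = ", df, " <= 0")
  val <- (m$yty - sum(beta * m$xty)) / df
  tol <- 1e-10 * max(m$yty, 1)
  if (val < -tol)
    stop("inconsistency error: negative residual variance (", fmt_num(val),
         "); the panel contradicts itself")
  max(val, 0)
}

#' Coefficient standard errors from a moment set
#'
#' Square roots of the diagonal of `sigma2 * (X'X)^{-1}`, the usual OLS
#' covariance of the coefficient estimates.
#'
#' @param m a `moment_set`.
#' @param sigma2 residual variance from [residual_variance()].
#' @return Named vector of standard errors.
#' @export
standard_errors <- function(m, sigma2) {
  kap <- kappa(m$xtx, exact = TRUE)
  if (!is.finite(kap) || kap > 1e12)
    stop("singularity error: X'X is singular or ill-conditioned")
  d <- diag(chol2inv(chol(m$xtx)))
  se <- sqrt(pmax(sigma2 * d, 0))
  names(se) <- m$terms
  se
}

new_sslm <- function(coefficients, se, sigma2, df, n, terms, spec, mode,
                     moments = NULL, extra = list()) {
  t_stats <- ifelse(se > 0, coefficients / se,
                    ifelse(coefficients == 0, 0, Inf * sign(coefficients)))
  p_values <- 2 * stats::pt(-abs(t_stats), df)
  structure(
    c(list(coefficients = coefficients, se = se, sigma2 = sigma2, df = df,
           n = n, t = t_stats, p = p_values, terms = terms, spec = spec,
           mode = mode, moments = moments), extra),
    class = "sslm"
  )
}

#' Fit a covariate-adjusted model from summary statistics
#'
#' The central fitting function: reconstructs the sufficient statistics of
#' the requested model from the panel ([build_moments()]) and solves
#' ordinary least squares, yielding coefficients, standard errors, t
#' statistics and two-sided p-values (t reference distribution with
#' `n - (p + 1)` degrees of freedom) -- without any subject-level data. With
#' explicit sample genotype moments and the sample phenotype covariance in
#' the panel, the result equals raw-data OLS to machine precision.
#'
#' @param panel a [summary_panel()].
#' @param spec a [model_spec()]; alternatively pass `response`, `weights`,
#'   `snp`, `covariates` directly and a spec is built for you.
#' @param mode `"auto"` (default; sample genotype moments when released,
#'   else Hardy-Weinberg moments from the allele frequency), `"exact"`, or
#'   `"hwe"`.
#' @param center treat the (combined) response as centered, i.e. force all
#'   response means to zero. Used internally for principal-component scores.
#' @param response,weights,snp,covariates shorthand forwarded to
#'   [model_spec()] when `spec` is missing.
#' @return An object of class `sslm` with `print`, `summary`, `coef`,
#'   `vcov` and `confint` methods.
#' @examples
#' raw <- simulate_dataset(sim_config(n_subjects = 300, n_snps = 50, seed = 1))
#' panel <- summarize_raw(raw, mode = "exact")
#' fit <- sslm(panel, response = "y1", snp = "snp0001",
#'             covariates = c("age", "sex"))
#' coef(fit)
#' @export
sslm <- function(panel, spec = NULL, mode = c("auto", "exact", "hwe"),
                 center = FALSE, response = NULL, weights = NULL, snp = NULL,
                 covariates = character()) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "summary_panel"))
  if (is.null(spec)) {
    if (is.null(response))
      stop("either `spec` or `response` must be supplied")
    spec <- model_spec(response, weights, snp, covariates)
  }
  stopifnot(inherits(spec, "model_spec"))
  m <- build_moments(panel, spec, mode, center)
  beta <- solve_coefficients(m)
  sigma2 <- residual_variance(m, beta)
  se <- standard_errors(m, sigma2)
  new_sslm(beta, se, sigma2, m$n - (m$p + 1L), m$n, m$terms, spec, mode,
           moments = m)
}

#' @export
print.sslm <- function(x, ...) {
  print(x$spec)
  cat("mode: ", x$mode, ";  n = ", x$n, ";  df = ", x$df, "\n\n", sep = "")
  print(stats::coef(x))
  invisible(x)
}

#' @export
coef.sslm <- function(object, ...) object$coefficients

#' @export
vcov.sslm <- function(object, ...) {
  if (is.null(object$moments))
    stop("no moment set stored; covariance of coefficients unavailable")
  V <- object$sigma2 * chol2inv(chol(object$moments$xtx))
  dimnames(V) <- list(object$terms, object$terms)
  V
}

#' @export
summary.sslm <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = object$t, `Pr(>|t|)` = object$p)
  rownames(tab) <- object$terms
  out <- list(table = tab, sigma2 = object$sigma2, df = object$df,
              n = object$n, mode = object$mode, spec = object$spec)
  class(out) <- "summary.sslm"
  out
}

#' @export
print.summary.sslm <- function(x, ...) {
  print(x$spec)
  cat("mode: ", x$mode, ";  n = ", x$n, "\n\n", sep = "")
  stats::printCoefmat(x$table, P.values = TRUE, has.Pvalue = TRUE)
  cat("\nResidual variance: ", fmt_num(x$sigma2), " on ", x$df,
      " degrees of freedom\n", sep = "")
  invisible(x)
}

#' @export
confint.sslm <- function(object, parm, level = 0.95, ...) {
  cf <- object$coefficients
  if (missing(parm)) parm <- object$terms
  a <- (1 - level) / 2
  q <- stats::qt(1 - a, object$df)
  out <- cbind(cf[parm] - q * object$se[parm], cf[parm] + q * object$se[parm])
  colnames(out) <- paste(format(100 * c(a, 1 - a), trim = TRUE), "%")
  out
}

#' Combine covariate-adjusted fits of individual phenotypes
#'
#' When adjusted fits of `y_1, ..., y_m` on the *same* design are already
#' available, the coefficient vector of the combined response
#' `sum_h c_h y_h` is simply `sum_h c_h beta_h` -- a shortcut that avoids
#' rebuilding the moments. Standard errors do not combine this way (the
#' residual variance of the combination involves the response covariances),
#' so only coefficients are returned; use [sslm()] with a weighted spec for
#' full inference.
#'
#' @param fits list of `sslm` objects sharing identical predictor terms and
#'   degrees of freedom.
#' @param weights numeric combination weights, one per fit.
#' @return Named combined coefficient vector.
#' @export
combine_fits <- function(fits, weights) {
  stopifnot(length(fits) >= 1L, length(weights) == length(fits))
  terms <- fits[[1L]]$terms
  df <- fits[[1L]]$df
  for (f in fits) {
    if (!inherits(f, "sslm"))
      stop("incompatibility error: all elements must be sslm fits")
    if (!identical(f$terms, terms) || f$df != df)
      stop("incompatibility error: fits do not share the same design")
  }
  out <- numeric(length(terms))
  for (i in seq_along(fits)) out <- out + weights[i] * fits[[i]]$coefficients
  names(out) <- terms
  out
}
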