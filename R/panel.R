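#' Construct a summary-statistic panel
#'
#' A summary panel is the complete set of statistics a biobank typically
#' releases in place of subject-level data: descriptive statistics for every
#' variable, the variable covariance matrix, per-SNP genotype information
#' (minor allele frequency and, optionally, sample genotype moments), and the
#' slope/intercept of every simple linear regression `variable ~ SNP`.
#' Everything downstream -- covariate-adjusted fits, linear combinations of
#' phenotypes, principal-component regressions -- is computed from this
#' object alone.
#'
#' @param variables data frame with columns `variable` (character, unique),
#'   `role` (`"phenotype"` or `"covariate"`), `mean`, `variance` (>= 0).
#'   Variances and covariances use the n-1 denominator throughout.
#' @param cov square numeric matrix of sample covariances between all
#'   non-genotype variables, with `dimnames` matching `variables$variable`.
#'   Must be symmetric; diagonal entries must agree with `variables$variance`.
#' @param snps data frame with columns `snp_id` (character, unique), `maf`
#'   in (0, 1), `n` (positive integer), and optional `geno_mean`, `geno_var`
#'   (sample genotype moments; `NA` if not released).
#' @param assoc data frame with columns `snp_id`, `variable`, `slope`,
#'   `intercept` -- one row per simple regression `variable ~ SNP`. The
#'   intercept may be `NA` when variable means are given in `variables`.
#' @param n single sample size shared by the panel. Defaults to the minimum
#'   of `snps$n` (with a warning if they are not all equal, since the
#'   reconstruction assumes complete cases).
#'
#' @return An object of class `summary_panel`.
#' @seealso [read_panel()], [write_panel()], [sslm()]
#' @export
summary_panel <- function(variables, cov, snps, assoc, n = NULL) {
  variables <- as.data.frame(variables, stringsAsFactors = FALSE)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  assoc <- as.data.frame(assoc, stringsAsFactors = FALSE)

  need_cols(variables, c("variable", "role", "mean", "variance"), "variables")
  need_cols(snps, c("snp_id", "maf", "n"), "snps")
  need_cols(assoc, c("snp_id", "variable", "slope"), "assoc")
  if (is.null(assoc$intercept)) assoc$intercept <- NA_real_
  if (is.null(snps$geno_mean)) snps$geno_mean <- NA_real_
  if (is.null(snps$geno_var)) snps$geno_var <- NA_real_

  variables$variable <- as.character(variables$variable)
  snps$snp_id <- as.character(snps$snp_id)
  assoc$snp_id <- as.character(assoc$snp_id)
  assoc$variable <- as.character(assoc$variable)

  if (anyDuplicated(variables$variable))
    stop("integrity error: duplicated variable names in `variables`")
  if (!all(variables$role %in% c("phenotype", "covariate")))
    stop("schema error: `role` must be 'phenotype' or 'covariate'")
  if (any(!is.finite(variables$mean)) || any(!is.finite(variables$variance)))
    stop("schema error: non-finite variable means/variances")
  if (any(variables$variance < 0))
    stop("integrity error: negative variable variance")

  if (anyDuplicated(snps$snp_id))
    stop("integrity error: duplicated snp_id in `snps`")
  if (any(!is.finite(snps$maf)) || any(snps$maf <= 0) || any(snps$maf >= 1))
    stop("domain error: maf must lie strictly in (0, 1)")
  if (any(snps$maf > 0.5))
    warning("maf > 0.5 for ", sum(snps$maf > 0.5),
            " SNP(s); genotype moments use the stored allele frequency as-is")
  gv <- snps$geno_var
  if (any(!is.na(gv) & gv < 0))
    stop("integrity error: negative geno_var")

  if (anyDuplicated(assoc[, c("snp_id", "variable")]))
    stop("integrity error: duplicated (snp_id, variable) pair in `assoc`")
  if (any(!is.finite(assoc$slope)))
    stop("integrity error: non-finite slope in `assoc`")
  unknown_snp <- setdiff(assoc$snp_id, snps$snp_id)
  if (length(unknown_snp))
    stop("integrity error: assoc references unknown snp_id: ",
         paste(utils::head(unknown_snp, 3), collapse = ", "))
  unknown_var <- setdiff(assoc$variable, variables$variable)
  if (length(unknown_var))
    stop("integrity error: assoc references unknown variable: ",
         paste(utils::head(unknown_var, 3), collapse = ", "))

  cov <- as.matrix(cov)
  if (nrow(cov) != ncol(cov))
    stop("shape error: covariance matrix must be square")
  if (is.null(rownames(cov)) || is.null(colnames(cov)))
    stop("schema error: covariance matrix needs variable dimnames")
  if (!identical(rownames(cov), colnames(cov)))
    stop("schema error: covariance row/column names disagree")
  if (!all(rownames(cov) %in% variables$variable))
    stop("integrity error: covariance matrix names unknown variable(s)")
  scale_c <- max(abs(cov), 1e-300)
  if (max(abs(cov - t(cov))) > 1e-12 * scale_c)
    stop("consistency error: covariance matrix asymmetric beyond tolerance")
  cov <- (cov + t(cov)) / 2  # kill representational asymmetry only
  dvar <- variables$variance[match(rownames(cov), variables$variable)]
  dcov <- diag(cov)
  bad <- abs(dcov - dvar) > 1e-8 * pmax(abs(dvar), 1)
  if (any(bad))
    stop("consistency error: cov diagonal disagrees with declared variance for: ",
         paste(utils::head(rownames(cov)[bad], 3), collapse = ", "))

  if (is.null(n)) {
    nn <- unique(snps$n)
    n <- min(snps$n)
    if (length(nn) > 1L)
      warning("per-SNP n differs across the panel; model fits use the minimum (",
              n, ") under the complete-case assumption")
  }
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n <= 0L)
    stop("domain error: panel n must be a positive integer")

  structure(
    list(variables = variables, cov = cov, snps = snps, assoc = assoc, n = n),
    class = "summary_panel"
  )
}

need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("schema error: ", what, " is missing column(s): ",
         paste(miss, collapse = ", "))
  invisible(df)
}

#' @export
print.summary_panel <- function(x, ...) {
  cat("Summary-statistic panel\n")
  cat("  n subjects:  ", x$n, "\n", sep = "")
  cat("  variables:   ", nrow(x$variables), " (",
      sum(x$variables$role == "phenotype"), " phenotypes, ",
      sum(x$variables$role == "covariate"), " covariates)\n", sep = "")
  cat("  SNPs:        ", nrow(x$snps), "\n", sep = "")
  cat("  assoc rows:  ", nrow(x$assoc), "\n", sep = "")
  exact <- sum(!is.na(x$snps$geno_mean) & !is.na(x$snps$geno_var))
  cat("  genotype moments: ", exact, "/", nrow(x$snps),
      " explicit (remainder HWE-derived from MAF)\n", sep = "")
  invisible(x)
}

#' Recover a variable mean from a simple-regression intercept
#'
#' For the simple regression `y ~ g` with intercept `a` and slope `b`, the
#' fitted line passes through the point of means, so `mean(y) = a + b * mean(g)`.
#' This recovers a phenotype mean when the release carries intercepts but not
#' descriptive means. When a mean is present in the panel's variable table it
#' takes precedence over this identity.
#'
#' @param intercept,slope simple-regression intercept and slope.
#' @param geno_mean mean genotype dosage of the marker regressed on.
#' @return The implied variable mean `intercept + slope * geno_mean`.
#' @export
mean_from_intercept <- function(intercept, slope, geno_mean) {
  stopifnot(is.finite(intercept), is.finite(slope), is.finite(geno_mean))
  intercept + slope * geno_mean
}

# 17 significant digits: round-trips IEEE doubles exactly through text
fmt17 <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

tsv_write <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt17)
  lines <- c(
    paste(names(df), collapse = "\t"),
    do.call(paste, c(unname(df), list(sep = "\t")))
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write a summary panel to TSV files
#'
#' Writes four tab-delimited files into `dir`: `assoc.tsv`, `snps.tsv`,
#' `variables.tsv` and `cov.tsv`. Rows are sorted (by `snp_id` then
#' `variable`) and numbers are printed with 17 significant digits, so two
#' writes of the same panel are byte-identical and a write/read round-trip
#' reproduces the panel exactly.
#'
#' @param panel a [summary_panel()].
#' @param dir output directory; created if absent.
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "summary_panel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  assoc <- panel$assoc[order(panel$assoc$snp_id, panel$assoc$variable),
                       c("snp_id", "variable", "slope", "intercept")]
  tsv_write(assoc, file.path(dir, "assoc.tsv"))

  snps <- panel$snps[order(panel$snps$snp_id),
                     c("snp_id", "maf", "n", "geno_mean", "geno_var")]
  tsv_write(snps, file.path(dir, "snps.tsv"))

  vars <- panel$variables[order(panel$variables$variable),
                          c("variable", "role", "mean", "variance")]
  tsv_write(vars, file.path(dir, "variables.tsv"))

  ord <- order(rownames(panel$cov))
  cm <- panel$cov[ord, ord, drop = FALSE]
  cov_df <- data.frame(variable = rownames(cm), as.data.frame(cm),
                       check.names = FALSE, stringsAsFactors = FALSE)
  tsv_write(cov_df, file.path(dir, "cov.tsv"))

  invisible(dir)
}

tsv_read <- function(path, what) {
  if (!file.exists(path))
    stop("I/O error: missing panel file ", what, " at ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = "NA")
}

#' Read a summary panel from TSV files
#'
#' Reads the four files written by [write_panel()] from `dir` and validates
#' the panel (unique identifiers, covariance symmetry, diagonal/variance
#' agreement, referential integrity of the association table).
#'
#' @param dir directory containing `assoc.tsv`, `snps.tsv`, `variables.tsv`,
#'   `cov.tsv`.
#' @return A validated [summary_panel()].
#' @export
read_panel <- function(dir) {
  assoc <- tsv_read(file.path(dir, "assoc.tsv"), "assoc.tsv")
  snps <- tsv_read(file.path(dir, "snps.tsv"), "snps.tsv")
  vars <- tsv_read(file.path(dir, "variables.tsv"), "variables.tsv")
  cov_df <- tsv_read(file.path(dir, "cov.tsv"), "cov.tsv")

  need_cols(cov_df, "variable", "cov.tsv")
  cm <- as.matrix(cov_df[, -1, drop = FALSE])
  rownames(cm) <- cov_df$variable
  storage.mode(cm) <- "double"

  summary_panel(variables = vars, cov = cm, snps = snps, assoc = assoc)
}
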