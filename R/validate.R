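#' Replicate-level validation of the summary-statistic reconstruction
#'
#' For each replicate: simulate a cohort, summarize it into a release-style
#' panel, fit every requested model per SNP both from the summary statistics
#' and from the subject-level oracle, and record per-SNP errors
#' (summary-based minus oracle) in the genotype slope, its standard error,
#' and -log10 p. Per replicate the errors are aggregated into a mean across
#' SNPs and an intra-genomic variance (the variance of the per-SNP error
#' within one simulated genome); across replicates the report carries the
#' mean and the max of each.
#'
#' @param config a [sim_config()]; `n_replicates` and `seed` drive the
#'   replication (replicate r uses `seed + r - 1`).
#' @param specs named list of model descriptions, each a list with elements
#'   `response`, and optionally `weights`, `covariates`, `center`. The
#'   genotype predictor is added per SNP.
#' @param cov_source `"true"` uses the panel's own (sample) covariance
#'   matrix; `"estimated"` replaces the whole variable covariance matrix by
#'   the slope-correlation approximation before fitting.
#' @param mode genotype-moment mode for the summary-based fits.
#' @return An object of class `error_report`: `per_snp` (long error table),
#'   `per_replicate` (per-replicate mean and intra-genomic variance per
#'   metric), and `summary` (cross-replicate mean/max aggregation).
#' @export
validate_method <- function(config, specs,
                            cov_source = c("true", "estimated"),
                            mode = c("exact", "hwe")) {
  cov_source <- match.arg(cov_source)
  mode <- match.arg(mode)
  stopifnot(inherits(config, "sim_config"))
  if (length(specs) == 0L)
    stop("empty-report error: no model specs supplied")
  if (config$n_snps == 0L)
    stop("empty-report error: zero SNPs requested")
  if (is.null(names(specs)) || any(!nzchar(names(specs))))
    names(specs) <- paste0("model", seq_along(specs))

  per_snp <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    cfg_r <- config
    cfg_r$seed <- config$seed + r - 1L
    raw <- simulate_dataset(cfg_r)
    panel <- summarize_raw(raw, mode = mode)
    if (cov_source == "estimated") {
      est <- estimate_cov_panel(panel, phenotypes = panel$variables$variable)
      panel <- set_panel_cov(panel, est)
    }
    rows <- vector("list", length(specs))
    for (k in seq_along(specs)) {
      sp <- specs[[k]]
      center <- isTRUE(sp$center)
      got <- ss_scan(panel, sp$response, sp$weights,
                     sp$covariates %||% character(),
                     mode = mode, center = center)
      want <- ols_scan(raw, sp$response, sp$weights,
                       sp$covariates %||% character(),
                       snps = unique(got$snp_id), center = center)
      g1 <- got[got$term == "genotype", ]
      g0 <- want[want$term == "genotype", ]
      stopifnot(identical(g1$snp_id, g0$snp_id))
      rows[[k]] <- data.frame(
        replicate = r, spec = names(specs)[k],
        snp_id = rep(g1$snp_id, 3L),
        metric = rep(c("slope", "se", "mlog10p"), each = nrow(g1)),
        error = c(g1$estimate - g0$estimate,
                  g1$se - g0$se,
                  -log10(pmax(g1$p, .Machine$double.xmin)) +
                    log10(pmax(g0$p, .Machine$double.xmin))),
        stringsAsFactors = FALSE
      )
    }
    per_snp[[r]] <- do.call(rbind, rows)
  }
  per_snp <- do.call(rbind, per_snp)
  error_report(per_snp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate a per-SNP error table into an error report
#'
#' Computes, for every (replicate, model, metric) cell, the mean error
#' across SNPs and the intra-genomic variance (variance of the per-SNP
#' error within the replicate), then summarizes across replicates with the
#' mean of the means, and the mean and max of the intra-genomic variances.
#' Exposed separately so a stored per-SNP table can be re-aggregated and
#' checked against the summary.
#'
#' @param per_snp data.frame with columns `replicate`, `spec`, `snp_id`,
#'   `metric`, `error`.
#' @return An object of class `error_report`.
#' @export
error_report <- function(per_snp) {
  need_cols(per_snp, c("replicate", "spec", "metric", "error"), "per_snp")
  sep <- "\x1f"  # unit separator: cannot collide with identifiers
  key <- interaction(per_snp$replicate, per_snp$spec, per_snp$metric,
                     drop = TRUE, sep = sep)
  mean_e <- tapply(per_snp$error, key, mean)
  var_e <- tapply(per_snp$error, key, stats::var)
  parts <- do.call(rbind, strsplit(names(mean_e), sep, fixed = TRUE))
  per_replicate <- data.frame(
    replicate = as.integer(parts[, 1L]), spec = parts[, 2L],
    metric = parts[, 3L], mean_error = as.numeric(mean_e),
    intra_var = as.numeric(var_e), stringsAsFactors = FALSE
  )
  per_replicate <- per_replicate[order(per_replicate$spec,
                                       per_replicate$metric,
                                       per_replicate$replicate), ]
  rownames(per_replicate) <- NULL

  key2 <- interaction(per_replicate$spec, per_replicate$metric, drop = TRUE,
                      sep = sep)
  agg <- function(x, f) as.numeric(tapply(x, key2, f))
  parts2 <- do.call(rbind, strsplit(levels(key2), sep, fixed = TRUE))
  summary_df <- data.frame(
    spec = parts2[, 1L], metric = parts2[, 2L],
    mean_error = agg(per_replicate$mean_error, mean),
    max_abs_mean_error = agg(per_replicate$mean_error, function(x) max(abs(x))),
    mean_intra_var = agg(per_replicate$intra_var, mean),
    max_intra_var = agg(per_replicate$intra_var, max),
    stringsAsFactors = FALSE
  )

  structure(list(per_snp = per_snp, per_replicate = per_replicate,
                 summary = summary_df),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  reps <- length(unique(x$per_replicate$replicate))
  cat("validation error report: ", reps, " replicate(s), ",
      length(unique(x$per_snp$snp_id)), " SNP(s) per genome\n\n", sep = "")
  df <- x$summary
  df$mean_error <- signif(df$mean_error, 3)
  df$max_abs_mean_error <- signif(df$max_abs_mean_error, 3)
  df$mean_intra_var <- signif(df$mean_intra_var, 3)
  df$max_intra_var <- signif(df$max_intra_var, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
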