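---
title: "Exact covariate adjustment and phenotype PCA from single-marker summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact covariate adjustment and phenotype PCA from single-marker summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumpca)
```

## The problem

Biobanks typically do not share subject-level genotypes and phenotypes.
What they do share is the output of millions of *simple* regressions: for
every marker $k$ and every variable $v$ (phenotypes and basic covariates
alike), the slope $b_{vk}$ and intercept of the one-predictor model
$v \sim g_k$, together with descriptive statistics — variable means and
variances, the variable covariance matrix, per-marker allele frequencies
and sample sizes. Researchers, however, usually need *multiple* regression:
a covariate-adjusted model
$y = \beta_0 + \beta_g g_k + \beta_1 x_1 + \cdots + \beta_p x_p + \varepsilon$,
possibly with a composite response — a weighted combination of phenotypes,
or a principal-component score.

`sumpca` closes that gap. Ordinary least squares depends on the data only
through the sufficient statistics $X'X$, $X'y$ and $y'y$, and each entry of
those matrices is a sum of products that can be rewritten in terms of the
released quantities. The reconstruction is algebraically exact: when the
release carries sample (rather than model-derived) moments, the fit is
identical to one computed on the raw data, up to floating-point rounding.

## The reconstruction identities

All covariances below are *sample* covariances with the $n-1$ denominator;
exactness depends on using the same convention as the release.

With intercept column first, for predictors $x_k, x_l$:

$$\textstyle\sum_i x_{ki} = n\,\bar x_k, \qquad
  \sum_i x_{ki}x_{li} = \widehat{\mathrm{cov}}(x_k, x_l)\,(n-1) + n\,\bar x_k \bar x_l,$$

which fills $X'X$ (`build_xtx()`). For a response
$y = \sum_h c_h y_h$:

$$\textstyle\sum_i y_i = n \sum_h c_h \bar y_h, \qquad
  \sum_i x_{ki} y_i = \Big(\sum_h c_h\,\widehat{\mathrm{cov}}(x_k, y_h)\Big)(n-1)
  + n\,\bar x_k \sum_h c_h \bar y_h,$$

$$y'y = \sum_h \sum_j c_h c_j \Big(\widehat{\mathrm{cov}}(y_h, y_j)(n-1)
  + n\,\bar y_h \bar y_j\Big).$$

Covariances among non-genotype variables come straight from the released
covariance matrix. The genotype's covariance with any variable follows from
the simple-regression slope itself,
$\widehat{\mathrm{cov}}(g, v) = b_{vg}\,\widehat{\mathrm{var}}(g)$, which
is why a release of single-marker slopes suffices. Coefficients are then
$\hat\beta = (X'X)^{-1}X'y$, the residual variance is
$\hat\sigma^2 = (y'y - \hat\beta'X'y)/(n-p-1)$, and standard errors are the
square roots of the diagonal of $\hat\sigma^2 (X'X)^{-1}$, with two-sided
$t$ tests on $n-p-1$ degrees of freedom.

Only one genotype may enter a model: marker–marker covariances (linkage
disequilibrium) are not part of the release, so joint multi-SNP models are
rejected rather than silently approximated.

### Genotype moments: exact vs Hardy–Weinberg mode

The genotype mean and variance appear throughout. If the release carries
the *sample* moments, reconstruction is exact ("exact mode"). If only the
allele frequency $p$ is available, the package falls back on the
Hardy–Weinberg values $2p$ and $2p(1-p)$ ("HWE mode"), which are only as
accurate as the HWE assumption for that marker; the resulting fits are
close but not machine-exact even on HWE-simulated data, because the sample
variance of a finite cohort deviates from $2\hat p(1-\hat p)$. Both modes
are first-class and the validation machinery quantifies the gap.
Frequencies above 0.5 are accepted with a warning — releases differ on
minor- versus effect-allele orientation, and the moment formulas use the
stored allele's frequency either way.

## Estimating the covariance matrix from slopes

When the variable covariance matrix is not released, the correlation of two
phenotypes can be approximated by the correlation of their slope vectors
across many markers:
$\widehat{\mathrm{cov}}(y_h, y_j) \approx
 \mathrm{cor}(b_h, b_j)\sqrt{\widehat{\mathrm{var}}(y_h)\,\widehat{\mathrm{var}}(y_j)}$
(`estimate_cov()`, Pearson correlation). The premise is that most markers
are (nearly) null, so slope noise is driven by residual phenotype
correlation. Its accuracy therefore improves as $1/\sqrt{S}$ in the number
of markers $S$ and degrades with the fraction of strongly associated
markers; the package reports the number of markers used and offers an
optional single-marker $|t|$ cutoff (`max_abs_t`) to drop strong
associations, reconstructing that $t$ from the release itself. Whether to
filter is left to the user: with genome-scale $S$ and polygenic traits the
unfiltered estimate is typically fine, which is why the default uses all
markers.

The estimate need not be positive semidefinite. `repair_psd()` clips
eigenvalues at $10^{-10}$ of the largest, reassembles, and rescales the
diagonal back to the declared variances; it is a no-op on PSD input and is
applied automatically (with a warning) before any eigendecomposition.

## Principal-component regressions

For centered phenotypes, the $j$-th principal-component score is the
combination weighted by the $j$-th eigenvector of their covariance matrix,
so a PC regression is just a weighted-combination fit with the response
means forced to zero (`pc_fit()` with `center = TRUE` internally). With
`scaled = TRUE` the eigenvectors come from the correlation matrix and each
weight is divided by the phenotype's standard deviation, equivalent to
running PCA on standardized phenotypes.

Two conventions make the decomposition deterministic: each eigenvector is
flipped so its largest-magnitude loading is positive (ties broken by lowest
index), and numerically tied eigenvalues are ordered by the variable index
of their dominant loading. Results are invariant to the stored sign up to a
global sign on the coefficients; $p$-values do not change.

### Centering and standardizing released fits

A release computed on uncentered phenotypes can be transformed after the
fact: subtracting $\mu$ from the response moves only the intercept (by
$-\mu$) and leaves every other coefficient and all standard errors
untouched; dividing by $\sigma$ divides all coefficients and standard
errors by $\sigma$ and the residual variance by $\sigma^2$. Note the
division is by $\sigma$, not $\sigma^2$ — the standard error has the
response's units, and a raw-data refit on $(y-\mu)/\sigma$ confirms the
$\sigma$ scaling; descriptions of this transform sometimes typeset the
divisor ambiguously. Slope $t$ statistics and $p$-values are unchanged by
either transform; the intercept's $t$ moves with $\mu$, exactly as a refit
would move it.

## Numerical choices

* The normal equations are solved by Cholesky factorization of $X'X$, not
  by explicit inversion; a condition-number guard at $10^{12}$ rejects
  (near-)singular designs, and the solve verifies its own residual at
  $10^{-8}$ relative.
* Reconstructed $\hat\sigma^2$ can come out marginally negative when the
  release was rounded. Values within $-10^{-10}\,y'y$ are clipped to zero;
  anything more negative is treated as a self-contradictory panel and
  raises an error rather than a silent repair.
* Panel validation enforces covariance symmetry to $10^{-12}$ relative and
  agreement between the covariance diagonal and the declared variances to
  $10^{-8}$ relative.
* Panels are written as sorted TSV with 17 significant digits, so writes
  are byte-reproducible and write/read round-trips restore every double
  exactly.
* A panel is assumed complete-case with a single shared $n$; if per-marker
  sample sizes differ, the minimum is used with a warning rather than
  modeling the heterogeneity.

## The synthetic cohort generator

`simulate_dataset()` builds the kind of cohort the method targets: allele
frequencies from Beta(2, 8) truncated to $[0.01, 0.5]$ (a realistic
common-variant frequency spectrum), genotypes Binomial(2, maf) — HWE holds
by construction — age Poisson with mean 50, sex Bernoulli(1/2), and three
phenotypes driven linearly by the first ten SNPs plus age and sex with
jointly Gaussian residuals.

The effect sizes are fixed defaults chosen once from the closed-form
covariance decomposition
$\Sigma_Y = \Gamma D_g \Gamma' + \lambda\,\delta\delta' + \tfrac14 \kappa\kappa' + \Sigma_\varepsilon$
so that the realized phenotype correlations average about $0.30$
($y_1,y_2$), $-0.08$ ($y_1,y_3$) and $0.07$ ($y_2,y_3$) — including a
negative correlation, which cannot arise from shared causal markers with
these effect signs alone and is carried by the residual covariance
(off-diagonals $0.242$, $-0.036$, $0.112$). All generator parameters are
overridable.

What the generator does **not** emulate: linkage disequilibrium between
markers, population structure, relatedness, missing data, genotyping
error, and non-Gaussian phenotypes. Passing validation on this generator
demonstrates the algebraic exactness of the reconstruction and the
statistical behavior of the covariance approximation under ideal sampling;
on real releases, departures from HWE (when only frequencies are released)
and missingness-induced inconsistencies between summary tables are the
dominant extra error sources.

## Validation design and problem sizes

`validate_method()` runs the full loop — simulate, summarize, fit per SNP
from the summaries and from the subject-level oracle
(`ols_oracle()`, an independent QR-based least-squares path) — and
aggregates per-SNP errors into a per-replicate mean and an *intra-genomic
variance* (the variance of the error across SNPs within one simulated
genome), then the mean and max of those across replicates. The report
retains the per-SNP error table so the aggregation can be re-derived and
audited.

The shipped validation and the acceptance script use desk-scale sizes
chosen to exercise every claim while staying fast: 500 subjects with 1,000
markers for the exactness and concordance checks (seven models per marker:
one single-phenotype adjustment, three random combinations, three PC
scores), 2,000 mostly-null markers for the covariance-approximation check,
marker counts {500, 2,000, 10,000} (averaged over three seeds) for its
convergence, and 20 replicates of the default 2,000-subject cohort for
calibration. At these sizes exact-mode errors sit at the $10^{-11}$ level
— pure floating-point rounding — and the approximate-covariance slope error
averages about 2% of the slope's standard error.

## Limitations

* One genotype per model; no LD-aware multi-marker fits.
* Complete-case, single-$n$ panels; real releases with per-marker
  missingness will show small internal inconsistencies that propagate into
  the reconstruction.
* The covariance approximation's error bound depends on the (unknown)
  fraction of truly associated markers; the package reports $S$ and
  exposes the $|t|$ filter but cannot certify the premise.
* Inference is standard OLS: no mixed models, kinship, or
  heteroskedasticity-robust standard errors.
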