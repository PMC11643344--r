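---
title: "Methods and design of gwaskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of gwaskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gwaskit is a headless toolkit for genome-wide association studies (GWAS)
and genomic prediction (GP) on biallelic SNP data. This vignette explains
the statistical machinery, the conventions the package commits to where
the field leaves a choice open, and what the built-in simulator does and
does not emulate.

## Data model and conventions

Genotypes live in a `geno_data` container: an `n x m` dosage matrix over
samples by variants, with BIM-style variant metadata and FAM-style sample
metadata. A dosage counts copies of the **A1 allele**, the first allele
of the variant table. gwaskit fixes A1 to the *minor* allele of the
loaded cohort: after parsing a VCF the ALT-allele counts are flipped at
any site where the ALT frequency exceeds 0.5 (a 50/50 tie keeps ALT).
This matches PLINK's additive coding and gives MAF filters and effect
signs a single, stable meaning. Missing calls are `NA`; any VCF genotype
with a `.` allele slot (including half-calls like `0/.`) is treated as
missing, and both `/` and `|` separators are accepted. Multiallelic and
symbolic records are skipped, not split: the methods downstream are
defined for biallelic SNPs.

PLINK 1 BED I/O is implemented directly (two-bit codes, SNP-major,
low-order bit pairs first, zero pad bits) because exact byte-level
fidelity is a core guarantee of the package: `read_plink(write_plink(x))`
is the identity, missing calls included, and the test suite checks a
hand-packed reference byte as well as hundreds of random round trips.

Quality control follows PLINK semantics. The "genotyping rate cutoff" is
a maximum per-variant missing-call rate (`--geno`), and thresholds are
inclusive: a variant is kept when `missing_rate <= missing_max` **and**
`maf >= maf_min`, with the missing filter accounted before the MAF filter
in conversion reports. MAF is computed over non-missing calls only.
Missing dosages are mean-imputed per variant before kinship, PCA,
regression or machine-learning steps; imputation never alters observed
calls. Sample-level missingness filtering (`--mind`) is intentionally
out of scope. Phenotype/genotype intersection happens before analysis, so
filters applied via the command-line workflow reflect the analyzed
cohort.

## Kinship and population structure

The default genomic relationship matrix is the standardized (unit
variance per SNP) estimator: each variant is centred at `2 f_j` and
scaled by `sqrt(2 f_j (1 - f_j))` with `f_j` estimated from the analyzed
cohort after imputation, and `K = W W' / m`. Zero-variance variants carry
no information and are excluded from both `W` and `m`. A centred-only
estimator is available as an option. Under Hardy-Weinberg the
standardized GRM has unit expected diagonal, which the tests verify on
simulated data.

PCA operates on centred (not re-standardized) dosages; component signs
are fixed by making each component's largest-magnitude loading positive,
so results are deterministic. Heatmap ordering uses average-linkage
hierarchical clustering on the distance `max(K) - K`, a max-shift chosen
over `1 - K` because standardized kinship entries can exceed 1.

## The mixed model

Association testing and GBLUP both build on the single-spectral-
decomposition linear mixed model

$$y \sim N(X\beta,\; \sigma_g^2 K + \sigma_e^2 I).$$

`fit_lmm_null()` eigendecomposes `K = U S U'` once, rotates `y` and `X`
by `U'`, and profiles the fixed effects and `sigma_g^2` analytically at
each candidate variance ratio `delta = sigma_e^2 / sigma_g^2`, leaving a
one-dimensional optimization. `delta` is maximized over a 100-point
log-spaced grid on `[1e-5, 1e5]` and then refined with `stats::optimize`
(Brent's bracketed search) between the best grid point's neighbours —
the grid guards against local optima, the refinement sharpens the
estimate. REML is the default criterion, with ML available; the reported
pseudo-heritability is `h2 = 1 / (1 + delta)`.

The per-SNP scan (`gwas_lmm`) keeps `delta` at the null-model estimate by
default — the fast approximation used by spectral-decomposition LMM
tools — and computes generalized-least-squares effects in the rotated
space, with two-sided Wald chi-square (1 df) p-values. An exact per-SNP
`delta` refit is available behind a flag and is never allowed to produce
a worse per-SNP restricted likelihood, which the tests assert. The tested
SNP stays inside the kinship (no leave-one-chromosome-out), matching a
single auto-generated kinship workflow. Covariates beyond the intercept
(for example principal components) can be supplied as an `X` matrix, but
the default is intercept-only.

Per-SNP ordinary least squares (`gwas_linreg`) is the deliberately
uncorrected baseline: classical t-tests with `n - 2` df. Zero-variance
variants are reported with `beta = 0`, `p = 1` rather than dropped, so
every output stays row-aligned with the input variant table. P-values
are clamped to the smallest positive double rather than underflowing to
zero, keeping `-log10(p)` finite in plots. Genomic inflation is
`lambda_GC = median(chi^2) / 0.4549364`, the median 1-df chi-square
quantile.

## Machine-learning association and prediction

The ML scan follows a repeated-split importance protocol: for each of
`n_iterations` (default 10) seeded randomized splits, a learner is
trained on `round(0.7 n)` samples and its per-variant importance vector
is recorded, along with the R-squared on the held-out 30% — the split
exists so that every importance vector is paired with an out-of-sample
quality check. Final scores are the elementwise **sum** across
iterations by default; mean and median are offered as alternatives.
Importances are not re-normalized before aggregation.

Learner conventions, chosen to match the defaults of the widely used
implementations so other toolchains can reproduce the numbers:

* **random forest** — `ranger`, 200 trees, maximum depth 3, impurity
  (variance) importance, single-threaded and seeded for bit
  reproducibility;
* **gradient-boosted trees** — `xgboost`, 200 rounds, maximum depth 3,
  squared-error objective, gain importance (normalized per model);
* **ridge** — closed-form SVD solution on per-variant standardized
  inputs, penalty chosen by generalized cross-validation over a
  13-point log grid on `[1e-3, 1e3]` per training split, importance =
  |standardized coefficient|. The kernel (SVD) form keeps the
  `m >> n` case at `O(n^2 m)`.

Binary traits are treated as 0/1-coded regression targets; there is no
separate classifier mode, keeping one code path for quantitative and
qualitative phenotypes alike.

Genomic prediction (`gp_holdout`) draws one seeded hold-out set (default
30 samples), trains `n_models` (default 10) models on the remaining
pool — the models differ only by learner seed, since nothing in the
protocol subsamples the training pool — and averages their predictions
per held-out sample. GBLUP is deterministic, so its `n_models` collapses
to one with a note in the result. Agreement is summarized by the Pearson
correlation and Bland-Altman statistics (`bias = mean(pred - obs)`,
limits of agreement `bias +/- 1.96 sd`). GBLUP predictions are
`mu + K[test, train] (K[train, train] + delta I)^{-1} (y_train - mu)`
with `mu` and `delta` from a REML fit on the training block only.

## Visualization

Every plot is backed by a typed result computed upstream; the plotting
layer never recomputes a statistic, and each image gets a JSON sidecar
with its machine-checkable summary (threshold line height, exceedance
count, lambda, and so on). The tests enforce the pass-through contract by
injecting sentinel values. SVG output is byte-deterministic for identical
inputs. The Manhattan significance line defaults to Bonferroni
`0.05 / m`; importance scans are drawn without a line because aggregated
importances have no significance scale. The heritability panel shows the
`h2` point estimate next to the `delta` profile-likelihood curve, making
the flatness (or sharpness) of the variance-ratio optimum visible.

## The simulator: what it emulates, and what it does not

`simulate_genotypes` draws from the Balding-Nichols model: ancestral
frequencies uniform on `[0.05, 0.5]`, per-population frequencies Beta
distributed around them with differentiation parameter `Fst`, genotypes
binomial, samples split evenly across populations, and i.i.d. missing
masks. This is the simplest standard model that produces the confounding
that distinguishes a structure-corrected from an uncorrected scan, which
is exactly what the validation needs. Variants are laid out on 5
chromosomes at evenly spaced positions so genome-coordinate plots have
realistic shape.

`simulate_phenotype` places `n_causal` causal markers among variants
with MAF at least 0.05, draws standard-normal effects on standardized
dosages, orthogonalizes the noise against the genetic value and scales
both so that the in-sample variance ratio equals `h2` **exactly** — a
sample-level construction chosen so parameter-recovery tests have a sharp
target rather than an expectation with simulation noise around it.
Qualitative traits threshold the liability at its median into balanced
0/1 classes.

What the simulator does **not** reproduce: linkage disequilibrium,
recombination maps, minor-allele-frequency spectra of real arrays,
epistasis, or any particular real dataset. Passing tests on simulated
data therefore demonstrates correctness of the algorithms and their
contracts — calibration under structure, detection of designed signals,
exact format fidelity — not performance claims about any specific crop
or cohort.

## Validation scales and numerical choices

The validation suite runs at desk scale, chosen so the full suite
completes in minutes while keeping each check statistically meaningful:
h2 recovery uses 20 replicates at n=500, m=2000 (true h2 0.5); the
structure control uses 2 populations at Fst 0.1, n=300, m=2000; the
designed-marker check uses n=300, m=1000 with one causal SNP at 30%
variance over 20 replicates and all five methods; prediction sanity uses
n=500, m=2000, 50 causal at h2 0.6 and 0. The dimensional contract is
additionally exercised at the full 2000 x 90010 shape through chunked
generation (columns are generated in blocks of about 2e7 cells to bound
peak memory).

One honest caveat surfaced by the validation: with 50 causal markers
among 2000, uniform-shrinkage predictors (GBLUP, ridge) reach a mean
hold-out correlation of about 0.26 at h2 = 0.6 — their efficiency bound
for a sparse architecture; a dense architecture measures about 0.33,
matching the classic `sqrt(n h2 / (n h2 + M))` expectation. Hold-out
correlations on 30-100 samples carry sampling noise of roughly +/- 0.1
per replicate, so single-replicate prediction accuracies should never be
over-read.

Numerical conventions collected in one place: eigenvalues of `K` are
clamped at zero and `K` must be PSD within `-1e-8` of its largest
eigenvalue; variants with variance below `1e-12` count as constant;
p-values live in `(0, 1]`; the missing rate is computed as an integer
count over `n` to keep threshold boundaries exact in floating point;
ridge treats zero-variance columns as zero-coefficient; all learners run
single-threaded under fixed seeds in tests, making every reported number
bit-reproducible.

## Known limitations

* No LD-aware methods (clumping, LOCO, conditional analysis).
* No covariate files in the CLI (the R API accepts an `X` matrix).
* No BGEN/PGEN or dosage formats; no indel normalization.
* The full eigendecomposition costs `O(n^3)`: comfortable to a few
  thousand samples, not designed for biobank scale.
* Classification metrics (AUC) are not offered for qualitative traits;
  they are modelled as 0/1 regression targets throughout.
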