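---
title: "Tissue-adjusted single-sample gene set scoring: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-adjusted single-sample gene set scoring: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Bulk tumor transcriptomes carry a strong normal-tissue signature: a naive
comparison of two cancer types largely recapitulates a comparison of the
tissues they arose from. To ask pathway-level questions about an
*individual* tumor — which biological processes are dysregulated in this
sample, relative to the tissue it came from — one needs (a) a per-sample
(not cohort-contrast) gene set statistic, (b) a normal-tissue reference to
measure deviation against, and (c) a calibrated null so the statistic
supports inference, not just ranking.

This package scores each tumor sample against a matched normal-tissue
reference profile with a modified Mahalanobis distance per gene set,
weights genes by their normal tissue-specificity, and calibrates the
distances against a column-permutation null via per-set gamma fits. The
output is three bounded score matrices per cohort (up-regulation only,
down-regulation only, and combined), with valid p-values and BH FDR values
for sample-level inference.

## The model

Inputs: `X` (n samples × p genes, linear-scale normalized expression,
zero-variance genes removed), a reference vector `t` (per-gene mean
expression in the matched normal tissue), a cross-tissue average `t_bar`,
and a gene set collection (membership only; no topology).

1. **Tissue specificity.** `t* = t / t_bar`, a linear fold-change. `t* > 1`
   marks genes enriched in the matched tissue.
2. **Signed deviations.** `Δ = X − t` (row-wise); `Δ⁺ = max(Δ, 0)`,
   `Δ⁻ = min(Δ, 0)`. Exactly `Δ⁺ + Δ⁻ = Δ` and `Δ⁺ ⊙ Δ⁻ = 0`.
3. **Weighted variances.** With `v_i` the unbiased sample variance of gene
   i computed on `X`: the positive direction uses `v_i · t*_i`, the
   negative direction `v_i / t*_i`; all covariances are set to zero. So
   up-regulation of a tissue-suppressed gene (`t* < 1`) and
   down-regulation of a tissue-enriched gene (`t* > 1`) are amplified —
   the deviations most characteristic of malignant divergence from the
   tissue of origin.
4. **Distances.** For set k with member columns J,
   `M⁺[i,k] = Σ_{j∈J} Δ⁺[i,j]² / (v_j t*_j)`, the diagonal-covariance
   closed form of the quadratic form `diag(Δ⁺_k Σ̂⁺_k⁻¹ Δ⁺_kᵀ)`; `M⁻`
   analogously; `M = M⁺ + M⁻`.
5. **Null.** Each gene column of `X` is independently permuted across
   samples (one permuted copy by default), destroying inter-gene
   correlation and sample-level shifts while preserving per-gene marginals
   — hence the same variances. Distances are recomputed on the permuted
   copy.
6. **Calibration.** A gamma distribution is fit by maximum likelihood to
   the nonzero null distances of every set and direction. Scores are the
   gamma CDF of the observed distances; `P = 1 − S` is a valid p-value
   under the permutation null; BH FDR is applied over a declared family.

## Tunable parameters

| parameter | default | why |
|---|---|---|
| `min_set_size` | 5 | below ~5 surviving members the quadratic form and the per-set gamma fit are statistically fragile; the originating method states no minimum, so this is this package's choice, configurable |
| `n_permutations` | 1 | the reference procedure uses a single permuted copy; more copies pool null distances per set before fitting, useful for small cohorts |
| `clamp_lo`, `clamp_hi` | 1e-4, 1e4 | bounds on `t*` (dimensionless fold-change) so one extreme ratio cannot dominate a set's distance; genes with `t_bar = 0` get `t* = 1` and are flagged rather than dropped — they still carry deviation signal, just no tissue weighting |
| `min_fit_n` (gamma) | 10 | fewer nonzero null distances than this yields `fit_ok = FALSE` and missing scores, never fabricated ones |
| FDR family | per-run | all samples × sets of a run, mirroring per-cohort analysis families; per-set and per-sample policies are available and change calls only through the adjustment, never through p-values |

Expression must be **linear-scale**. `t* = t/t_bar` is a linear
fold-change; feeding log-transformed values silently changes both the
weighting and the deviation semantics.

## Numerical choices

- **Column variances** are computed with a two-pass centered sum, and
  columns that are exactly constant are forced to exactly zero variance,
  so zero-variance removal never depends on floating-point cancellation.
- **Gamma MLE** solves the profile shape equation
  `log(a) − digamma(a) = log(mean x) − mean(log x)` by Newton iteration
  from a method-of-moments start (relative tolerance 1e-10, ≤ 100
  iterations); the rate is `shape / mean`. Constant input (zero variance
  of log-values) is a degenerate MLE and is reported as a failed fit.
- **Zero distances** map to score 0 and p-value 1 through the gamma CDF
  with no special-casing; a sample exactly equal to the reference scores
  0. Note the converse of the preparation step: a *whole cohort* equal to
  the reference is not scoreable, because every gene then has zero
  variance and is removed — the zero-deviation contract therefore applies
  per sample, not per cohort.
- **Missing values** in `X` are an error; imputation is the caller's job.
- Reference vectors are aligned to the gene axis **by name** when named;
  unnamed vectors must match the post-preparation gene axis exactly.

## The simulation study

`estimate_type1_error()` reproduces the built-in null experiment: a
10,000 × 100 matrix of i.i.d. Poisson(λ = 5) counts, library-size
normalized, scored for a single set of the first 20 genes with the
per-gene mean as reference and neutral tissue weights (the simulated world
has no tissue structure, so weighting must be a no-op). The reported
number is the fraction of the 10,000 sample-level p-values below α = 0.05.
`estimate_power()` plants a constant offset of `λ·δ` on the first 1,000
samples × 20 genes (added to counts, before normalization) for
δ ∈ {0.1, …, 2} and reports the rejection fraction among affected samples,
plus the unaffected samples' rate as a specificity check.

Design points the source text leaves open, decided here once:
library-size normalization is depth-matching to the mean total (CPM-like
up to a constant — the simplest scheme preserving within-sample
proportions); the reference is the per-gene mean of the normalized matrix
actually being scored (a self-contained run, including under
contamination); the power criterion uses raw p < α, matching the type I
error convention; the stated matrix size with an extra digit in the
source is read as 10,000 samples, the only orientation under which "the
first 1,000 samples" and a per-sample error rate are coherent.

## What the fixture generator emulates — and does not

`cmd_fixtures()` builds a toy cohort: gamma-distributed baseline gene
means, Poisson sampling around them, a matched-tissue reference equal to
the baseline and a cross-tissue average that is a noisy rescaling of it
(so `t*` varies around 1). One planted set is dysregulated: its genes are
tripled (plus a constant) in 60% of samples. The planted set is made twice
the size of the background sets — a deliberate construction choice so that
two properties hold at once: the planted set tops the mean-score ranking
(which needs a majority of affected samples), and affected samples clear
the permutation null decisively enough to produce FDR calls (which needs
enough signal genes to overcome the null's contamination by the shifted
values themselves).

What a green fixture test does **not** establish: the generator draws
independent Poisson genes, so it exercises calibration and signal
recovery, not robustness to inter-gene correlation, overdispersion, batch
effects, or normalization mismatch between tumor and reference data —
all of which real cohorts have. In particular, the permutation null
assumes uncorrelated expression; correlated gene sets in real data make
the null conservative or anticonservative depending on the direction of
correlation, and no test here measures that.

## Known limitations

- Bulk expression only; single-cell data would need a cell-type (not
  tissue-type) reference model and is out of scope.
- No bundled normal-tissue reference profiles; callers supply `t` and
  `t_bar` computed under a normalization pipeline equivalent to their
  tumor data's.
- Gene matching is exact string equality; identifier-namespace translation
  is the caller's job.
- Diagonal covariance only: inter-gene covariance within sets is
  deliberately ignored, matching the method; sets are unordered, with no
  use of pathway topology.
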