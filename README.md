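# tpac — tissue-adjusted single-sample gene set scoring

Single-sample gene set testing for bulk tumor RNA-seq, scored against a
normal-tissue reference. For each tumor `i` and gene set `k` the package
computes a squared modified Mahalanobis distance on the deviations of the
tumor from the matched normal tissue profile `t`, split by direction and
weighted by normal tissue-specificity `t* = t / t̄`:

```
Δ  = X − t            Δ⁺ = max(Δ, 0)     Δ⁻ = min(Δ, 0)
M⁺[i,k] = Σ_{j∈k} Δ⁺[i,j]² / (v_j · t*_j)
M⁻[i,k] = Σ_{j∈k} Δ⁻[i,j]² / (v_j / t*_j)
M = M⁺ + M⁻
```

with `v_j` the unbiased sample variance of gene `j`. Distances are
calibrated against a column-permutation null: each gene column is
independently shuffled across samples, distances recomputed, and a gamma
distribution fit by maximum likelihood to each set's nonzero null
distances. Scores are the gamma CDF of the observed distances, so
`S ∈ [0, 1]`, `P = 1 − S` is a valid p-value under the null of
uncorrelated expression with no sample-level shift, and BH FDR values
support inference on individual tumors. Three matrices are produced per
run: `S⁺` (up-regulation relative to normal tissue), `S⁻`
(down-regulation) and `S` (combined).

Intended users: cancer transcriptomics analysts who have a normalized
tumor cohort matrix (samples × genes, linear scale), per-gene normal
tissue reference means, and a GMT gene set collection, and who want
per-tumor pathway dysregulation calls rather than a cohort contrast.

## Worked example

The built-in fixture generator plants one dysregulated set (`SET_01`,
up-shifted in 60% of the 50 tumors):

```r
library(tpac)
fx  <- cmd_fixtures(tempfile("fix"), seed = 1)
res <- tpac(fx$X, fx$t, fx$t_bar, fx$collection, seed = 2)
res
#> Tissue-adjusted gene set scores
#>   samples: 50  sets: 10
#>   permutations: 1  seed: 2
#>   dropped genes: 0  dropped sets: 0  gamma fit failures: 0

round(head(colMeans(res$S), 4), 3)
#> SET_01 SET_02 SET_03 SET_04
#>  0.580  0.508  0.502  0.498

call_significant(res, q = 0.25)
#> Significance calls at FDR < 0.25 ( per-run family, total scores )
#>   significant: 21 of 500 (4.2%)
```

The planted set tops the mean-score ranking (0.580; the null sets hover
around 0.5, the mean of a calibrated score), and the FDR calls at
q = 0.25 concentrate in its affected samples. `scores_long(res)` exports
a tidy table (sample, set, direction, score, p, FDR, call) ready for
survival or stage models.

The built-in null simulation (10,000 samples × 100 genes of Poisson(5)
counts, library-size normalized, one 20-gene set) checks calibration:

```r
estimate_type1_error(null_sim_config(seed = 1))
#> Simulation result (seed 1)
#>  condition delta  rate     n
#>       null     0 0.054 10000
```

i.e. an empirical type I error of 0.054 at α = 0.05.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/tpac.R", package = "tpac"))')
Rscript $CLI fixtures --out fix/ --seed 1
Rscript $CLI score --expression fix/expression.tsv \
    --ref-tissue fix/reference_tissue.tsv \
    --ref-average fix/reference_average.tsv \
    --gmt fix/sets.gmt --out out/ --seed 1
Rscript $CLI simulate --mode null --seed 1 --out sim/
```

`score` writes nine TSVs (scores, p-values, FDR × three directions) and a
`provenance.json` recording dropped genes/sets, gamma parameters, seed
and config. Missing scores (failed gamma fits) are serialized as empty
fields.

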