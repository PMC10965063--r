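# insider

Interpretable covariate-aware sparse decomposition of bulk expression
matrices.

## The problem

Bulk RNA-seq cohorts are structured: every sample has a donor, a
phenotype, and a tissue, and expression variation is entangled across
all of them — including phenotype × tissue interactions (a disease may
shift expression differently in different brain regions) — on top of
sample-level noise. PCA-style factorizations mix these sources into the
same components; per-gene linear models separate them but learn nothing
shared across genes. This package is for analysts who want both: a
low-rank factorization whose components are *attached to covariates*.

## The model

A samples × genes matrix $Z$ is approximated as

$$\hat Z = (X_D D + X_P P + X_T T + X_W W + X_U U)\,V$$

where each $X_b$ is a covariate's indicator design (donor, phenotype,
tissue, phenotype × tissue interaction, optionally the per-sample
identity, or a continuous covariate column) and the factor matrices
$D, P, T, W, U$ share one $K \times M$ gene-loading matrix $V$ of
*metagenes*. Fitting minimizes the squared error over observed entries
plus a ridge penalty $\tfrac\lambda2\sum_b\|B_b\|_F^2$ on the factor
blocks and an elastic net
$\lambda_1(\tfrac{1-\alpha}2\|V\|_F^2+\alpha|V|_1)$ on the loadings, by
alternating block coordinate descent: closed-form masked ridge updates
per block, randomized coordinate descent with safe-by-verification
screening per loading column, relative-change stopping at $10^{-10}$.
Missing entries (NA) are handled exactly throughout, including whole
missing samples, whose expression is still predicted through their
covariates. Hyperparameters $\{K, \lambda, \alpha\}$ are selected on a
10% held-out-entry split (rank first, then the penalty pair).

See `vignettes/covariate-aware-decomposition.Rmd` for the full model
account, and `?insider`, `?tune_insider`, `?adjusted_expression` for
the API.

## Worked example

Simulate from the model's own design — 250 × 200, rank 5, two
categorical covariates plus a per-sample interaction, 30% of genes
silenced, Gaussian noise with sd 0.5 — then fit and interpret:

```r
library(insider)

sim <- simulate_insider_design(noise = 0.5, seed = 42)
fit <- insider(sim$Z, sim$design, K = 5, lambda = 0.1, seed = 1,
               max_iter = 400)
fit
#> <insider_fit> K = 5, lambda = 0.1, alpha = 0, 400 iteration(s)
#>   blocks: E, F, interaction
#>   250 samples x 200 genes, final objective 6317.15

rmse(reconstruct(fit), sim$truth)
#> [1] 0.1052
baseline_rmse(sim$truth, sim$Z, sim$Z$mask, sim$Z$mask)
#> [1] 3.2042
```

The fit recovers the noiseless signal to RMSE 0.105 where predicting
the grand mean would err by 3.20 — the factorization explains
essentially all structured variation, at roughly the noise floor
(noise sd 0.5 spread over a rank-5 approximation). Metagenes are then
ranked by how much they vary across a covariate's levels:

```r
metagene_variance_ranking(fit, "F")
#> # A tibble: 5 × 2
#>   metagene variance
#>      <int>    <dbl>
#> 1        5   21.8
#> 2        1    5.01
#> 3        4    4.57
#> 4        3    1.46
#> 5        2    0.984
```

Metagene 5 dominates the differences between the second covariate's
levels. Level contrasts and tail gene sets (for external enrichment
tools) come from the same fit:

```r
prof <- contrast_profile(fit, "F", "F1", "F2")
quantile_gene_sets(prof, q = 0.025)$upper |> head()
#> [1] "gene_66"  "gene_79"  "gene_123" "gene_124" "gene_133"
```

## Acceptance script

`scripts/acceptance.R` regenerates the package's validation benchmarks
from scratch: it simulates the four generative designs (the
factorization's own design with and without the interaction block, the
flattened trilinear design with held-out hyperparameter selection, the
multivariate linear design scored on a hold-out against per-gene ridge
and grand-mean baselines, and the 400 × 1000 missing-data design with
5% missing entries and a structured missing-sample pattern), fits the
model per each design's protocol, and writes the mean recovery RMSEs
over five seeds as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
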