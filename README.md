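# motifBLMM

Transcription factor (TF) binding motifs leave a quantitative footprint in
functional genomics data: the more strongly a motif scores in a gene's
promoter (or a linked enhancer), the more that gene's expression or
chromatin signal tracks the activity of the TFs binding that motif.
**motifBLMM** infers these per-condition *motif activities* from two
matrices — an expression/signal matrix `Y` (G genes × C conditions) and a
motif log-odds score matrix `M` (T motifs × G genes) — under a Bayesian
linear mixed model that, unlike classical ridge-based motif activity
analysis, allows conditions to be correlated (biological replicates, time
courses, related tissues) both in the signal and in the noise.

## The model

The doubly centered signal is modeled as a linear function of motif
scores,

```
Y = Mᵀ ω + ε,            ω ~ MN(0, σ² I_T, V_C),    vec(ε) ~ N(0, δ Σ_C ⊗ I_G)
```

so that marginally

```
vec(Y) ~ N(0, σ² V_C ⊗ Π_G + δ Σ_C ⊗ I_G),      Π_G = Mᵀ M .
```

`V_C` is the condition covariance of the activities and `Σ_C` the condition
covariance of the noise. The posterior mean of the activities is

```
vec(ω̂) = (V_C ⊗ M) [σ² V_C ⊗ Π_G + δ Σ_C ⊗ I_G]⁻¹ vec(Y) .
```

Restricting `V_C = σ² I_C` and `Σ_C = δ I_C` recovers ridge regression
with penalty `λ = δ/σ²`; leaving both *freeform* (any symmetric positive
definite matrix) gives the full mixed model, fit by maximum likelihood
over Cholesky factors with an analytic-gradient L-BFGS and an L2 penalty
on the off-diagonal of `Σ_C`. All linear algebra runs through a joint
diagonalization of the two Kronecker factors (never forming the GC × GC
covariance), so a fit at G ≈ 1000, C = 50 takes seconds. A corollary worth
knowing: when `Σ_C ∝ V_C` the condition covariance cancels from the
posterior and the mixed model collapses onto ridge — correlated noise
erases the advantage of modeling correlated conditions.

The package also ships the full simulation benchmark for comparing the
two model assumptions: condition covariance generators (independent,
all-positive, many replicate blocks, two blocks), unstructured Wishart
and V-structured noise, calibration of σ² by bisection so the motif
component explains a target fraction (default 0.2) of the variance,
recovery metrics, k-fold cross-validation over genes, motif-score
permutation nulls, group-difference motif ranking and IQR-based outlier
motif selection.

## Worked example

Simulate a dataset with two fully correlated replicate groups (C = 10
conditions, 978 genes, 623 motifs, motifs explaining 20% of the
variance), then fit both model assumptions and score recovery of the
simulated activities:

```r
library(motifBLMM)

cfg <- simulation_config(G = 978, C = 10, T_motifs = 623,
                         v_kind = "blocks_two", noise_rho = 0, seed = 1)
ds <- simulate_dataset(cfg)
ds
#> simulated_dataset: G=978 genes, C=10 conditions, T=623 motifs
#>   V: blocks_two, noise rho=0.00, sigma2=4.013e-05, empirical signal fraction=0.202

fit_b <- fit_freeform(ds$Y, ds$M, max_iter = 500)   # mixed model
fit_r <- fit_ridge(ds$Y, ds$M)                      # identity covariances

recovery_scores(ds$omega_true, fit_b$omega_hat)
#> recovery: pearson=0.4831 spearman=0.4801 mse=3.128e-05
recovery_scores(ds$omega_true, fit_r$omega_hat)
#> recovery: pearson=0.2610 spearman=0.2572 mse=3.792e-05
```

With correlated conditions and unstructured noise the mixed model
recovers the true activities substantially better (pooled Pearson 0.48
vs 0.26 here); with noise structured like `V_C` (`noise_rho = 0.7`) the
two become indistinguishable — the cancellation above. On real data,
where the truth is unknown, use cross-validated prediction instead:

```r
cv <- kfold_crossval(ds$Y, ds$M, k = 10, model = "ridge", seed = 1)
round(c(train = mean(cv$train_pearson), test = mean(cv$test_pearson)), 3)
#> train  test
#> 0.706 0.116
```

(test-set correlation is bounded by the 20% signal fraction;
`permutation_null()` shows it collapses to ≈ 0 when the gene-to-score
link is destroyed). `run_benchmark()` sweeps the full grid of condition
counts, covariance regimes and noise structuredness in one call.

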