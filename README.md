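# latentlink

Side-by-side canonical correlation analysis (CCA) and partial least squares
correlation (PLS) for two participant-by-variable blocks — typically a brain
matrix **X** (e.g., 68 regional cortical-thickness estimates) and a behavior
matrix **Y** (e.g., 11 checklist subscale scores) — together with the
resampling battery needed to say whether the latent variables they extract
would generalize: permutation significance, split-half reproducibility,
train-test reliability, bootstrap stability, and between-method similarity.

It is written for researchers running brain-behavior association analyses on
large cohort data, and for anyone who wants to study *when* such analyses
generalize: a built-in synthetic-data generator plants known latent structure
under controllable pathology (zero-inflated ordinal scores, skew,
within-block correlation, site/scanner/age/sex/head-size nuisance), so every
stage can be validated by parameter recovery without access to restricted
data.

## The model

After residualizing nuisance covariates from both blocks and Z-transforming
(optionally on average ranks, giving Spearman products), the methods
decompose a cross-product matrix by SVD:

- **PLS** decomposes the cross-block correlation matrix
  `R_XY = U S V'`. The singular vectors are the loadings; each singular
  value is the covariance captured by one latent variable (LV) pair.
- **CCA** decomposes the *adjusted* matrix
  `Omega = R_XX^(-1/2) R_XY R_YY^(-1/2) = U S V'`, normalizing away the
  within-block correlations. The singular values are canonical
  correlations, and the reported loadings are the reweighted canonical
  weights `Wx = R_XX^(-1/2) U`, `Wy = R_YY^(-1/2) V`.

Generalizability of each LV is then quantified by:

- a **sum-of-squares permutation test** on the eigenspectrum
  (`T_k = sum_{i>=k} s_i^2` against a row-shuffled null);
- **split-half** resampling: correlation of loadings estimated in two
  independent halves, summarized by a Z-test (mean/SD > 1.96);
- **train-test** resampling: singular values of the held-out 20% predicted
  by projecting the training singular vectors onto the test cross-product
  (`s_pred = diag(U' C_test V)`);
- **bootstrap** resampling: percentile 95% confidence intervals for every
  loading element, with sign-flip correction against the full-sample model;
- **between-method correlation**: full cross-LV Pearson correlations of the
  CCA and PLS loadings.

## Worked example

```r
library(latentlink)

# a 2,000-participant cohort, 68 brain x 11 zero-inflated ordinal behavior
# columns, one planted LV with cross-block correlation 0.3
study <- generate_study(synth_config(
  2000, n_latent = 1, effect_sizes = 0.3,
  behavior_family = "ordinal_zero_inflated", zero_inflation = 0.4, seed = 1))

cfg <- analysis_config(correlation_type = "spearman",
                       n_perm = 1000, n_splithalf = 300,
                       n_traintest = 300, n_boot = 200, seed = 1)
report <- run_pipeline(cfg, study$brain, study$behavior, study$covariates)
report
#> <latentlink_report: n = 2000, methods = cca + pls, spearman correlations>
#>   CCA LV1: s = 0.331 (25.4% of squared spectrum), permutation p = 0.004995
#>   PLS LV1: s = 0.398 (38.8% of squared spectrum), permutation p = 0.2128
```

The planted LV is real, so the numbers show the machinery working on hard
data: the PLS LV1 singular value (0.398, a covariance) is larger than the
CCA one (0.331, a canonical correlation on whitened blocks), while the
zero-inflated ordinal marginals (mean zero proportion 0.40, mean skewness
2.04 in `report$diagnostics$behavior`) keep split-half and train-test
Z-scores modest — the skew-degrades-generalizability behavior that motivates
running the whole battery rather than trusting a single fit.

```r
report$splithalf$cca$z_U[1, ]
#>   lv      mean         sd        z significant
#> 1  1 0.3122087 0.09075904 3.439973        TRUE
```

A thin command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "latentlink.R", package = "latentlink"))')
Rscript $CLI simulate --config sim.yaml --out data/
Rscript $CLI all --brain data/brain.tsv --behavior data/behavior.tsv \
    --covariates data/covariates.tsv --out results/ --seed 1
```

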