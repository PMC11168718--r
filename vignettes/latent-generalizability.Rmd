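---
title: "Methods: two-block latent models and their generalizability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-block latent models and their generalizability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentlink)
```

## The problem

Multivariate brain-behavior analyses pair a brain matrix **X** (n
participants by p regional measures, e.g. cortical thickness) with a
behavior matrix **Y** (n by q subscale or task scores) and extract latent
variable (LV) pairs — weighted composites of each block with maximal
association. Two closely related methods dominate: CCA maximizes the
*correlation* of the composites, PLS correlation maximizes their
*covariance*. Both are exact SVD problems, and both can produce LVs that
are statistically significant in one sample yet fail to reappear in
another. This package implements the two methods on a shared preprocessing
path and, around them, the resampling battery that distinguishes a
generalizable LV from a sample artifact.

## Model and preprocessing

Both blocks are first residualized: each column is regressed by OLS on an
intercept, continuous covariates (age in months, total head size), and
dummy-coded categorical covariates (sex, site, scanner model), keeping the
residuals, which are then Z-transformed (n−1 denominator). Covariate
columns that are exact linear combinations of others — scanner model is
spanned by site whenever each site uses a single scanner — do not change
the projection; `residualize()` drops them and records their names (an
error is available via `strict = TRUE` for genuinely unintended
collinearity).

On the default Spearman path, residuals are then replaced by their average
ranks and Z-transformed again. The order — residualize, then rank, then
Z — keeps the covariate adjustment a plain linear regression on the
observed scores and makes every Pearson product of the transformed
matrices an exact Spearman correlation of the residuals; ranking before
residualization is available by composing the exported functions
differently, but is not the default because the Z-transformed residual is
the quantity the downstream algebra assumes. Skewed, zero-inflated scores
are the norm for checklist data, and rank-based correlation is the
standard guard against them.

From the transformed blocks, `build_cross_products()` forms

- `R_XY` (p × q), `R_XX`, `R_YY`: correlation matrices of one shared type;
- `Omega = R_XX^(−1/2) R_XY R_YY^(−1/2)`: the adjusted cross-product.

`fit_pls()` takes the SVD of `R_XY`; its singular vectors are the loadings.
`fit_cca()` takes the SVD of `Omega`; the singular values are canonical
correlations and the loadings reported are the reweighted weights
`Wx = R_XX^(−1/2) U`, `Wy = R_YY^(−1/2) V`, which satisfy
`Wx' R_XX Wx = I` — the defining normalization of canonical weights. This
reweighting is the standard generalized-SVD reading of CCA; structure
coefficients (`R_XX Wx`, the correlations of variables with latent scores)
are computed as a secondary view. Exactly `min(p, q)` LVs are returned.
Latent scores are `X U` / `Y V` (PLS) or `X Wx` / `Y Wy` (CCA); on the
analysis-transformed data the CCA score pair for LV i correlates at
exactly `s_i`, a property the test suite asserts to 1e-8.

The within-block matrices use the *same* correlation type as `R_XY`:
`Omega` is built from all three, and mixing types would make the canonical
bound `s_i ≤ 1` fail.

## Significance, reproducibility, reliability, stability

**Permutation (significance).** Rows of the transformed brain block are
shuffled, breaking the cross-block link while leaving both within-block
structures untouched; the statistic is the trailing sum of squared singular
values `T_k = Σ_{i≥k} s_i²`, compared at each k (LV₁–LV_L for LV₁,
LV₂–LV_L for LV₂, ...). This spectrum-wide statistic is deliberately more
stringent than testing each singular value alone. Because row permutation
leaves `R_XX` invariant, only `R_XY` is recomputed per permutation — a
substantial speedup at no approximation. P-values use the add-one
estimator `(b + 1)/(B + 1)`, so they can never be zero and are slightly
conservative. The permutation shuffles *residualized* rows; residuals are
exchangeable under the null and re-residualizing per permutation would
change nothing in the linear model used here.

**Split-half (reproducibility).** Each iteration splits the cohort into
halves (extra participant to the first half when n is odd), residualizes
and transforms *within* each half, fits each half, and records the Pearson
correlation between the two halves' loadings per LV and block. Each half
is first sign-aligned to the full-sample model: the SVD's sign is
arbitrary per LV, and without alignment reflections bimodalize the r
distribution and force the Z toward zero. Because a half could also
reproduce the reference with *inverted* sign (a genuine failure mode that
alignment would mask into r ≈ +1 vs r ≈ −1), `alignment = "none"` is
provided for the literal, uncorrected reading. LVs are matched across
halves by index only; axis swapping between nearly tied singular values is
possible and intentionally not corrected.

**Train-test (reliability).** An 80/20 split; each side is residualized
and transformed separately; the training SVD's singular vectors are
projected onto the test side's cross-product matrix:
`s_pred = diag(U' C_test V)` with `C_test = R_XY` (PLS) or `Omega` (CCA) —
for CCA the *generalized singular vectors* are projected, because they are
the vectors whose projection reproduces S on the training side. That
identity (`diag(U' C_train V) = S`, exact to 1e-12) is asserted on every
fixture, which guarantees the reliability signal is entirely
out-of-sample. The test split must satisfy `n_test ≥ q + 2`.

**Bootstrap (stability).** Participants are resampled with replacement to
the original n, keeping **X** and **Y** rows paired; each refit is
sign-aligned to the full-sample model; every loading element gets a
percentile interval (plain percentile, not BCa — the simplest estimator
matching a "95% bootstrapped confidence interval") and a stability flag
when the interval excludes zero. Degenerate resamples (a constant column)
are redrawn and counted.

All resampling distributions are summarized by the Z-test: mean divided by
SD, significant when |z| > 1.96 (two-sided p < .05 under normality).

## The synthetic generator

`generate_study()` builds both blocks from shared latent scores:

    X = Σ_l d_l z_l a_l' + M Γx + Ex,   Y likewise with b_l and Ey,

with `z_l` i.i.d. standard normal, `a_l`/`b_l` random orthonormal columns,
and `d_l = sqrt(r_l / (1 − r_l))` calibrated so that
`cor(X a_l, Y b_l) = r_l` exactly in population when the noise is
uncorrelated — the Monte-Carlo tests verify this to ±0.03 at n = 20,000.
Noise is equicorrelated within each block (one `rho` per block, unit
column variance). Covariates (uniform age 107–133 months, binary sex,
21 sites nested in 5 scanner models, Gaussian head size) enter as linear
effects with random slopes of SD `covariate_effect_scale`; because
generation is linear, linear residualization removes them exactly, which
the tests check to 1e-10.

Checklist-like behavior scores are produced by a rank-preserving quantile
map: values below the `zero_inflation` quantile become 0; the rest are
binned into `{1..max_score}` against a geometrically decaying target
marginal (decay 0.3), reproducing the right skew of summed ordinal
ratings without fitting any real data — no public per-subscale marginals
exist, so the skew family is a stand-in, not a fit. The map is
deterministic given the column (ties share a bin); the `seed` argument is
reserved for stochastic tie-breaking and currently unused. Defaults
(n_brain = 68, n_behavior = 11, zero_inflation = 0.4, max_score = 20,
within-block rho 0.3, covariate slope SD 0.1, weak-to-moderate effects)
mirror a large multi-site pediatric cohort with checklist outcomes.

What the generator does *not* emulate: regional measurement error with
spatial structure, family/sibling clustering, longitudinal waves, missing
data, and site-by-covariate interactions. Passing recovery tests therefore
show the machinery is correct and calibrated under linear latent structure
with realistic marginals — not that any particular real dataset satisfies
those assumptions.

## Numerical choices

- **Eigenvalue floor**: `inv_sqrt_psd()` zeroes eigenvalues below
  `eps = 1e-10` times the largest (pseudo-inverse square root). In the
  intended regime n ≫ p the within-block matrices are well-conditioned and
  the floor only guards degenerate resamples. Negative eigenvalues beyond
  tolerance are an error, not silently clipped.
- **Sign convention**: each LV is oriented so the largest-magnitude
  behavior loading is positive — the direction of an LV is only
  interpretable relatively, and a fixed convention makes runs reproducible
  across LAPACK builds.
- **Ties**: average ranks (the standard Spearman convention, and the one
  that makes Pearson-on-ranks exactly Spearman).
- **Z-transform**: n−1 denominator throughout; scale cancels in every
  correlation, but one convention makes the latent-score identities
  exactly testable.
- **Near-equal singular values**: no special handling; a message flags
  gaps < 1e-6 (CCA), since LV order then follows the decomposition's
  arbitrary tie-break.
- **Seeding**: one master seed spawns named substreams (covariates,
  loadings, latents, noise, slopes; permutation, split-half, train-test,
  bootstrap), so components are reproducible independently and enlarging
  one stage never perturbs another.

## Design choices where the design was open

- **Pearson vs cosine for between-method similarity.** Between-method
  similarity is reported as Pearson correlations of loadings. One caveat
  found while validating: for *equicorrelated* noise the CCA-vs-PLS
  difference concentrates along the constant vector, which Pearson's
  centering removes, so the property test for "similarity decreases as
  within-block correlation grows" measures the uncentered cosine of the
  LV₁ loadings instead.
- **Permutation scope.** The test permutes residualized rows once;
  alternatives (re-residualizing per permutation, permuting raw rows) are
  equivalent under the linear model and substantially slower.
- **CCA loadings.** Reweighted weights `Wx`, `Wy` are primary; structure
  coefficients are available on the model object.
- **Split-half alignment.** Reference-alignment by default, `"none"`
  provided; split-half null distributions center at 0 either way.

## Problem sizes

The reference workflow for a real cohort is 10,000 permutation /
split-half / train-test iterations and 1,000 bootstrap samples. The test
suite and the acceptance script run the same code at desk scale — e.g.,
n = 2,000 cohorts with 300–500 resampling iterations, 200 null cohorts of
n = 300 at B = 500 for type-I calibration, and n = 200,000 only for the
near-identity population checks where sampling noise must be negligible.
These sizes were chosen so each check's Monte-Carlo error is small
relative to the margin it asserts.

## Known limitations

- Only by-index LV matching across resamples; heavily tied spectra make
  per-LV summaries hard to interpret (flagged, not fixed).
- Linear residualization only; no site harmonization beyond it, no
  imputation (rows must be complete).
- Classical CCA/PLS only — no sparse, kernel or regularized variants, and
  no dimensionality-reduction preprocessing, which would change the
  maximization problem the two methods are being compared on.
- Resampling does not stratify by site or family.
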