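# Small fixtures shared across test files. Everything is generated in code;
# sizes are desk-scale so the whole suite stays fast.

# Standardized Gaussian block pair with no planted structure.
null_blocks <- function(n = 100, p = 6, q = 4, seed = 42) {
  set.seed(seed)
  list(X = scale(matrix(rnorm(n * p), n, p)),
       Y = scale(matrix(rnorm(n * q), n, q)))
}

# Cross-product set from independent Gaussian data (Pearson path).
null_cp <- function(n = 100, p = 6, q = 4, seed = 42, eps = 1e-10) {
  b <- null_blocks(n, p, q, seed)
  build_cross_products(b$X, b$Y, type = "pearson", eps = eps)
}

# Hand-built cross-product set with identity within-block correlations, so
# CCA and PLS coincide exactly.
identity_cp <- function(R_XY) {
  p <- nrow(R_XY); q <- ncol(R_XY)
  structure(
    list(R_XY = R_XY, R_XX = diag(p), R_YY = diag(q), Omega = R_XY,
         correlation_type = "pearson", ridge_eps = 1e-10, n = 1000L,
         inv_sqrt_xx = diag(p), inv_sqrt_yy = diag(q)),
    class = "cross_product_set")
}

# Planted single-LV study used by several recovery tests.
recovery_study <- function(n = 400, effect = 0.6, seed = 7, p = 10, q = 5,
                           family = "gaussian", zero_inflation = 0.4) {
  generate_study(synth_config(
    n, n_brain = p, n_behavior = q, n_latent = 1, effect_sizes = effect,
    behavior_family = family, zero_inflation = zero_inflation, seed = seed))
}
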