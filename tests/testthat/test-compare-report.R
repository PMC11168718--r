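test_that("between-method correlations are self-consistent and sign-equivariant", {
  cp <- null_cp(300, 8, 5, seed = 50)
  pls <- fit_pls(cp)
  self <- between_method_correlation(pls, pls)
  expect_equal(unname(diag(self$r_U_cross)), rep(1, 5), tolerance = 1e-12)
  expect_true(all(abs(self$r_U_cross) <= 1 + 1e-12))

  # a joint sign flip of one LV flips one row, magnitudes unchanged
  flipped <- pls
  flipped$U[, 2] <- -flipped$U[, 2]
  flipped$V[, 2] <- -flipped$V[, 2]
  cmpf <- between_method_correlation(flipped, pls)
  expect_equal(abs(cmpf$r_U_cross), abs(self$r_U_cross), tolerance = 1e-12)
  expect_equal(unname(cmpf$r_U_cross[2, 2]), -1, tolerance = 1e-12)

  other <- fit_pls(null_cp(300, 6, 5, seed = 51))
  expect_error(between_method_correlation(pls, other), "mismatch")
})

test_that("CCA-PLS loading similarity is near-perfect without within-block correlation", {
  # weak effects keep the signal-induced within-block correlation (and the
  # per-column variance heterogeneity that separates R_XY from Omega at the
  # population level) small; n is large enough to resolve the spectrum gaps
  st <- generate_study(synth_config(
    200000, n_brain = 10, n_behavior = 4, n_latent = 4,
    effect_sizes = c(0.30, 0.22, 0.14, 0.06),
    within_block_rho_brain = 0, within_block_rho_behavior = 0,
    behavior_family = "gaussian", covariate_effect_scale = 0, seed = 52))
  cp <- build_cross_products(scale(st$brain$values), scale(st$behavior$values),
                             type = "pearson")
  cmp <- between_method_correlation(fit_cca(cp), fit_pls(cp))
  expect_true(all(abs(diag(cmp$r_U_cross)) > 0.99))
  expect_true(all(abs(diag(cmp$r_V_cross)) > 0.99))
})

test_that("LV1 between-method similarity degrades as within-block correlation grows", {
  # measured as the cosine between the LV1 loading vectors: the whitening
  # correction for equicorrelated noise lies largely along the constant
  # vector, which mean-centering would discard
  cosim <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  sim1 <- vapply(c(0, 0.35, 0.7), function(rho) {
    st <- generate_study(synth_config(
      4000, n_brain = 10, n_behavior = 6, n_latent = 1, effect_sizes = 0.4,
      within_block_rho_brain = rho, within_block_rho_behavior = rho,
      behavior_family = "gaussian", covariate_effect_scale = 0, seed = 53))
    cp <- build_cross_products(scale(st$brain$values),
                               scale(st$behavior$values), type = "pearson")
    cca <- fit_cca(cp); pls <- fit_pls(cp)
    cosim(cca$Wx[, 1], pls$U[, 1])
  }, numeric(1))
  expect_true(all(diff(sim1) <= 0))
})

test_that("pca_variance_profile counts components against an eigen oracle", {
  expect_equal(pca_variance_profile(diag(10), threshold = 0.9), 9)
  # one dominant component: equicorrelation 0.95 puts 96% on the first axis
  R <- matrix(0.95, 5, 5); diag(R) <- 1
  expect_equal(pca_variance_profile(R, threshold = 0.9), 1)

  set.seed(54)
  X <- matrix(rnorm(600), 100, 6) %*% matrix(rnorm(36), 6, 6)
  R6 <- cor(X)
  ev <- sort(eigen(R6, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  oracle <- which(cumsum(ev) / sum(ev) >= 0.9)[1]
  expect_equal(pca_variance_profile(R6, threshold = 0.9), oracle)
  expect_equal(pca_variance_profile(X, threshold = 0.9), oracle)
  expect_error(pca_variance_profile(diag(3), threshold = 0), "threshold")
})

test_that("distribution diagnostics report skew, zeros and variance structure", {
  m <- cbind(sym = rep(c(-2, -1, 1, 2), 25),
             zeros = c(rep(0, 75), rep(5, 25)),
             skewed = rexp(100))
  d <- distribution_diagnostics(m)
  expect_equal(d$columns$skewness[1], 0, tolerance = 1e-12)
  expect_equal(d$columns$zero_proportion[2], 0.75)
  expect_gt(d$columns$skewness[3], 0)
  expect_true(d$pca_components_for_threshold >= 1 &&
              d$pca_components_for_threshold <= 3)

  # constant columns are flagged, not fatal
  d2 <- distribution_diagnostics(cbind(const = rep(1, 50), x = rnorm(50),
                                       y = rnorm(50)))
  expect_true(d2$columns$constant[1])
  expect_true(is.na(d2$columns$skewness[1]))

  st <- generate_study(synth_config(10000, zero_inflation = 0.5, seed = 55))
  d3 <- distribution_diagnostics(st$behavior)
  expect_lt(abs(mean(d3$columns$zero_proportion) - 0.5), 0.02)
})

test_that("the pipeline is deterministic and honors its configuration", {
  st <- recovery_study(n = 250, effect = 0.6, seed = 56)
  cfg <- analysis_config(n_perm = 60, n_splithalf = 30, n_traintest = 30,
                         n_boot = 30, seed = 5)
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  r1 <- run_pipeline(cfg, st$brain, st$behavior, st$covariates, out_dir = d1)
  r2 <- run_pipeline(cfg, st$brain, st$behavior, st$covariates, out_dir = d2)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  expect_identical(r1$singular_values, r2$singular_values)
  expect_named(r1$models, c("cca", "pls"))
  expect_s3_class(r1$comparison, "method_comparison")
  expect_true(file.exists(file.path(d1, "pls_bootstrap_ci.tsv")))

  # PLS-only configuration: no CCA sections, no comparison, no error
  cfg_pls <- analysis_config(methods = "pls", n_perm = 20, n_splithalf = 0,
                             n_traintest = 0, n_boot = 0, seed = 5)
  rp <- run_pipeline(cfg_pls, st$brain, st$behavior, st$covariates)
  expect_named(rp$models, "pls")
  expect_null(rp$comparison)
  expect_null(rp$splithalf)
})

test_that("a full-sample subset rerun reproduces the main run exactly", {
  st <- recovery_study(n = 200, effect = 0.5, seed = 57)
  cfg <- analysis_config(n_perm = 30, n_splithalf = 15, n_traintest = 15,
                         n_boot = 15, seed = 8)
  cfg_sub <- cfg
  cfg_sub$subset <- seq_len(200)
  r1 <- run_pipeline(cfg, st$brain, st$behavior, st$covariates)
  r2 <- run_pipeline(cfg_sub, st$brain, st$behavior, st$covariates)
  expect_equal(r1$singular_values, r2$singular_values)
  expect_equal(r1$splithalf$pls$r_U, r2$splithalf$pls$r_U)

  # predicate subsets select rows through the covariate table
  cfg_f <- analysis_config(methods = "pls", n_perm = 0, n_splithalf = 0,
                           n_traintest = 0, n_boot = 0, seed = 8,
                           subset = function(cov) cov$sex == "F")
  rf <- run_pipeline(cfg_f, st$brain, st$behavior, st$covariates)
  expect_equal(rf$n, sum(st$covariates$sex == "F"))
})
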