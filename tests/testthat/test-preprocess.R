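test_that("residualization centers, projects out designs, and Z-transforms", {
  # intercept-only: residuals of [1,2,3] are [-1,0,1] before Z-scaling
  b <- data_block(matrix(c(1, 2, 3), 3, 1))
  r <- residualize(b, covariates = NULL)
  expect_equal(r$values[, 1], c(-1, 0, 1) / sd(c(-1, 0, 1)),
               ignore_attr = TRUE)

  # binary covariate, hand OLS: group means 1.5 and 5
  b2 <- data_block(matrix(c(1, 2, 4, 6), 4, 1))
  cov2 <- data.frame(g = factor(c(0, 0, 1, 1)))
  r2 <- residualize(b2, cov2)
  expected <- c(-0.5, 0.5, -1, 1)
  expect_equal(r2$values[, 1], expected / sd(expected), ignore_attr = TRUE)

  # every residual column has mean 0, SD 1 (n-1) and is orthogonal to the
  # design
  set.seed(1)
  b3 <- data_block(matrix(rnorm(200), 50, 4))
  cov3 <- data.frame(age = rnorm(50), sex = factor(rep(c("F", "M"), 25)),
                     site = factor(sample(letters[1:3], 50, TRUE)))
  r3 <- residualize(b3, cov3)
  expect_equal(colMeans(r3$values), rep(0, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(apply(r3$values, 2, sd), rep(1, 4), tolerance = 1e-8,
               ignore_attr = TRUE)
  design <- model.matrix(~ ., data = cov3)[, -1]
  expect_lt(max(abs(cor(r3$values, design))), 1e-10)
})

test_that("residualization errors and aliasing behave as documented", {
  b <- data_block(matrix(rnorm(40), 10, 4))
  cov <- data.frame(participant_id = sprintf("x%02d", 1:10), age = rnorm(10))
  expect_error(residualize(b, cov), "IDs")

  # exactly collinear continuous covariates: dropped by default with the
  # aliased column recorded, error under strict = TRUE
  cov2 <- data.frame(a = rnorm(10))
  cov2$b <- 2 * cov2$a
  r <- residualize(b, cov2)
  expect_equal(r$aliased_columns, "b")
  expect_error(residualize(b, cov2, strict = TRUE), "collinear.*b")
})

test_that("residualized correlations are invariant to affine covariate rescaling", {
  set.seed(4)
  X <- data_block(matrix(rnorm(300), 50, 6))
  cov <- data.frame(age = runif(50, 100, 140), head = rnorm(50, 1400, 100))
  cov_scaled <- data.frame(age = (cov$age - 120) / 7, head = cov$head / 1000)
  r1 <- residualize(X, cov)$values
  r2 <- residualize(X, cov_scaled)$values
  expect_equal(cor(r1), cor(r2), tolerance = 1e-10)
})

test_that("rank standardization follows the average-rank tie convention", {
  z <- function(v) (v - mean(v)) / sd(v)
  expect_equal(rank_standardize(matrix(c(10, 20, 30)))$values[, 1],
               z(c(1, 2, 3)), ignore_attr = TRUE)
  expect_equal(rank_standardize(matrix(c(5, 5, 7)))$values[, 1],
               z(c(1.5, 1.5, 3)), ignore_attr = TRUE)
  # monotone invariance
  set.seed(5)
  x <- matrix(rnorm(40), 40, 1)
  expect_equal(rank_standardize(x)$values, rank_standardize(exp(x))$values,
               ignore_attr = TRUE)
  expect_error(rank_standardize(matrix(rep(1, 5))), "constant")
})

test_that("correlation matrices match their definitions", {
  expect_equal(correlation_matrix(matrix(c(1, 2, 3)), matrix(c(1, 4, 9)),
                                  type = "spearman")[1, 1], 1)
  expect_equal(correlation_matrix(matrix(c(1, 2, 3)), matrix(c(3, 2, 1)),
                                  type = "pearson")[1, 1], -1)
  expect_equal(correlation_matrix(matrix(c(1, 2, 3)), matrix(c(3, 2, 1)),
                                  type = "spearman")[1, 1], -1)

  # Spearman with ties equals Pearson on average ranks, exactly
  x <- matrix(c(1, 2, 2, 4)); y <- matrix(c(1, 3, 2, 4))
  expect_equal(correlation_matrix(x, y, type = "spearman")[1, 1],
               cor(rank(x), rank(y)))
  set.seed(6)
  A <- matrix(sample(1:4, 60, TRUE), 20, 3)
  B <- matrix(rnorm(40), 20, 2)
  ranked <- function(m) apply(m, 2, rank, ties.method = "average")
  expect_equal(correlation_matrix(A, B, type = "spearman"),
               cor(ranked(A), ranked(B)), tolerance = 1e-12)

  expect_error(correlation_matrix(matrix(1, 5, 1), matrix(rnorm(5))),
               "constant")
  expect_error(correlation_matrix(matrix(1:2), matrix(1:2)), "3 rows")
})

test_that("inv_sqrt_psd inverts square roots with an eigenvalue floor", {
  expect_equal(inv_sqrt_psd(diag(3)), diag(3))
  expect_equal(inv_sqrt_psd(diag(c(4, 9))), diag(c(1 / 2, 1 / 3)))
  set.seed(7)
  A <- crossprod(matrix(rnorm(9), 3, 3)) + diag(3)
  R <- inv_sqrt_psd(A)
  expect_lt(max(abs(R %*% A %*% R - diag(3))), 1e-10)
  expect_equal(R, t(R))
  # rank-deficient: pseudo-inverse square root
  P <- tcrossprod(c(1, 0)) * 4
  Rp <- inv_sqrt_psd(P)
  expect_equal(Rp, tcrossprod(c(1, 0)) / 2, tolerance = 1e-12)
  expect_error(inv_sqrt_psd(diag(c(1, -1))), "semi-definite")
  expect_error(inv_sqrt_psd(matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")
})

test_that("cross-product sets satisfy shape and adjustment contracts", {
  b <- null_blocks(200, 68, 11, seed = 8)
  cp <- build_cross_products(b$X, b$Y, type = "pearson")
  expect_equal(dim(cp$R_XY), c(68, 11))
  expect_equal(dim(cp$Omega), c(68, 11))
  expect_equal(diag(cp$R_XX), rep(1, 68), ignore_attr = TRUE)
  expect_true(all(abs(cp$R_XY) <= 1 + 1e-12))
  expect_equal(cp$Omega, cp$inv_sqrt_xx %*% cp$R_XY %*% cp$inv_sqrt_yy)
  # canonical-correlation bound on Omega's spectrum
  expect_lte(max(svd(cp$Omega)$d), 1 + 1e-8)

  # exactly-identity within-block correlations leave R_XY unadjusted
  cpi <- identity_cp(matrix(c(0.4, 0.1, 0.2, 0.3), 2, 2))
  expect_equal(cpi$Omega, cpi$R_XY)

  # as within-block correlation vanishes (large n, rho = 0), Omega -> R_XY
  big <- null_blocks(20000, 6, 4, seed = 9)
  cpb <- build_cross_products(big$X, big$Y, type = "pearson")
  expect_lt(max(abs(cpb$Omega - cpb$R_XY)), 0.02)
})

test_that("prepare_block composes residualization and ranking per path", {
  st <- recovery_study(n = 80, seed = 10)
  sp <- prepare_block(st$brain, st$covariates, "spearman")
  expect_equal(sp$transform, "rank_then_z")
  pe <- prepare_block(st$brain, st$covariates, "pearson")
  expect_equal(pe$transform, "z_only")
  # Pearson products of the Spearman path equal Spearman correlations of
  # the residuals
  expect_equal(cor(sp$values), cor(pe$values, method = "spearman"),
               tolerance = 1e-12)
})
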