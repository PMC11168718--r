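test_that("sign alignment flips jointly and preserves magnitudes", {
  set.seed(40)
  U <- matrix(rnorm(12), 4, 3); V <- matrix(rnorm(9), 3, 3)
  # aligning to itself changes nothing
  a <- sign_align(U, V, U, V)
  expect_identical(a$U, U)
  expect_false(any(a$flipped))
  # a jointly negated column is restored
  U2 <- U; V2 <- V
  U2[, 2] <- -U2[, 2]; V2[, 2] <- -V2[, 2]
  a2 <- sign_align(U2, V2, U, V)
  expect_equal(a2$U, U)
  expect_equal(a2$V, V)
  expect_equal(a2$flipped, c(FALSE, TRUE, FALSE))
  # |corr| to the reference is sign-invariant
  for (l in 1:3) {
    expect_equal(abs(cor(a2$U[, l], U[, l])), abs(cor(U2[, l], U[, l])))
  }
  expect_error(sign_align(U[, 1:2], V, U, V), "shape")
})

test_that("predicted singular values are exact on the training side", {
  cp <- null_cp(300, 8, 5, seed = 41)
  for (m in list(fit_pls(cp), fit_cca(cp))) {
    C <- if (m$method == "cca") cp$Omega else cp$R_XY
    expect_equal(predict_singular_values(m$U, m$V, C), unname(m$S),
                 tolerance = 1e-12)
    expect_equal(predict_singular_values(m$U, m$V, C * 0), rep(0, m$L))
  }
  # construction oracle: C = U diag(d) V' with random orthonormal U, V
  set.seed(41)
  U <- qr.Q(qr(matrix(rnorm(48), 8, 6)))[, 1:4]
  V <- qr.Q(qr(matrix(rnorm(20), 5, 4)))
  d <- c(0.9, 0.5, 0.2, 0.1)
  expect_equal(predict_singular_values(U, V, U %*% diag(d) %*% t(V)), d,
               tolerance = 1e-12)
  expect_error(predict_singular_values(U[1:3, ], V, diag(5)), "mismatch")
})

test_that("split-half recovers a planted LV and is deterministic", {
  st <- recovery_study(n = 600, effect = 0.6, seed = 42)
  sh <- split_half(st$brain, st$behavior, st$covariates, method = "pls",
                   iters = 60, seed = 9, correlation_type = "spearman")
  expect_true(all(abs(sh$r_U) <= 1 + 1e-12))
  expect_equal(nrow(sh$r_U), 60 - sh$skipped)
  expect_gt(mean(sh$r_U[, 1]), 0.6)
  expect_gt(sh$z_U$z[1], 1.96)
  expect_gt(sh$z_V$z[1], 1.96)

  sh2 <- split_half(st$brain, st$behavior, st$covariates, method = "pls",
                    iters = 60, seed = 9, correlation_type = "spearman")
  expect_identical(sh$r_U, sh2$r_U)

  # CCA path runs and returns the same shape
  shc <- split_half(st$brain, st$behavior, st$covariates, method = "cca",
                    iters = 20, seed = 9)
  expect_equal(ncol(shc$r_U), 5)
})

test_that("split-half r distributions are centered at zero for null data", {
  st <- recovery_study(n = 600, effect = 0, seed = 43)
  sh <- split_half(st$brain, st$behavior, st$covariates, method = "pls",
                   iters = 60, seed = 3)
  expect_lt(abs(mean(sh$r_U[, 1])), 0.35)
})

test_that("split-half reproducibility grows with planted effect size", {
  ms <- vapply(c(0.15, 0.4, 0.7), function(eff) {
    st <- recovery_study(n = 500, effect = eff, seed = 44)
    sh <- split_half(st$brain, st$behavior, st$covariates, method = "pls",
                     iters = 40, seed = 11)
    mean(sh$r_U[, 1])
  }, numeric(1))
  expect_true(all(diff(ms) > 0))
})

test_that("alignment mode 'none' leaves reflections uncorrected", {
  st <- recovery_study(n = 200, effect = 0, seed = 45)
  raw <- split_half(st$brain, st$behavior, st$covariates, method = "pls",
                    iters = 40, seed = 2, alignment = "none")
  expect_equal(raw$alignment_mode, "none")
  expect_true(all(is.finite(raw$r_U[, 1])))
})

test_that("train-test reliability detects a planted LV and validates inputs", {
  st <- recovery_study(n = 600, effect = 0.6, seed = 46)
  tt <- train_test(st$brain, st$behavior, st$covariates, method = "pls",
                   iters = 60, seed = 5, correlation_type = "spearman")
  expect_gt(tt$z$z[1], 1.96)
  expect_gt(mean(tt$s_pred[, 1]), 0)

  tt2 <- train_test(st$brain, st$behavior, st$covariates, method = "pls",
                    iters = 60, seed = 5, correlation_type = "spearman")
  expect_identical(tt$s_pred, tt2$s_pred)

  expect_error(
    train_test(st$brain, st$behavior, st$covariates, train_fraction = 0.999),
    "test split too small")
  expect_error(
    train_test(st$brain, st$behavior, st$covariates, train_fraction = 1.2),
    "train_fraction")
})

test_that("null train-test distributions center near zero", {
  st <- recovery_study(n = 600, effect = 0, seed = 47)
  tt <- train_test(st$brain, st$behavior, st$covariates, method = "pls",
                   iters = 80, seed = 6)
  m <- mean(tt$s_pred[, 1])
  se <- sd(tt$s_pred[, 1]) / sqrt(nrow(tt$s_pred))
  expect_lt(abs(m), max(2 * se, 0.05))
})

test_that("bootstrap CIs are ordered, stable where planted, deterministic", {
  st <- recovery_study(n = 600, effect = 0.6, seed = 48)
  bt <- bootstrap_stability(st$brain, st$behavior, st$covariates,
                            method = "pls", n_boot = 120, seed = 4,
                            correlation_type = "spearman")
  expect_true(all(bt$ci_U$lo <= bt$ci_U$hi))
  expect_true(all(bt$ci_V$lo <= bt$ci_V$hi))
  # the largest-|loading| behavior element of the planted LV is stable
  ref_v <- model_loadings(bt$reference)$y[, 1]
  expect_true(bt$stable_V[which.max(abs(ref_v)), 1])

  bt2 <- bootstrap_stability(st$brain, st$behavior, st$covariates,
                             method = "pls", n_boot = 120, seed = 4,
                             correlation_type = "spearman")
  expect_identical(bt$ci_U, bt2$ci_U)
})

test_that("null bootstrap flags few stable LV1 elements", {
  frac <- vapply(1:3, function(s) {
    st <- recovery_study(n = 300, effect = 0, seed = 100 + s)
    bt <- bootstrap_stability(st$brain, st$behavior, st$covariates,
                              method = "pls", n_boot = 100, seed = s)
    mean(c(bt$stable_U[, 1], bt$stable_V[, 1]))
  }, numeric(1))
  expect_lte(mean(frac), 0.15)
})
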