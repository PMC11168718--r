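# Shared resampling plumbing: residualize/transform a row subset of both
# blocks (nuisance removal always happens after resampling) and fit one
# method. Errors from degenerate resamples (e.g., a behavior column constant
# within a half) propagate to the caller, which skips or redraws.
fit_on_rows <- function(X, Y, covariates, idx, method, correlation_type, eps) {
  Xi <- prepare_block(subset_block_or_matrix(X, idx),
                      subset_covariates(covariates, idx), correlation_type)
  Yi <- prepare_block(subset_block_or_matrix(Y, idx),
                      subset_covariates(covariates, idx), correlation_type)
  # blocks are already transformed, so Pearson products here realize the
  # requested correlation type exactly
  cp <- build_cross_products(Xi$values, Yi$values, type = "pearson", eps = eps)
  if (method == "cca") fit_cca(cp) else fit_pls(cp)
}

subset_block_or_matrix <- function(x, idx) {
  if (inherits(x, "data_block")) subset_block(x, idx)
  else block_values(x)[idx, , drop = FALSE]
}

prepared_cross_products <- function(X, Y, covariates, method, correlation_type,
                                    eps) {
  Xp <- prepare_block(X, covariates, correlation_type)
  Yp <- prepare_block(Y, covariates, correlation_type)
  build_cross_products(Xp$values, Yp$values, type = "pearson", eps = eps)
}

#' Correct arbitrary sign flips between SVD solutions
#'
#' The sign of each LV is arbitrary: resampled decompositions can return a
#' reflected solution. Per LV, if the combined inner product
#' `<u, u_ref> + <v, v_ref>` is negative, both `u` and `v` are negated (a
#' joint flip leaves the solution unchanged); otherwise the column is kept.
#'
#' @param U,V loading matrices of the resampled model.
#' @param U_ref,V_ref loadings of the reference (full-sample) model, same
#'   shapes.
#' @return list with the aligned `U`, `V` and the per-LV `flipped` flags.
#' @export
sign_align <- function(U, V, U_ref, V_ref) {
  if (!all(dim(U) == dim(U_ref)) || !all(dim(V) == dim(V_ref))) {
    stop("shape mismatch between loadings and reference", call. = FALSE)
  }
  sums <- colSums(U * U_ref) + colSums(V * V_ref)
  flip <- sums < 0
  U[, flip] <- -U[, flip, drop = FALSE]
  V[, flip] <- -V[, flip, drop = FALSE]
  list(U = U, V = V, flipped = flip)
}

per_lv_ztests <- function(mat, threshold) {
  lapply(seq_len(ncol(mat)), function(l) {
    v <- mat[, l]
    v <- v[is.finite(v)]
    if (length(v) < 2L || stats::sd(v) <= 0) return(NULL)
    ztest(v, threshold = threshold)
  })
}

z_summary_frame <- function(zlist) {
  do.call(rbind, lapply(seq_along(zlist), function(l) {
    zt <- zlist[[l]]
    if (is.null(zt)) {
      data.frame(lv = l, mean = NA_real_, sd = NA_real_, z = NA_real_,
                 significant = NA)
    } else {
      data.frame(lv = l, mean = zt$mean, sd = zt$sd, z = zt$z,
                 significant = zt$significant)
    }
  }))
}

#' Split-half reproducibility of loadings
#'
#' Repeatedly splits the cohort into two random halves (the first half gets
#' the extra participant when `n` is odd), residualizes, transforms and
#' decomposes each half independently, and records the Pearson correlation
#' between the two halves' loadings for every LV on both sides. Each half is
#' first sign-aligned to the full-sample reference model
#' (`alignment = "reference"`); `alignment = "none"` records raw
#' correlations, whose distributions bimodalize when reflections occur.
#' A per-LV Z-test summarizes each correlation distribution.
#'
#' @param X,Y raw [data_block]s (or matrices).
#' @param covariates covariate table residualized out inside every half
#'   (`NULL` to skip).
#' @param method `"pls"` or `"cca"`.
#' @param iters number of random splits (the reference analysis used 10,000).
#' @param seed integer seed.
#' @param correlation_type `"spearman"` or `"pearson"`.
#' @param alignment `"reference"` or `"none"`.
#' @param eps eigenvalue floor.
#' @param z_threshold cutoff for the Z-test.
#' @return An object of class `split_half_result`: `r_U`, `r_V`
#'   (`iters x L` correlation distributions), `z_U`, `z_V` (per-LV
#'   summaries), `skipped` (degenerate splits), `iters`, `seed`,
#'   `alignment_mode`, `reference` (the full-sample model).
#' @export
split_half <- function(X, Y, covariates = NULL, method = c("pls", "cca"),
                       iters = 10000L, seed = NULL,
                       correlation_type = c("spearman", "pearson"),
                       alignment = c("reference", "none"),
                       eps = 1e-10, z_threshold = 1.96) {
  method <- match.arg(method)
  correlation_type <- match.arg(correlation_type)
  alignment <- match.arg(alignment)
  iters <- check_count(iters, "iters")
  n <- nrow(block_values(X))
  if (n < 4L) stop("need at least 4 participants to split", call. = FALSE)

  reference <- fit_on_rows(X, Y, covariates, seq_len(n), method,
                           correlation_type, eps)
  ref_load <- model_loadings(reference)
  L <- reference$L

  set_substream(seed, "split_half")
  r_U <- matrix(NA_real_, iters, L)
  r_V <- matrix(NA_real_, iters, L)
  skipped <- 0L
  n1 <- ceiling(n / 2)
  for (it in seq_len(iters)) {
    idx <- sample.int(n)
    ok <- tryCatch({
      m1 <- fit_on_rows(X, Y, covariates, idx[seq_len(n1)], method,
                        correlation_type, eps)
      m2 <- fit_on_rows(X, Y, covariates, idx[-seq_len(n1)], method,
                        correlation_type, eps)
      l1 <- model_loadings(m1); l2 <- model_loadings(m2)
      if (alignment == "reference") {
        a1 <- sign_align(l1$x, l1$y, ref_load$x, ref_load$y)
        a2 <- sign_align(l2$x, l2$y, ref_load$x, ref_load$y)
        l1 <- list(x = a1$U, y = a1$V); l2 <- list(x = a2$U, y = a2$V)
      }
      for (l in seq_len(L)) {
        r_U[it, l] <- stats::cor(l1$x[, l], l2$x[, l])
        r_V[it, l] <- stats::cor(l1$y[, l], l2$y[, l])
      }
      TRUE
    }, error = function(e) FALSE)
    if (!ok) skipped <- skipped + 1L
  }
  keep <- stats::complete.cases(r_U) & stats::complete.cases(r_V)
  r_U <- r_U[keep, , drop = FALSE]
  r_V <- r_V[keep, , drop = FALSE]
  colnames(r_U) <- colnames(r_V) <- sprintf("LV%d", seq_len(L))
  structure(
    list(r_U = r_U, r_V = r_V,
         z_U = z_summary_frame(per_lv_ztests(r_U, z_threshold)),
         z_V = z_summary_frame(per_lv_ztests(r_V, z_threshold)),
         iters = iters, skipped = skipped, seed = seed,
         method = method, alignment_mode = alignment,
         reference = reference),
    class = "split_half_result"
  )
}

#' @export
print.split_half_result <- function(x, ...) {
  cat(sprintf("<split_half_result: %s, %d iterations (%d skipped), alignment = %s>\n",
              toupper(x$method), x$iters, x$skipped, x$alignment_mode))
  cat("brain loadings (U):\n"); print(round(x$z_U, 3))
  cat("behavior loadings (V):\n"); print(round(x$z_V, 3))
  invisible(x)
}

#' Predicted singular values of a held-out cross-product matrix
#'
#' Projects training singular vectors onto the test set's cross-product
#' matrix: `s_pred = diag(U' C_test V)`. On the training cross-product this
#' returns the training singular values exactly, so any departure is purely
#' out-of-sample.
#'
#' @param U_train,V_train training singular vectors (generalized singular
#'   vectors for CCA).
#' @param C_test test cross-product matrix (`R_XY` for PLS, `Omega` for CCA).
#' @return vector of predicted singular values, one per LV.
#' @export
predict_singular_values <- function(U_train, V_train, C_test) {
  if (nrow(U_train) != nrow(C_test) || nrow(V_train) != ncol(C_test) ||
      ncol(U_train) != ncol(V_train)) {
    stop("shape mismatch between loadings and test cross-product", call. = FALSE)
  }
  unname(diag(crossprod(U_train, C_test %*% V_train)))
}

#' Train-test reliability of singular values
#'
#' Repeatedly splits the cohort into train/test partitions (default 80/20),
#' residualizes and transforms each side separately, decomposes the training
#' side, and solves for the test side's singular values by projecting the
#' training singular vectors onto the test cross-product matrix. A predicted
#' singular value distribution consistently larger than zero (per-LV Z-test)
#' indicates that the training solution reliably predicts unseen data.
#'
#' @inheritParams split_half
#' @param train_fraction fraction of participants in the training side.
#' @return An object of class `train_test_result`: `s_pred` (`iters x L`),
#'   `z` (per-LV summaries), `train_fraction`, `skipped`, `iters`, `seed`,
#'   `reference`.
#' @export
train_test <- function(X, Y, covariates = NULL, method = c("pls", "cca"),
                       iters = 10000L, train_fraction = 0.8, seed = NULL,
                       correlation_type = c("spearman", "pearson"),
                       eps = 1e-10, z_threshold = 1.96) {
  method <- match.arg(method)
  correlation_type <- match.arg(correlation_type)
  iters <- check_count(iters, "iters")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  n <- nrow(block_values(X))
  q <- ncol(block_values(Y))
  n_train <- floor(train_fraction * n)
  n_test <- n - n_train
  if (n_test < q + 2L) {
    stop(sprintf(
      "test split too small for stable correlations (n_test = %d < %d)",
      n_test, q + 2L), call. = FALSE)
  }

  reference <- fit_on_rows(X, Y, covariates, seq_len(n), method,
                           correlation_type, eps)
  L <- reference$L

  set_substream(seed, "train_test")
  s_pred <- matrix(NA_real_, iters, L)
  skipped <- 0L
  for (it in seq_len(iters)) {
    idx <- sample.int(n)
    tr <- idx[seq_len(n_train)]
    te <- idx[-seq_len(n_train)]
    ok <- tryCatch({
      m_tr <- fit_on_rows(X, Y, covariates, tr, method, correlation_type, eps)
      cp_te <- prepared_cross_products(
        subset_block_or_matrix(X, te), subset_block_or_matrix(Y, te),
        subset_covariates(covariates, te), method, correlation_type, eps)
      C <- if (method == "cca") cp_te$Omega else cp_te$R_XY
      s_pred[it, ] <- predict_singular_values(m_tr$U, m_tr$V, C)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) skipped <- skipped + 1L
  }
  s_pred <- s_pred[stats::complete.cases(s_pred), , drop = FALSE]
  colnames(s_pred) <- sprintf("LV%d", seq_len(L))
  structure(
    list(s_pred = s_pred,
         z = z_summary_frame(per_lv_ztests(s_pred, z_threshold)),
         train_fraction = train_fraction, iters = iters, skipped = skipped,
         seed = seed, method = method, reference = reference),
    class = "train_test_result"
  )
}

#' @export
print.train_test_result <- function(x, ...) {
  cat(sprintf("<train_test_result: %s, %d iterations (%d skipped), train fraction %.2f>\n",
              toupper(x$method), x$iters, x$skipped, x$train_fraction))
  print(round(x$z, 3))
  invisible(x)
}

#' Bootstrap stability of individual loading elements
#'
#' Draws bootstrap samples of participants with replacement (keeping brain
#' and behavior rows paired), refits the model on each sample after
#' residualization/transformation, sign-aligns it to the full-sample
#' reference, and accumulates per-element distributions of the loadings.
#' Each element of `U` and `V` gets a percentile confidence interval; an
#' element is flagged stable when its interval excludes zero. Degenerate
#' resamples (e.g., a constant column) are redrawn.
#'
#' @inheritParams split_half
#' @param n_boot number of bootstrap samples (the reference analysis used
#'   1,000).
#' @param conf confidence level of the percentile intervals.
#' @return An object of class `bootstrap_result`: `ci_U`, `ci_V` (lists with
#'   `lo`/`hi` matrices), `stable_U`, `stable_V` (logical matrices),
#'   `n_boot`, `redrawn`, `seed`, `reference`.
#' @export
bootstrap_stability <- function(X, Y, covariates = NULL,
                                method = c("pls", "cca"), n_boot = 1000L,
                                seed = NULL,
                                correlation_type = c("spearman", "pearson"),
                                conf = 0.95, eps = 1e-10) {
  method <- match.arg(method)
  correlation_type <- match.arg(correlation_type)
  n_boot <- check_count(n_boot, "n_boot")
  n <- nrow(block_values(X))
  if (n < 10L) stop("need at least 10 participants to bootstrap", call. = FALSE)

  reference <- fit_on_rows(X, Y, covariates, seq_len(n), method,
                           correlation_type, eps)
  ref_load <- model_loadings(reference)
  p <- nrow(ref_load$x); q <- nrow(ref_load$y); L <- reference$L

  set_substream(seed, "bootstrap")
  boot_U <- array(NA_real_, c(p, L, n_boot))
  boot_V <- array(NA_real_, c(q, L, n_boot))
  redrawn <- 0L
  for (b in seq_len(n_boot)) {
    for (attempt in seq_len(25L)) {
      idx <- sample.int(n, n, replace = TRUE)
      ok <- tryCatch({
        m <- fit_on_rows(X, Y, covariates, idx, method, correlation_type, eps)
        lb <- model_loadings(m)
        al <- sign_align(lb$x, lb$y, ref_load$x, ref_load$y)
        boot_U[, , b] <- al$U
        boot_V[, , b] <- al$V
        TRUE
      }, error = function(e) FALSE)
      if (ok) break
      redrawn <- redrawn + 1L
      if (attempt == 25L) {
        stop("bootstrap resampling failed repeatedly (degenerate resamples)",
             call. = FALSE)
      }
    }
  }
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  qci <- function(a) {
    lo <- apply(a, c(1L, 2L), stats::quantile, probs = probs[1], names = FALSE)
    hi <- apply(a, c(1L, 2L), stats::quantile, probs = probs[2], names = FALSE)
    dimnames(lo) <- dimnames(hi) <- dimnames(a)[1:2]
    list(lo = lo, hi = hi)
  }
  dimnames(boot_U) <- c(dimnames(ref_load$x), list(NULL))
  dimnames(boot_V) <- c(dimnames(ref_load$y), list(NULL))
  ci_U <- qci(boot_U); ci_V <- qci(boot_V)
  structure(
    list(ci_U = ci_U, ci_V = ci_V,
         stable_U = ci_U$lo > 0 | ci_U$hi < 0,
         stable_V = ci_V$lo > 0 | ci_V$hi < 0,
         n_boot = n_boot, conf = conf, redrawn = redrawn, seed = seed,
         method = method, reference = reference),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result: %s, %d samples (%d redrawn), %.0f%% CIs>\n",
              toupper(x$method), x$n_boot, x$redrawn, 100 * x$conf))
  cat(sprintf("  stable elements: U %d/%d, V %d/%d (LV1: U %d, V %d)\n",
              sum(x$stable_U), length(x$stable_U),
              sum(x$stable_V), length(x$stable_V),
              sum(x$stable_U[, 1]), sum(x$stable_V[, 1])))
  invisible(x)
}
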