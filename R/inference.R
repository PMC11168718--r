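#' Trailing sums of the squared singular spectrum
#'
#' `T_k = sum_{i = k..L} s_i^2`: the statistic family behind the
#' sum-of-squares permutation test (analogous to Wilks' lambda), assessed
#' on the eigenspectrum (squared singular values).
#'
#' @param S non-increasing, non-negative singular values.
#' @return numeric vector `T` of the same length; `T[1]` is the total sum of
#'   squares and `T` is non-increasing in `k`.
#' @examples
#' sum_of_squares_spectrum(c(2, 1))
#' @export
sum_of_squares_spectrum <- function(S) {
  if (any(S < 0) || any(!is.finite(S))) {
    stop("singular values must be finite and non-negative", call. = FALSE)
  }
  if (is.unsorted(rev(S), strictly = FALSE) && length(S) > 1L &&
      any(diff(S) > 1e-8)) {
    stop("singular values must be non-increasing", call. = FALSE)
  }
  rev(cumsum(rev(S^2)))
}

#' Sum-of-squares permutation test on the eigenspectrum
#'
#' Shuffles the rows of the (transformed) brain block to break the
#' brain-behavior link while preserving both within-block structures,
#' recomputes the decomposition for every permutation, and compares the
#' observed trailing sums of squared singular values `T_k` with their null
#' distribution. LV `k` is significant when fewer than `alpha` of the
#' permuted `T_k` reach the observed one; the add-one estimator
#' `p = (b + 1) / (B + 1)` is used, so p-values lie in `[1/(B+1), 1]`.
#'
#' Row permutation leaves `R_XX` and `R_YY` unchanged, so only `R_XY` (and
#' `Omega` via fixed whitening matrices) is recomputed per permutation.
#'
#' @param X,Y transformed blocks (`residualized_block`s or matrices) with
#'   matching participant order. Pass rank-standardized blocks (or use
#'   `type = "spearman"`) for the Spearman path.
#' @param method `"pls"` or `"cca"`.
#' @param B number of permutations (the reference analysis used 10,000).
#' @param seed integer seed.
#' @param type correlation type applied to the supplied blocks.
#' @param eps eigenvalue floor for the whitening matrices.
#' @param alpha significance level for the per-LV flags.
#' @param keep_null keep the `B x L` matrix of permuted statistics.
#' @return An object of class `permutation_result`: `observed_T`,
#'   `p_values`, `significant`, `S`, `B`, `alpha`, `seed`, and `null_T`
#'   when `keep_null`.
#' @export
permutation_test <- function(X, Y, method = c("pls", "cca"), B = 10000L,
                             seed = NULL, type = c("pearson", "spearman"),
                             eps = 1e-10, alpha = 0.05, keep_null = TRUE) {
  method <- match.arg(method)
  type <- match.arg(type)
  B <- check_count(B, "B")
  Xm <- block_values(X); Ym <- block_values(Y)
  if (nrow(Xm) != nrow(Ym)) stop("X and Y have different row counts", call. = FALSE)
  if (type == "spearman") {
    Xm <- rank_standardize(Xm)$values
    Ym <- rank_standardize(Ym)$values
  }
  cp <- build_cross_products(Xm, Ym, type = "pearson", eps = eps)
  model <- if (method == "cca") fit_cca(cp) else fit_pls(cp)
  T_obs <- sum_of_squares_spectrum(model$S)
  L <- model$L
  n <- nrow(Xm)

  set_substream(seed, "permutation")
  null_T <- matrix(NA_real_, B, L)
  for (b in seq_len(B)) {
    idx <- sample.int(n)
    Rb <- stats::cor(Xm[idx, , drop = FALSE], Ym)
    if (method == "cca") Rb <- cp$inv_sqrt_xx %*% Rb %*% cp$inv_sqrt_yy
    d <- svd(Rb, nu = 0L, nv = 0L)$d[seq_len(L)]
    null_T[b, ] <- rev(cumsum(rev(d^2)))
  }
  exceed <- colSums(null_T >= matrix(T_obs, B, L, byrow = TRUE))
  p <- (exceed + 1) / (B + 1)
  names(p) <- names(T_obs) <- sprintf("LV%d", seq_len(L))
  structure(
    list(observed_T = T_obs, p_values = p, significant = p < alpha,
         S = model$S, method = method, B = B, alpha = alpha, seed = seed,
         null_T = if (keep_null) null_T else NULL),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result: %s, B = %d>\n", toupper(x$method), x$B))
  print(data.frame(T_obs = round(x$observed_T, 4), p = round(x$p_values, 4),
                   significant = x$significant))
  invisible(x)
}

#' Z-test on a resampling distribution
#'
#' Mean of the distribution divided by its standard deviation; a magnitude
#' above 1.96 corresponds to p < .05 for a distribution significantly
#' different from zero.
#'
#' @param distribution numeric vector (>= 2 values, non-degenerate).
#' @param threshold significance cutoff on `|z|` (default 1.96).
#' @return An object of class `z_test`: `mean`, `sd`, `z`, `significant`,
#'   `threshold`, `n`.
#' @examples
#' ztest(c(0.1, 0.3, 0.2, 0.25))
#' @export
ztest <- function(distribution, threshold = 1.96) {
  distribution <- distribution[is.finite(distribution)]
  if (length(distribution) < 2L) {
    stop("need at least 2 finite values", call. = FALSE)
  }
  s <- stats::sd(distribution)
  if (s <= 0) {
    stop("degenerate distribution: standard deviation is zero", call. = FALSE)
  }
  m <- mean(distribution)
  z <- m / s
  structure(list(mean = m, sd = s, z = z,
                 significant = abs(z) > threshold,
                 threshold = threshold, n = length(distribution)),
            class = "z_test")
}

#' @export
print.z_test <- function(x, ...) {
  cat(sprintf("<z_test: mean = %.4f, sd = %.4f, z = %.3f (%ssignificant at %.2f)>\n",
              x$mean, x$sd, x$z, if (x$significant) "" else "not ", x$threshold))
  invisible(x)
}
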