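#' Between-method similarity of CCA and PLS loadings
#'
#' Full cross-LV Pearson correlation matrices between the loadings of two
#' fitted models (brain side and behavior side separately): entry `(i, j)`
#' correlates LV `i` of the first model with LV `j` of the second. The
#' diagonal is the respective-LV similarity; large off-diagonal entries
#' reveal axis rotation between methods (a CCA LV matching a different PLS
#' LV).
#'
#' @param model_a,model_b fitted `latent_model`s on identical transformed
#'   data (typically one CCA, one PLS).
#' @return An object of class `method_comparison` with fields `r_U_cross`,
#'   `r_V_cross` and the two method labels. Pearson correlation is scale
#'   invariant, so the differing scales of CCA weights and PLS singular
#'   vectors do not affect the entries.
#' @export
between_method_correlation <- function(model_a, model_b) {
  stopifnot(inherits(model_a, "latent_model"), inherits(model_b, "latent_model"))
  la <- model_loadings(model_a); lb <- model_loadings(model_b)
  if (nrow(la$x) != nrow(lb$x) || nrow(la$y) != nrow(lb$y)) {
    stop("variable-set mismatch between models", call. = FALSE)
  }
  r_U <- stats::cor(la$x, lb$x)
  r_V <- stats::cor(la$y, lb$y)
  lva <- sprintf("%s_LV%d", model_a$method, seq_len(model_a$L))
  lvb <- sprintf("%s_LV%d", model_b$method, seq_len(model_b$L))
  dimnames(r_U) <- dimnames(r_V) <- list(lva, lvb)
  structure(list(r_U_cross = r_U, r_V_cross = r_V,
                 method_a = model_a$method, method_b = model_b$method),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison: %s vs %s>\n", toupper(x$method_a),
              toupper(x$method_b)))
  k <- min(nrow(x$r_U_cross), ncol(x$r_U_cross))
  cat("respective-LV loading correlations (U / V):\n")
  print(round(rbind(U = diag(x$r_U_cross)[seq_len(k)],
                    V = diag(x$r_V_cross)[seq_len(k)]), 3))
  invisible(x)
}

#' Number of principal components needed to reach a variance threshold
#'
#' Eigendecomposes the within-block correlation matrix and returns the
#' smallest `k` whose top-`k` eigenvalues sum to at least `threshold` of the
#' total. A compressed variance structure (small `k`) signals redundancy
#' among the variables.
#'
#' @param block a [data_block]/matrix of raw data, or a correlation matrix
#'   (square, symmetric, unit diagonal).
#' @param threshold fraction of total variance, in `(0, 1]` (default 0.90).
#' @param type correlation type when `block` is raw data.
#' @return integer component count in `[1, q]`.
#' @examples
#' pca_variance_profile(diag(10), threshold = 0.9)  # identity: 9
#' @export
pca_variance_profile <- function(block, threshold = 0.9,
                                 type = c("pearson", "spearman")) {
  type <- match.arg(type)
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  m <- block_values(block)
  is_cor <- nrow(m) == ncol(m) && max(abs(m - t(m))) < 1e-8 &&
    all(abs(diag(m) - 1) < 1e-8)
  R <- if (is_cor) m else correlation_matrix(m, type = type)
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(ev, 1))) {
    stop("correlation matrix is not positive semi-definite", call. = FALSE)
  }
  ev <- pmax(ev, 0)
  which(cumsum(ev) >= threshold * sum(ev) - 1e-12)[1]
}

#' Distributional diagnostics of a block
#'
#' Summaries of the statistical pathologies that drive generalizability:
#' per-column skewness (third standardized moment) and proportion of zeros,
#' the condition number of the within-block correlation matrix, and the
#' number of principal components needed to explain 90% of the variance.
#' Constant columns yield `NA` skewness and are flagged, not fatal.
#'
#' @param block a [data_block] or matrix.
#' @param pca_threshold variance fraction for the component count.
#' @param type correlation type for the within-block matrix.
#' @return An object of class `block_diagnostics`: `columns` (data.frame
#'   with `variable`, `skewness`, `zero_proportion`), `condition_number`,
#'   `pca_components_for_threshold`, `threshold`.
#' @export
distribution_diagnostics <- function(block, pca_threshold = 0.9,
                                     type = c("pearson", "spearman")) {
  type <- match.arg(type)
  m <- block_values(block)
  if (!nrow(m) || !ncol(m)) stop("empty block", call. = FALSE)
  sk <- col_skewness(m)
  zp <- colMeans(m == 0)
  nonconst <- apply(m, 2L, stats::sd) > 0
  cond <- NA_real_
  ncomp <- NA_integer_
  if (sum(nonconst) >= 2L) {
    R <- correlation_matrix(m[, nonconst, drop = FALSE], type = type)
    ev <- pmax(eigen((R + t(R)) / 2, symmetric = TRUE,
                     only.values = TRUE)$values, 0)
    cond <- max(ev) / max(min(ev), .Machine$double.eps)
    ncomp <- pca_variance_profile(R, threshold = pca_threshold)
  }
  structure(
    list(columns = data.frame(
           variable = colnames(m) %||% sprintf("v%d", seq_len(ncol(m))),
           skewness = as.numeric(sk),
           zero_proportion = as.numeric(zp),
           constant = !nonconst,
           row.names = NULL),
         condition_number = cond,
         pca_components_for_threshold = ncomp,
         threshold = pca_threshold),
    class = "block_diagnostics"
  )
}

#' @export
print.block_diagnostics <- function(x, ...) {
  cat(sprintf("<block_diagnostics: %d variables, condition number %.1f, %d component(s) for %.0f%% variance>\n",
              nrow(x$columns), x$condition_number,
              x$pca_components_for_threshold, 100 * x$threshold))
  print(transform(x$columns, skewness = round(skewness, 3),
                  zero_proportion = round(zero_proportion, 3)))
  invisible(x)
}
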