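#' Regress nuisance covariates out of a data block
#'
#' Per-column ordinary least squares of the block on an intercept plus all
#' covariate columns (continuous covariates as-is, categorical covariates
#' dummy-coded against a first-level reference), keeping the residuals and
#' Z-transforming them (mean 0, SD 1 with the n-1 denominator). Residuals
#' are exactly orthogonal to every retained design column.
#'
#' Covariate columns that are exact linear combinations of earlier ones
#' (e.g., scanner model when sites are nested within scanners) are aliased:
#' the fitted projection is unchanged by them, so by default they are dropped
#' and recorded; with `strict = TRUE` a rank-deficient design is an error
#' naming the collinear columns.
#'
#' @param block a [data_block] (or numeric matrix).
#' @param covariates data.frame of per-participant covariates, optionally with
#'   a `participant_id` column (checked against the block's IDs). `NULL`
#'   means intercept-only (centering + scaling).
#' @param strict error on rank-deficient designs instead of dropping aliased
#'   columns.
#' @return An object of class `residualized_block`: `values` (residuals,
#'   Z-transformed), `design_columns_used`, `aliased_columns`, `transform`
#'   (`"z_only"`), plus the block's IDs, names and role.
#' @examples
#' b <- data_block(matrix(rnorm(40), 10, 4))
#' cov <- data.frame(age = rnorm(10), sex = factor(rep(c("F", "M"), 5)))
#' r <- residualize(b, cov)
#' round(colMeans(r$values), 12)
#' @export
residualize <- function(block, covariates = NULL, strict = FALSE) {
  values <- block_values(block)
  ids <- block_ids(block)
  n <- nrow(values)
  if (!is.null(covariates)) {
    if (!is.null(covariates$participant_id) && !is.null(ids) &&
        !identical(as.character(covariates$participant_id), as.character(ids))) {
      stop("participant IDs of block and covariates do not match (order matters)",
           call. = FALSE)
    }
    if (nrow(covariates) != n) {
      stop("covariate table and block have different numbers of rows",
           call. = FALSE)
    }
    covs <- covariates[, setdiff(names(covariates), "participant_id"),
                       drop = FALSE]
    covs <- droplevels(covs)
    # factors reduced to a single observed level (possible in small
    # resamples) carry no information beyond the intercept
    single <- vapply(covs, function(v) is.factor(v) && nlevels(v) < 2L,
                     logical(1))
    covs <- covs[, !single, drop = FALSE]
    design <- if (ncol(covs)) stats::model.matrix(~ ., data = covs)
              else matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    design <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  }

  qd <- qr(design)
  aliased <- character(0)
  if (qd$rank < ncol(design)) {
    aliased <- colnames(design)[qd$pivot[(qd$rank + 1L):ncol(design)]]
    if (strict) {
      stop("rank-deficient covariate design; collinear column(s): ",
           paste(aliased, collapse = ", "), call. = FALSE)
    }
    design <- design[, qd$pivot[seq_len(qd$rank)], drop = FALSE]
    qd <- qr(design)
  }
  res <- qr.resid(qd, values)
  res <- zscore_columns(res, what = "residualized block")
  structure(
    list(values = res,
         participant_ids = ids,
         variable_names = colnames(values),
         role = if (is.list(block) && !is.null(block$role)) block$role else NA_character_,
         design_columns_used = colnames(design),
         aliased_columns = aliased,
         transform = "z_only"),
    class = "residualized_block"
  )
}

#' @export
print.residualized_block <- function(x, ...) {
  cat(sprintf("<residualized_block: %d x %d, transform = %s, %d design column(s)>\n",
              nrow(x$values), ncol(x$values), x$transform,
              length(x$design_columns_used)))
  invisible(x)
}

#' Replace columns by average ranks and Z-transform
#'
#' Each column becomes its within-column average ranks (ties get the mean
#' rank), then is Z-transformed. Pearson cross-products of the output equal
#' Spearman correlations of the input, which is how the Spearman
#' cross-product matrices are realized while keeping latent-score identities
#' exact.
#'
#' @param block a `residualized_block`, [data_block] or matrix.
#' @return A `residualized_block` with `transform = "rank_then_z"`.
#' @examples
#' rank_standardize(matrix(c(5, 5, 7, 1, 2, 3), 3, 2))$values
#' @export
rank_standardize <- function(block) {
  values <- block_values(block)
  ranked <- apply(values, 2L, rank, ties.method = "average")
  ranked <- matrix(ranked, nrow(values), ncol(values), dimnames = dimnames(values))
  res <- zscore_columns(ranked, what = "rank-standardized block")
  structure(
    list(values = res,
         participant_ids = block_ids(block),
         variable_names = colnames(values),
         role = if (is.list(block) && !is.null(block$role)) block$role else NA_character_,
         design_columns_used = if (is.list(block)) block$design_columns_used else NULL,
         aliased_columns = if (is.list(block)) block$aliased_columns else NULL,
         transform = "rank_then_z"),
    class = "residualized_block"
  )
}

#' Column-by-column correlation matrix between two matrices
#'
#' @param A,B numeric matrices with equal row counts (>= 3). `B = NULL`
#'   gives the within-block correlation of `A`.
#' @param type `"spearman"` (Pearson on average ranks) or `"pearson"`.
#' @return `ncol(A) x ncol(B)` correlation matrix.
#' @export
correlation_matrix <- function(A, B = NULL,
                               type = c("spearman", "pearson")) {
  type <- match.arg(type)
  A <- block_values(A)
  if (!is.null(B)) {
    B <- block_values(B)
    if (nrow(A) != nrow(B)) stop("row counts differ", call. = FALSE)
  }
  if (nrow(A) < 3L) stop("need at least 3 rows for a correlation", call. = FALSE)
  sd_ok <- function(m) {
    s <- apply(m, 2L, stats::sd)
    if (any(s <= 0)) {
      stop("constant column(s): correlation undefined (",
           paste(colnames(m)[s <= 0] %||% which(s <= 0), collapse = ", "), ")",
           call. = FALSE)
    }
  }
  sd_ok(A); if (!is.null(B)) sd_ok(B)
  stats::cor(A, B, method = type)
}

#' Inverse square root of a symmetric positive semi-definite matrix
#'
#' Eigendecomposition-based `M^(-1/2)`. Eigenvalues below `eps` times the
#' largest eigenvalue are treated as exactly zero (pseudo-inverse square
#' root), guarding degenerate resamples; eigenvalues negative beyond
#' tolerance raise an error.
#'
#' @param M symmetric PSD matrix.
#' @param eps relative eigenvalue floor (default `1e-10`).
#' @return Symmetric matrix `M^(-1/2)`.
#' @examples
#' inv_sqrt_psd(diag(c(4, 9)))
#' @export
inv_sqrt_psd <- function(M, eps = 1e-10) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("M must be square", call. = FALSE)
  scale_m <- max(abs(M), 1)
  if (max(abs(M - t(M))) > 1e-8 * scale_m) {
    stop("M is not symmetric within tolerance", call. = FALSE)
  }
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lmax <- max(e$values, 0)
  if (any(e$values < -1e-8 * max(lmax, 1))) {
    stop("M is not positive semi-definite (negative eigenvalue beyond tolerance)",
         call. = FALSE)
  }
  inv <- ifelse(e$values > eps * lmax, 1 / sqrt(pmax(e$values, 0)), 0)
  R <- e$vectors %*% (inv * t(e$vectors))
  (R + t(R)) / 2
}

#' Build the cross-product matrices decomposed by PLS and CCA
#'
#' Computes `R_XY`, `R_XX`, `R_YY` with one correlation type (Spearman by
#' default, matching the robust-to-skew analysis path) and the adjusted
#' cross-product `Omega = R_XX^(-1/2) R_XY R_YY^(-1/2)` whose SVD is the
#' CCA solution. PLS decomposes `R_XY` directly.
#'
#' @param X,Y `residualized_block`s (or matrices) with matching participant
#'   order.
#' @param type correlation type for all three matrices.
#' @param eps relative eigenvalue floor forwarded to [inv_sqrt_psd()].
#' @return An object of class `cross_product_set` with fields `R_XY`, `R_XX`,
#'   `R_YY`, `Omega`, `correlation_type`, `ridge_eps`, `n`, plus the cached
#'   inverse square roots used for CCA reweighting.
#' @export
build_cross_products <- function(X, Y, type = c("spearman", "pearson"),
                                 eps = 1e-10) {
  type <- match.arg(type)
  Xm <- block_values(X); Ym <- block_values(Y)
  idx <- block_ids(X); idy <- block_ids(Y)
  if (!is.null(idx) && !is.null(idy) &&
      !identical(as.character(idx), as.character(idy))) {
    stop("participant order of X and Y differs", call. = FALSE)
  }
  R_XY <- correlation_matrix(Xm, Ym, type = type)
  R_XX <- correlation_matrix(Xm, type = type)
  R_YY <- correlation_matrix(Ym, type = type)
  isx <- inv_sqrt_psd(R_XX, eps = eps)
  isy <- inv_sqrt_psd(R_YY, eps = eps)
  Omega <- isx %*% R_XY %*% isy
  structure(
    list(R_XY = R_XY, R_XX = R_XX, R_YY = R_YY, Omega = Omega,
         correlation_type = type, ridge_eps = eps, n = nrow(Xm),
         inv_sqrt_xx = isx, inv_sqrt_yy = isy),
    class = "cross_product_set"
  )
}

#' @export
print.cross_product_set <- function(x, ...) {
  cat(sprintf("<cross_product_set: %d x %d, %s, n = %d>\n",
              nrow(x$R_XY), ncol(x$R_XY), x$correlation_type, x$n))
  invisible(x)
}

#' Residualize and transform a block for analysis
#'
#' Convenience wrapper over [residualize()] and [rank_standardize()]:
#' residualizes when covariates are supplied, then rank-standardizes on the
#' Spearman path or leaves the Z-transformed residuals on the Pearson path.
#' The resampling routines call this on every half, training set and
#' bootstrap sample, so nuisance removal always happens after resampling.
#'
#' @inheritParams residualize
#' @param correlation_type `"spearman"` or `"pearson"`.
#' @return A `residualized_block`.
#' @export
prepare_block <- function(block, covariates = NULL,
                          correlation_type = c("spearman", "pearson")) {
  correlation_type <- match.arg(correlation_type)
  rb <- residualize(block, covariates)
  if (correlation_type == "spearman") rb <- rank_standardize(rb)
  rb
}
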