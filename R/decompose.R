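# Sign convention shared by both methods: each LV is oriented so that the
# behavior-side loading element with the largest magnitude is positive. The
# direction of an LV is only defined up to a joint sign, so fixing one makes
# outputs reproducible across platforms and LAPACK builds.
fix_lv_signs <- function(model) {
  ref <- if (model$method == "cca") model$Wy else model$V
  for (l in seq_along(model$S)) {
    j <- which.max(abs(ref[, l]))
    if (ref[j, l] < 0) {
      model$U[, l] <- -model$U[, l]
      model$V[, l] <- -model$V[, l]
      if (!is.null(model$Wx)) {
        model$Wx[, l] <- -model$Wx[, l]
        model$Wy[, l] <- -model$Wy[, l]
        model$structure_x[, l] <- -model$structure_x[, l]
        model$structure_y[, l] <- -model$structure_y[, l]
      }
    }
  }
  model
}

new_latent_model <- function(method, sv, cp, var_x, var_y) {
  L <- min(nrow(cp$R_XY), ncol(cp$R_XY))
  U <- sv$u[, seq_len(L), drop = FALSE]
  V <- sv$v[, seq_len(L), drop = FALSE]
  S <- sv$d[seq_len(L)]
  if (any(!is.finite(S))) stop("non-finite singular values", call. = FALSE)
  lv <- sprintf("LV%d", seq_len(L))
  dimnames(U) <- list(var_x, lv)
  dimnames(V) <- list(var_y, lv)
  names(S) <- lv
  model <- list(method = method, U = U, V = V, S = S,
                varexp = variance_explained(S), L = L,
                correlation_type = cp$correlation_type, n = cp$n)
  if (method == "cca") {
    model$Wx <- cp$inv_sqrt_xx %*% U
    model$Wy <- cp$inv_sqrt_yy %*% V
    dimnames(model$Wx) <- dimnames(U)
    dimnames(model$Wy) <- dimnames(V)
    model$structure_x <- cp$R_XX %*% model$Wx
    model$structure_y <- cp$R_YY %*% model$Wy
  }
  class(model) <- "latent_model"
  fix_lv_signs(model)
}

#' Partial least squares correlation of two blocks
#'
#' Singular value decomposition of the cross-block correlation matrix
#' `R_XY`. The singular vectors `U` and `V` are the brain and behavior
#' loadings; the singular values measure the covariance captured by each
#' latent variable pair. Exactly `min(p, q)` LVs are returned.
#'
#' @param cp a [build_cross_products()] result.
#' @return An object of class `latent_model` with fields `method`, `U`, `V`,
#'   `S` (non-increasing), `varexp` (fractions `s_i^2 / sum s^2`), `L`.
#' @examples
#' X <- matrix(rnorm(600), 100, 6); Y <- matrix(rnorm(300), 100, 3)
#' m <- fit_pls(build_cross_products(scale(X), scale(Y), type = "pearson"))
#' m$S
#' @export
fit_pls <- function(cp) {
  stopifnot(inherits(cp, "cross_product_set"))
  if (any(!is.finite(cp$R_XY))) stop("non-finite entries in R_XY", call. = FALSE)
  new_latent_model("pls", svd(cp$R_XY), cp,
                   rownames(cp$R_XY), colnames(cp$R_XY))
}

#' Canonical correlation analysis via the adjusted cross-product matrix
#'
#' Singular value decomposition of `Omega = R_XX^(-1/2) R_XY R_YY^(-1/2)`.
#' The singular values are the canonical correlations; the singular vectors
#' (generalized singular vectors) are reweighted into canonical weights
#' `Wx = R_XX^(-1/2) U` and `Wy = R_YY^(-1/2) V`, which are the loadings
#' reported for CCA. Structure coefficients (correlations of each variable
#' with the latent scores, `R_XX Wx` and `R_YY Wy`) are returned as a
#' secondary view.
#'
#' @param cp a [build_cross_products()] result.
#' @return A `latent_model` with additional fields `Wx`, `Wy`,
#'   `structure_x`, `structure_y`.
#' @export
fit_cca <- function(cp) {
  stopifnot(inherits(cp, "cross_product_set"))
  if (any(!is.finite(cp$Omega))) stop("non-finite entries in Omega", call. = FALSE)
  model <- new_latent_model("cca", svd(cp$Omega), cp,
                            rownames(cp$R_XY), colnames(cp$R_XY))
  gaps <- -diff(model$S)
  if (length(gaps) && any(gaps < 1e-6)) {
    message("near-equal singular values (gap < 1e-6) at LV ",
            paste(which(gaps < 1e-6), collapse = ", "),
            "; LV order follows the SVD")
  }
  model
}

#' @export
print.latent_model <- function(x, ...) {
  cat(sprintf("<latent_model: %s, %d LVs, %d x %d, %s correlations, n = %d>\n",
              toupper(x$method), x$L, nrow(x$U), nrow(x$V),
              x$correlation_type, x$n))
  show <- utils::head(seq_len(x$L), 5L)
  cat("  S     :", paste(format(round(x$S[show], 4)), collapse = "  "),
      if (x$L > 5L) "..." else "", "\n")
  cat("  varexp:", paste(format(round(x$varexp[show], 3)), collapse = "  "),
      if (x$L > 5L) "..." else "", "\n")
  invisible(x)
}

#' Loadings of a fitted latent model
#'
#' The per-variable weights defining each LV: the singular vectors for PLS,
#' the reweighted (canonical) weights for CCA.
#'
#' @param model a `latent_model`.
#' @return list with elements `x` (brain side) and `y` (behavior side).
#' @export
model_loadings <- function(model) {
  stopifnot(inherits(model, "latent_model"))
  if (model$method == "cca") list(x = model$Wx, y = model$Wy)
  else list(x = model$U, y = model$V)
}

#' Latent scores of participants on each LV
#'
#' Projects the analysis-transformed matrices onto the loadings: `X U` and
#' `Y V` for PLS, `X Wx` and `Y Wy` for CCA. On the same transformed data
#' used to build the cross-products, the CCA score pair for LV `i`
#' correlates at exactly `s_i`.
#'
#' @param model a `latent_model`.
#' @param X,Y the transformed blocks (`residualized_block`s or matrices)
#'   the cross-products were built from.
#' @param standardize multiply each score column by its singular value
#'   (display convention used for latent-score plots).
#' @return An object of class `latent_scores`: `scores_x`, `scores_y`
#'   (`n x L`), `standardized_by_singular_values`.
#' @export
latent_scores <- function(model, X, Y, standardize = FALSE) {
  stopifnot(inherits(model, "latent_model"))
  Xm <- block_values(X); Ym <- block_values(Y)
  w <- model_loadings(model)
  if (ncol(Xm) != nrow(w$x) || ncol(Ym) != nrow(w$y)) {
    stop("dimension mismatch between blocks and loadings", call. = FALSE)
  }
  sx <- Xm %*% w$x
  sy <- Ym %*% w$y
  if (standardize) {
    sx <- sweep(sx, 2L, model$S, `*`)
    sy <- sweep(sy, 2L, model$S, `*`)
  }
  structure(list(scores_x = sx, scores_y = sy,
                 standardized_by_singular_values = standardize),
            class = "latent_scores")
}

#' Fraction of the squared singular spectrum per LV
#'
#' @param S non-negative singular values.
#' @return `s_i^2 / sum_j s_j^2`.
#' @examples
#' variance_explained(c(0.5, 0.3))
#' @export
variance_explained <- function(S) {
  if (any(S < 0) || any(!is.finite(S))) {
    stop("singular values must be finite and non-negative", call. = FALSE)
  }
  tot <- sum(S^2)
  if (tot <= 0) stop("all singular values are zero", call. = FALSE)
  S^2 / tot
}
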