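# Internal helpers shared across modules.

# Deterministic sub-seed for a named random substream. Each top-level seed
# spawns independent streams (covariates, latents, noise, copula, ...) so a
# change in one component never perturbs the draws of another. Kept in
# [0, 2^31 - 2] so set.seed() accepts it on every platform.
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919) %% 2147483587)
}

set_substream <- function(seed, name) {
  if (!is.null(seed)) set.seed(substream_seed(seed, name))
  invisible(NULL)
}

# Third standardized moment (population denominator n). Constant columns
# give NA rather than an error: callers flag, not abort.
col_skewness <- function(x) {
  x <- as.matrix(x)
  apply(x, 2L, function(v) {
    v <- v[is.finite(v)]
    m <- mean(v)
    s2 <- mean((v - m)^2)
    if (s2 <= .Machine$double.eps) return(NA_real_)
    mean((v - m)^3) / s2^1.5
  })
}

# Column z-scoring with the n-1 denominator. Errors on constant columns:
# downstream correlations are undefined there.
zscore_columns <- function(x, what = "matrix") {
  x <- as.matrix(x)
  sds <- apply(x, 2L, stats::sd)
  bad <- !is.finite(sds) | sds <= 0
  if (any(bad)) {
    stop(sprintf("constant column(s) in %s: %s", what,
                 paste(colnames(x)[bad] %||% which(bad), collapse = ", ")),
         call. = FALSE)
  }
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

check_probability <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  }
  x
}

# Extract the numeric matrix from a data_block / residualized_block / matrix.
block_values <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.list(x) && !is.null(x$values)) return(as.matrix(x$values))
  as.matrix(x)
}

block_ids <- function(x) {
  if (is.list(x) && !is.null(x$participant_ids)) return(x$participant_ids)
  rownames(block_values(x))
}
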