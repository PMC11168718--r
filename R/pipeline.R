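#' Configuration for an end-to-end two-block analysis
#'
#' @param correlation_type correlation used for all cross-product matrices.
#' @param methods which models to fit: any of `"cca"`, `"pls"`.
#' @param n_perm,n_splithalf,n_traintest,n_boot iteration counts for the
#'   resampling stages (set any to 0 to skip the stage). The reference
#'   analysis used 10,000 / 10,000 / 10,000 / 1,000; defaults here are
#'   desk-scale.
#' @param train_fraction training fraction for the reliability analysis.
#' @param z_threshold Z-test cutoff (1.96, i.e. p < .05).
#' @param alpha permutation significance level.
#' @param ci_level bootstrap confidence level.
#' @param eps relative eigenvalue floor for whitening.
#' @param seed master seed; each stage draws from its own substream.
#' @param subset optional row filter for sensitivity reruns: integer or
#'   logical index, or a predicate `function(covariates)` returning one.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(correlation_type = c("spearman", "pearson"),
                            methods = c("cca", "pls"),
                            n_perm = 1000L, n_splithalf = 500L,
                            n_traintest = 500L, n_boot = 500L,
                            train_fraction = 0.8, z_threshold = 1.96,
                            alpha = 0.05, ci_level = 0.95, eps = 1e-10,
                            seed = 1L, subset = NULL) {
  correlation_type <- match.arg(correlation_type)
  methods <- match.arg(methods, c("cca", "pls"), several.ok = TRUE)
  stopifnot(alpha > 0, alpha < 1, ci_level > 0, ci_level < 1,
            z_threshold > 0, train_fraction > 0, train_fraction < 1)
  structure(
    list(correlation_type = correlation_type, methods = methods,
         n_perm = as.integer(n_perm), n_splithalf = as.integer(n_splithalf),
         n_traintest = as.integer(n_traintest), n_boot = as.integer(n_boot),
         train_fraction = train_fraction, z_threshold = z_threshold,
         alpha = alpha, ci_level = ci_level, eps = eps,
         seed = as.integer(seed), subset = subset),
    class = "analysis_config"
  )
}

resolve_subset <- function(subset, covariates, n) {
  if (is.null(subset)) return(seq_len(n))
  if (is.function(subset)) subset <- subset(covariates)
  if (is.logical(subset)) {
    if (length(subset) != n) stop("logical subset has wrong length", call. = FALSE)
    return(which(subset))
  }
  idx <- as.integer(subset)
  if (any(idx < 1L) || any(idx > n)) stop("subset index out of range", call. = FALSE)
  idx
}

#' Run the full two-block comparison pipeline
#'
#' Orchestrates preprocessing, model fitting (CCA and/or PLS), the
#' sum-of-squares permutation test, split-half reproducibility, train-test
#' reliability, bootstrap stability, between-method comparison and
#' data-structure diagnostics, and optionally writes a `report.json` plus
#' per-stage TSV files. Sensitivity and post hoc reruns (row subsets, extra
#' covariate columns) are expressed through the config, not separate code
#' paths.
#'
#' @param config an [analysis_config()].
#' @param brain,behavior [data_block]s (or matrices).
#' @param covariates covariate data.frame (or `NULL`).
#' @param out_dir directory for the report files (created if needed);
#'   `NULL` returns the report without writing.
#' @return An object of class `latentlink_report` (a nested list; see the
#'   top-level names `config`, `singular_values`, `varexp`, `permutation`,
#'   `splithalf`, `traintest`, `bootstrap`, `comparison`, `diagnostics`).
#' @export
run_pipeline <- function(config, brain, behavior, covariates = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  n <- nrow(block_values(brain))
  idx <- resolve_subset(config$subset, covariates, n)
  brain <- subset_block_or_matrix(brain, idx)
  behavior <- subset_block_or_matrix(behavior, idx)
  covariates <- subset_covariates(covariates, idx)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ct <- config$correlation_type
  Xp <- stage("preprocess", prepare_block(brain, covariates, ct))
  Yp <- stage("preprocess", prepare_block(behavior, covariates, ct))
  cp <- stage("cross_products",
              build_cross_products(Xp$values, Yp$values, type = "pearson",
                                   eps = config$eps))

  models <- list()
  for (m in config$methods) {
    models[[m]] <- stage(paste0("fit_", m),
                         if (m == "cca") fit_cca(cp) else fit_pls(cp))
  }

  per_method <- function(fun_name, fun) {
    out <- list()
    for (m in config$methods) out[[m]] <- stage(paste(fun_name, m), fun(m))
    out
  }

  permutation <- if (config$n_perm > 0L) per_method("permutation", function(m) {
    permutation_test(Xp, Yp, method = m, B = config$n_perm,
                     seed = substream_seed(config$seed, paste0("perm_", m)),
                     type = "pearson", eps = config$eps, alpha = config$alpha,
                     keep_null = FALSE)
  }) else NULL

  splithalf <- if (config$n_splithalf > 0L) per_method("splithalf", function(m) {
    split_half(brain, behavior, covariates, method = m,
               iters = config$n_splithalf,
               seed = substream_seed(config$seed, paste0("split_", m)),
               correlation_type = ct, eps = config$eps,
               z_threshold = config$z_threshold)
  }) else NULL

  traintest <- if (config$n_traintest > 0L) per_method("traintest", function(m) {
    train_test(brain, behavior, covariates, method = m,
               iters = config$n_traintest,
               train_fraction = config$train_fraction,
               seed = substream_seed(config$seed, paste0("tt_", m)),
               correlation_type = ct, eps = config$eps,
               z_threshold = config$z_threshold)
  }) else NULL

  bootstrap <- if (config$n_boot > 0L) per_method("bootstrap", function(m) {
    bootstrap_stability(brain, behavior, covariates, method = m,
                        n_boot = config$n_boot,
                        seed = substream_seed(config$seed, paste0("boot_", m)),
                        correlation_type = ct, conf = config$ci_level,
                        eps = config$eps)
  }) else NULL

  comparison <- if (all(c("cca", "pls") %in% config$methods)) {
    stage("comparison", between_method_correlation(models$cca, models$pls))
  } else NULL

  diagnostics <- list(
    brain = stage("diagnostics", distribution_diagnostics(brain)),
    behavior = stage("diagnostics", distribution_diagnostics(behavior))
  )

  report <- structure(
    list(config = config,
         n = length(idx),
         models = models,
         singular_values = lapply(models, `[[`, "S"),
         varexp = lapply(models, `[[`, "varexp"),
         permutation = permutation,
         splithalf = splithalf,
         traintest = traintest,
         bootstrap = bootstrap,
         comparison = comparison,
         diagnostics = diagnostics),
    class = "latentlink_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.latentlink_report <- function(x, ...) {
  cat(sprintf("<latentlink_report: n = %d, methods = %s, %s correlations>\n",
              x$n, paste(x$config$methods, collapse = " + "),
              x$config$correlation_type))
  for (m in names(x$models)) {
    cat(sprintf("  %s LV1: s = %.3f (%.1f%% of squared spectrum)",
                toupper(m), x$singular_values[[m]][1],
                100 * x$varexp[[m]][1]))
    if (!is.null(x$permutation)) {
      cat(sprintf(", permutation p = %.4g", x$permutation[[m]]$p_values[1]))
    }
    cat("\n")
  }
  invisible(x)
}
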