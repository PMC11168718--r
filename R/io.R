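# TSV/JSON writers shared by run_pipeline() and the command-line interface.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

mat_to_df <- function(m, rowlab = "variable") {
  df <- data.frame(rownames(m) %||% sprintf("v%d", seq_len(nrow(m))), m,
                   row.names = NULL, check.names = FALSE)
  names(df)[1] <- rowlab
  df
}

#' Read a participant-keyed TSV/CSV table
#'
#' Delimiter is inferred from the extension (`.csv` vs anything else = tab).
#'
#' @param path file path.
#' @param id_column name of the participant-ID column (default
#'   `participant_id`; used as rownames when present).
#' @return data.frame.
#' @export
read_table_file <- function(path, id_column = "participant_id") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = TRUE, check.names = FALSE)
  if (id_column %in% names(df)) df[[id_column]] <- as.character(df[[id_column]])
  df
}

#' Read a data block from a TSV/CSV file
#'
#' @inheritParams read_table_file
#' @param role block role, `"brain"` or `"behavior"`.
#' @return A [data_block].
#' @export
read_block_file <- function(path, role = c("brain", "behavior"),
                            id_column = "participant_id") {
  role <- match.arg(role)
  df <- read_table_file(path, id_column)
  ids <- if (id_column %in% names(df)) df[[id_column]] else NULL
  m <- as.matrix(df[, setdiff(names(df), id_column), drop = FALSE])
  storage.mode(m) <- "double"
  data_block(m, participant_ids = ids, role = role)
}

#' Write a synthetic study to disk
#'
#' Writes `brain.tsv`, `behavior.tsv`, `covariates.tsv` (participant-keyed)
#' and `truth.json` (planted loadings and effect sizes) into `dir`.
#'
#' @param study a [generate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  block_df <- function(b) {
    data.frame(participant_id = b$participant_ids, b$values,
               row.names = NULL, check.names = FALSE)
  }
  write_tsv(block_df(study$brain), file.path(dir, "brain.tsv"))
  write_tsv(block_df(study$behavior), file.path(dir, "behavior.tsv"))
  write_tsv(study$covariates, file.path(dir, "covariates.tsv"))
  truth <- study$truth
  truth$covariate_slopes <- lapply(truth$covariate_slopes, unname)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a fitted model to disk
#'
#' Writes `singular_values.tsv`, `loadings_brain.tsv`,
#' `loadings_behavior.tsv` and `model.json` into `dir` (names prefixed with
#' the method when `prefix = TRUE`).
#'
#' @param model a `latent_model`.
#' @param dir output directory.
#' @param prefix prefix file names with the method name.
#' @return `dir`, invisibly.
#' @export
write_model <- function(model, dir, prefix = FALSE) {
  stopifnot(inherits(model, "latent_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pre <- if (prefix) paste0(model$method, "_") else ""
  load <- model_loadings(model)
  write_tsv(data.frame(lv = seq_along(model$S), singular_value = model$S,
                       varexp = model$varexp, row.names = NULL),
            file.path(dir, paste0(pre, "singular_values.tsv")))
  write_tsv(mat_to_df(load$x), file.path(dir, paste0(pre, "loadings_brain.tsv")))
  write_tsv(mat_to_df(load$y), file.path(dir, paste0(pre, "loadings_behavior.tsv")))
  jsonlite::write_json(
    list(method = model$method, correlation_type = model$correlation_type,
         n = model$n, L = model$L, singular_values = model$S,
         varexp = model$varexp),
    file.path(dir, paste0(pre, "model.json")), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

report_to_list <- function(report) {
  cfg <- report$config
  cfg$subset <- if (is.null(cfg$subset)) NULL else "custom"
  zdf <- function(d) d[, c("lv", "mean", "sd", "z", "significant")]
  out <- list(
    config = unclass(cfg),
    n = report$n,
    singular_values = report$singular_values,
    varexp = report$varexp
  )
  if (!is.null(report$permutation)) {
    out$permutation <- lapply(report$permutation, function(p) {
      list(observed_T = p$observed_T, p_values = p$p_values,
           significant = p$significant, B = p$B, alpha = p$alpha)
    })
  }
  if (!is.null(report$splithalf)) {
    out$splithalf <- lapply(report$splithalf, function(s) {
      list(z_U = zdf(s$z_U), z_V = zdf(s$z_V), iters = s$iters,
           skipped = s$skipped, alignment_mode = s$alignment_mode)
    })
  }
  if (!is.null(report$traintest)) {
    out$traintest <- lapply(report$traintest, function(t) {
      list(z = zdf(t$z), train_fraction = t$train_fraction,
           iters = t$iters, skipped = t$skipped)
    })
  }
  if (!is.null(report$bootstrap)) {
    out$bootstrap <- lapply(report$bootstrap, function(b) {
      list(n_boot = b$n_boot, conf = b$conf, redrawn = b$redrawn,
           n_stable_U = unname(colSums(b$stable_U)),
           n_stable_V = unname(colSums(b$stable_V)))
    })
  }
  if (!is.null(report$comparison)) {
    out$comparison <- list(
      r_U_cross = unname(report$comparison$r_U_cross),
      r_V_cross = unname(report$comparison$r_V_cross),
      diagonal_U = unname(diag(report$comparison$r_U_cross)),
      diagonal_V = unname(diag(report$comparison$r_V_cross)))
  }
  out$diagnostics <- lapply(report$diagnostics, function(d) {
    list(columns = d$columns, condition_number = d$condition_number,
         pca_components_for_threshold = d$pca_components_for_threshold,
         threshold = d$threshold)
  })
  out
}

bootstrap_ci_frame <- function(boot) {
  one <- function(ci, stable, block) {
    lo <- ci$lo; hi <- ci$hi
    data.frame(
      block = block,
      lv = rep(seq_len(ncol(lo)), each = nrow(lo)),
      variable = rep(rownames(lo) %||% sprintf("v%d", seq_len(nrow(lo))),
                     ncol(lo)),
      lo = as.numeric(lo), hi = as.numeric(hi),
      stable = as.logical(stable), row.names = NULL)
  }
  rbind(one(boot$ci_U, boot$stable_U, "brain"),
        one(boot$ci_V, boot$stable_V, "behavior"))
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` plus per-stage TSV side files (singular values and
#' loadings per method, split-half correlation distributions, predicted
#' singular values, bootstrap CIs).
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "latentlink_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_to_list(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (m in names(report$models)) {
    write_model(report$models[[m]], dir, prefix = TRUE)
  }
  for (m in names(report$splithalf %||% list())) {
    s <- report$splithalf[[m]]
    write_tsv(data.frame(s$r_U, check.names = FALSE),
              file.path(dir, paste0(m, "_splithalf_r_brain.tsv")))
    write_tsv(data.frame(s$r_V, check.names = FALSE),
              file.path(dir, paste0(m, "_splithalf_r_behavior.tsv")))
  }
  for (m in names(report$traintest %||% list())) {
    write_tsv(data.frame(report$traintest[[m]]$s_pred, check.names = FALSE),
              file.path(dir, paste0(m, "_traintest_spred.tsv")))
  }
  for (m in names(report$bootstrap %||% list())) {
    write_tsv(bootstrap_ci_frame(report$bootstrap[[m]]),
              file.path(dir, paste0(m, "_bootstrap_ci.tsv")))
  }
  invisible(dir)
}
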