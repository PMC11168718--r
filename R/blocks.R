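#' Participant-by-variable data block
#'
#' Container for one side of a two-block analysis: an `n x p` numeric matrix
#' of measurements (e.g., cortical thickness for 68 regions, or behavioral
#' subscale scores), ordered participant identifiers, variable names, and a
#' role tag. Both blocks entering an analysis must share the same participant
#' order; [residualize()] and the resampling routines check this.
#'
#' @param values numeric matrix (participants in rows, variables in columns).
#' @param participant_ids character vector of row identifiers; defaults to
#'   the rownames of `values` or `sub0001`-style labels.
#' @param variable_names column labels; defaults to colnames of `values`.
#' @param role `"brain"` or `"behavior"`.
#'
#' @return An object of class `data_block` with fields `values`,
#'   `participant_ids`, `variable_names`, `role`.
#' @examples
#' b <- data_block(matrix(rnorm(20), 5, 4), role = "brain")
#' dim(b$values)
#' @export
data_block <- function(values,
                       participant_ids = NULL,
                       variable_names = NULL,
                       role = c("brain", "behavior")) {
  role <- match.arg(role)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  n <- nrow(values)
  p <- ncol(values)
  if (is.null(participant_ids)) {
    participant_ids <- rownames(values) %||% sprintf("sub%04d", seq_len(n))
  }
  if (is.null(variable_names)) {
    variable_names <- colnames(values) %||%
      sprintf("%s%02d", substr(role, 1, 3), seq_len(p))
  }
  if (length(participant_ids) != n) {
    stop("participant_ids length must equal nrow(values)", call. = FALSE)
  }
  if (length(variable_names) != p) {
    stop("variable_names length must equal ncol(values)", call. = FALSE)
  }
  if (anyNA(values)) stop("data_block values must not contain NA", call. = FALSE)
  dimnames(values) <- list(participant_ids, variable_names)
  if (n < p) {
    warning(sprintf("block has fewer participants (%d) than variables (%d)", n, p),
            call. = FALSE)
  }
  structure(
    list(values = values, participant_ids = participant_ids,
         variable_names = variable_names, role = role),
    class = "data_block"
  )
}

#' @export
print.data_block <- function(x, ...) {
  cat(sprintf("<data_block: %s, %d participants x %d variables>\n",
              x$role, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.data_block <- function(x) dim(x$values)

# Row subset preserving class and metadata (used by every resampling loop).
subset_block <- function(block, idx) {
  data_block(block$values[idx, , drop = FALSE],
             participant_ids = make.unique(block$participant_ids[idx]),
             variable_names = block$variable_names,
             role = block$role)
}

subset_covariates <- function(covariates, idx) {
  if (is.null(covariates)) return(NULL)
  out <- covariates[idx, , drop = FALSE]
  if (!is.null(out$participant_id)) {
    # keep IDs in lockstep with subset_block() under resampling with
    # replacement
    out$participant_id <- make.unique(as.character(out$participant_id))
  }
  rownames(out) <- NULL
  out
}
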