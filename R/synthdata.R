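#' Configuration for the synthetic two-block study generator
#'
#' Describes a simulated cohort in which a brain block and a behavior block
#' share `n_latent` planted latent variables of known strength, on top of
#' equicorrelated within-block noise and linear nuisance-covariate effects
#' (age, sex, head size, site, scanner). The defaults emulate a large
#' multi-site pediatric cohort: 68 cortical-thickness-like brain columns,
#' 11 right-skewed zero-inflated ordinal behavior columns (checklist
#' subscale scores), 21 sites nested in 5 scanner models.
#'
#' @param n_participants number of participants.
#' @param n_brain number of brain variables (default 68).
#' @param n_behavior number of behavior variables (default 11).
#' @param n_latent number of planted latent variable pairs.
#' @param effect_sizes per-LV cross-block correlation along the planted
#'   directions, non-increasing, each in `[0, 1)`. Recycled/truncated to
#'   `n_latent`.
#' @param within_block_rho_brain,within_block_rho_behavior equicorrelation of
#'   the noise within each block, in `[0, 1)`.
#' @param zero_inflation probability mass at zero per behavior column when
#'   `behavior_family = "ordinal_zero_inflated"`.
#' @param max_score ordinal ceiling of the behavior scores (scores take
#'   values in `{0, ..., max_score}`).
#' @param behavior_family `"ordinal_zero_inflated"` (checklist-like) or
#'   `"gaussian"` (performance-score-like).
#' @param covariate_effect_scale standard deviation of the standardized
#'   covariate slopes planted into both blocks.
#' @param n_sites,n_scanners numbers of acquisition sites and scanner models;
#'   each site uses exactly one scanner model.
#' @param seed master seed; spawns independent named substreams for
#'   covariates, latent scores, loadings, noise and slopes.
#'
#' @return An object of class `synth_config`.
#' @seealso [generate_study()]
#' @export
synth_config <- function(n_participants,
                         n_brain = 68L,
                         n_behavior = 11L,
                         n_latent = 1L,
                         effect_sizes = 0.3,
                         within_block_rho_brain = 0.3,
                         within_block_rho_behavior = 0.3,
                         zero_inflation = 0.4,
                         max_score = 20L,
                         behavior_family = c("ordinal_zero_inflated", "gaussian"),
                         covariate_effect_scale = 0.1,
                         n_sites = 21L,
                         n_scanners = 5L,
                         seed = 1L) {
  behavior_family <- match.arg(behavior_family)
  n_participants <- check_count(n_participants, "n_participants", min = 2L)
  n_brain <- check_count(n_brain, "n_brain")
  n_behavior <- check_count(n_behavior, "n_behavior")
  n_latent <- check_count(n_latent, "n_latent", min = 0L)
  n_sites <- check_count(n_sites, "n_sites")
  n_scanners <- check_count(n_scanners, "n_scanners")
  max_score <- check_count(max_score, "max_score")
  check_probability(zero_inflation, "zero_inflation")
  check_probability(within_block_rho_brain, "within_block_rho_brain")
  check_probability(within_block_rho_behavior, "within_block_rho_behavior")
  if (within_block_rho_brain >= 1 || within_block_rho_behavior >= 1) {
    stop("within-block equicorrelation must be < 1", call. = FALSE)
  }
  if (n_latent > min(n_brain, n_behavior)) {
    stop("n_latent must not exceed min(n_brain, n_behavior)", call. = FALSE)
  }
  effect_sizes <- rep_len(as.numeric(effect_sizes), max(n_latent, 1L))
  effect_sizes <- effect_sizes[seq_len(n_latent)]
  if (any(effect_sizes < 0) || any(effect_sizes >= 1)) {
    stop("effect sizes are cross-block correlations and must lie in [0, 1)",
         call. = FALSE)
  }
  if (is.unsorted(rev(effect_sizes), strictly = FALSE) && n_latent > 1L) {
    stop("effect_sizes must be non-increasing", call. = FALSE)
  }
  structure(
    list(n_participants = n_participants, n_brain = n_brain,
         n_behavior = n_behavior, n_latent = n_latent,
         effect_sizes = effect_sizes,
         within_block_rho_brain = within_block_rho_brain,
         within_block_rho_behavior = within_block_rho_behavior,
         zero_inflation = zero_inflation, max_score = max_score,
         behavior_family = behavior_family,
         covariate_effect_scale = covariate_effect_scale,
         n_sites = n_sites, n_scanners = n_scanners,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Simulate the nuisance covariate table
#'
#' Draws per-participant age (months, uniform over a 9-11-year-equivalent
#' range), binary sex assigned at birth, acquisition site, MRI scanner model
#' and total head size. Sites are nested in scanners: every site uses exactly
#' one scanner model, as in a harmonized multi-site protocol.
#'
#' @param n number of participants (>= 2).
#' @param n_sites number of sites (default 21).
#' @param n_scanners number of scanner models (default 5).
#' @param seed integer seed.
#'
#' @return A data.frame with columns `participant_id`, `age`, `sex` (factor
#'   F/M), `site` (factor), `scanner` (factor), `head_size`.
#' @examples
#' cov <- generate_covariates(200, n_sites = 21, n_scanners = 5, seed = 1)
#' table(cov$scanner)
#' @export
generate_covariates <- function(n, n_sites = 21L, n_scanners = 5L, seed = 1L) {
  n <- check_count(n, "n", min = 2L)
  if (n_sites < 1L || n_scanners < 1L) {
    stop("n_sites and n_scanners must be >= 1", call. = FALSE)
  }
  n_sites <- check_count(n_sites, "n_sites")
  n_scanners <- check_count(n_scanners, "n_scanners")
  set_substream(seed, "covariates")
  site <- sample.int(n_sites, n, replace = TRUE)
  scanner_of_site <- ((seq_len(n_sites) - 1L) %% n_scanners) + 1L
  scanner <- scanner_of_site[site]
  sex <- sample(c(0L, 1L), n, replace = TRUE)
  age <- round(stats::runif(n, min = 107, max = 133), 1)
  head_size <- stats::rnorm(n, mean = 1400 + 60 * sex, sd = 100)
  data.frame(
    participant_id = sprintf("sub%04d", seq_len(n)),
    age = age,
    sex = factor(ifelse(sex == 1L, "M", "F"), levels = c("F", "M")),
    site = factor(sprintf("site%02d", site),
                  levels = sprintf("site%02d", seq_len(n_sites))),
    scanner = factor(sprintf("scanner%d", scanner),
                     levels = sprintf("scanner%d", seq_len(n_scanners))),
    head_size = head_size,
    stringsAsFactors = FALSE
  )
}

# Random orthonormal loading matrix (p x L), deterministic given the RNG
# state; column signs fixed so the largest-|element| entry is positive.
random_orthonormal <- function(p, L) {
  if (L == 0L) return(matrix(numeric(0), p, 0L))
  Q <- qr.Q(qr(matrix(stats::rnorm(p * max(L, 1L)), p, L)))[, seq_len(L), drop = FALSE]
  for (l in seq_len(L)) {
    j <- which.max(abs(Q[, l]))
    if (Q[j, l] < 0) Q[, l] <- -Q[, l]
  }
  Q
}

# Equicorrelated noise: every pair of columns within the block correlates at
# rho, unit marginal variance.
equicorrelated_noise <- function(n, p, rho) {
  e <- matrix(stats::rnorm(n * p), n, p)
  if (rho <= 0) return(e)
  g <- stats::rnorm(n)
  sqrt(rho) * matrix(g, n, p) + sqrt(1 - rho) * e
}

# Design matrix of standardized covariate terms used when planting nuisance
# effects (site/scanner enter as per-level shifts).
covariate_effect_design <- function(covariates) {
  cbind(
    age = as.numeric(scale(covariates$age)),
    sex = as.numeric(covariates$sex == "M") - mean(covariates$sex == "M"),
    head_size = as.numeric(scale(covariates$head_size)),
    stats::model.matrix(~ site + scanner - 1, data = covariates)
  )
}

#' Generate a paired brain/behavior study with planted latent structure
#'
#' Builds both blocks from shared standard-normal latent scores `z_l`:
#' `X = sum_l d_l z_l a_l' + covariate effects + noise`, and likewise for the
#' behavior block with loadings `b_l`, where `a_l`, `b_l` are random
#' orthonormal columns and `d_l = sqrt(r_l / (1 - r_l))` is calibrated so the
#' population correlation between the planted composites `X a_l` and `Y b_l`
#' equals the configured effect size `r_l` when the within-block noise is
#' uncorrelated. Noise is equicorrelated within each block; covariates enter
#' as linear effects with random standardized slopes. When
#' `behavior_family = "ordinal_zero_inflated"`, the continuous behavior
#' matrix is passed through [apply_ordinal_copula()], producing right-skewed
#' zero-inflated integer scores while preserving ranks.
#'
#' @param config a [synth_config()].
#' @return An object of class `synthetic_study`: fields `brain`, `behavior`
#'   ([data_block]s), `covariates` (data.frame), `truth` (planted loadings,
#'   effect sizes, covariate slopes) and `config`.
#' @examples
#' st <- generate_study(synth_config(200, n_brain = 10, n_behavior = 5,
#'                                   effect_sizes = 0.5, seed = 7))
#' st$truth$effect_sizes
#' @export
generate_study <- function(config) {
  if (!inherits(config, "synth_config")) {
    stop("`config` must be a synth_config", call. = FALSE)
  }
  n <- config$n_participants
  p <- config$n_brain
  q <- config$n_behavior
  L <- config$n_latent

  covariates <- generate_covariates(n, config$n_sites, config$n_scanners,
                                    seed = config$seed)

  set_substream(config$seed, "loadings")
  A <- random_orthonormal(p, L)
  B <- random_orthonormal(q, L)

  set_substream(config$seed, "latents")
  Z <- matrix(stats::rnorm(n * max(L, 1L)), n)[, seq_len(L), drop = FALSE]

  d <- sqrt(config$effect_sizes / (1 - config$effect_sizes))

  set_substream(config$seed, "noise")
  Ex <- equicorrelated_noise(n, p, config$within_block_rho_brain)
  Ey <- equicorrelated_noise(n, q, config$within_block_rho_behavior)

  M <- covariate_effect_design(covariates)
  set_substream(config$seed, "slopes")
  Gx <- matrix(stats::rnorm(ncol(M) * p, sd = config$covariate_effect_scale),
               ncol(M), p, dimnames = list(colnames(M), NULL))
  Gy <- matrix(stats::rnorm(ncol(M) * q, sd = config$covariate_effect_scale),
               ncol(M), q, dimnames = list(colnames(M), NULL))

  signal_x <- if (L > 0L) Z %*% (t(A) * d) else 0
  signal_y <- if (L > 0L) Z %*% (t(B) * d) else 0
  X <- signal_x + M %*% Gx + Ex
  Y_cont <- signal_y + M %*% Gy + Ey

  if (config$behavior_family == "ordinal_zero_inflated") {
    Y <- apply_ordinal_copula(Y_cont, config$zero_inflation, config$max_score,
                              seed = substream_seed(config$seed, "copula"))
  } else {
    Y <- Y_cont
  }

  ids <- covariates$participant_id
  brain <- data_block(X, participant_ids = ids,
                      variable_names = sprintf("thick%02d", seq_len(p)),
                      role = "brain")
  behavior <- data_block(Y, participant_ids = ids,
                         variable_names = sprintf("score%02d", seq_len(q)),
                         role = "behavior")
  truth <- list(
    true_brain_loadings = A,
    true_behavior_loadings = B,
    effect_sizes = config$effect_sizes,
    latent_strengths = d,
    covariate_slopes = list(brain = Gx, behavior = Gy)
  )
  structure(
    list(brain = brain, behavior = behavior, covariates = covariates,
         truth = truth, config = config),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study: n = %d, brain %d, behavior %d (%s), %d planted LV(s)>\n",
    x$config$n_participants, x$config$n_brain, x$config$n_behavior,
    x$config$behavior_family, x$config$n_latent))
  if (x$config$n_latent > 0L) {
    cat("  effect sizes:", paste(format(x$config$effect_sizes), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Map continuous scores to zero-inflated right-skewed ordinal scores
#'
#' Per column: entries below the `zero_inflation` empirical quantile map to
#' zero; the rest are binned into `{1, ..., max_score}` by a monotone
#' quantile map whose target marginal decays geometrically (mass
#' `(1 - decay)^(k-1)`), reproducing checklist-style right skew. The map is
#' rank-based, so the relative order of non-zero entries within a column is
#' never changed.
#'
#' @param y_continuous numeric matrix (or vector) of latent continuous scores.
#' @param zero_inflation target proportion of zeros per column, in `[0, 1]`.
#' @param max_score ordinal ceiling (>= 1).
#' @param seed reserved for future stochastic tie-breaking; the quantile map
#'   itself is deterministic (ties share a bin), so the argument currently
#'   has no effect.
#' @param decay geometric decay rate of the non-zero target marginal.
#' @return Integer matrix of the same shape with values in `0:max_score`.
#' @examples
#' y <- matrix(rnorm(300), 100, 3)
#' o <- apply_ordinal_copula(y, zero_inflation = 0.4, max_score = 5)
#' colMeans(o == 0)
#' @export
apply_ordinal_copula <- function(y_continuous, zero_inflation, max_score,
                                 seed = NULL, decay = 0.3) {
  check_probability(zero_inflation, "zero_inflation")
  max_score <- check_count(max_score, "max_score")
  y <- as.matrix(y_continuous)
  n <- nrow(y)
  if (zero_inflation >= 1) {
    warning("zero_inflation = 1: all entries map to 0 (degenerate column)",
            call. = FALSE)
    return(matrix(0L, n, ncol(y), dimnames = dimnames(y)))
  }
  w <- (1 - decay)^(seq_len(max_score) - 1L)
  # bin upper edges on the uniform scale, spanning (zero_inflation, 1]
  edges <- zero_inflation + (1 - zero_inflation) * cumsum(w) / sum(w)
  out <- apply(y, 2L, function(col) {
    u <- (rank(col, ties.method = "average") - 0.5) / n
    s <- findInterval(u, c(zero_inflation, edges[-max_score]), left.open = TRUE)
    as.integer(s)
  })
  out <- matrix(as.integer(out), n, ncol(y), dimnames = dimnames(y))
  out
}
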