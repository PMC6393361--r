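# Module activity scoring: z-transform of node p-values, sqrt(k)-normalized
# aggregation, and Monte-Carlo background calibration.

#' Transform a p-value to a standard-normal z-score
#'
#' `z = qnorm(1 - p)`, with `p` clamped into `[clamp_epsilon,
#' 1 - clamp_epsilon]` first so that extreme p-values map to large but finite
#' z. Monotone decreasing in p; `p = 0.5` maps to 0.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param clamp_epsilon clamp bound in `(0, 0.5)`; default `1e-12`.
#' @return Numeric vector of z-scores.
#' @export
z_from_p <- function(p, clamp_epsilon = 1e-12) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("validation error: p-values outside [0, 1]", call. = FALSE)
  stopifnot(clamp_epsilon > 0, clamp_epsilon < 0.5)
  stats::qnorm(1 - pmin(pmax(p, clamp_epsilon), 1 - clamp_epsilon))
}

#' Aggregate node z-scores into a module activity score
#'
#' `zA = sum(z) / sqrt(k)` for `k` scored nodes, so that under independent
#' standard-normal node scores the aggregate of any random set is again
#' standard normal.
#'
#' @param zs numeric vector of node z-scores (non-empty).
#' @return The aggregate score `zA`.
#' @export
aggregate_score <- function(zs) {
  if (!length(zs))
    stop("validation error: aggregate_score of an empty node set",
         call. = FALSE)
  sum(zs) / sqrt(length(zs))
}

#' Node z-scores from an annotated network
#'
#' Extracts the p-values annotated under one contrast and z-transforms them.
#' Nodes without a measured p-value (interaction nodes, metabolites,
#' complexes, unmeasured genes) are absent from the result: they are never
#' imputed and contribute nothing to module scores.
#'
#' @param network an annotated `unified_network`.
#' @param contrast contrast label to use; default: the single annotated
#'   contrast (error if several).
#' @param clamp_epsilon passed to [z_from_p()].
#' @return Named numeric vector of z-scores (names are node ids), class
#'   `node_zscores`.
#' @export
node_scores <- function(network, contrast = NULL, clamp_epsilon = 1e-12) {
  expr <- network$expr
  if (!nrow(expr))
    stop("network carries no expression annotation; run annotate_network()",
         call. = FALSE)
  if (is.null(contrast)) {
    contrasts <- unique(expr$contrast)
    if (length(contrasts) > 1L)
      stop("several contrasts annotated (", paste(contrasts, collapse = ", "),
           "); pick one", call. = FALSE)
    contrast <- contrasts
  }
  expr <- expr[expr$contrast == contrast, , drop = FALSE]
  if (!nrow(expr)) stop("no annotation under contrast ", contrast,
                        call. = FALSE)
  z <- z_from_p(expr$pvalue, clamp_epsilon)
  structure(stats::setNames(z, expr$node_id), class = "node_zscores",
            contrast = contrast)
}

#' Monte-Carlo calibration of the aggregate score
#'
#' For each module size `k = 1..k_max`, draws `n_draws` uniform random
#' size-`k` subsets of the scored nodes (connectivity is not required) and
#' records the sample mean and standard deviation of their aggregate scores.
#' The corrected module score standardizes the raw aggregate against this
#' background, removing the size bias of `zA` under the empirical score
#' distribution.
#'
#' @param scores a [node_scores()] vector (or any named numeric of z-scores).
#' @param k_max largest module size to calibrate (at most the number of
#'   scored nodes).
#' @param n_draws Monte-Carlo draws per size; default 2000, minimum 100.
#' @param seed integer seed; calibration is reproducible given the seed.
#' @return A `calibration_table`: data frame with columns `k`, `mu`, `sigma`
#'   plus attributes `n_draws`, `seed`.
#' @export
calibrate <- function(scores, k_max, n_draws = 2000L, seed) {
  z <- as.numeric(scores)
  if (k_max < 1L || k_max > length(z))
    stop("validation error: k_max must be in 1..number of scored nodes",
         call. = FALSE)
  if (n_draws < 100L)
    stop("validation error: n_draws must be at least 100", call. = FALSE)
  if (missing(seed)) stop("calibrate() requires an explicit seed",
                          call. = FALSE)
  # one uniform random ordered k_max-subset per draw; its length-k prefix is
  # a uniform random k-subset, so all sizes share the draws
  perm <- with_seed(seed, vapply(seq_len(n_draws),
                                 function(i) sample.int(length(z), k_max),
                                 integer(k_max)))
  zmat <- matrix(z[perm], nrow = k_max)
  cs <- if (k_max == 1L) zmat else apply(zmat, 2, cumsum)
  agg <- cs / sqrt(seq_len(k_max))
  mu <- rowMeans(agg)
  sigma <- apply(agg, 1, stats::sd)
  structure(data.frame(k = seq_len(k_max), mu = mu, sigma = sigma),
            n_draws = n_draws, seed = seed,
            class = c("calibration_table", "data.frame"))
}

SIGMA_FLOOR <- 1e-9

#' Background-corrected module score
#'
#' `sA = (zA - mu_k) / max(sigma_k, sigma_floor)` where `k` is the number of
#' scored nodes in the module and `zA` aggregates their z-scores; unscored
#' members (interaction nodes, unmeasured molecules) contribute nothing.
#'
#' @param module_nodes character vector of member node ids.
#' @param scores [node_scores()] vector.
#' @param calib [calibrate()] table covering the module's scored size.
#' @param sigma_floor lower bound guarding degenerate calibrations.
#' @return The corrected score `sA`.
#' @export
corrected_score <- function(module_nodes, scores, calib,
                            sigma_floor = SIGMA_FLOOR) {
  zs <- scores[names(scores) %in% module_nodes]
  k <- length(zs)
  if (k == 0L)
    stop("validation error: module contains no scored node", call. = FALSE)
  if (k > max(calib$k))
    stop("validation error: module scored size ", k,
         " exceeds calibrated k_max ", max(calib$k), call. = FALSE)
  zA <- aggregate_score(as.numeric(zs))
  (zA - calib$mu[k]) / max(calib$sigma[k], sigma_floor)
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive `n` child seeds from one master seed (all below 2^31).
derive_seeds <- function(master, n) {
  with_seed(master, sample.int(.Machine$integer.max - 1L, n))
}
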