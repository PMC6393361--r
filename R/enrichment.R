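# Gene-set overrepresentation: hypergeometric Z-score, label-permutation
# p-values, and the standard result filters.

#' Overrepresentation Z-score
#'
#' Standardized deviation of the changed-gene count `r` in a set from its
#' hypergeometric expectation given `N` measured background genes of which
#' `R` are changed and `n` fall in the set:
#' `z = (r - n*R/N) / sqrt(n * (R/N) * (1 - R/N) * (1 - (n-1)/(N-1)))`.
#'
#' @param N measured genes in the background.
#' @param R changed genes in the background.
#' @param n measured genes in the set.
#' @param r changed genes in the set.
#' @return The Z-score, or `NA` when the variance is undefined (`n = 0`, or
#'   `R` equal to 0 or `N`) — a "not evaluable" marker, never a number.
#' @export
zscore <- function(N, R, n, r) {
  stopifnot(N >= 2, R >= 0, R <= N, n >= 0, n <= N, r >= 0)
  if (any(r > pmin(n, R)))
    stop("validation error: r exceeds min(n, R)", call. = FALSE)
  p <- R / N
  varr <- n * p * (1 - p) * (1 - (n - 1) / (N - 1))
  if (n == 0 || R == 0 || R == N || varr <= 0)
    return(rep(NA_real_, length(r)))
  (r - n * p) / sqrt(varr)
}

#' Read gene sets from a GMT file
#'
#' One set per line: set id, description, then member ids, tab-separated.
#'
#' @param path GMT file.
#' @return Named list of class `gene_sets`; each element is a character
#'   vector of member ids with a `name` attribute (the description field).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("GMT parse error: line ", bad[1],
         " has fewer than 3 fields", call. = FALSE)
  ids <- vapply(fields, `[`, "", 1)
  if (anyDuplicated(ids))
    stop("GMT parse error: duplicate set id", call. = FALSE)
  sets <- lapply(fields, function(f) {
    members <- unique(f[-(1:2)])
    attr(members, "name") <- f[2]
    members
  })
  structure(stats::setNames(sets, ids), class = "gene_sets")
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors (optionally with `name`
#'   attributes), as produced by [read_gmt()].
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    nm <- attr(sets[[i]], "name") %||% names(sets)[i]
    paste(c(names(sets)[i], nm, as.character(sets[[i]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
}

# Shared permutation machinery: n_perm random R-subsets of 1..N as an
# R x n_perm index matrix.
permutation_draws <- function(N, R, n_perm, seed) {
  with_seed(seed, {
    matrix(vapply(seq_len(n_perm), function(i) sample.int(N, R),
                  integer(R)), nrow = R)
  })
}

#' Label-permutation p-value for one gene set
#'
#' Draws `n_perm` uniform random `R`-subsets of the measured background as
#' pseudo changed-gene sets, recomputes the Z-score for each, and returns the
#' add-one estimator `(1 + #\{z* >= z\}) / (n_perm + 1)`.
#'
#' @param set character vector of member gene ids.
#' @param background character vector of measured gene ids.
#' @param R number of changed genes to permute.
#' @param n_perm number of permutations (default 2000, minimum 100).
#' @param seed integer seed.
#' @param changed optional: the observed changed-gene ids (defaults to the
#'   first `R` of `background`, only sensible when supplied).
#' @return List with `perm_p`, `z_obs`, `n`, `r`; `perm_p` is `NA` when the
#'   set shares no member with the background.
#' @export
permutation_pvalue <- function(set, background, R, n_perm = 2000L, seed,
                               changed = NULL) {
  if (n_perm < 100L)
    stop("validation error: n_perm must be at least 100", call. = FALSE)
  if (R > length(background))
    stop("validation error: R exceeds background size", call. = FALSE)
  N <- length(background)
  member <- background %in% set
  n <- sum(member)
  if (n == 0L)
    return(list(perm_p = NA_real_, z_obs = NA_real_, n = 0L, r = NA_integer_))
  if (is.null(changed)) changed <- background[seq_len(R)]
  r <- sum(background %in% set & background %in% changed)
  z_obs <- zscore(N, R, n, r)
  draws <- permutation_draws(N, R, n_perm, seed)
  r_star <- colSums(matrix(member[draws], nrow = R))
  z_star <- zscore(N, R, n, r_star)
  perm_p <- if (is.na(z_obs)) NA_real_ else
    (1 + sum(z_star >= z_obs, na.rm = TRUE)) / (n_perm + 1)
  list(perm_p = perm_p, z_obs = z_obs, n = n, r = r)
}

#' Run overrepresentation analysis over a gene-set collection
#'
#' The background is the measured genes of `table`; changed genes are those
#' selected by `criterion`. Per set, membership is intersected with the
#' background before counting (unmeasured members are invisible). One shared
#' stream of `n_perm` permuted changed-gene sets (uniform `R`-subsets of the
#' background) serves all sets.
#'
#' @param sets a `gene_sets` list (see [read_gmt()]) or named list of
#'   character vectors.
#' @param table a `gene_stat_table`.
#' @param criterion significance criterion (string or [parse_criterion()]).
#' @param n_perm number of permutations (default 2000).
#' @param seed integer seed.
#' @return Data frame of class `enrichment_result` with columns `set_id`,
#'   `name`, `N`, `R`, `n`, `r`, `z`, `perm_p`, sorted by `z` descending
#'   (not-evaluable rows last).
#' @export
run_enrichment <- function(sets, table, criterion, n_perm = 2000L, seed) {
  if (!nrow(table)) stop("validation error: empty gene table", call. = FALSE)
  if (n_perm < 100L)
    stop("validation error: n_perm must be at least 100", call. = FALSE)
  background <- table$gene_id
  N <- length(background)
  changed <- evaluate_criterion(criterion, table)
  R <- length(changed)
  is_changed <- background %in% changed
  draws <- permutation_draws(N, max(R, 1L), n_perm, seed)
  rows <- lapply(seq_along(sets), function(i) {
    member <- background %in% sets[[i]]
    n <- sum(member)
    r <- sum(member & is_changed)
    z <- if (R == 0L) NA_real_ else zscore(N, R, n, r)
    perm_p <- if (is.na(z)) NA_real_ else {
      r_star <- colSums(matrix(member[draws], nrow = R))
      z_star <- zscore(N, R, n, r_star)
      (1 + sum(z_star >= z, na.rm = TRUE)) / (n_perm + 1)
    }
    data.frame(set_id = names(sets)[i],
               name = attr(sets[[i]], "name") %||% names(sets)[i],
               N = N, R = R, n = n, r = r, z = z, perm_p = perm_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$z, out$set_id, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Filter enrichment results
#'
#' Keeps rows with `z > z_min`, `perm_p < p_max` and at least `min_changed`
#' changed genes. The defaults are the conventional overrepresentation
#' filters (Z > 1.96, permuted p < 0.05, at least five changed genes); a
#' lenient screen uses `min_changed = 3`.
#'
#' @param rows an `enrichment_result`.
#' @param z_min minimum Z-score (exclusive; default 1.96).
#' @param p_max maximum permutation p-value (exclusive; default 0.05).
#' @param min_changed minimum changed genes in the set (inclusive;
#'   default 5).
#' @return The kept rows, same class.
#' @export
filter_results <- function(rows, z_min = 1.96, p_max = 0.05,
                           min_changed = 5L) {
  keep <- !is.na(rows$z) & !is.na(rows$perm_p) &
    rows$z > z_min & rows$perm_p < p_max & rows$r >= min_changed
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment over %d gene set(s); background N = %s, changed R = %s\n",
              nrow(x), if (nrow(x)) x$N[1] else "-",
              if (nrow(x)) x$R[1] else "-"))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("  ... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}
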