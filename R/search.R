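# Active-module discovery: seeded greedy expansion over the bipartite
# network, maximizing the background-corrected aggregate score, followed by
# overlap-filtered selection of the top modules.

#' Search parameters for active-module discovery
#'
#' @param n_modules number of modules to keep after overlap filtering
#'   (default 5).
#' @param overlap_threshold maximum allowed overlap between two selected
#'   modules, in `[0, 1]` (default 0.8).
#' @param search_depth search depth in biological steps; one step is a
#'   gene -> interaction -> gene hop, i.e. two edges of the bipartite graph,
#'   so candidates are scored nodes within `2 * search_depth` graph hops of
#'   the growing module (default 2).
#' @param max_module_scored cap on the number of scored nodes per module
#'   (default 30); also the largest size the calibration table must cover.
#' @param n_calibration_draws Monte-Carlo draws per size for [calibrate()]
#'   (default 2000).
#' @param seed master seed for all stochastic stages.
#' @param skip_absorbed_seeds skip a seed already absorbed into an earlier
#'   candidate module whose corrected score is at least the seed's singleton
#'   score (default FALSE). A pure speed-up for large networks: the skipped
#'   seed's greedy run would at best rediscover a module already found.
#' @param prune after growth stops, repeatedly drop the scored member whose
#'   removal most increases the corrected score while keeping the module
#'   connected (default TRUE). A hill-climbing refinement on the same
#'   objective: early adoptions can turn unprofitable once the module has
#'   grown past them.
#' @param overlap_measure `"min"` (intersection over the smaller member set,
#'   default) or `"jaccard"`.
#' @return A list of class `search_params`.
#' @export
search_params <- function(n_modules = 5L, overlap_threshold = 0.8,
                          search_depth = 2L, max_module_scored = 30L,
                          n_calibration_draws = 2000L, seed = NULL,
                          skip_absorbed_seeds = FALSE, prune = TRUE,
                          overlap_measure = c("min", "jaccard")) {
  stopifnot(n_modules >= 1L, search_depth >= 1L,
            overlap_threshold >= 0, overlap_threshold <= 1,
            max_module_scored >= 1L)
  structure(list(n_modules = as.integer(n_modules),
                 overlap_threshold = overlap_threshold,
                 search_depth = as.integer(search_depth),
                 max_module_scored = as.integer(max_module_scored),
                 n_calibration_draws = as.integer(n_calibration_draws),
                 seed = seed,
                 skip_absorbed_seeds = isTRUE(skip_absorbed_seeds),
                 prune = isTRUE(prune),
                 overlap_measure = match.arg(overlap_measure)),
            class = "search_params")
}

# Adjacency list (sorted integer neighbours) of the bipartite network.
network_adjacency <- function(network) {
  ids <- network$nodes$node_id
  idx <- stats::setNames(seq_along(ids), ids)
  a <- idx[network$edges$interaction_id]
  b <- idx[network$edges$participant_id]
  from <- c(a, b)
  to <- c(b, a)
  adj <- rep(list(integer()), length(ids))
  if (length(from)) {
    ord <- order(from, to)
    adj_split <- split(to[ord], factor(from[ord], levels = seq_along(ids)))
    adj <- lapply(adj_split, unname)
  }
  list(ids = ids, idx = idx, adj = adj, deg = lengths(adj))
}

# Breadth-first scan of all nodes within `D` hops of the module; returns
# candidate scored nodes and BFS parent pointers for shortest-path
# reconstruction. Scored non-member nodes may also sit on connecting paths
# (they are adopted, and counted, together with the endpoint candidate).
bfs_candidates <- function(graph, member_idx, scored_mask, D) {
  n <- length(graph$ids)
  dist <- rep(-1L, n)
  parent <- rep(0L, n)
  dist[member_idx] <- 0L
  frontier <- member_idx
  cands <- integer()
  for (d in seq_len(D)) {
    nb <- unlist(graph$adj[frontier], use.names = FALSE)
    if (!length(nb)) break
    src <- rep.int(frontier, graph$deg[frontier])
    new <- dist[nb] < 0L
    nb <- nb[new]; src <- src[new]
    first <- !duplicated(nb)
    nb <- nb[first]; src <- src[first]
    if (!length(nb)) break
    dist[nb] <- d
    parent[nb] <- src
    cands <- c(cands, nb[scored_mask[nb]])
    frontier <- nb
  }
  list(cand = cands, parent = parent)
}

module_state_score <- function(S, k, mu, sigma, sigma_floor) {
  (S / sqrt(k) - mu[k]) / max(sigma[k], sigma_floor)
}

grow_module <- function(graph, z, scored_mask, mu, sigma, params, seed_idx,
                        sigma_floor = SIGMA_FLOOR) {
  D <- 2L * params$search_depth
  k_max <- params$max_module_scored
  member_mask <- logical(length(graph$ids))
  member_mask[seed_idx] <- TRUE
  member_idx <- seed_idx
  S <- z[seed_idx]
  k <- 1L
  sA <- module_state_score(S, 1L, mu, sigma, sigma_floor)
  repeat {
    if (k >= k_max) break
    bfs <- bfs_candidates(graph, member_idx, scored_mask, D)
    cand <- bfs$cand
    if (!length(cand)) break
    best <- sA
    best_pick <- 0L
    best_path <- NULL
    for (ci in cand) {
      path <- ci
      v <- bfs$parent[ci]
      while (v != 0L && !member_mask[v]) {
        path <- c(path, v)
        v <- bfs$parent[v]
      }
      sc_path <- path[scored_mask[path]]
      k_new <- k + length(sc_path)
      if (k_new > k_max) next
      s_new <- module_state_score(S + sum(z[sc_path]), k_new, mu, sigma,
                                  sigma_floor)
      if (s_new > best ||
          (s_new == best && best_pick != 0L &&
             graph$ids[ci] < graph$ids[best_pick])) {
        best <- s_new
        best_pick <- ci
        best_path <- path
      }
    }
    if (best_pick == 0L) break
    member_mask[best_path] <- TRUE
    member_idx <- c(member_idx, best_path)
    S <- S + sum(z[best_path[scored_mask[best_path]]])
    k <- k + sum(scored_mask[best_path])
    sA <- best
    if (params$prune) {
      st <- prune_module(graph, z, scored_mask, mu, sigma,
                         list(member_idx = member_idx, S = S, k = k,
                              sA = sA), seed_idx, sigma_floor)
      member_mask[] <- FALSE
      member_mask[st$member_idx] <- TRUE
      member_idx <- st$member_idx
      S <- st$S
      k <- st$k
      sA <- st$sA
    }
  }
  st <- list(member_idx = member_idx, S = S, k = k, sA = sA)
  list(member_idx = st$member_idx,
       scored_members = st$member_idx[scored_mask[st$member_idx]],
       k = st$k, zA = st$S / sqrt(st$k), sA = st$sA, seed_idx = seed_idx)
}

# Hill-climbing refinement on the same objective: repeatedly drop the scored
# member whose removal most increases the corrected score while keeping the
# module connected, then trim connector nodes left dangling.
prune_module <- function(graph, z, scored_mask, mu, sigma, st, seed_idx,
                         sigma_floor = SIGMA_FLOOR) {
  connected_without <- function(members, drop) {
    rest <- setdiff(members, drop)
    if (length(rest) <= 1L) return(TRUE)
    inside <- logical(length(graph$ids))
    inside[rest] <- TRUE
    seen <- logical(length(graph$ids))
    frontier <- rest[1]
    seen[frontier] <- TRUE
    while (length(frontier)) {
      nb <- unlist(graph$adj[frontier], use.names = FALSE)
      nb <- nb[inside[nb] & !seen[nb]]
      nb <- unique(nb)
      seen[nb] <- TRUE
      frontier <- nb
    }
    all(seen[rest])
  }
  repeat {
    sc <- st$member_idx[scored_mask[st$member_idx]]
    if (st$k <= 1L) break
    best <- st$sA
    best_drop <- 0L
    for (v in sc) {
      s_new <- module_state_score(st$S - z[v], st$k - 1L, mu, sigma,
                                  sigma_floor)
      if (s_new > best && connected_without(st$member_idx, v)) {
        best <- s_new
        best_drop <- v
      }
    }
    if (best_drop == 0L) break
    st$member_idx <- setdiff(st$member_idx, best_drop)
    st$S <- st$S - z[best_drop]
    st$k <- st$k - 1L
    st$sA <- best
    # trim unscored connectors left with at most one module neighbour
    repeat {
      inside <- logical(length(graph$ids))
      inside[st$member_idx] <- TRUE
      deg_in <- vapply(st$member_idx, function(u)
        sum(inside[graph$adj[[u]]]), 0L)
      dangling <- st$member_idx[!scored_mask[st$member_idx] & deg_in <= 1L &
                                  st$member_idx != seed_idx]
      if (!length(dangling)) break
      st$member_idx <- setdiff(st$member_idx, dangling)
    }
  }
  st
}

#' Greedy search for active modules
#'
#' Starting from every scored node as a seed, grows a module by repeatedly
#' adopting — among all scored nodes within `2 * search_depth` bipartite hops
#' of the current module — the candidate that maximally increases the
#' background-corrected score, together with its shortest connecting path.
#' Scored nodes on the connecting path are adopted (and counted) with the
#' candidate, so a strong gene behind a weak one can be reached when the
#' pair jointly raises the score. Growth stops when no candidate increases
#' the score or the scored-node cap is reached; an optional prune phase
#' (`params$prune`) then drops members whose removal increases the score.
#'
#' @param network an annotated `unified_network`.
#' @param scores [node_scores()] vector.
#' @param calib [calibrate()] table covering `max_module_scored`.
#' @param params [search_params()].
#' @return List of candidate modules (class `active_module`; fields
#'   `members`, `scored_members`, `scored_k`, `zA`, `sA`, `seed`), sorted by
#'   corrected score descending, ties by fewer members then smallest seed id;
#'   duplicated member sets are reported once.
#' @export
greedy_search <- function(network, scores, calib, params = search_params()) {
  if (!length(scores))
    stop("validation error: no scored nodes", call. = FALSE)
  if (max(calib$k) < params$max_module_scored)
    stop("calibration table does not cover max_module_scored", call. = FALSE)
  graph <- network_adjacency(network)
  sc_ids <- intersect(names(scores), graph$ids)
  if (!length(sc_ids))
    stop("validation error: scored node ids not present in the network",
         call. = FALSE)
  z <- rep(NA_real_, length(graph$ids))
  z[graph$idx[sc_ids]] <- as.numeric(scores[sc_ids])
  scored_mask <- !is.na(z)
  mu <- calib$mu
  sigma <- calib$sigma

  scored_idx <- which(scored_mask)
  seed_order <- scored_idx[order(-z[scored_idx], graph$ids[scored_idx])]
  singleton_sA <- (z - mu[1]) / max(sigma[1], SIGMA_FLOOR)

  absorbed_best <- rep(-Inf, length(graph$ids))
  out <- list()
  seen_keys <- character()
  for (seed in seed_order) {
    if (params$skip_absorbed_seeds &&
        absorbed_best[seed] >= singleton_sA[seed]) next
    mod <- grow_module(graph, z, scored_mask, mu, sigma, params, seed)
    sm <- mod$scored_members
    absorbed_best[sm] <- pmax(absorbed_best[sm], mod$sA)
    key <- paste(sort(mod$member_idx), collapse = ",")
    if (key %in% seen_keys) next
    seen_keys <- c(seen_keys, key)
    out[[length(out) + 1L]] <- structure(
      list(members = sort(graph$ids[mod$member_idx]),
           scored_members = sort(graph$ids[mod$scored_members]),
           scored_k = mod$k, zA = mod$zA, sA = mod$sA,
           seed = graph$ids[mod$seed_idx]),
      class = "active_module")
  }
  sA <- vapply(out, `[[`, 0, "sA")
  sizes <- vapply(out, function(m) length(m$members), 0L)
  seeds <- vapply(out, `[[`, "", "seed")
  out[order(-sA, sizes, seeds)]
}

#' Select non-redundant top modules
#'
#' Walks the ranked candidate list, accepting a module unless its overlap
#' with an already accepted module exceeds the threshold; stops after
#' `n_modules` acceptances. Overlap between member sets A and B is
#' `|A intersect B| / min(|A|, |B|)` (or Jaccard, per
#' `params$overlap_measure`).
#'
#' @param candidates ranked list from [greedy_search()].
#' @param params [search_params()].
#' @return List of accepted `active_module`s (at most `n_modules`).
#' @export
select_modules <- function(candidates, params = search_params()) {
  accepted <- list()
  for (mod in candidates) {
    if (length(accepted) >= params$n_modules) break
    ok <- TRUE
    for (acc in accepted) {
      inter <- length(intersect(mod$members, acc$members))
      denom <- if (params$overlap_measure == "min")
        min(length(mod$members), length(acc$members))
      else length(union(mod$members, acc$members))
      if (denom > 0 && inter / denom > params$overlap_threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) accepted[[length(accepted) + 1L]] <- mod
  }
  accepted
}

#' Per-module report
#'
#' @param module an `active_module`.
#' @param network the `unified_network` it was found in.
#' @param criterion significance criterion (string or [parse_criterion()])
#'   used only for the changed-gene count.
#' @param table `gene_stat_table` with the statistics behind the scores.
#' @return List of class `module_report`: member counts by node kind,
#'   per-pathway interaction-node contributions (an interaction present in
#'   j pathways tallies in all j), the changed-gene count `n_significant`,
#'   and a per-node attribute table.
#' @export
module_report <- function(module, network, criterion, table) {
  nodes <- network$nodes[network$nodes$node_id %in% module$members, ,
                         drop = FALSE]
  kind_counts <- table(factor(nodes$kind,
                              levels = c("interaction", "gene_product",
                                         "metabolite", "complex")))
  prov <- nodes$provenance[nodes$kind == "interaction"]
  contrib <- if (length(prov)) {
    tb <- sort(table(unlist(strsplit(prov, ";", fixed = TRUE))),
               decreasing = TRUE)
    stats::setNames(as.integer(tb), names(tb))
  } else stats::setNames(integer(), character())
  sig_genes <- intersect(evaluate_criterion(criterion, table),
                         module$members)
  stat <- table[match(nodes$node_id, table$gene_id),
                c("log2fc", "pvalue"), drop = FALSE]
  node_table <- data.frame(node_id = nodes$node_id, kind = nodes$kind,
                           log2fc = stat$log2fc, pvalue = stat$pvalue,
                           scored = nodes$node_id %in% module$scored_members,
                           significant = nodes$node_id %in% sig_genes,
                           stringsAsFactors = FALSE)
  node_table <- node_table[order(node_table$kind, node_table$node_id), ,
                           drop = FALSE]
  rownames(node_table) <- NULL
  structure(list(n_members = length(module$members),
                 kind_counts = stats::setNames(as.integer(kind_counts),
                                               names(kind_counts)),
                 pathway_contributions = contrib,
                 n_pathways = length(contrib),
                 n_significant = length(sig_genes),
                 scored_k = module$scored_k, zA = module$zA, sA = module$sA,
                 node_table = node_table),
            class = "module_report")
}

#' @export
print.active_module <- function(x, ...) {
  cat(sprintf("active_module: %d members (%d scored), zA = %.3f, sA = %.3f, seed %s\n",
              length(x$members), x$scored_k, x$zA, x$sA, x$seed))
  invisible(x)
}

#' @export
print.module_report <- function(x, ...) {
  cat(sprintf("module report: %d members (%s)\n", x$n_members,
              paste(sprintf("%s %d", names(x$kind_counts), x$kind_counts),
                    collapse = ", ")))
  cat(sprintf("  scored nodes: %d; raw zA = %.3f; corrected sA = %.3f\n",
              x$scored_k, x$zA, x$sA))
  cat(sprintf("  changed genes under criterion: %d\n", x$n_significant))
  cat(sprintf("  combines interactions from %d pathway(s)\n", x$n_pathways))
  invisible(x)
}

#' Find active modules in an annotated network
#'
#' Convenience wrapper running [node_scores()], [calibrate()],
#' [greedy_search()] and [select_modules()] in sequence with seeds derived
#' from `params$seed`.
#'
#' @param network an annotated `unified_network`.
#' @param contrast contrast label (default: the single annotated contrast).
#' @param params [search_params()]; `seed` must be set.
#' @param clamp_epsilon p-value clamp for the z-transform.
#' @return A list of class `active_module_set` with elements `modules`
#'   (selected), `candidates` (all ranked candidates), `calibration`,
#'   `scores`, `params`, `contrast`.
#' @export
find_active_modules <- function(network, contrast = NULL,
                                params = search_params(),
                                clamp_epsilon = 1e-12) {
  if (is.null(params$seed))
    stop("params$seed must be set for active-module discovery",
         call. = FALSE)
  scores <- node_scores(network, contrast, clamp_epsilon)
  k_max <- min(params$max_module_scored, length(scores))
  params$max_module_scored <- k_max
  calib <- calibrate(scores, k_max, params$n_calibration_draws,
                     seed = derive_seeds(params$seed, 1L))
  cands <- greedy_search(network, scores, calib, params)
  mods <- select_modules(cands, params)
  structure(list(modules = mods, candidates = cands, calibration = calib,
                 scores = scores, params = params,
                 contrast = attr(scores, "contrast")),
            class = "active_module_set")
}

#' @export
print.active_module_set <- function(x, ...) {
  cat(sprintf("active modules (contrast %s): %d selected of %d candidate(s)\n",
              x$contrast, length(x$modules), length(x$candidates)))
  for (i in seq_along(x$modules)) {
    m <- x$modules[[i]]
    cat(sprintf("  %d. sA = %.3f (zA = %.3f), %d members, %d scored\n",
                i, m$sA, m$zA, length(m$members), m$scored_k))
  }
  invisible(x)
}

#' @export
summary.active_module_set <- function(object, ...) {
  data.frame(rank = seq_along(object$modules),
             corrected_score = vapply(object$modules, `[[`, 0, "sA"),
             raw_score = vapply(object$modules, `[[`, 0, "zA"),
             n_members = vapply(object$modules,
                                function(m) length(m$members), 0L),
             scored_k = vapply(object$modules, `[[`, 0L, "scored_k"),
             seed_node = vapply(object$modules, `[[`, "", "seed"),
             stringsAsFactors = FALSE)
}
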