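# Independent oracles used by the tests.

# Hypergeometric mean/variance of the changed count r by direct enumeration
# of its probability mass (binomial coefficients, no distribution function).
hyper_moments <- function(N, R, n) {
  r <- max(0L, n + R - N):min(n, R)
  pr <- choose(R, r) * choose(N - R, n - r) / choose(N, n)
  m <- sum(r * pr)
  v <- sum((r - m)^2 * pr)
  list(mean = m, var = v)
}

zscore_oracle <- function(N, R, n, r) {
  mo <- hyper_moments(N, R, n)
  if (mo$var <= 0) return(NA_real_)
  (r - mo$mean) / sqrt(mo$var)
}

# Adjacency between scored nodes: reachable within `hops` bipartite hops
# through unscored intermediates only (matching the greedy candidate rule).
scored_projection <- function(network, scored_ids, hops = 4L) {
  ids <- network$nodes$node_id
  adj <- rep(list(character()), length(ids))
  names(adj) <- ids
  for (i in seq_len(nrow(network$edges))) {
    a <- network$edges$interaction_id[i]
    b <- network$edges$participant_id[i]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  reach_one <- function(start) {
    seen <- start
    frontier <- start
    found <- character()
    for (d in seq_len(hops)) {
      nb <- setdiff(unique(unlist(adj[frontier])), seen)
      if (!length(nb)) break
      seen <- c(seen, nb)
      sc <- nb[nb %in% scored_ids]
      found <- c(found, sc)
      frontier <- setdiff(nb, sc)
    }
    setdiff(found, start)
  }
  nb <- lapply(scored_ids, reach_one)
  names(nb) <- scored_ids
  nb
}

# Every connected subset of the scored projection graph (breadth-first
# closure over subsets; feasible for <= 10 scored nodes).
connected_scored_subsets <- function(proj) {
  nodes <- names(proj)
  subsets <- lapply(nodes, function(v) v)
  seen <- vapply(subsets, function(s) paste(sort(s), collapse = ","), "")
  i <- 1L
  while (i <= length(subsets)) {
    s <- subsets[[i]]
    cand <- setdiff(unique(unlist(proj[s])), s)
    for (u in cand) {
      key <- paste(sort(c(s, u)), collapse = ",")
      if (!(key %in% seen)) {
        subsets[[length(subsets) + 1L]] <- c(s, u)
        seen <- c(seen, key)
      }
    }
    i <- i + 1L
  }
  subsets
}

subset_score <- function(subset, scores, calib) {
  z <- as.numeric(scores[subset])
  k <- length(z)
  (sum(z) / sqrt(k) - calib$mu[k]) / max(calib$sigma[k], 1e-9)
}

# Exhaustive optimum over connected scored subsets, plus whether a monotone
# greedy path reaches it: an independent best-improvement simulation on the
# projection graph (no connector/prune machinery) started from every seed.
exhaustive_optimum <- function(network, scores, calib) {
  proj <- scored_projection(network, names(scores))
  subsets <- connected_scored_subsets(proj)
  sc <- vapply(subsets, subset_score, 0, scores = scores, calib = calib)
  best_idx <- which.max(sc)
  best_set <- sort(subsets[[best_idx]])
  greedy_best <- max(vapply(names(proj), function(seed)
    oracle_greedy_from(seed, proj, scores, calib), 0))
  list(score = sc[best_idx], set = best_set,
       reachable = abs(greedy_best - sc[best_idx]) < 1e-9)
}

# Best-improvement hill climbing over add / connectivity-preserving remove
# moves, mirroring the search's move set on the subset lattice.
oracle_greedy_from <- function(seed, proj, scores, calib) {
  proj_connected <- function(s) {
    if (length(s) <= 1L) return(TRUE)
    seen <- s[1]
    repeat {
      nb <- intersect(unique(unlist(proj[seen])), s)
      nb <- setdiff(nb, seen)
      if (!length(nb)) break
      seen <- c(seen, nb)
    }
    length(seen) == length(s)
  }
  s <- seed
  score <- subset_score(s, scores, calib)
  repeat {
    adds <- setdiff(unique(unlist(proj[s])), s)
    moves <- lapply(adds, function(u) c(s, u))
    if (length(s) > 1L)
      moves <- c(moves, Filter(proj_connected,
                               lapply(s, function(v) setdiff(s, v))))
    if (!length(moves)) break
    trial <- vapply(moves, subset_score, 0, scores = scores, calib = calib)
    if (max(trial) <= score) break
    s <- moves[[which.max(trial)]]
    score <- max(trial)
  }
  score
}

# Random tiny network for the search-equivalence checks: a handful of
# interactions over a small gene pool, a scored subset with normal z-scores.
random_tiny_instance <- function(seed) {
  with_seed_local(seed, {
    n_genes <- sample(6:12, 1)
    genes <- sprintf("ensembl:T%02d", seq_len(n_genes))
    n_int <- sample(5:10, 1)
    ia <- data.frame(pathway_id = "P1",
                     local_id = sprintf("I%02d", seq_len(n_int)),
                     type = "undirected", stringsAsFactors = FALSE)
    pp <- do.call(rbind, lapply(seq_len(n_int), function(i) {
      k <- sample(2:3, 1)
      data.frame(pathway_id = "P1", local_id = sprintf("I%02d", i),
                 participant_id = sample(genes, k), kind = "gene_product",
                 role = "participant", stringsAsFactors = FALSE)
    }))
    col <- pathway_collection(
      data.frame(pathway_id = "P1", title = "t", source_db = "synthetic",
                 stringsAsFactors = FALSE), ia, pp)
    net <- build_network(col)
    present <- net$nodes$node_id[net$nodes$kind == "gene_product"]
    n_scored <- min(length(present), sample(4:10, 1))
    scored <- sort(sample(present, n_scored))
    z <- stats::setNames(stats::rnorm(n_scored, 1, 1.5), scored)
    list(network = net, scores = structure(z, class = "node_zscores"))
  })
}
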