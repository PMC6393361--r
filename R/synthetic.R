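# Synthetic pathway collections and expression tables with known ground
# truth: recurring interactions within and across pathways, high-degree
# currency metabolites, multi-probe genes, and a planted connected module of
# gene products with small p-values.

#' Specification of a synthetic pathway collection
#'
#' Defaults emulate the shape of a curated human pathway collection:
#' right-skewed interactions-per-pathway counts (log-normal, median near 22,
#' mean well above it), a small share of interactions recurring in a second
#' pathway or duplicated within their own pathway, a participant mix
#' dominated by gene products and complexes, and a handful of ubiquitous
#' currency metabolites attached to many interactions.
#'
#' @param n_pathways number of pathways.
#' @param interactions_meanlog,interactions_sdlog log-normal parameters for
#'   interactions per pathway (rounded, minimum 1).
#' @param cross_pathway_share_rate fraction of interactions copied into a
#'   second random pathway.
#' @param within_pathway_dup_rate fraction of interactions duplicated inside
#'   their own pathway (raises multi-occurrence but not multi-pathway
#'   counts).
#' @param participant_kind_mix named proportions over gene_product,
#'   metabolite, complex (summing to 1).
#' @param n_gene_products,n_metabolites,n_complexes entity pool sizes.
#' @param n_currency_metabolites number of currency-metabolite ids.
#' @param currency_attach_rate probability an interaction gains one currency
#'   metabolite participant.
#' @param type_mix named proportions over the six interaction types.
#' @param seed integer seed.
#' @return List of class `collection_spec`.
#' @export
collection_spec <- function(n_pathways = 40L,
                            interactions_meanlog = log(22),
                            interactions_sdlog = 0.9,
                            cross_pathway_share_rate = 0.08,
                            within_pathway_dup_rate = 0.04,
                            participant_kind_mix = c(gene_product = 0.55,
                                                     metabolite = 0.15,
                                                     complex = 0.30),
                            n_gene_products = 1000L, n_metabolites = 150L,
                            n_complexes = 300L,
                            n_currency_metabolites = 10L,
                            currency_attach_rate = 0.15,
                            type_mix = c(directed = 0.495,
                                         complex_participation = 0.193,
                                         catalysis = 0.175,
                                         inhibition = 0.043,
                                         conversion = 0.033,
                                         undirected = 0.061),
                            seed = 1L) {
  stopifnot(n_pathways >= 1L,
            cross_pathway_share_rate >= 0, cross_pathway_share_rate <= 1,
            within_pathway_dup_rate >= 0, within_pathway_dup_rate <= 1,
            currency_attach_rate >= 0, currency_attach_rate <= 1,
            abs(sum(participant_kind_mix) - 1) < 1e-8,
            all(names(participant_kind_mix) %in% PARTICIPANT_KINDS),
            abs(sum(type_mix) - 1) < 1e-8,
            all(names(type_mix) %in% INTERACTION_TYPES))
  if (cross_pathway_share_rate > 0 && n_pathways < 2L)
    stop("validation error: cross-pathway sharing needs at least 2 pathways",
         call. = FALSE)
  structure(as.list(environment()), class = "collection_spec")
}

synthetic_pools <- function(spec) {
  list(gene_product = sprintf("ensembl:SYNG%05d",
                              seq_len(spec$n_gene_products)),
       metabolite = sprintf("chebi:SYNM%05d", seq_len(spec$n_metabolites)),
       complex = sprintf("reactome:SYNC%05d", seq_len(spec$n_complexes)),
       currency = sprintf("chebi:CURR%03d",
                          seq_len(spec$n_currency_metabolites)))
}

# One raw record: list(type, ids, kinds, roles) with >= 2 distinct
# non-currency participants.
draw_record <- function(spec, pools) {
  type <- sample(names(spec$type_mix), 1L, prob = spec$type_mix)
  draw_kind <- function(n)
    sample(names(spec$participant_kind_mix), n, replace = TRUE,
           prob = spec$participant_kind_mix)
  if (type %in% DIRECTED_TYPES) {
    n_extra <- if (type == "catalysis") 1L else stats::rbinom(1L, 1L, 0.2)
    kinds <- if (type == "conversion")
      c("metabolite", "metabolite", draw_kind(n_extra))
    else draw_kind(2L + n_extra)
    roles <- c("source", "target",
               if (n_extra) sample(c("source", "target"), n_extra,
                                   replace = TRUE))
  } else {
    n <- 2L + stats::rpois(1L, if (type == "complex_participation") 1.0
                           else 0.4)
    kinds <- draw_kind(n)
    roles <- rep("participant", n)
  }
  ids <- character(length(kinds))
  for (kd in unique(kinds)) {
    sel <- kinds == kd
    ids[sel] <- sample(pools[[kd]], sum(sel), replace = FALSE)
  }
  list(type = type, ids = ids, kinds = kinds, roles = roles)
}

record_core_key <- function(rec) {
  paste(rec$type, paste(sort(paste(rec$ids, rec$roles, sep = "\x1f")),
                        collapse = "\x1e"), sep = "\x1d")
}

#' Generate a synthetic pathway collection with ground truth
#'
#' Draws unique base interactions (their canonical keys are guaranteed
#' distinct even after currency-metabolite exclusion), attaches currency
#' metabolites, then copies a known share of interactions into a second
#' pathway and duplicates another share within their own pathway. The
#' returned ground truth records every expected merge, the provenance of
#' every unique interaction, and the exact network summary
#' [build_network()] + [summarize_network()] must produce under exclusion of
#' the currency ids.
#'
#' @param spec a [collection_spec()].
#' @return List with elements `collection` (a [pathway_collection()]) and
#'   `truth` (bookkeeping list; `truth$summary` mirrors the
#'   `network_summary` fields).
#' @export
generate_collection <- function(spec = collection_spec()) {
  pools <- synthetic_pools(spec)
  with_seed(spec$seed, {
    sizes <- pmax(1L, as.integer(round(stats::rlnorm(
      spec$n_pathways, spec$interactions_meanlog, spec$interactions_sdlog))))
    pw_ids <- sprintf("SYNP%04d", seq_len(spec$n_pathways))
    base_pathway <- rep(seq_len(spec$n_pathways), sizes)
    B <- length(base_pathway)
    records <- vector("list", B)
    seen <- character(B)
    for (i in seq_len(B)) {
      for (attempt in seq_len(200L)) {
        rec <- draw_record(spec, pools)
        key <- record_core_key(rec)
        if (!(key %in% seen[seq_len(i - 1L)])) break
      }
      records[[i]] <- rec
      seen[i] <- key
    }
    # currency attachment (before copying, so all copies share participants)
    has_currency <- stats::runif(B) < spec$currency_attach_rate &
      spec$n_currency_metabolites > 0L
    for (i in which(has_currency)) {
      rec <- records[[i]]
      cur <- sample(pools$currency, 1L)
      role <- if (rec$type %in% DIRECTED_TYPES)
        sample(c("source", "target"), 1L) else "participant"
      rec$ids <- c(rec$ids, cur)
      rec$kinds <- c(rec$kinds, "metabolite")
      rec$roles <- c(rec$roles, role)
      records[[i]] <- rec
    }
    n_cross <- round(spec$cross_pathway_share_rate * B)
    cross_idx <- if (n_cross > 0) sort(sample.int(B, n_cross)) else integer()
    cross_target <- vapply(cross_idx, function(i) {
      others <- setdiff(seq_len(spec$n_pathways), base_pathway[i])
      if (length(others) == 1L) others else sample(others, 1L)
    }, 0L)
    n_dup <- round(spec$within_pathway_dup_rate * B)
    dup_idx <- if (n_dup > 0) sort(sample.int(B, n_dup)) else integer()
  })

  all_base <- c(seq_len(length(records)), cross_idx, dup_idx)
  all_pathway <- c(base_pathway, cross_target, base_pathway[dup_idx])
  local_id <- sprintf("int%06d", seq_along(all_base))
  B <- length(records)

  np <- vapply(records, function(r) length(r$ids), 0L)
  ia <- data.frame(pathway_id = pw_ids[all_pathway], local_id = local_id,
                   type = vapply(records, `[[`, "", "type")[all_base],
                   stringsAsFactors = FALSE)
  pp <- data.frame(
    pathway_id = rep(pw_ids[all_pathway], np[all_base]),
    local_id = rep(local_id, np[all_base]),
    participant_id = unlist(lapply(records[all_base], `[[`, "ids")),
    kind = unlist(lapply(records[all_base], `[[`, "kinds")),
    role = unlist(lapply(records[all_base], `[[`, "roles")),
    stringsAsFactors = FALSE)
  pw <- data.frame(pathway_id = pw_ids,
                   title = sprintf("Synthetic pathway %d",
                                   seq_len(spec$n_pathways)),
                   source_db = "synthetic", stringsAsFactors = FALSE)
  collection <- pathway_collection(pw, ia, pp)

  # ground-truth bookkeeping (record-level knowledge, not build_network)
  occurrences <- tabulate(all_base, nbins = B)
  prov <- lapply(seq_len(B), function(i)
    sort(unique(pw_ids[all_pathway[all_base == i]])))
  currency_ids <- pools$currency
  core <- lapply(records, function(r) {
    keep <- !(r$ids %in% currency_ids)
    list(ids = r$ids[keep], kinds = r$kinds[keep], roles = r$roles[keep],
         type = r$type)
  })
  part_ids <- unlist(lapply(core, `[[`, "ids"))
  part_kinds <- unlist(lapply(core, `[[`, "kinds"))
  first <- !duplicated(part_ids)
  kind_of <- stats::setNames(part_kinds[first], part_ids[first])
  n_edges <- sum(vapply(core, function(r)
    length(unique(paste(r$ids, r$roles, sep = "\x1f"))), 0L))
  g <- igraph::graph_from_data_frame(
    data.frame(from = rep(sprintf("interaction#%06d", seq_len(B)),
                          vapply(core, function(r)
                            length(unique(r$ids)), 0L)),
               to = unlist(lapply(core, function(r) unique(r$ids))),
               stringsAsFactors = FALSE),
    directed = FALSE)
  comp_sizes <- sort(igraph::components(g)$csize, decreasing = TRUE)
  census_tb <- table(vapply(core, `[[`, "", "type"))
  truth <- list(
    currency_ids = currency_ids,
    n_unique_interactions = B,
    occurrence_counts = occurrences,
    provenance = prov,
    planted = NULL,
    summary = list(
      n_nodes = B + length(kind_of),
      n_edges = n_edges,
      n_gene_products = sum(kind_of == "gene_product"),
      n_metabolites = sum(kind_of == "metabolite"),
      n_complexes = sum(kind_of == "complex"),
      n_interaction_nodes = B,
      n_components = length(comp_sizes),
      component_sizes = as.integer(comp_sizes),
      interaction_type_census = stats::setNames(as.integer(census_tb),
                                                names(census_tb)),
      n_interactions_multi_occurrence = sum(occurrences > 1L),
      n_interactions_multi_pathway = sum(lengths(prov) > 1L)))
  list(collection = collection, truth = truth)
}

#' Specification of a planted expression signal
#'
#' @param planted_size number of gene products in the planted connected
#'   module (default 15).
#' @param planted_p_alpha planted p-values are drawn from Beta(alpha, 1);
#'   `alpha = 1` embeds a pure null, small alpha concentrates p near 0
#'   (default 0.05).
#' @param effect_log2fc_mean,effect_log2fc_sd absolute log2 fold change of
#'   planted genes is Normal(mean, sd) with random sign (defaults 1.0, 0.3).
#' @param background_log2fc_sd background log2 fold changes are
#'   Normal(0, sd) (default 0.2); background p-values are Uniform(0, 1).
#' @param probes_per_gene_lambda probes per gene is `1 + Poisson(lambda)`
#'   (default 0.5, i.e. 1.5 probes per gene on average).
#' @param probes_per_gene_fixed when set, every gene gets exactly this many
#'   probes instead of the Poisson draw.
#' @param multi_map_rate probability a probe additionally maps to a second
#'   random gene (default 0.02).
#' @param unmapped_rate extra probes without any gene mapping, as a fraction
#'   of the mapped probe count (default 0.05).
#' @param undetected_rate extra decoy probes undetected in every sample, as
#'   a fraction of the mapped probe count (default 0.02).
#' @param n_samples number of per-sample detection-flag columns (default 6).
#' @param n_extra_genes measured genes absent from the network, widening the
#'   enrichment background (default 0).
#' @param seed integer seed.
#' @return List of class `plant_spec`.
#' @export
plant_spec <- function(planted_size = 15L, planted_p_alpha = 0.05,
                       effect_log2fc_mean = 1.0, effect_log2fc_sd = 0.3,
                       background_log2fc_sd = 0.2,
                       probes_per_gene_lambda = 0.5,
                       probes_per_gene_fixed = NULL, multi_map_rate = 0.02,
                       unmapped_rate = 0.05, undetected_rate = 0.02,
                       n_samples = 6L, n_extra_genes = 0L, seed = 1L) {
  stopifnot(planted_size >= 2L, planted_p_alpha > 0, planted_p_alpha <= 1)
  structure(as.list(environment()), class = "plant_spec")
}

# Gene-gene adjacency through shared interaction nodes.
gene_projection <- function(network) {
  genes <- network$nodes$node_id[network$nodes$kind == "gene_product"]
  ed <- network$edges[network$edges$participant_id %in% genes, , drop = FALSE]
  by_int <- split(ed$participant_id, ed$interaction_id)
  by_int <- lapply(by_int, unique)
  by_int <- by_int[lengths(by_int) >= 2L]
  pairs <- lapply(by_int, function(g) {
    g <- sort(g)
    cbind(rep(g, each = length(g)), rep(g, length(g)))
  })
  el <- do.call(rbind, pairs)
  if (is.null(el)) el <- matrix(character(), ncol = 2)
  el <- el[el[, 1] < el[, 2], , drop = FALSE]
  igraph::graph_from_data_frame(unique(as.data.frame(el)), directed = FALSE,
                                vertices = genes)
}

#' Generate a synthetic expression table with a planted active module
#'
#' Selects a random connected set of `planted_size` gene products
#' (connectivity through shared interaction nodes), gives them small
#' p-values (Beta(alpha, 1)) and strong fold changes, gives all other genes
#' uniform-null p-values and weak fold changes, and fans the gene statistics
#' out to probes (a gene's probes replicate its statistics, so the
#' probe-merge step recovers them exactly). Decoy probes exercise the
#' detection filter (all samples undetected) and the unmapped-probe drop.
#'
#' @param network a `unified_network` with at least `planted_size` gene
#'   products connected through interaction nodes.
#' @param plant a [plant_spec()].
#' @return List with `probes` (probe statistics data frame with detection
#'   flags), `idmap` (probe-to-gene map), and `truth` (planted gene ids,
#'   per-gene statistics table, decoy probe ids).
#' @export
generate_expression <- function(network, plant = plant_spec()) {
  genes <- sort(network$nodes$node_id[network$nodes$kind == "gene_product"])
  if (!length(genes)) stop("network has no gene products", call. = FALSE)
  g <- gene_projection(network)
  comp <- igraph::components(g)
  eligible <- which(comp$csize >= plant$planted_size)
  if (!length(eligible))
    stop("no connected gene set of size ", plant$planted_size,
         " available; largest has ", max(comp$csize), " gene(s)",
         call. = FALSE)
  with_seed(plant$seed, {
    comp_pick <- if (length(eligible) == 1L) eligible else
      sample(eligible, 1L, prob = comp$csize[eligible])
    members <- igraph::V(g)$name[comp$membership == comp_pick]
    # randomized BFS growth to a connected planted set
    start <- sample(members, 1L)
    planted <- start
    frontier <- setdiff(igraph::V(g)$name[
      as.integer(igraph::neighbors(g, start))], planted)
    while (length(planted) < plant$planted_size) {
      nxt <- if (length(frontier) == 1L) frontier else sample(frontier, 1L)
      planted <- c(planted, nxt)
      nb <- igraph::V(g)$name[as.integer(igraph::neighbors(g, nxt))]
      frontier <- setdiff(unique(c(frontier, nb)), planted)
    }
    planted <- sort(planted)

    all_genes <- c(genes,
                   if (plant$n_extra_genes > 0)
                     sprintf("ensembl:EXTG%05d",
                             seq_len(plant$n_extra_genes)))
    n_g <- length(all_genes)
    is_planted <- all_genes %in% planted
    pvals <- stats::runif(n_g)
    pvals[is_planted] <- stats::rbeta(sum(is_planted),
                                      plant$planted_p_alpha, 1)
    fc <- stats::rnorm(n_g, 0, plant$background_log2fc_sd)
    fc[is_planted] <- sample(c(-1, 1), sum(is_planted), replace = TRUE) *
      stats::rnorm(sum(is_planted), plant$effect_log2fc_mean,
                   plant$effect_log2fc_sd)
    gene_stats <- data.frame(gene_id = all_genes, log2fc = fc,
                             pvalue = pvals, stringsAsFactors = FALSE)

    n_probes <- if (!is.null(plant$probes_per_gene_fixed))
      rep(as.integer(plant$probes_per_gene_fixed), n_g)
    else 1L + stats::rpois(n_g, plant$probes_per_gene_lambda)
    probe_gene <- rep(seq_len(n_g), n_probes)
    n_main <- length(probe_gene)
    probe_id <- sprintf("probe:%06d", seq_len(n_main))
    probes <- data.frame(probe_id = probe_id,
                         log2fc = fc[probe_gene],
                         pvalue = pvals[probe_gene],
                         stringsAsFactors = FALSE)
    idmap <- data.frame(probe_id = probe_id,
                        gene_id = all_genes[probe_gene],
                        stringsAsFactors = FALSE)
    multi <- which(stats::runif(n_main) < plant$multi_map_rate)
    second <- character()
    if (length(multi)) {
      second <- vapply(probe_gene[multi], function(gi)
        sample(all_genes[-gi], 1L), "")
      idmap <- rbind(idmap, data.frame(probe_id = probe_id[multi],
                                       gene_id = second,
                                       stringsAsFactors = FALSE))
    }
    n_unm <- round(plant$unmapped_rate * n_main)
    n_und <- round(plant$undetected_rate * n_main)
    decoy_id <- sprintf("probe:X%06d", seq_len(n_unm + n_und))
    decoys <- data.frame(probe_id = decoy_id,
                         log2fc = stats::rnorm(n_unm + n_und, 0,
                                               plant$background_log2fc_sd),
                         pvalue = stats::runif(n_unm + n_und),
                         stringsAsFactors = FALSE)
    undetected_ids <- utils::tail(decoy_id, n_und)
    if (n_und > 0)  # undetected decoys are mapped, so only the filter drops them
      idmap <- rbind(idmap,
                     data.frame(probe_id = undetected_ids,
                                gene_id = sample(all_genes, n_und,
                                                 replace = TRUE),
                                stringsAsFactors = FALSE))
    probes <- rbind(probes, decoys)
    det <- matrix(stats::runif(nrow(probes) * plant$n_samples) < 0.9,
                  nrow = nrow(probes))
    none <- rowSums(det) == 0L
    det[cbind(which(none),
              sample.int(plant$n_samples, sum(none), replace = TRUE))] <- TRUE
    det[probes$probe_id %in% undetected_ids, ] <- FALSE
    for (s in seq_len(plant$n_samples))
      probes[[sprintf("detected_s%d", s)]] <- det[, s]
  })
  idmap <- idmap[order(idmap$probe_id, idmap$gene_id), , drop = FALSE]
  rownames(idmap) <- rownames(probes) <- NULL
  list(probes = probes, idmap = idmap,
       truth = list(planted_genes = planted, gene_stats = gene_stats,
                    # genes receiving a foreign multi-mapped probe: their
                    # merged statistics may differ from gene_stats
                    multi_mapped_genes = sort(unique(second)),
                    undetected_probes = undetected_ids,
                    unmapped_probes = setdiff(decoy_id, idmap$probe_id)))
}

#' Permute gene labels of a statistics table
#'
#' Reassigns the (log2FC, p-value) pairs to a uniform random permutation of
#' the gene ids: the statistic multiset is conserved while any
#' network-localized signal is destroyed.
#'
#' @param table a `gene_stat_table` (or data frame with `gene_id`).
#' @param seed integer seed.
#' @return The permuted table (same class and attributes).
#' @export
permute_labels <- function(table, seed) {
  if (!nrow(table)) stop("validation error: empty table", call. = FALSE)
  out <- table
  with_seed(seed, {
    out$gene_id <- sample(table$gene_id)
  })
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pathway gene sets from a collection
#'
#' One gene set per pathway, holding the pathway's gene-product participant
#' ids; pathways without gene products are omitted.
#'
#' @param collection a [pathway_collection()].
#' @return A `gene_sets` list usable with [run_enrichment()].
#' @export
gene_sets_from_collection <- function(collection) {
  pp <- collection$participants
  pp <- pp[pp$kind == "gene_product", , drop = FALSE]
  sets <- lapply(split(pp$participant_id, pp$pathway_id),
                 function(x) sort(unique(x)))
  title_of <- stats::setNames(collection$pathways$title,
                              collection$pathways$pathway_id)
  for (i in seq_along(sets))
    attr(sets[[i]], "name") <- unname(title_of[names(sets)[i]])
  structure(sets, class = "gene_sets")
}
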