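# Unified interaction-as-node network: integration of a pathway collection
# into one bipartite graph in which every deduplicated interaction is a node
# linked to its participant molecules.

#' Canonical key of an interaction record
#'
#' Two interaction records receive the same key exactly when they have the
#' same interaction type and the same multiset of (entity id, role) pairs;
#' the key ignores the pathway the record came from and its local id. The key
#' drives cross-pathway deduplication: the same biochemical interaction drawn
#' in many pathways collapses onto one interaction node whose provenance
#' records all contributing pathways.
#'
#' @param type interaction type string(s), one per record.
#' @param participant_ids,roles character vectors, one entry per participant.
#' @param record index (same length as `participant_ids`) grouping
#'   participants into records; defaults to a single record.
#' @return Character vector of keys, one per record (in order of first
#'   appearance of each record index).
#' @export
canonical_interaction_key <- function(type, participant_ids, roles,
                                      record = rep(1L, length(participant_ids))) {
  stopifnot(length(participant_ids) == length(roles),
            length(participant_ids) == length(record))
  rec <- as.character(record)
  first <- !duplicated(rec)
  pair <- paste(participant_ids, roles, sep = "\x1f")
  parts <- vapply(split(pair, factor(rec, levels = rec[first])),
                  function(x) paste(sort(x), collapse = "\x1e"), "")
  if (length(type) == 1L) type <- rep(type, length(parts))
  paste(type, parts, sep = "\x1d")
}

#' Build the unified network from a pathway collection
#'
#' Applies the currency-metabolite exclusion list, drops interaction records
#' left with fewer than two distinct participants, deduplicates the remaining
#' records by [canonical_interaction_key()], and assembles the bipartite
#' network: one node per merged interaction (with pathway provenance and raw
#' occurrence count) and one node per distinct participant entity, joined by
#' role-attributed edges.
#'
#' The exclusion list is applied before the two-participant rule: an
#' interaction reduced to a single participant after removing ubiquitous
#' small molecules (ATP, H2O, H+, ...) carries no path information and is
#' discarded (counted in the build report).
#'
#' @param collection a validated [pathway_collection()].
#' @param exclusion_list character vector of entity ids to remove (e.g. from
#'   [read_exclusion_list()]). Default empty.
#' @return An object of class `unified_network`: list with `nodes` (node_id,
#'   kind, label, type, occurrence_count, provenance), `edges`
#'   (interaction_id, participant_id, role), `expr` (per-contrast expression
#'   attributes, empty until [annotate_network()]), and `report` (dropped
#'   record / excluded participant counts).
#' @export
build_network <- function(collection, exclusion_list = character()) {
  validate_collection(collection)
  ia <- collection$interactions
  pp <- collection$participants
  exclusion_list <- unique(as.character(exclusion_list))

  n_part0 <- nrow(pp)
  keep <- !(pp$participant_id %in% exclusion_list)
  pp <- pp[keep, , drop = FALSE]
  n_excluded <- n_part0 - nrow(pp)

  empty_net <- function(n_dropped) {
    structure(list(
      nodes = data.frame(node_id = character(), kind = character(),
                         label = character(), type = character(),
                         occurrence_count = integer(),
                         provenance = character(), stringsAsFactors = FALSE),
      edges = data.frame(interaction_id = character(),
                         participant_id = character(), role = character(),
                         stringsAsFactors = FALSE),
      expr = empty_expr(),
      report = list(n_records_in = nrow(ia), n_records_dropped = n_dropped,
                    n_participant_rows_excluded = n_excluded,
                    n_interaction_nodes = 0L),
      exclusion_list = exclusion_list),
      class = "unified_network")
  }
  if (!nrow(pp)) return(empty_net(nrow(ia)))

  rec <- paste(pp$pathway_id, pp$local_id, sep = "\r")
  # distinct participant entities per record, post-exclusion
  ent_first <- !duplicated(paste(rec, pp$participant_id, sep = "\x1f"))
  n_distinct <- table(rec[ent_first])
  ok_rec <- names(n_distinct)[n_distinct >= 2L]
  n_dropped <- nrow(ia) - length(ok_rec)
  if (!length(ok_rec)) return(empty_net(n_dropped))

  pp <- pp[rec %in% ok_rec, , drop = FALSE]
  rec <- paste(pp$pathway_id, pp$local_id, sep = "\r")
  ia_rec <- paste(ia$pathway_id, ia$local_id, sep = "\r")
  ia <- ia[ia_rec %in% ok_rec, , drop = FALSE]
  ia_rec <- ia_rec[ia_rec %in% ok_rec]
  type_of <- stats::setNames(ia$type, ia_rec)

  # participant rows duplicated within a record (same id+role) collapse
  dup <- duplicated(paste(rec, pp$participant_id, pp$role, sep = "\x1f"))
  pp <- pp[!dup, , drop = FALSE]
  rec <- rec[!dup]

  ord <- order(rec)
  pp <- pp[ord, , drop = FALSE]
  rec <- rec[ord]
  keys_by_rec <- canonical_interaction_key(unname(type_of[rec[!duplicated(rec)]]),
                                           pp$participant_id, pp$role, rec)
  rec_levels <- rec[!duplicated(rec)]
  key_of_rec <- stats::setNames(keys_by_rec, rec_levels)

  ukeys <- sort(unique(keys_by_rec))
  int_id <- stats::setNames(sprintf("interaction:%06d", seq_along(ukeys)),
                            ukeys)

  rec_key <- unname(key_of_rec[ia_rec])
  occurrence <- as.integer(table(factor(rec_key, levels = ukeys)))
  prov_list <- lapply(split(ia$pathway_id, factor(rec_key, levels = ukeys)),
                      function(x) sort(unique(x)))
  prov_chr <- vapply(prov_list, paste, "", collapse = ";")
  key_type <- vapply(strsplit(ukeys, "\x1d", fixed = TRUE), `[`, "", 1)

  part_first <- !duplicated(pp$participant_id)
  part_nodes <- data.frame(node_id = pp$participant_id[part_first],
                           kind = pp$kind[part_first],
                           stringsAsFactors = FALSE)
  part_nodes <- part_nodes[order(part_nodes$node_id), , drop = FALSE]

  nodes <- rbind(
    data.frame(node_id = unname(int_id), kind = "interaction",
               label = unname(int_id), type = key_type,
               occurrence_count = occurrence, provenance = unname(prov_chr),
               stringsAsFactors = FALSE),
    data.frame(node_id = part_nodes$node_id, kind = part_nodes$kind,
               label = part_nodes$node_id, type = NA_character_,
               occurrence_count = NA_integer_, provenance = NA_character_,
               stringsAsFactors = FALSE))
  rownames(nodes) <- NULL

  edges <- data.frame(interaction_id = unname(int_id[key_of_rec[rec]]),
                      participant_id = pp$participant_id, role = pp$role,
                      stringsAsFactors = FALSE)
  edges <- unique(edges)
  edges <- edges[order(edges$interaction_id, edges$participant_id,
                       edges$role), , drop = FALSE]
  rownames(edges) <- NULL

  structure(list(nodes = nodes, edges = edges, expr = empty_expr(),
                 report = list(n_records_in = nrow(collection$interactions),
                               n_records_dropped = n_dropped,
                               n_participant_rows_excluded = n_excluded,
                               n_interaction_nodes = length(ukeys)),
                 exclusion_list = exclusion_list),
            class = "unified_network")
}

empty_expr <- function() {
  data.frame(node_id = character(), contrast = character(),
             log2fc = numeric(), pvalue = numeric(), stringsAsFactors = FALSE)
}

network_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[, c("interaction_id", "participant_id")],
    directed = FALSE, vertices = network$nodes$node_id)
}

#' Connected components of a unified network
#'
#' @param network a `unified_network`.
#' @return List of character vectors of node ids (each sorted), ordered by
#'   decreasing component size with ties broken by smallest member id.
#' @export
connected_components <- function(network) {
  if (!nrow(network$nodes)) return(list())
  g <- network_igraph(network)
  comp <- igraph::components(g)
  parts <- split(network$nodes$node_id, comp$membership)
  parts <- lapply(parts, sort)
  first <- vapply(parts, `[`, "", 1)
  parts <- parts[order(-lengths(parts), first)]
  names(parts) <- NULL
  parts
}

#' Summarize a unified network
#'
#' Census of the integrated network: node counts by kind, edge count,
#' component structure, interaction-type census over the merged interaction
#' nodes, and how many merged interactions were seen more than once
#' (`n_interactions_multi_occurrence`) versus in more than one pathway
#' (`n_interactions_multi_pathway`) — a duplicate drawn twice inside one
#' pathway raises the former but not the latter.
#'
#' @param network a `unified_network`.
#' @return An object of class `network_summary` (a list of counts).
#' @export
summarize_network <- function(network) {
  nodes <- network$nodes
  comps <- connected_components(network)
  is_int <- nodes$kind == "interaction"
  prov_sizes <- if (any(is_int))
    lengths(strsplit(nodes$provenance[is_int], ";", fixed = TRUE)) else
      integer()
  census <- if (any(is_int)) {
    tb <- table(nodes$type[is_int])
    stats::setNames(as.integer(tb), names(tb))
  } else stats::setNames(integer(), character())
  structure(list(
    n_nodes = nrow(nodes),
    n_edges = nrow(network$edges),
    n_gene_products = sum(nodes$kind == "gene_product"),
    n_metabolites = sum(nodes$kind == "metabolite"),
    n_complexes = sum(nodes$kind == "complex"),
    n_interaction_nodes = sum(is_int),
    n_components = length(comps),
    component_sizes = lengths(comps),
    interaction_type_census = census,
    n_interactions_multi_occurrence =
      sum(nodes$occurrence_count[is_int] > 1L),
    n_interactions_multi_pathway = sum(prov_sizes > 1L)),
    class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("unified network summary\n")
  cat(sprintf("  nodes: %d (%d interactions, %d gene products, %d metabolites, %d complexes)\n",
              x$n_nodes, x$n_interaction_nodes, x$n_gene_products,
              x$n_metabolites, x$n_complexes))
  cat(sprintf("  edges: %d\n", x$n_edges))
  cat(sprintf("  components: %d (largest %s)\n", x$n_components,
              if (length(x$component_sizes)) x$component_sizes[1] else 0L))
  cat(sprintf("  interactions seen >1 time: %d; in >1 pathway: %d\n",
              x$n_interactions_multi_occurrence,
              x$n_interactions_multi_pathway))
  if (length(x$interaction_type_census))
    cat("  type census:",
        paste(sprintf("%s=%d", names(x$interaction_type_census),
                      x$interaction_type_census), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.unified_network <- function(x, ...) {
  cat(sprintf("unified_network: %d nodes (%d interaction), %d edges\n",
              nrow(x$nodes), sum(x$nodes$kind == "interaction"),
              nrow(x$edges)))
  cat(sprintf("  build report: %d record(s) in, %d dropped (<2 participants), %d participant row(s) excluded\n",
              x$report$n_records_in, x$report$n_records_dropped,
              x$report$n_participant_rows_excluded))
  contrasts <- unique(x$expr$contrast)
  if (length(contrasts))
    cat("  expression contrasts:", paste(contrasts, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.unified_network <- function(object, ...) summarize_network(object)

#' Read a currency-metabolite exclusion list
#'
#' Plain text, one entity id per line; `#` starts a comment; blank lines are
#' ignored.
#'
#' @param path file to read.
#' @return Character vector of entity ids.
#' @export
read_exclusion_list <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}
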