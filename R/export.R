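# Cytoscape-compatible exports: GraphML, SIF, and node/edge attribute TSVs.

network_to_igraph_attr <- function(network, node_ids = NULL) {
  nodes <- network$nodes
  edges <- network$edges
  if (!is.null(node_ids)) {
    nodes <- nodes[nodes$node_id %in% node_ids, , drop = FALSE]
    edges <- edges[edges$interaction_id %in% node_ids &
                     edges$participant_id %in% node_ids, , drop = FALSE]
  }
  vert <- data.frame(name = nodes$node_id, kind = nodes$kind,
                     label = nodes$label,
                     provenance = ifelse(is.na(nodes$provenance), "",
                                         nodes$provenance),
                     occurrence_count = ifelse(is.na(nodes$occurrence_count),
                                               0L, nodes$occurrence_count),
                     stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(
    data.frame(from = edges$interaction_id, to = edges$participant_id,
               role = edges$role, stringsAsFactors = FALSE),
    directed = FALSE, vertices = vert)
}

#' Export a network (or subnetwork) as GraphML
#'
#' Node attributes: kind, label, provenance (";"-joined pathway ids),
#' occurrence_count; edge attribute: role.
#'
#' @param network a `unified_network`.
#' @param path output file.
#' @param node_ids optional subset of node ids (e.g. a module's members).
#' @export
write_graphml <- function(network, path, node_ids = NULL) {
  g <- network_to_igraph_attr(network, node_ids)
  igraph::write_graph(g, path, format = "graphml")
  invisible(NULL)
}

#' Export a network as SIF plus attribute TSVs
#'
#' SIF rows use the interaction node as the relation hub:
#' `interaction_id <role> participant_id`. Alongside `path`, node and edge
#' attribute tables are written as `<path>.nodes.tsv` / `<path>.edges.tsv`.
#'
#' @param network a `unified_network`.
#' @param path output SIF file.
#' @export
write_sif <- function(network, path) {
  ed <- network$edges
  writeLines(sprintf("%s\t%s\t%s", ed$interaction_id, ed$role,
                     ed$participant_id), path)
  write_tsv(network$nodes, paste0(path, ".nodes.tsv"))
  write_tsv(ed, paste0(path, ".edges.tsv"))
  invisible(NULL)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(NULL)
}
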