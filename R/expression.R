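# Probe-level expression handling: detection filtering, probe-to-gene
# mapping, multi-probe merging, and annotation of the unified network.

#' Read a probe statistics table
#'
#' TSV with columns `probe_id`, `log2fc`, `pvalue`, then any number of
#' optional `detected_<sample>` logical columns (TRUE = detected in that
#' sample; FALSE encodes a detection p-value of 1).
#'
#' @param path TSV file.
#' @return Data frame of probe statistics.
#' @export
read_probe_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("probe_id", "log2fc", "pvalue")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("probe table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$probe_id))
    stop("probe table: duplicate probe_id", call. = FALSE)
  if (any(df$pvalue < 0 | df$pvalue > 1, na.rm = TRUE))
    stop("probe table: p-values outside [0, 1]", call. = FALSE)
  det <- grep("^detected_", names(df))
  for (j in det) df[[j]] <- as.logical(df[[j]])
  df
}

#' Remove probes undetected in every sample
#'
#' Probes whose detection p-value is 1 in all samples measure nothing;
#' encoded here as all `detected_<sample>` flags FALSE. Rows with at least
#' one detected sample are retained. Without detection columns the filter is
#' a no-op with a warning.
#'
#' @param probes probe statistics data frame (see [read_probe_table()]).
#' @return The filtered data frame, with attribute `n_removed`.
#' @export
filter_undetected <- function(probes) {
  det <- grep("^detected_", names(probes))
  if (!length(det)) {
    warning("no detected_<sample> columns; detection filter is a no-op")
    attr(probes, "n_removed") <- 0L
    return(probes)
  }
  if (!nrow(probes)) {
    attr(probes, "n_removed") <- 0L
    return(probes)
  }
  flags <- as.matrix(probes[, det, drop = FALSE])
  any_detected <- rowSums(flags, na.rm = TRUE) > 0
  out <- probes[any_detected, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!any_detected)
  out
}

#' Read a probe-to-gene identifier map
#'
#' Two-column TSV `probe_id`, `gene_id`; a probe mapping to several genes
#' appears on several rows.
#'
#' @param path TSV file.
#' @return Data frame with columns `probe_id`, `gene_id`.
#' @export
read_idmap <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("probe_id", "gene_id"), names(df))
  if (length(miss))
    stop("id map lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(df$gene_id)))
    stop("id map: empty gene_id", call. = FALSE)
  unique(df[, c("probe_id", "gene_id")])
}

#' Map probes to genes and merge multi-probe genes
#'
#' Probes without a mapping are dropped (count reported); a probe mapping to
#' several genes contributes to each of them. When several probes measure one
#' gene, one representative row is kept per gene:
#' \describe{
#'   \item{`min_p`}{smallest p-value; ties by largest |log2FC|, then
#'     lexicographic probe id.}
#'   \item{`max_abs_fc`}{largest |log2FC|; ties by smallest p-value, then
#'     probe id.}
#' }
#'
#' @param probes filtered probe statistics data frame.
#' @param idmap data frame `probe_id`, `gene_id` (see [read_idmap()]).
#' @param merge_rule `"min_p"` (default) or `"max_abs_fc"`.
#' @param contrast_label label describing the comparison (e.g. `"frontal"`).
#' @return A `gene_stat_table`: data frame with columns `gene_id`, `log2fc`,
#'   `pvalue`, `probe_id` (the representative probe), attributes
#'   `contrast_label`, `n_unmapped_probes`.
#' @export
map_and_merge <- function(probes, idmap,
                          merge_rule = c("min_p", "max_abs_fc"),
                          contrast_label = "contrast") {
  merge_rule <- match.arg(merge_rule)
  if (!nrow(idmap)) {
    warning("empty id map: no probes could be assigned to genes")
    out <- data.frame(gene_id = character(), log2fc = numeric(),
                      pvalue = numeric(), probe_id = character(),
                      stringsAsFactors = FALSE)
    return(as_gene_stat_table(out, contrast_label, nrow(probes)))
  }
  mapped <- merge(probes[, c("probe_id", "log2fc", "pvalue")], idmap,
                  by = "probe_id")
  n_unmapped <- sum(!(probes$probe_id %in% idmap$probe_id))
  if (!nrow(mapped)) {
    out <- data.frame(gene_id = character(), log2fc = numeric(),
                      pvalue = numeric(), probe_id = character(),
                      stringsAsFactors = FALSE)
    return(as_gene_stat_table(out, contrast_label, n_unmapped))
  }
  ord <- if (merge_rule == "min_p")
    order(mapped$gene_id, mapped$pvalue, -abs(mapped$log2fc),
          mapped$probe_id)
  else
    order(mapped$gene_id, -abs(mapped$log2fc), mapped$pvalue,
          mapped$probe_id)
  mapped <- mapped[ord, , drop = FALSE]
  out <- mapped[!duplicated(mapped$gene_id),
                c("gene_id", "log2fc", "pvalue", "probe_id"), drop = FALSE]
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  as_gene_stat_table(out, contrast_label, n_unmapped)
}

as_gene_stat_table <- function(df, contrast_label, n_unmapped) {
  attr(df, "contrast_label") <- contrast_label
  attr(df, "n_unmapped_probes") <- n_unmapped
  class(df) <- c("gene_stat_table", "data.frame")
  df
}

#' Annotate the network with gene-level expression statistics
#'
#' Gene-product nodes whose id matches a `gene_id` in the table receive the
#' gene's log2 fold change and p-value under the table's contrast label;
#' interaction, metabolite, complex, and unmatched gene nodes stay
#' unmeasured for that contrast. Several contrasts may be annotated in turn
#' and coexist.
#'
#' @param network a `unified_network`.
#' @param table a `gene_stat_table`.
#' @param contrast label override; defaults to the table's
#'   `contrast_label` attribute.
#' @return The network with expression attributes added; its `expr` element
#'   gains one row per annotated (node, contrast). Errors if no gene id
#'   matches any node (namespace mismatch signal).
#' @export
annotate_network <- function(network, table, contrast = NULL) {
  if (is.null(contrast))
    contrast <- attr(table, "contrast_label") %||% "contrast"
  gene_nodes <- network$nodes$node_id[network$nodes$kind == "gene_product"]
  hit <- table$gene_id %in% gene_nodes
  if (!any(hit))
    stop("annotation error: no gene id in the table matches a gene-product ",
         "node (identifier namespace mismatch?)", call. = FALSE)
  add <- data.frame(node_id = table$gene_id[hit], contrast = contrast,
                    log2fc = table$log2fc[hit], pvalue = table$pvalue[hit],
                    stringsAsFactors = FALSE)
  expr <- network$expr
  expr <- expr[!(expr$contrast == contrast &
                   expr$node_id %in% add$node_id), , drop = FALSE]
  expr <- rbind(expr, add)
  expr <- expr[order(expr$contrast, expr$node_id), , drop = FALSE]
  rownames(expr) <- NULL
  network$expr <- expr
  network$report$n_annotated <- c(network$report$n_annotated,
                                  stats::setNames(nrow(add), contrast))
  network
}

`%||%` <- function(a, b) if (is.null(a)) b else a
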