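# Shared fixtures built in code.

# Two pathways; P1 holds A -> B, P2 holds a second copy of A -> B plus
# B -> D. After merging this yields 2 interaction nodes, 3 gene products,
# 4 edges; the A -> B node has provenance {P1, P2} and occurrence count 2.
tiny_collection <- function() {
  pathway_collection(
    pathways = data.frame(pathway_id = c("P1", "P2"),
                          title = c("one", "two"),
                          source_db = "synthetic", stringsAsFactors = FALSE),
    interactions = data.frame(
      pathway_id = c("P1", "P2", "P2"),
      local_id = c("I1", "I1b", "I2"),
      type = "directed", stringsAsFactors = FALSE),
    participants = data.frame(
      pathway_id = c("P1", "P1", "P2", "P2", "P2", "P2"),
      local_id = c("I1", "I1", "I1b", "I1b", "I2", "I2"),
      participant_id = c("ensembl:A", "ensembl:B", "ensembl:A", "ensembl:B",
                         "ensembl:B", "ensembl:D"),
      kind = "gene_product",
      role = c("source", "target", "source", "target", "source", "target"),
      stringsAsFactors = FALSE))
}

# Path A - I1 - B: one directed interaction joining two gene products.
path_collection <- function() {
  pathway_collection(
    pathways = data.frame(pathway_id = "P1", title = "p",
                          source_db = "synthetic", stringsAsFactors = FALSE),
    interactions = data.frame(pathway_id = "P1", local_id = "I1",
                              type = "directed", stringsAsFactors = FALSE),
    participants = data.frame(
      pathway_id = "P1", local_id = c("I1", "I1"),
      participant_id = c("ensembl:A", "ensembl:B"), kind = "gene_product",
      role = c("source", "target"), stringsAsFactors = FALSE))
}

gene_table <- function(gene_id, log2fc, pvalue, contrast = "test") {
  df <- data.frame(gene_id = gene_id, log2fc = log2fc, pvalue = pvalue,
                   stringsAsFactors = FALSE)
  attr(df, "contrast_label") <- contrast
  class(df) <- c("gene_stat_table", "data.frame")
  df
}

# Standard-normal identity calibration up to k_max.
identity_calibration <- function(k_max = 10L) {
  structure(data.frame(k = seq_len(k_max), mu = 0, sigma = 1),
            class = c("calibration_table", "data.frame"))
}

# A random small collection spec used by property tests.
random_spec <- function(seed) {
  with_seed_local(seed, {
    n_pw <- sample(1:50, 1)
    collection_spec(
      n_pathways = n_pw,
      interactions_meanlog = log(sample(3:10, 1)),
      interactions_sdlog = stats::runif(1, 0.4, 1.0),
      cross_pathway_share_rate = if (n_pw >= 2) stats::runif(1, 0, 0.3) else 0,
      within_pathway_dup_rate = stats::runif(1, 0, 0.1),
      n_gene_products = 300L, n_metabolites = 60L, n_complexes = 80L,
      n_currency_metabolites = sample(0:5, 1),
      currency_attach_rate = stats::runif(1, 0, 0.3),
      seed = seed)
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

module_gene_jaccard <- function(module, network, planted) {
  kinds <- network$nodes$kind[match(module$members, network$nodes$node_id)]
  genes <- module$members[kinds == "gene_product"]
  length(intersect(genes, planted)) / length(union(genes, planted))
}
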