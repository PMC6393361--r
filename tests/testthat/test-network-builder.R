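test_that("canonical keys merge identical records and separate distinct ones", {
  key <- function(type, ids, roles)
    canonical_interaction_key(type, ids, roles)
  # same A -> B drawn in two pathways: identical keys (pathway ignored)
  expect_equal(key("directed", c("ensembl:A", "ensembl:B"),
                   c("source", "target")),
               key("directed", c("ensembl:B", "ensembl:A"),
                   c("target", "source")))
  # A -> B vs B -> A: roles differ
  expect_false(key("directed", c("ensembl:A", "ensembl:B"),
                   c("source", "target")) ==
               key("directed", c("ensembl:A", "ensembl:B"),
                   c("target", "source")))
  # same participants, different interaction type
  expect_false(key("directed", c("ensembl:A", "ensembl:B"),
                   c("source", "target")) ==
               key("complex_participation", c("ensembl:A", "ensembl:B"),
                   c("participant", "participant")))
})

test_that("build_network merges duplicate interactions with provenance", {
  net <- build_network(tiny_collection())
  expect_equal(sum(net$nodes$kind == "interaction"), 2L)
  expect_equal(sum(net$nodes$kind == "gene_product"), 3L)
  expect_equal(nrow(net$nodes), 5L)
  expect_equal(nrow(net$edges), 4L)
  ab <- net$nodes[net$nodes$kind == "interaction" &
                    net$nodes$occurrence_count == 2L, ]
  expect_equal(nrow(ab), 1L)
  expect_equal(ab$provenance, "P1;P2")
})

test_that("exclusion is applied before the two-participant rule", {
  col <- pathway_collection(
    data.frame(pathway_id = "P1", title = "p", source_db = "synthetic",
               stringsAsFactors = FALSE),
    data.frame(pathway_id = "P1", local_id = "I1", type = "directed",
               stringsAsFactors = FALSE),
    data.frame(pathway_id = "P1", local_id = c("I1", "I1"),
               participant_id = c("ensembl:A", "chebi:ATP"),
               kind = c("gene_product", "metabolite"),
               role = c("source", "target"), stringsAsFactors = FALSE))
  net <- build_network(col, exclusion_list = "chebi:ATP")
  expect_equal(nrow(net$nodes), 0L)
  expect_equal(net$report$n_records_dropped, 1L)
  expect_equal(net$report$n_participant_rows_excluded, 1L)
})

test_that("an empty collection builds an empty network", {
  col <- pathway_collection(
    data.frame(pathway_id = "P1", title = "p", source_db = "synthetic",
               stringsAsFactors = FALSE),
    data.frame(pathway_id = character(), local_id = character(),
               type = character(), stringsAsFactors = FALSE),
    data.frame(pathway_id = character(), local_id = character(),
               participant_id = character(), kind = character(),
               role = character(), stringsAsFactors = FALSE))
  net <- build_network(col)
  expect_equal(nrow(net$nodes), 0L)
  expect_equal(length(connected_components(net)), 0L)
})

test_that("connected components partition the network, largest first", {
  net <- build_network(tiny_collection())
  comps <- connected_components(net)
  expect_length(comps, 1L)
  expect_length(comps[[1]], 5L)

  # two disjoint interactions -> two components of three nodes each
  col <- pathway_collection(
    data.frame(pathway_id = "P1", title = "p", source_db = "synthetic",
               stringsAsFactors = FALSE),
    data.frame(pathway_id = "P1", local_id = c("I1", "I2"),
               type = "directed", stringsAsFactors = FALSE),
    data.frame(pathway_id = "P1", local_id = c("I1", "I1", "I2", "I2"),
               participant_id = c("ensembl:A", "ensembl:B", "ensembl:C",
                                  "ensembl:D"),
               kind = "gene_product",
               role = c("source", "target", "source", "target"),
               stringsAsFactors = FALSE))
  comps2 <- connected_components(build_network(col))
  expect_length(comps2, 2L)
  expect_equal(lengths(comps2), c(3L, 3L))
  # tie broken by smallest member id
  expect_true(comps2[[1]][1] < comps2[[2]][1])
})

test_that("summarize counts multi-occurrence and multi-pathway separately", {
  s <- summarize_network(build_network(tiny_collection()))
  expect_equal(s$n_interaction_nodes, 2L)
  expect_equal(s$n_interactions_multi_occurrence, 1L)
  expect_equal(s$n_interactions_multi_pathway, 1L)
  expect_equal(s$n_nodes, s$n_gene_products + s$n_metabolites +
                 s$n_complexes + s$n_interaction_nodes)
  expect_equal(sum(s$component_sizes), s$n_nodes)

  # duplicate A -> B twice inside one pathway: multi-occurrence only
  col <- tiny_collection()
  col$interactions$pathway_id[2] <- "P1"
  col$participants$pathway_id[3:4] <- "P1"
  col <- pathway_collection(col$pathways,
                            col$interactions[1:2, ],
                            col$participants[1:4, ])
  s2 <- summarize_network(build_network(col))
  expect_equal(s2$n_interactions_multi_occurrence, 1L)
  expect_equal(s2$n_interactions_multi_pathway, 0L)
})

test_that("build_network satisfies its structural invariants on generated collections", {
  for (seed in c(3, 19, 57)) {
    gen <- generate_collection(random_spec(seed))
    net <- build_network(gen$collection, gen$truth$currency_ids)
    nodes <- net$nodes
    is_int <- stats::setNames(nodes$kind == "interaction", nodes$node_id)
    # bipartite: every edge joins an interaction node to a participant node
    expect_true(all(is_int[net$edges$interaction_id]))
    expect_true(all(!is_int[net$edges$participant_id]))
    # degree rule over distinct participants
    deg <- table(unique(net$edges[, c("interaction_id",
                                      "participant_id")])$interaction_id)
    expect_gte(min(deg), 2L)
    expect_equal(sort(names(deg)), sort(nodes$node_id[nodes$kind ==
                                                        "interaction"]))
    # exclusion completeness
    expect_length(intersect(nodes$node_id, gen$truth$currency_ids), 0L)
    # unique (interaction, participant, role) triples
    expect_false(any(duplicated(net$edges)))
  }
})

test_that("build_network is order-invariant and deterministic", {
  gen <- generate_collection(random_spec(23))
  col <- gen$collection
  net1 <- build_network(col, gen$truth$currency_ids)
  shuffled <- with_seed_local(99, pathway_collection(
    col$pathways[sample(nrow(col$pathways)), ],
    col$interactions[sample(nrow(col$interactions)), ],
    col$participants[sample(nrow(col$participants)), ]))
  net2 <- build_network(shuffled, gen$truth$currency_ids)
  expect_equal(net1$nodes, net2$nodes)
  expect_equal(net1$edges, net2$edges)
})

test_that("generator ground truth predicts the network summary exactly", {
  for (seed in c(5, 31)) {
    gen <- generate_collection(random_spec(seed))
    s <- summarize_network(build_network(gen$collection,
                                         gen$truth$currency_ids))
    expect_equal(unclass(s), gen$truth$summary)
  }
})

test_that("graph exports are written and re-readable", {
  net <- build_network(tiny_collection())
  g1 <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, g1)
  g <- igraph::read_graph(g1, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  s1 <- withr::local_tempfile(fileext = ".sif")
  write_sif(net, s1)
  expect_equal(length(readLines(s1)), nrow(net$edges))
  expect_true(file.exists(paste0(s1, ".nodes.tsv")))
})

test_that("exclusion lists parse with comments and blanks", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# currency metabolites", "chebi:ATP  ", "",
               "chebi:H2O # water"), f)
  expect_equal(read_exclusion_list(f), c("chebi:ATP", "chebi:H2O"))
})
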