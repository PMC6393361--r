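small_spec <- function(...) {
  collection_spec(n_pathways = 6, interactions_meanlog = log(14),
                  n_gene_products = 60L, n_metabolites = 20L,
                  n_complexes = 25L, ...)
}

test_that("cross-pathway sharing controls interaction provenance", {
  gen0 <- generate_collection(small_spec(cross_pathway_share_rate = 0,
                                         within_pathway_dup_rate = 0,
                                         seed = 4))
  expect_true(all(lengths(gen0$truth$provenance) == 1L))
  gen1 <- generate_collection(collection_spec(
    n_pathways = 2, interactions_meanlog = log(6),
    cross_pathway_share_rate = 1, within_pathway_dup_rate = 0,
    n_gene_products = 80L, n_metabolites = 20L, n_complexes = 20L,
    seed = 4))
  expect_true(all(lengths(gen1$truth$provenance) == 2L))
  expect_error(collection_spec(n_pathways = 1,
                               cross_pathway_share_rate = 0.5),
               "at least 2 pathways")
})

test_that("collection generation is deterministic under its seed", {
  a <- generate_collection(small_spec(seed = 13))
  b <- generate_collection(small_spec(seed = 13))
  expect_true(collections_equal(a$collection, b$collection))
  expect_identical(a$truth$summary, b$truth$summary)
})

test_that("every generated artifact revalidates against the type invariants", {
  gen <- generate_collection(small_spec(seed = 21))
  expect_silent(validate_collection(gen$collection))
  net <- build_network(gen$collection, gen$truth$currency_ids)
  expr <- generate_expression(net, plant_spec(planted_size = 5, seed = 22))
  expect_true(all(expr$probes$pvalue >= 0 & expr$probes$pvalue <= 1))
  expect_false(any(duplicated(expr$probes$probe_id)))
  expect_true(all(expr$idmap$probe_id %in% expr$probes$probe_id))
})

test_that("the planted module is connected and carries the planted signal", {
  gen <- generate_collection(small_spec(seed = 31))
  net <- build_network(gen$collection, gen$truth$currency_ids)
  expr <- generate_expression(net, plant_spec(planted_size = 6,
                                              planted_p_alpha = 0.05,
                                              seed = 32))
  planted <- expr$truth$planted_genes
  expect_length(planted, 6L)
  # connectivity through shared interaction nodes
  sub_edges <- net$edges[net$edges$participant_id %in% planted, ]
  ints <- unique(sub_edges$interaction_id)
  both <- net$edges[net$edges$interaction_id %in% ints &
                      net$edges$participant_id %in% planted, ]
  g <- igraph::graph_from_data_frame(both[, 1:2], directed = FALSE)
  memb <- igraph::components(g)$membership[planted]
  expect_equal(length(unique(memb)), 1L)
  # planted p-values are small relative to the uniform background
  stats <- expr$truth$gene_stats
  expect_lt(stats::median(stats$pvalue[stats$gene_id %in% planted]), 0.05)
})

test_that("planted p-values follow Beta(alpha, 1) closed forms", {
  alpha <- 0.2
  ps <- unlist(lapply(1:8, function(s) {
    gen <- generate_collection(small_spec(seed = s))
    net <- build_network(gen$collection, gen$truth$currency_ids)
    expr <- generate_expression(net, plant_spec(planted_size = 10,
                                                planted_p_alpha = alpha,
                                                seed = 100 + s))
    stats <- expr$truth$gene_stats
    stats$pvalue[stats$gene_id %in% expr$truth$planted_genes]
  }))
  # Beta(alpha,1) median is 2^(-1/alpha); CDF is p^alpha
  expect_equal(stats::median(ps), 2^(-1 / alpha), tolerance = 0.5)
  ks <- stats::ks.test(ps, function(q) q^alpha)
  expect_gt(ks$p.value, 0.01)
  # alpha = 1 embeds a uniform null
  gen <- generate_collection(small_spec(seed = 3))
  net <- build_network(gen$collection, gen$truth$currency_ids)
  expr1 <- generate_expression(net, plant_spec(planted_size = 10,
                                               planted_p_alpha = 1,
                                               seed = 5))
  stats1 <- expr1$truth$gene_stats
  expect_gt(stats::ks.test(stats1$pvalue, "punif")$p.value, 0.01)
})

test_that("fixed probes-per-gene yields an exact probe count", {
  gen <- generate_collection(small_spec(seed = 41))
  net <- build_network(gen$collection, gen$truth$currency_ids)
  expr <- generate_expression(net, plant_spec(planted_size = 5,
                                              probes_per_gene_fixed = 2,
                                              unmapped_rate = 0,
                                              undetected_rate = 0,
                                              seed = 42))
  n_genes <- sum(net$nodes$kind == "gene_product")
  expect_equal(nrow(expr$probes), 2L * n_genes)
})

test_that("an infeasible plant errors naming the largest available set", {
  gen <- generate_collection(collection_spec(
    n_pathways = 2, interactions_meanlog = log(2), n_gene_products = 400L,
    cross_pathway_share_rate = 0, seed = 6))
  net <- build_network(gen$collection, gen$truth$currency_ids)
  expect_error(generate_expression(net, plant_spec(planted_size = 200,
                                                   seed = 1)),
               "largest has")
})

test_that("label permutation conserves the statistic multiset", {
  tab <- gene_table(sprintf("g%02d", 1:30),
                    log2fc = stats::rnorm(30), pvalue = stats::runif(30))
  perm <- permute_labels(tab, seed = 7)
  expect_setequal(perm$gene_id, tab$gene_id)
  expect_equal(sort(perm$pvalue), sort(tab$pvalue))
  expect_equal(sort(perm$log2fc), sort(tab$log2fc))
  # pairs move together
  key0 <- sort(paste(tab$log2fc, tab$pvalue))
  expect_equal(sort(paste(perm$log2fc, perm$pvalue)), key0)
  # single-gene table is unchanged
  one <- permute_labels(tab[1, ], seed = 3)
  expect_equal(one$gene_id, tab$gene_id[1])
  expect_identical(permute_labels(tab, seed = 7), perm)
})

test_that("pathway gene sets reflect the collection", {
  gen <- generate_collection(small_spec(seed = 51))
  sets <- gene_sets_from_collection(gen$collection)
  expect_true(all(names(sets) %in% gen$collection$pathways$pathway_id))
  pp <- gen$collection$participants
  p1 <- names(sets)[1]
  expect_setequal(as.character(sets[[p1]]),
                  unique(pp$participant_id[pp$pathway_id == p1 &
                                             pp$kind == "gene_product"]))
})
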