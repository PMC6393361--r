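# End-to-end pipeline: configuration plus the simulate / build / modules /
# enrich stages, each rerunnable and seed-deterministic.

#' Pipeline configuration
#'
#' Collects file paths, the significance criterion, search and enrichment
#' parameters, and the master seed for a pipeline run. Any field can be
#' overridden; defaults follow the conventional analysis settings (criterion
#' `(log2FC < -0.58 OR log2FC > 0.58) AND pvalue < 0.05`; five modules,
#' overlap threshold 0.8, search depth 2; 2000 permutations; filters
#' Z > 1.96, permuted p < 0.05, at least five changed genes).
#'
#' @param collection,exclusion_list,probe_table,idmap,gene_sets input file
#'   paths (interchange JSON/TSV, plain-text exclusion list, probe TSV,
#'   2-column id-map TSV, GMT).
#' @param out_dir output directory.
#' @param criterion criterion string.
#' @param merge_rule probe-merge rule, `"min_p"` or `"max_abs_fc"`.
#' @param contrast_label contrast label for annotation.
#' @param n_modules,overlap_threshold,search_depth,max_module_scored,n_calibration_draws
#'   see [search_params()].
#' @param skip_absorbed_seeds see [search_params()].
#' @param n_perm enrichment permutations.
#' @param z_min,p_max,min_changed enrichment result filters.
#' @param seed master seed; all stage seeds are derived from it.
#' @param simulate named list of overrides for [collection_spec()] /
#'   [plant_spec()] fields used by [cmd_simulate()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(collection = NULL, exclusion_list = NULL,
                            probe_table = NULL, idmap = NULL,
                            gene_sets = NULL, out_dir = ".",
                            criterion = "(log2FC < -0.58 OR log2FC > 0.58) AND pvalue < 0.05",
                            merge_rule = "min_p",
                            contrast_label = "contrast",
                            n_modules = 5L, overlap_threshold = 0.8,
                            search_depth = 2L, max_module_scored = 30L,
                            n_calibration_draws = 2000L,
                            skip_absorbed_seeds = TRUE,
                            n_perm = 2000L, z_min = 1.96, p_max = 0.05,
                            min_changed = 5L, seed = 1L,
                            simulate = list()) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [pipeline_config()] arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, vals)
}

config_paths <- function(config, stage, needed) {
  for (field in needed) {
    p <- config[[field]]
    if (is.null(p))
      stop(sprintf("usage error: %s requires config field \"%s\"", stage,
                   field), call. = FALSE)
    if (!file.exists(p))
      stop(sprintf("usage error: %s input does not exist: %s", field, p),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Simulate a complete fixture bundle
#'
#' Generates a synthetic pathway collection with planted expression signal
#' and writes every pipeline input into `out_dir`: `collection.json`,
#' `exclusion.txt` (the currency metabolites), `probes.tsv`, `idmap.tsv`,
#' `genesets.gmt` (per-pathway gene sets), and `truth.json` (ground-truth
#' bookkeeping).
#'
#' @param config a [pipeline_config()]; `config$simulate` may override any
#'   [collection_spec()] or [plant_spec()] field.
#' @return Invisibly, a list with the generated objects and the ground
#'   truth.
#' @export
cmd_simulate <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 2L)
  sim <- config$simulate
  cargs <- sim[names(sim) %in% names(formals(collection_spec))]
  pargs <- sim[names(sim) %in% names(formals(plant_spec))]
  cspec <- do.call(collection_spec, c(cargs, list(seed = seeds[1])))
  gen <- generate_collection(cspec)
  network <- build_network(gen$collection, gen$truth$currency_ids)
  pspec <- do.call(plant_spec, c(pargs, list(seed = seeds[2])))
  expr <- generate_expression(network, pspec)

  p <- function(f) file.path(config$out_dir, f)
  write_collection(gen$collection, p("collection.json"), "json")
  writeLines(c("# synthetic currency metabolites", gen$truth$currency_ids),
             p("exclusion.txt"))
  write_tsv(expr$probes, p("probes.tsv"))
  write_tsv(expr$idmap, p("idmap.tsv"))
  write_gmt(gene_sets_from_collection(gen$collection), p("genesets.gmt"))
  truth <- list(collection = gen$truth[c("n_unique_interactions",
                                         "currency_ids", "summary")],
                planted_genes = expr$truth$planted_genes,
                undetected_probes = expr$truth$undetected_probes)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  message(sprintf("simulated bundle in %s: %d pathways, %d interactions, %d probes",
                  config$out_dir, nrow(gen$collection$pathways),
                  gen$truth$n_unique_interactions, nrow(expr$probes)))
  invisible(list(collection = gen$collection, truth = gen$truth,
                 expression = expr, network = network))
}

#' Build the unified network and write its exports
#'
#' Reads the collection and exclusion list, builds the network, and writes
#' `network.graphml`, `network.sif` (+ attribute TSVs) and `summary.tsv`
#' into `out_dir`.
#'
#' @param config a [pipeline_config()] with `collection` (and optionally
#'   `exclusion_list`) set.
#' @return Invisibly, the `unified_network`.
#' @export
cmd_build <- function(config) {
  config_paths(config, "build", "collection")
  collection <- read_collection(config$collection)
  excl <- if (!is.null(config$exclusion_list)) {
    config_paths(config, "build", "exclusion_list")
    read_exclusion_list(config$exclusion_list)
  } else character()
  network <- build_network(collection, excl)
  if (!nrow(network$nodes))
    warning("empty network: every interaction record was dropped")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  if (nrow(network$nodes)) write_graphml(network, p("network.graphml"))
  write_sif(network, p("network.sif"))
  s <- summarize_network(network)
  scalar <- vapply(s, function(x) length(x) == 1L, TRUE)
  write_tsv(data.frame(statistic = names(s)[scalar],
                       value = unlist(s[scalar]), stringsAsFactors = FALSE),
            p("summary.tsv"))
  write_tsv(data.frame(component = seq_along(s$component_sizes),
                       size = s$component_sizes), p("components.tsv"))
  write_tsv(data.frame(type = names(s$interaction_type_census),
                       count = s$interaction_type_census,
                       stringsAsFactors = FALSE), p("type_census.tsv"))
  message(sprintf("built network: %d nodes, %d edges (%d records dropped)",
                  s$n_nodes, s$n_edges, network$report$n_records_dropped))
  invisible(network)
}

#' Discover active modules and write module reports
#'
#' Runs the full expression-to-modules chain: detection filtering,
#' probe-to-gene merging, network annotation, z-scoring, Monte-Carlo
#' calibration, greedy search, and overlap-filtered selection. Writes per
#' module a node table (`module_<i>.tsv`) and subnetwork GraphML, plus
#' `modules_summary.tsv` and `pathway_contributions.tsv`.
#'
#' @param config a [pipeline_config()] with `collection`, `probe_table`,
#'   `idmap` (and optionally `exclusion_list`) set.
#' @return Invisibly, the `active_module_set`.
#' @export
cmd_modules <- function(config) {
  config_paths(config, "modules", c("collection", "probe_table", "idmap"))
  network <- build_quiet(config)
  probes <- filter_undetected(read_probe_table(config$probe_table))
  table <- map_and_merge(probes, read_idmap(config$idmap),
                         config$merge_rule, config$contrast_label)
  network <- annotate_network(network, table)
  seeds <- derive_seeds(config$seed, 4L)
  params <- search_params(n_modules = config$n_modules,
                          overlap_threshold = config$overlap_threshold,
                          search_depth = config$search_depth,
                          max_module_scored = config$max_module_scored,
                          n_calibration_draws = config$n_calibration_draws,
                          seed = seeds[3],
                          skip_absorbed_seeds = config$skip_absorbed_seeds)
  result <- find_active_modules(network, config$contrast_label, params)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  contrib_rows <- list()
  for (i in seq_along(result$modules)) {
    mod <- result$modules[[i]]
    rep_i <- module_report(mod, network, config$criterion, table)
    node_tab <- rep_i$node_table
    node_tab$z <- ifelse(node_tab$scored,
                         unname(result$scores[node_tab$node_id]), NA_real_)
    write_tsv(format_num(node_tab), p(sprintf("module_%d.tsv", i)))
    write_graphml(network, p(sprintf("module_%d.graphml", i)), mod$members)
    if (length(rep_i$pathway_contributions))
      contrib_rows[[i]] <- data.frame(
        module = i, pathway_id = names(rep_i$pathway_contributions),
        n_interactions = rep_i$pathway_contributions,
        stringsAsFactors = FALSE)
  }
  write_tsv(format_num(summary(result)), p("modules_summary.tsv"))
  contrib <- if (length(contrib_rows)) do.call(rbind, contrib_rows) else
    data.frame(module = integer(), pathway_id = character(),
               n_interactions = integer(), stringsAsFactors = FALSE)
  write_tsv(contrib, p("pathway_contributions.tsv"))
  message(sprintf("selected %d module(s); top corrected score %.3f",
                  length(result$modules),
                  if (length(result$modules)) result$modules[[1]]$sA else NA))
  invisible(result)
}

build_quiet <- function(config) {
  collection <- read_collection(config$collection)
  excl <- if (!is.null(config$exclusion_list))
    read_exclusion_list(config$exclusion_list) else character()
  build_network(collection, excl)
}

#' Run overrepresentation enrichment and write result tables
#'
#' Writes the full ranked table (`enrichment.tsv`) and the filtered table
#' (`enrichment_filtered.tsv`) using the configured filter triple.
#'
#' @param config a [pipeline_config()] with `probe_table`, `idmap` and
#'   `gene_sets` set.
#' @return Invisibly, the full `enrichment_result`.
#' @export
cmd_enrich <- function(config) {
  config_paths(config, "enrich", c("probe_table", "idmap", "gene_sets"))
  probes <- filter_undetected(read_probe_table(config$probe_table))
  table <- map_and_merge(probes, read_idmap(config$idmap),
                         config$merge_rule, config$contrast_label)
  if (!nrow(table)) stop("empty background: no measured genes",
                         call. = FALSE)
  sets <- read_gmt(config$gene_sets)
  seeds <- derive_seeds(config$seed, 4L)
  rows <- run_enrichment(sets, table, config$criterion, config$n_perm,
                         seed = seeds[4])
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  kept <- filter_results(rows, config$z_min, config$p_max,
                         config$min_changed)
  full <- as.data.frame(rows)
  full$kept <- rows$set_id %in% kept$set_id
  write_tsv(format_num(full), file.path(config$out_dir, "enrichment.tsv"))
  write_tsv(format_num(as.data.frame(kept)),
            file.path(config$out_dir, "enrichment_filtered.tsv"))
  message(sprintf("enrichment over %d set(s): %d pass the filters",
                  nrow(rows), nrow(kept)))
  invisible(rows)
}

# Fixed-precision numeric formatting so stage outputs are byte-stable.
format_num <- function(df, digits = 6) {
  for (j in seq_along(df))
    if (is.double(df[[j]]))
      df[[j]] <- ifelse(is.na(df[[j]]), NA,
                        formatC(df[[j]], digits = digits, format = "g"))
  df
}
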