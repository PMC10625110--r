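#' Run the full synthetic EMT regulome pipeline
#'
#' Chains every stage on one configuration: simulate all inputs; run
#' per-dataset differential expression and the direction-consistency
#' integration; build the merged interaction graph restricted to the
#' consensus DEGs and rank hubs by maximal clique centrality; quantify
#' and classify the inhibitor screen and summarize target kinases by
#' family; and build the function-connectivity regulome from two
#' enrichment queries — the consensus DEG set (origin `EMT`) and the
#' top hub's interaction neighbourhood (origin `hub-interactome`) —
#' exported as GraphML. Recovery statistics against the planted truth are
#' computed for each stage.
#'
#' @param config an [emt_config()] object.
#' @param out_dir optional directory; when given, all synthetic inputs
#'   and stage outputs (consensus TSV, hub TSV, classification TSV,
#'   regulome GraphML + edges) are written there.
#' @param min_fraction,alpha consistency-integration parameters.
#' @param cutoff regulome edge-similarity cutoff.
#' @param scatter_method scatter statistic for the screen.
#' @return An `emt_pipeline` list: `config`, `consensus`, `hub_scores`,
#'   `cliques`, `screen_auc`, `classification`, `kinase_summary`,
#'   `enrichment` (list per origin), `network`, `recovery` (named list of
#'   recovery statistics against the planted truth), `truth`, `files`.
#' @examples
#' \donttest{
#' res <- run_emt_pipeline(emt_config(seed = 1, n_inhibitors = 30,
#'   n_kinases = 20, n_replicates = 2, cells_per_well = 8))
#' res$recovery
#' }
#' @export
run_emt_pipeline <- function(config, out_dir = NULL, min_fraction = 0.8,
                             alpha = 0.05, cutoff = 0.375,
                             scatter_method = "centroid") {
  validate_emt_config(config)
  if (!is.null(out_dir)) {
    sim <- simulate_emt_inputs(config, out_dir)
  } else {
    sim <- list(counts = simulate_count_datasets(config),
                interactome = simulate_interactome(config),
                screen = simulate_screen_tracks(config),
                terms = simulate_term_annotation(config),
                files = character(0))
  }

  # differential expression + consistency integration
  de_tables <- lapply(sim$counts$datasets, simple_de)
  consensus <- integrate_consistency(de_tables,
                                     min_fraction = min_fraction,
                                     alpha = alpha)

  # interaction graph restricted to the consensus signature, MCC hubs
  graph <- build_interaction_graph(sim$interactome$edges,
                                   restrict_to = consensus$gene)
  cliques <- maximal_cliques(graph)
  hubs <- mcc_scores(graph)

  # inhibitor screen
  screen_auc <- quantify_screen(sim$screen$tracks,
                                method = scatter_method)
  classification <- classify_inhibitors(screen_auc)
  kinase_summary <- summarize_kinases(classification,
                                      sim$screen$inhibitor_kinase,
                                      sim$screen$kinase_family)

  # regulome: enrichment of the consensus DEGs and of the top hub's
  # interaction neighbourhood, joined into one similarity network
  top_hub <- hubs$gene[1]
  neighbours <- unique(c(top_hub,
                         igraph::V(graph)$name[
                           as.integer(igraph::neighbors(
                             graph, top_hub))]))
  enrichment <- list(
    EMT = enrich_terms(consensus$gene, sim$terms$annotation,
                       alpha = alpha, origin = "EMT"),
    `hub-interactome` = enrich_terms(
      neighbours, sim$terms$annotation, alpha = alpha,
      origin = "hub-interactome"))
  network <- build_function_network(enrichment, cutoff = cutoff)

  recovery <- pipeline_recovery(sim, consensus, hubs, classification,
                                config)

  files <- sim$files
  if (!is.null(out_dir)) {
    files["consensus"] <- file.path(out_dir, "consensus.tsv")
    write_consensus(consensus, files["consensus"])
    files["hubs"] <- file.path(out_dir, "hubs.tsv")
    write_hub_scores(hubs, files["hubs"])
    files["classification"] <- file.path(out_dir, "classification.tsv")
    utils::write.table(classification$final, files["classification"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files["regulome_graphml"] <- file.path(out_dir, "regulome.graphml")
    files["regulome_edges"] <- file.path(out_dir, "regulome_edges.tsv")
    write_function_network(network, files["regulome_graphml"],
                           files["regulome_edges"])
  }

  structure(list(config = config, consensus = consensus,
                 hub_scores = hubs, cliques = cliques,
                 screen_auc = screen_auc,
                 classification = classification,
                 kinase_summary = kinase_summary,
                 enrichment = enrichment, network = network,
                 recovery = recovery,
                 truth = list(genes = sim$counts$truth,
                              hubs = sim$interactome$truth,
                              inhibitors = sim$screen$truth,
                              terms = sim$terms$truth),
                 files = files),
            class = "emt_pipeline")
}

# Recovery statistics of every stage against the planted truth.
pipeline_recovery <- function(sim, consensus, hubs, classification,
                              config) {
  gt <- sim$counts$truth
  consistent <- gt$gene[gt$role == "consistent"]
  decoys <- gt$gene[gt$role == "decoy"]
  cons_dir <- stats::setNames(consensus$direction, consensus$gene)
  deg_recovery <- if (length(consistent)) {
    truth_dir <- gt$direction[match(consistent, gt$gene)]
    got <- cons_dir[consistent]
    mean(!is.na(got) & got == truth_dir)
  } else NA_real_
  decoy_retention <- if (length(decoys)) {
    mean(decoys %in% consensus$gene)
  } else NA_real_

  planted_hubs <- sim$interactome$truth$gene[sim$interactome$truth$is_hub]
  hub_recovery <- if (length(planted_hubs)) {
    top <- hubs$gene[hubs$rank <= length(planted_hubs)]
    mean(planted_hubs %in% top)
  } else NA_real_

  tr <- sim$screen$truth
  planted_inh <- tr[tr$category != "unclassified", , drop = FALSE]
  screen_recovery <- if (nrow(planted_inh)) {
    got <- classification$final$category[
      match(planted_inh$inhibitor, classification$final$inhibitor)]
    mean(got == planted_inh$category)
  } else NA_real_

  list(deg_recovery = deg_recovery,
       decoy_retention = decoy_retention,
       hub_recovery = hub_recovery,
       screen_recovery = screen_recovery)
}

#' @export
print.emt_pipeline <- function(x, ...) {
  cat("EMT regulome pipeline (seed ", x$config$seed, ")\n", sep = "")
  cat("  consensus DEGs : ", sum(x$consensus$direction == "up"), " up / ",
      sum(x$consensus$direction == "down"), " down\n", sep = "")
  cat("  top hubs (MCC) : ",
      paste(utils::head(x$hub_scores$gene, x$config$n_hubs),
            collapse = ", "), "\n", sep = "")
  tab <- table(x$classification$final$category)
  cat("  screen         : ",
      paste(names(tab), tab, sep = " = ", collapse = ", "), "\n",
      sep = "")
  cat("  regulome       : ", nrow(x$network$nodes), " terms, ",
      nrow(x$network$edges), " edges, ", max(x$network$nodes$cluster),
      " clusters\n", sep = "")
  cat("  recovery       : DEG ", round(100 * x$recovery$deg_recovery, 1),
      "%, decoy ", round(100 * x$recovery$decoy_retention, 1),
      "%, hubs ", round(100 * x$recovery$hub_recovery, 1),
      "%, screen ", round(100 * x$recovery$screen_recovery, 1), "%\n",
      sep = "")
  invisible(x)
}
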