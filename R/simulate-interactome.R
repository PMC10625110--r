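#' Simulate protein-interaction edge lists with planted MCC hubs
#'
#' Emulates merged exports from several interaction databases over the
#' shared gene universe. Each planted hub gene is embedded in three
#' mutually disjoint cliques of size four (disjoint apart from the hub),
#' so its maximal-clique-centrality is exactly `3 * 3! = 18` and provably
#' separates it from the sparse Erdos-Renyi background, whose nodes sit in
#' small cliques only. Hubs and their clique partners are drawn from the
#' fully consistent planted DEGs so that restricting the graph to a
#' consensus DEG set retains them.
#'
#' Edges are split across three source tags (`stringdb`, `bioplex`,
#' `ania`); a fraction is listed under two sources to exercise duplicate
#' merging downstream.
#'
#' @param config an [emt_config()] object; requires
#'   `n_consistent_degs >= n_hubs * 10` (each hub needs nine dedicated
#'   clique partners).
#' @return A list with `edges` (data.frame `node_a`, `node_b`, `source`),
#'   and `truth` (data.frame `gene`, `is_hub`).
#' @examples
#' sim <- simulate_interactome(emt_config(seed = 1, n_genes = 300,
#'   n_consistent_degs = 60, n_decoy_degs = 0))
#' head(sim$edges)
#' @export
simulate_interactome <- function(config) {
  validate_emt_config(config)
  need <- config$n_hubs * 10L
  if (config$n_consistent_degs < need) {
    stop("configuration error: need n_consistent_degs >= ", need,
         " to embed ", config$n_hubs, " hubs in disjoint cliques",
         call. = FALSE)
  }
  restore <- .Random.seed_guard(sim_seed(config, 3))
  on.exit(restore(), add = TRUE)

  genes <- gene_universe(config)
  pl <- planted_genes(config)
  consistent <- pl$gene[pl$role == "consistent"]
  hubs <- consistent[seq_len(config$n_hubs)]
  partners <- consistent[config$n_hubs + seq_len(config$n_hubs * 9L)]

  edge_a <- character(0)
  edge_b <- character(0)
  p <- 0L
  for (h in hubs) {
    for (cl in 1:3) {
      members <- c(h, partners[p + 1:3])
      p <- p + 3L
      pr <- utils::combn(members, 2)
      edge_a <- c(edge_a, pr[1, ])
      edge_b <- c(edge_b, pr[2, ])
    }
  }
  clique_nodes <- c(hubs, partners)

  # sparse background over the remaining genes; kept off the clique nodes
  # so planted MCC values stay exact
  background <- setdiff(genes, clique_nodes)
  nb <- length(background)
  if (nb >= 2) {
    n_bg_edges <- round(1.5 * nb)
    ia <- sample.int(nb, n_bg_edges, replace = TRUE)
    ib <- sample.int(nb, n_bg_edges, replace = TRUE)
    keep <- ia != ib
    a <- pmin(ia[keep], ib[keep])
    b <- pmax(ia[keep], ib[keep])
    dup <- duplicated(paste(a, b))
    edge_a <- c(edge_a, background[a[!dup]])
    edge_b <- c(edge_b, background[b[!dup]])
  }

  src <- sample(c("stringdb", "bioplex", "ania"), length(edge_a),
                replace = TRUE)
  edges <- data.frame(node_a = edge_a, node_b = edge_b, source = src,
                      stringsAsFactors = FALSE)
  # ~10% of edges reported by a second database
  second <- which(stats::runif(nrow(edges)) < 0.1)
  if (length(second)) {
    alt <- vapply(edges$source[second], function(s) {
      sample(setdiff(c("stringdb", "bioplex", "ania"), s), 1)
    }, character(1))
    edges <- rbind(edges,
                   data.frame(node_a = edges$node_a[second],
                              node_b = edges$node_b[second],
                              source = alt, stringsAsFactors = FALSE))
  }
  edges <- edges[order(edges$node_a, edges$node_b, edges$source), ]
  rownames(edges) <- NULL

  truth <- data.frame(gene = genes, is_hub = genes %in% hubs,
                      stringsAsFactors = FALSE)
  list(edges = edges, truth = truth)
}
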