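#' Hypergeometric term enrichment with FDR control
#'
#' Classic over-representation analysis: for each term, the one-sided
#' hypergeometric upper-tail probability of observing at least the
#' realized overlap between the query and the term's member set within
#' the annotation universe, followed by Benjamini-Hochberg adjustment
#' across all tested terms. Terms with `fdr < alpha` are flagged as
#' retained.
#'
#' @param query character vector of query genes; members outside the
#'   annotation universe are dropped with a warning.
#' @param annotation a `term_annotation` (see [read_gmt()]).
#' @param alpha FDR threshold for retention.
#' @param origin label recorded on every row (e.g. `"EMT"`,
#'   `"YWHAG-kinome"`); distinguishes query provenance when several
#'   enrichment results are merged into one function network.
#' @return An `enrichment_result` data.frame: `term`, `name`, `k`
#'   (query-term overlap), `K` (term size), `n` (query size), `N`
#'   (universe size), `p_value`, `fdr`, `retained`, `origin`,
#'   `overlap_genes` (`;`-joined overlap members).
#' @examples
#' ann <- read_gmt(textConnection(
#'   "T1\tdesc\tg1\tg2\tg3\tg4\nT2\tdesc\tg5\tg6"),
#'   universe = paste0("g", 1:10))
#' enrich_terms(c("g1", "g2", "g3", "g4", "g7"), ann)
#' @export
enrich_terms <- function(query, annotation, alpha = 0.05,
                         origin = "query") {
  stopifnot(inherits(annotation, "term_annotation"))
  query <- unique(query)
  if (!length(query)) stop("empty query gene set", call. = FALSE)
  outside <- setdiff(query, annotation$universe)
  if (length(outside)) {
    warning("dropping ", length(outside),
            " query gene(s) outside the annotation universe",
            call. = FALSE)
    query <- setdiff(query, outside)
    if (!length(query)) {
      stop("empty query after restricting to the universe", call. = FALSE)
    }
  }
  N <- length(annotation$universe)
  n <- length(query)
  terms <- names(annotation$sets)
  K <- lengths(annotation$sets)
  ov <- lapply(annotation$sets, intersect, query)
  k <- lengths(ov)
  # P(X >= k) for X ~ Hypergeom(N, K, n)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fdr <- stats::p.adjust(p, method = "BH")
  res <- data.frame(
    term = terms,
    name = unname(annotation$names[terms]),
    k = unname(k), K = unname(K), n = n, N = N,
    p_value = unname(p), fdr = unname(fdr),
    retained = unname(fdr) < alpha,
    origin = origin,
    overlap_genes = vapply(ov, function(g) paste(sort(g), collapse = ";"),
                           character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  res <- res[order(res$p_value, res$term), ]
  rownames(res) <- NULL
  structure(res, alpha = alpha,
            class = c("enrichment_result", "data.frame"))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment_result (origin ", x$origin[1], "): ", sum(x$retained),
      " of ", nrow(x), " terms at FDR < ", attr(x, "alpha"), "\n",
      sep = "")
  print(utils::head(as.data.frame(x)[c("term", "name", "k", "K",
                                       "p_value", "fdr")], 8))
  invisible(x)
}

# Wang S-values of every ancestor of `term`: S(term) = 1 and
# S(parent) = max over child paths of w * S(child), propagated up the DAG.
wang_svalues <- function(term, dag, edge_weight = 0.8) {
  if (!term %in% names(dag$parents)) {
    stop("unknown term '", term, "'", call. = FALSE)
  }
  s <- stats::setNames(1, term)
  frontier <- term
  while (length(frontier)) {
    nxt <- character(0)
    for (ch in frontier) {
      for (pa in dag$parents[[ch]]) {
        cand <- edge_weight * s[[ch]]
        if (is.na(s[pa]) || cand > s[[pa]]) {
          s[pa] <- cand
          nxt <- c(nxt, pa)
        }
      }
    }
    frontier <- unique(nxt)
  }
  s
}

#' Wang semantic similarity between two terms of a rooted DAG
#'
#' The graph-based measure of Wang et al.: each term's semantic value is
#' spread over its ancestors with a per-edge decay (`edge_weight` for
#' is_a), and similarity is the summed contribution of common ancestors
#' relative to both terms' total semantic values:
#' `sim = sum_{a in anc(t1) n anc(t2)} (S1(a) + S2(a)) / (SV1 + SV2)`.
#'
#' @param t1,t2 term ids present in `dag`.
#' @param dag a `term_dag` (see [read_obo_dag()]).
#' @param edge_weight decay per is_a edge, in `(0, 1)`; 0.8 is the
#'   standard choice.
#' @return Similarity in `[0, 1]`; 1 for identical terms.
#' @examples
#' dag <- new_term_dag(list(R = character(0), A = "R"))
#' wang_similarity("A", "R", dag)   # (0.8 + 0.8) / (1.8 + 1) = 0.571...
#' @export
wang_similarity <- function(t1, t2, dag, edge_weight = 0.8) {
  s1 <- wang_svalues(t1, dag, edge_weight)
  s2 <- wang_svalues(t2, dag, edge_weight)
  common <- intersect(names(s1), names(s2))
  sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
}

#' Pairwise Wang similarity matrix for a set of terms
#'
#' @param terms character vector of term ids.
#' @inheritParams wang_similarity
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
term_similarity_matrix <- function(terms, dag, edge_weight = 0.8) {
  sv <- lapply(terms, wang_svalues, dag = dag, edge_weight = edge_weight)
  names(sv) <- terms
  m <- matrix(1, length(terms), length(terms),
              dimnames = list(terms, terms))
  if (length(terms) > 1) {
    for (i in seq_len(length(terms) - 1)) {
      for (j in (i + 1):length(terms)) {
        common <- intersect(names(sv[[i]]), names(sv[[j]]))
        s <- sum(sv[[i]][common] + sv[[j]][common]) /
          (sum(sv[[i]]) + sum(sv[[j]]))
        m[i, j] <- m[j, i] <- s
      }
    }
  }
  m
}

# Best-match-average similarity between two term sets given a pairwise
# similarity matrix.
bma_similarity <- function(sim, terms_a, terms_b) {
  sub <- sim[terms_a, terms_b, drop = FALSE]
  mean(c(apply(sub, 1, max), apply(sub, 2, max)))
}

#' Cluster terms by semantic similarity
#'
#' Hierarchical clustering (Ward linkage) on the distance
#' `1 - wang_similarity`, cut into `k` clusters. With `k = "auto"` the
#' cut maximizing the mean silhouette width over `k = 2..10` is chosen.
#' Between-cluster best-match-average (BMA) similarities are reported.
#'
#' @param terms character vector of term ids (>= 2).
#' @param dag a `term_dag`.
#' @param k number of clusters, or `"auto"`.
#' @param edge_weight Wang is_a decay.
#' @return A `term_clusters` list: `assignment` (named integer),
#'   `k`, `silhouette` (mean width of the chosen cut, NA for k forced),
#'   `bma` (k x k between-cluster BMA matrix), `hclust`.
#' @export
cluster_terms <- function(terms, dag, k = "auto", edge_weight = 0.8) {
  terms <- unique(terms)
  if (length(terms) < 2) stop("need >= 2 terms to cluster", call. = FALSE)
  if (is.numeric(k) && k > length(terms)) {
    stop("k exceeds the number of terms", call. = FALSE)
  }
  sim <- term_similarity_matrix(terms, dag, edge_weight)
  d <- stats::as.dist(1 - sim)
  hc <- stats::hclust(d, method = "ward.D2")
  sil_mean <- NA_real_
  if (identical(k, "auto")) {
    ks <- 2:min(10, length(terms) - 1)
    sil <- vapply(ks, function(kk) {
      cl <- stats::cutree(hc, kk)
      mean(cluster::silhouette(cl, d)[, "sil_width"])
    }, numeric(1))
    k <- ks[which.max(sil)]
    sil_mean <- max(sil)
  }
  assignment <- stats::cutree(hc, k)
  bma <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      bma[i, j] <- bma_similarity(sim, terms[assignment == i],
                                  terms[assignment == j])
    }
  }
  structure(list(assignment = assignment, k = k, silhouette = sil_mean,
                 bma = bma, hclust = hc),
            class = "term_clusters")
}

#' @export
print.term_clusters <- function(x, ...) {
  cat("term_clusters: ", length(x$assignment), " terms in ", x$k,
      " clusters", sep = "")
  if (!is.na(x$silhouette)) {
    cat(" (mean silhouette ", round(x$silhouette, 3), ")", sep = "")
  }
  cat("\n")
  print(table(x$assignment))
  invisible(x)
}

# Combined shared-gene coefficient between two gene sets:
# combine_k * Jaccard + (1 - combine_k) * overlap coefficient.
combined_coefficient <- function(a, b, combine_k = 0.5,
                                 method = c("combined", "jaccard",
                                            "overlap")) {
  method <- match.arg(method)
  ov <- set_overlap(a, b)
  switch(method,
         combined = combine_k * ov$jaccard +
           (1 - combine_k) * ov$overlap_coefficient,
         jaccard = ov$jaccard,
         overlap = ov$overlap_coefficient)
}

# words ignored when deriving cluster annotation labels
.annotation_stopwords <- c(
  "of", "the", "and", "to", "in", "a", "an", "by", "via", "term",
  "process", "regulation", "positive", "negative", "pathway", "cell",
  "cellular")

#' Build an enrichment-map style function-connectivity network
#'
#' Joins retained enriched terms (from one or several enrichment runs,
#' each carrying its origin label) into an undirected network in which
#' two terms are connected when the shared-gene similarity of their
#' query-overlap gene sets reaches `cutoff`. Similarity is the combined
#' coefficient `combine_k * Jaccard + (1 - combine_k) * overlap` by
#' default (pure Jaccard or overlap selectable). Clusters are the
#' connected components above the cutoff; each cluster is annotated with
#' the most frequent non-stopword tokens of its term names.
#'
#' @param results an `enrichment_result` or list of them.
#' @param cutoff edge similarity cutoff in `[0, 1]` (0.375 is the
#'   enrichment-map convention used for the regulome).
#' @param combine_k weight of the Jaccard part of the combined
#'   coefficient.
#' @param method `"combined"`, `"jaccard"` or `"overlap"`.
#' @return A `function_network` list: `graph` (igraph with node
#'   attributes `origin`, `cluster`, `annotation`, `n_genes` and edge
#'   attribute `similarity`), `nodes`, `edges` (data.frames).
#' @export
build_function_network <- function(results, cutoff = 0.375,
                                   combine_k = 0.5,
                                   method = c("combined", "jaccard",
                                              "overlap")) {
  method <- match.arg(method)
  if (!is.numeric(cutoff) || cutoff < 0 || cutoff > 1) {
    stop("parameter error: cutoff must lie in [0, 1]", call. = FALSE)
  }
  if (inherits(results, "enrichment_result")) results <- list(results)
  kept <- do.call(rbind, lapply(results, function(r) {
    as.data.frame(r)[r$retained, , drop = FALSE]
  }))
  if (is.null(kept) || nrow(kept) < 2) {
    stop("need >= 2 retained enriched terms to build a network",
         call. = FALSE)
  }
  # a term enriched for several origins keeps one node per origin-term
  kept$node_id <- paste(kept$origin, kept$term, sep = ":")
  sets <- strsplit(kept$overlap_genes, ";", fixed = TRUE)
  names(sets) <- kept$node_id

  n <- nrow(kept)
  ei <- integer(0); ej <- integer(0); es <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- combined_coefficient(sets[[i]], sets[[j]],
                                combine_k = combine_k, method = method)
      if (s >= cutoff) {
        ei <- c(ei, i); ej <- c(ej, j); es <- c(es, s)
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = kept$node_id)
  if (length(ei)) {
    g <- igraph::add_edges(g, rbind(ei, ej))
    g <- igraph::set_edge_attr(g, "similarity", value = es)
  }
  comp <- igraph::components(g)$membership
  ann <- vapply(seq_len(max(comp)), function(cl) {
    toks <- tolower(unlist(strsplit(kept$name[comp == cl], "[^A-Za-z]+")))
    toks <- toks[nzchar(toks) & !toks %in% .annotation_stopwords]
    if (!length(toks)) return("unannotated")
    paste(names(sort(table(toks), decreasing = TRUE))[1:min(3, length(unique(toks)))],
          collapse = " ")
  }, character(1))
  g <- igraph::set_vertex_attr(g, "term", value = kept$term)
  g <- igraph::set_vertex_attr(g, "origin", value = kept$origin)
  g <- igraph::set_vertex_attr(g, "cluster", value = comp)
  g <- igraph::set_vertex_attr(g, "annotation", value = ann[comp])
  g <- igraph::set_vertex_attr(g, "n_genes", value = lengths(sets))
  nodes <- data.frame(node_id = kept$node_id, term = kept$term,
                      name = kept$name, origin = kept$origin,
                      cluster = unname(comp),
                      annotation = ann[comp],
                      n_genes = unname(lengths(sets)),
                      stringsAsFactors = FALSE)
  edges <- data.frame(node_a = kept$node_id[ei], node_b = kept$node_id[ej],
                      similarity = es, stringsAsFactors = FALSE)
  structure(list(graph = g, nodes = nodes, edges = edges,
                 cutoff = cutoff, method = method, combine_k = combine_k),
            class = "function_network")
}

#' @export
print.function_network <- function(x, ...) {
  cat("function_network: ", nrow(x$nodes), " terms, ", nrow(x$edges),
      " edges at similarity >= ", x$cutoff, " (",
      max(x$nodes$cluster), " clusters)\n", sep = "")
  invisible(x)
}

#' Export a function network as GraphML and edge-list TSV
#'
#' @param network a `function_network`.
#' @param graphml_path output GraphML path (written via igraph).
#' @param edges_path optional output TSV of edges with similarities.
#' @export
write_function_network <- function(network, graphml_path,
                                   edges_path = NULL) {
  stopifnot(inherits(network, "function_network"))
  igraph::write_graph(network$graph, graphml_path, format = "graphml")
  if (!is.null(edges_path)) {
    utils::write.table(network$edges, edges_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(graphml_path)
}
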