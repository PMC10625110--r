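#' Build a merged gene-gene interaction graph from edge lists
#'
#' Merges edge lists from several interaction databases into one simple
#' undirected graph over gene symbols. Duplicate and reversed pairs are
#' collapsed into a single edge whose `sources` attribute accumulates the
#' contributing database tags; self-loops are dropped with a warning.
#' Optionally restricts to the subgraph induced by a gene set (typically
#' the consensus DEG list).
#'
#' @param edges one or more edge inputs: paths to 3-column TSVs
#'   (`node_a`, `node_b`, `source`; no header, `#` comments allowed) or
#'   data.frames with those columns, in a list or vector.
#' @param restrict_to optional character vector of genes; the result is
#'   the induced subgraph on them.
#' @return An [igraph][igraph::graph] object with vertex attribute `name`
#'   and edge attribute `sources` (`;`-joined database tags).
#' @examples
#' g <- build_interaction_graph(data.frame(
#'   node_a = c("a", "b"), node_b = c("b", "a"),
#'   source = c("stringdb", "bioplex")))
#' igraph::E(g)$sources
#' @export
build_interaction_graph <- function(edges, restrict_to = NULL) {
  if (is.data.frame(edges)) edges <- list(edges)
  parts <- lapply(edges, function(e) {
    if (is.character(e)) read_edge_list(e) else {
      stopifnot(all(c("node_a", "node_b", "source") %in% colnames(e)))
      e[c("node_a", "node_b", "source")]
    }
  })
  df <- do.call(rbind, parts)
  loops <- df$node_a == df$node_b
  if (any(loops)) {
    warning("dropping ", sum(loops), " self-loop(s): ",
            paste(utils::head(unique(df$node_a[loops]), 5),
                  collapse = ", "), call. = FALSE)
    df <- df[!loops, , drop = FALSE]
  }
  a <- pmin(df$node_a, df$node_b)
  b <- pmax(df$node_a, df$node_b)
  key <- paste(a, b, sep = "\r")
  src <- vapply(split(df$source, key), function(s) {
    paste(sort(unique(s)), collapse = ";")
  }, character(1))
  uk <- names(src)
  ab <- do.call(rbind, strsplit(uk, "\r", fixed = TRUE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ab[, 1], to = ab[, 2], sources = unname(src),
               stringsAsFactors = FALSE),
    directed = FALSE)
  if (!is.null(restrict_to)) {
    keep <- intersect(igraph::V(g)$name, restrict_to)
    g <- igraph::induced_subgraph(g, keep)
  }
  g
}

#' Enumerate the maximal cliques of an interaction graph
#'
#' Every maximal clique is reported exactly once; isolated nodes are
#' reported as singleton cliques so that MCC ranking stays total over the
#' node set. Enumeration is Bron-Kerbosch with pivoting (via igraph); a
#' configurable cap guards against pathological dense graphs.
#'
#' @param graph an igraph object (simple, undirected).
#' @param max_cliques_cap abort with an error if the graph has more
#'   maximal cliques than this.
#' @return A `clique_set`: list of character vectors (node names), sorted
#'   by decreasing size then lexicographically.
#' @examples
#' g <- build_interaction_graph(data.frame(
#'   node_a = c("a", "a", "b", "c"), node_b = c("b", "c", "c", "d"),
#'   source = "x"))
#' maximal_cliques(g)
#' @export
maximal_cliques <- function(graph, max_cliques_cap = 1e6) {
  stopifnot(igraph::is_igraph(graph))
  n_cl <- igraph::count_max_cliques(graph, min = 1)
  if (n_cl > max_cliques_cap) {
    stop("graph has ", n_cl, " maximal cliques, above the cap of ",
         max_cliques_cap, "; raise max_cliques_cap to proceed",
         call. = FALSE)
  }
  cl <- igraph::max_cliques(graph, min = 1)
  cl <- lapply(cl, function(v) sort(igraph::V(graph)$name[v]))
  first <- vapply(cl, `[`, character(1), 1)
  cl <- cl[order(-lengths(cl), first)]
  structure(cl, class = "clique_set")
}

#' @export
print.clique_set <- function(x, ...) {
  cat("clique_set: ", length(x), " maximal cliques (sizes ",
      paste(range(lengths(x)), collapse = "-"), ")\n", sep = "")
  invisible(x)
}

#' Maximal clique centrality (MCC) hub scores
#'
#' For each node `v`, `MCC(v) = sum over maximal cliques C containing v of
#' (|C| - 1)!`. Isolated nodes sit in a singleton maximal clique and score
#' `0! = 1`, keeping the ranking total. Nodes are ranked by decreasing
#' MCC; ties share the minimum rank and are ordered lexicographically by
#' gene id for reproducible reports. A `degree` column is included for
#' comparison.
#'
#' @param graph an igraph object.
#' @param top_k optional; if given, only the `top_k` best-ranked rows are
#'   returned (ties at the boundary included).
#' @param max_cliques_cap passed to [maximal_cliques()].
#' @return A `hub_scores` data.frame: `gene`, `mcc`, `degree`, `rank`.
#' @examples
#' g <- build_interaction_graph(data.frame(
#'   node_a = c("a", "a", "b", "c"), node_b = c("b", "c", "c", "d"),
#'   source = "x"))
#' mcc_scores(g)   # c: 2! + 1! = 3; a, b: 2; d: 1
#' @export
mcc_scores <- function(graph, top_k = NULL, max_cliques_cap = 1e6) {
  if (!is.null(top_k) && (!is.numeric(top_k) || top_k < 1)) {
    stop("parameter error: top_k must be >= 1", call. = FALSE)
  }
  cl <- maximal_cliques(graph, max_cliques_cap = max_cliques_cap)
  nodes <- sort(igraph::V(graph)$name)
  mcc <- stats::setNames(numeric(length(nodes)), nodes)
  for (C in cl) mcc[C] <- mcc[C] + factorial(length(C) - 1)
  deg <- igraph::degree(graph)[nodes]
  ord <- order(-mcc, nodes)
  res <- data.frame(gene = nodes[ord], mcc = unname(mcc[ord]),
                    degree = unname(deg[ord]), stringsAsFactors = FALSE)
  res$rank <- match(res$mcc, res$mcc)   # ties share the minimum rank
  if (!is.null(top_k)) res <- res[res$rank <= top_k, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("hub_scores", "data.frame")
  res
}

#' @export
print.hub_scores <- function(x, ...) {
  cat("hub_scores: ", nrow(x), " nodes, top MCC ",
      if (nrow(x)) x$mcc[1] else NA, "\n", sep = "")
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... ", nrow(x) - 10, " more rows\n", sep = "")
  invisible(x)
}

#' Overlap statistics between two gene sets
#'
#' Exact intersection counts with Jaccard and overlap (Szymkiewicz-
#' Simpson) coefficients, for interactome partner-overlap style
#' comparisons (e.g. shared interactors of two adaptor isoforms, or an
#' interactor list against an annotation catalogue).
#'
#' @param a,b character vectors (duplicates ignored).
#' @return A `set_overlap` list: `size_a`, `size_b`, `intersection`,
#'   `jaccard`, `overlap_coefficient`, `common` (the shared elements).
#' @examples
#' set_overlap(c("p", "q", "r"), c("q", "r", "s", "t"))
#' @export
set_overlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  common <- intersect(a, b)
  un <- length(union(a, b))
  mn <- min(length(a), length(b))
  structure(list(
    size_a = length(a), size_b = length(b),
    intersection = length(common),
    jaccard = if (un == 0) 0 else length(common) / un,
    overlap_coefficient = if (mn == 0) 0 else length(common) / mn,
    common = sort(common)), class = "set_overlap")
}

#' @export
print.set_overlap <- function(x, ...) {
  cat("set_overlap: |A| = ", x$size_a, ", |B| = ", x$size_b,
      ", |A n B| = ", x$intersection,
      " (Jaccard ", signif(x$jaccard, 3),
      ", overlap ", signif(x$overlap_coefficient, 3), ")\n", sep = "")
  invisible(x)
}

#' @rdname mcc_scores
#' @param scores a `hub_scores` data.frame.
#' @param path output TSV path.
#' @export
write_hub_scores <- function(scores, path) {
  utils::write.table(as.data.frame(scores), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
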