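# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths (and igraph).

# All maximal cliques of a graph given its adjacency matrix, by explicit
# enumeration of every vertex subset (n <= 16). Returns a list of sorted
# name vectors; isolated vertices appear as singleton cliques.
brute_maximal_cliques <- function(adj) {
  n <- nrow(adj)
  stopifnot(n <= 16, isSymmetric(unname(adj)))
  nodes <- rownames(adj)
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  cliques <- list()
  for (m in seq_len(2^n - 1)) {
    vs <- which(bitwAnd(bitwShiftR(m, 0:(n - 1)), 1L) == 1L)
    sub <- adj[vs, vs, drop = FALSE]
    diag(sub) <- 1
    if (!all(sub == 1)) next
    # maximal iff no outside vertex is adjacent to every member
    out <- setdiff(seq_len(n), vs)
    if (length(out) &&
        any(rowSums(adj[out, vs, drop = FALSE]) == length(vs))) next
    cliques[[length(cliques) + 1]] <- sort(nodes[vs])
  }
  cliques
}

# MCC by direct evaluation of the definition over brute-forced cliques.
brute_mcc <- function(adj) {
  nodes <- rownames(adj)
  if (is.null(nodes)) nodes <- as.character(seq_len(nrow(adj)))
  mcc <- stats::setNames(numeric(length(nodes)), nodes)
  for (C in brute_maximal_cliques(adj)) {
    mcc[C] <- mcc[C] + factorial(length(C) - 1)
  }
  mcc
}

# Random simple undirected graph as an adjacency matrix.
random_adjacency <- function(n, p) {
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  adj <- adj + t(adj)
  rownames(adj) <- colnames(adj) <- sprintf("v%02d", seq_len(n))
  adj
}

# Hypergeometric upper-tail P(X >= k) by exhaustive enumeration of all
# C(N, n) draws from a universe with K marked elements (N <= 15).
enumerate_hyper_tail <- function(k, K, n, N) {
  stopifnot(N <= 15, K <= N, n <= N)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)   # elements 1..K are the marked ones
  mean(hits >= k)
}

# Mean pairwise distance by an explicit double loop.
double_loop_pairwise <- function(xy) {
  n <- nrow(xy)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + sqrt(sum((xy[i, ] - xy[j, ])^2))
    }
  }
  tot / (n * (n - 1) / 2)
}

# Linear-interpolation percentile (closest-ranks), written independently
# of stats::quantile.
lin_interp_percentile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Direct application of the quantile classification rules to one
# inducer's WT/KD AUC panels.
oracle_classify <- function(auc_wt, auc_kd) {
  q25w <- lin_interp_percentile(auc_wt, 0.25)
  q75w <- lin_interp_percentile(auc_wt, 0.75)
  q25k <- lin_interp_percentile(auc_kd, 0.25)
  q75k <- lin_interp_percentile(auc_kd, 0.75)
  out <- character(length(auc_wt))
  for (i in seq_along(auc_wt)) {
    out[i] <- if (auc_wt[i] <= q25w && auc_kd[i] <= q25k) {
      "independent_inhibitor"
    } else if (auc_wt[i] <= q25w && auc_kd[i] > q25k) {
      "dependent_inhibitor"
    } else if (auc_wt[i] < q75w && auc_kd[i] >= q75k) {
      "dependent_activator"
    } else "unclassified"
  }
  out
}

# Direction-consistency integration applied gene-by-gene from explicit
# support patterns ("U" significant up, "D" significant down, "." not
# significant), one string position per dataset.
oracle_integrate <- function(patterns, min_fraction) {
  vapply(patterns, function(pat) {
    calls <- strsplit(pat, "")[[1]]
    n <- length(calls)
    n_up <- sum(calls == "U")
    n_down <- sum(calls == "D")
    if (n_up / n >= min_fraction && n_down == 0) "up"
    else if (n_down / n >= min_fraction && n_up == 0) "down"
    else NA_character_
  }, character(1))
}

# Adjusted Rand index between two labellings (mclust is the reference).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Small toy track table: `cells` positions per timepoint, with treated
# scatter a fixed multiple of the control scatter.
toy_tracks <- function(ratio, times = seq(0, 48, 4), n_cells = 4,
                       base = 10) {
  rows <- list()
  for (t in times) {
    ang <- 2 * pi * seq_len(n_cells) / n_cells
    for (trt in c("UNTREATED", "INHX")) {
      r <- base * (1 + t / 48) * if (trt == "INHX") ratio else 1
      rows[[length(rows) + 1]] <- data.frame(
        genotype = "WT", inducer = "DMOG", inhibitor = trt,
        replicate = 1L, time_h = t, cell_id = seq_len(n_cells),
        x = r * cos(ang), y = r * sin(ang))
    }
  }
  do.call(rbind, rows)
}

# Minimal edge-list data.frame for graph construction in tests.
edge_df <- function(a, b, src = "x") {
  data.frame(node_a = a, node_b = b, source = src,
             stringsAsFactors = FALSE)
}

# Package graph built from an adjacency matrix, keeping isolated vertices.
graph_from_adj <- function(adj) {
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  nodes <- rownames(adj)
  if (nrow(idx) == 0) {
    return(igraph::add_vertices(igraph::make_empty_graph(directed = FALSE),
                                length(nodes), name = nodes))
  }
  g <- build_interaction_graph(edge_df(nodes[idx[, 1]], nodes[idx[, 2]]))
  iso <- setdiff(nodes, igraph::V(g)$name)
  if (length(iso)) g <- igraph::add_vertices(g, length(iso), name = iso)
  g
}
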