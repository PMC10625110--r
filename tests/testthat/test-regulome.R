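toy_annotation <- function() {
  new_term_annotation(
    list(T1 = paste0("g", 1:4), T2 = paste0("g", 5:6),
         T3 = paste0("g", c(1, 2, 7))),
    universe = paste0("g", 1:10))
}

# root R, two branches A and B, two leaves each
toy_dag <- function() {
  new_term_dag(list(R = character(0), A = "R", B = "R",
                    A1 = "A", A2 = "A", B1 = "B", B2 = "B"))
}

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  ann <- toy_annotation()
  res <- enrich_terms(paste0("g", 1:5), ann, alpha = 0.05)
  # N=10, K=4, n=5, k=4: p = C(4,4) C(6,1) / C(10,5) = 6/252
  r1 <- res[res$term == "T1", ]
  expect_equal(r1$p_value, 6 / 252, tolerance = 1e-12)
  expect_equal(r1$p_value, enumerate_hyper_tail(4, 4, 5, 10),
               tolerance = 1e-12)
  expect_equal(c(r1$k, r1$K, r1$n, r1$N), c(4, 4, 5, 10))
  # zero overlap: P(X >= 0) = 1
  res0 <- enrich_terms(paste0("g", 7:9), ann)
  expect_equal(res0$p_value[res0$term == "T2"], 1)
  # random configurations against the enumeration oracle
  set.seed(14)
  for (i in 1:20) {
    N <- sample(6:15, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    uni <- paste0("u", seq_len(N))
    ann_i <- new_term_annotation(list(TT = uni[seq_len(K)]),
                                 universe = uni)
    query <- sample(uni, n)
    got <- enrich_terms(query, ann_i, alpha = 1)
    k <- length(intersect(query, uni[seq_len(K)]))
    expect_equal(got$p_value[got$term == "TT"],
                 enumerate_hyper_tail(k, K, n, N), tolerance = 1e-12)
  }
  expect_error(enrich_terms(character(0), ann), "empty")
  expect_warning(enrich_terms(c("g1", "g2", "g3", "nope"), ann),
                 "outside")
})

test_that("FDR values are BH step-up adjusted and bound p from above", {
  ann <- toy_annotation()
  res <- enrich_terms(paste0("g", 1:5), ann, alpha = 0.05)
  expect_true(all(res$fdr >= res$p_value - 1e-12))
  expect_true(all(res$fdr <= 1))
  # hand-derived step-up on the sorted p-vector of this query
  p <- sort(res$p_value)
  m <- length(p)
  adj <- rev(cummin(rev(p * m / seq_len(m))))
  expect_equal(sort(res$fdr), pmin(adj, 1), tolerance = 1e-12)
})

test_that("Wang similarity follows the S-value recursion", {
  dag <- toy_dag()
  expect_equal(wang_similarity("A1", "A1", dag), 1)
  # child vs parent with w = 0.8: common ancestor R contributes
  # S_A(R) + S_R(R) = 0.8 + 1.0 over SV(A) + SV(R) = 1.8 + 1.0
  two <- new_term_dag(list(R = character(0), A = "R"))
  expect_equal(wang_similarity("A", "R", two), 1.8 / 2.8,
               tolerance = 1e-12)
  # siblings share branch + root; cross-branch terms share only the root
  sib <- wang_similarity("A1", "A2", dag)
  cross <- wang_similarity("A1", "B1", dag)
  # hand evaluation: S(A1) = {A1:1, A:0.8, R:0.64}, SV = 2.44
  expect_equal(sib, (0.8 + 0.8 + 0.64 + 0.64) / (2.44 + 2.44),
               tolerance = 1e-12)
  expect_equal(cross, (0.64 + 0.64) / (2.44 + 2.44), tolerance = 1e-12)
  expect_lt(cross, sib)
  # symmetry and range
  expect_equal(wang_similarity("B2", "A1", dag),
               wang_similarity("A1", "B2", dag))
  m <- term_similarity_matrix(c("A1", "A2", "B1", "B2", "R"), dag)
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(m, t(m))
  expect_error(wang_similarity("nope", "A1", dag), "unknown")
})

test_that("semantic clustering recovers planted branches", {
  dag <- toy_dag()
  cl <- cluster_terms(c("A1", "A2", "B1", "B2"), dag, k = 2)
  expect_equal(cl$k, 2)
  expect_equal(ari(cl$assignment, c(1, 1, 2, 2)), 1)
  # auto-k on generated 7-branch annotation
  sim <- simulate_term_annotation(emt_config(seed = 4, n_terms = 35))
  auto <- cluster_terms(sim$truth$term, sim$dag, k = "auto")
  expect_equal(auto$k, 7)
  expect_equal(ari(auto$assignment[sim$truth$term], sim$truth$cluster), 1)
  # terms at the same DAG position always co-cluster
  dup_dag <- new_term_dag(list(R = character(0), A = "R", B = "R",
                               X1 = "A", X2 = "A", X3 = "A",
                               Y1 = "B"))
  dcl <- cluster_terms(c("X1", "X2", "X3", "Y1"), dup_dag, k = 2)
  expect_equal(length(unique(dcl$assignment[c("X1", "X2", "X3")])), 1)
  # between-cluster BMA is below the within-cluster diagonal
  expect_true(all(diag(auto$bma) >= auto$bma[upper.tri(auto$bma)]))
  expect_error(cluster_terms("A1", dag), ">= 2")
  expect_error(cluster_terms(c("A1", "A2"), dag, k = 5), "exceeds")
})

test_that("combined coefficient arithmetic drives network edges", {
  a <- paste0("g", 1:4); b <- paste0("g", 3:5)
  cc <- emtregulome:::combined_coefficient(a, b)
  expect_equal(cc, 0.5 * (2 / 5) + 0.5 * (2 / 3), tolerance = 1e-12)
  expect_gte(cc, 0.375)
  expect_equal(emtregulome:::combined_coefficient(a, a), 1)
  expect_equal(emtregulome:::combined_coefficient(a, c("x", "y")), 0)
  # symmetric
  expect_equal(emtregulome:::combined_coefficient(b, a), cc)
})

fake_enrichment <- function(terms, genes, origin = "EMT",
                            retained = TRUE) {
  structure(data.frame(
    term = terms, name = paste("name of", terms),
    k = lengths(genes), K = lengths(genes), n = 10, N = 100,
    p_value = 1e-4, fdr = 1e-3, retained = retained, origin = origin,
    overlap_genes = vapply(genes, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE),
    alpha = 0.05, class = c("enrichment_result", "data.frame"))
}

test_that("function networks connect terms above the similarity cutoff", {
  enr <- fake_enrichment(
    c("TA", "TB", "TC", "TD"),
    list(paste0("g", 1:4), paste0("g", 3:5), paste0("g", 1:4),
         paste0("h", 1:3)))
  net <- build_function_network(enr, cutoff = 0.375)
  key <- function(e) paste(pmin(e$node_a, e$node_b),
                           pmax(e$node_a, e$node_b))
  expect_setequal(key(net$edges),
                  key(data.frame(node_a = c("EMT:TA", "EMT:TA", "EMT:TB"),
                                 node_b = c("EMT:TB", "EMT:TC", "EMT:TC"))))
  expect_equal(net$edges$similarity[
    net$edges$node_a == "EMT:TA" & net$edges$node_b == "EMT:TC"], 1)
  # TD is disjoint: its own cluster, no edges
  expect_equal(sum(net$nodes$cluster[net$nodes$term == "TD"] ==
                     net$nodes$cluster[net$nodes$term != "TD"]), 0)
  # cutoff monotonicity: lowering the cutoff never removes an edge
  lower <- build_function_network(enr, cutoff = 0.1)
  expect_true(all(key(net$edges) %in% key(lower$edges)))
  # identical sets connect at cutoff 1; nothing else does
  strict <- build_function_network(enr, cutoff = 1)
  expect_setequal(key(strict$edges),
                  key(data.frame(node_a = "EMT:TA", node_b = "EMT:TC")))
  # node order invariance of clusters
  perm <- fake_enrichment(
    c("TD", "TB", "TA", "TC"),
    list(paste0("h", 1:3), paste0("g", 3:5), paste0("g", 1:4),
         paste0("g", 1:4)))
  net_p <- build_function_network(perm, cutoff = 0.375)
  co <- function(net, t1, t2) {
    cl <- setNames(net$nodes$cluster, net$nodes$term)
    cl[t1] == cl[t2]
  }
  for (pair in list(c("TA", "TB"), c("TA", "TD"), c("TB", "TC"))) {
    expect_equal(co(net, pair[1], pair[2]), co(net_p, pair[1], pair[2]))
  }
  expect_error(build_function_network(enr, cutoff = 1.5), "cutoff")
  # origins are preserved on the nodes
  multi <- list(enr, fake_enrichment("TZ", list(paste0("g", 1:4)),
                                     origin = "hub-interactome"))
  net_m <- build_function_network(multi, cutoff = 0.375)
  expect_setequal(unique(net_m$nodes$origin),
                  c("EMT", "hub-interactome"))
})

test_that("GraphML export round-trips through an XML parser", {
  enr <- fake_enrichment(c("TA", "TB"),
                         list(paste0("g", 1:4), paste0("g", 3:5)))
  net <- build_function_network(enr, cutoff = 0.375)
  gml <- withr::local_tempfile(fileext = ".graphml")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_function_network(net, gml, tsv)
  x <- xml2::read_xml(gml)
  expect_equal(xml2::xml_name(x), "graphml")
  nodes <- xml2::xml_find_all(x, ".//*[local-name() = 'node']")
  expect_length(nodes, 2)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), 2)
  expect_setequal(igraph::vertex_attr(back, "origin"), "EMT")
  ed <- read.delim(tsv)
  expect_equal(nrow(ed), 1)
})
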