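small_cfg <- function(seed = 1, n_samples_per_group = 3, ...) {
  emt_config(seed = seed, n_genes = 200,
             n_samples_per_group = n_samples_per_group,
             n_consistent_degs = 50, n_decoy_degs = 10,
             n_inhibitors = 12, n_kinases = 8, n_replicates = 2,
             cells_per_well = 6, n_terms = 14, ...)
}

test_that("configuration validation rejects impossible settings", {
  expect_error(emt_config(n_genes = 0), "positive")
  expect_error(emt_config(consistency_fraction = 1.2), "\\[0, 1\\]")
  expect_error(emt_config(n_genes = 50, n_consistent_degs = 40,
                          n_decoy_degs = 20), "exceed")
  expect_error(emt_config(n_timepoints = 1), "4 h grid")
  expect_error(emt_config(n_terms = 3, n_term_clusters = 7),
               "n_term_clusters")
})

test_that("count datasets have the configured shape and planted effects", {
  cfg <- small_cfg(n_datasets = 5)
  sim <- simulate_count_datasets(cfg)
  expect_length(sim$datasets, 5)
  for (ds in sim$datasets) {
    expect_equal(dim(ds$counts), c(200, 6))
    expect_true(all(ds$counts >= 0))
  }
  # consistency_fraction = 1 plants the effect in every dataset
  tr <- sim$truth
  part <- as.matrix(tr[tr$role == "consistent",
                       grep("^in_", names(tr))])
  expect_true(all(part))
  # decoys participate in ceiling(0.6 * 5) = 3 datasets
  dec <- as.matrix(tr[tr$role == "decoy", grep("^in_", names(tr))])
  expect_true(all(rowSums(dec) == 3))
  # null genes participate nowhere
  nul <- as.matrix(tr[tr$role == "null", grep("^in_", names(tr))])
  expect_false(any(nul))
})

test_that("planted expression effects point the planted way", {
  cfg <- small_cfg(n_samples_per_group = 6)
  sim <- simulate_count_datasets(cfg)
  de <- simple_de(sim$datasets[[1]])
  tr <- sim$truth
  up <- tr$gene[tr$role == "consistent" & tr$direction == "up"]
  down <- tr$gene[tr$role == "consistent" & tr$direction == "down"]
  expect_gt(mean(de$log2FC[match(up, de$gene)]), 1)
  expect_lt(mean(de$log2FC[match(down, de$gene)]), -1)
  # planted log2FC is recovered on average
  expect_equal(mean(de$log2FC[match(up, de$gene)]),
               cfg$planted_log2fc, tolerance = 0.2)
})

test_that("generated inputs are byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_emt_inputs(small_cfg(seed = 11), d1)
  simulate_emt_inputs(small_cfg(seed = 11), d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(length(f1) > 10)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in setdiff(f1, "manifest.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  # and a different seed changes the data
  d3 <- withr::local_tempdir()
  simulate_emt_inputs(small_cfg(seed = 12), d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "tracks.csv"))),
    unname(tools::md5sum(file.path(d3, "tracks.csv")))))
})

test_that("planted hubs sit in three disjoint K4s and score MCC 18", {
  sim <- simulate_interactome(small_cfg())
  g <- build_interaction_graph(sim$edges)
  scores <- mcc_scores(g)
  hubs <- sim$truth$gene[sim$truth$is_hub]
  expect_length(hubs, 5)
  expect_equal(scores$mcc[match(hubs, scores$gene)], rep(18, 5))
  expect_equal(scores$degree[match(hubs, scores$gene)], rep(9, 5))
  # a degree-1 background node lies in a single edge clique: MCC 1
  deg1 <- scores$gene[scores$degree == 1]
  if (length(deg1)) {
    expect_equal(scores$mcc[match(deg1, scores$gene)],
                 rep(1, length(deg1)))
  }
})

test_that("screen tracks cover the full well layout with a growing trend", {
  cfg <- small_cfg()
  sim <- simulate_screen_tracks(cfg)
  tr <- sim$tracks
  wells <- unique(tr[c("genotype", "inducer", "inhibitor")])
  expect_equal(nrow(wells), 2 * 2 * (cfg$n_inhibitors + 1))
  expect_setequal(unique(tr$time_h), seq(0, 48, 4))
  # untreated EMT wells scatter more at 48 h than at 0 h
  for (gt in c("WT", "KD")) {
    un <- tr[tr$inhibitor == "UNTREATED" & tr$genotype == gt &
               tr$inducer == "DMOG", ]
    s0 <- scatter_distance(un[un$time_h == 0, c("x", "y")])
    s48 <- scatter_distance(un[un$time_h == 48, c("x", "y")])
    expect_gt(s48, s0)
  }
  # every kinase annotation resolves and families are complete
  expect_true(all(sim$inhibitor_kinase$kinase %in%
                    sim$kinase_family$kinase))
  expect_setequal(unique(sim$truth$category),
                  c("independent_inhibitor", "dependent_inhibitor",
                    "dependent_activator", "unclassified"))
})

test_that("term branches are coherent and the DAG is rooted", {
  cfg <- small_cfg()
  sim <- simulate_term_annotation(cfg)
  # 7 depth-1 branches under the root
  depth1 <- names(sim$dag$depth)[sim$dag$depth == 1]
  expect_length(depth1, 7)
  # two terms of one branch overlap above the 0.375 network cutoff
  tr <- sim$truth
  b1 <- tr$term[tr$cluster == 1]
  ov <- set_overlap(sim$annotation$sets[[b1[1]]],
                    sim$annotation$sets[[b1[2]]])
  expect_gte(0.5 * ov$jaccard + 0.5 * ov$overlap_coefficient, 0.375)
  # cross-branch sets share < 10% of genes
  b2 <- tr$term[tr$cluster == 2]
  cross <- set_overlap(sim$annotation$sets[[b1[1]]],
                       sim$annotation$sets[[b2[1]]])
  expect_lt(cross$overlap_coefficient, 0.1)
})

test_that("generated files round-trip through the module readers", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg(seed = 3)
  sim <- simulate_emt_inputs(cfg, dir)

  ds <- sim$counts$datasets[[1]]
  back <- read_count_dataset(file.path(dir, "counts_DS1.tsv"),
                             file.path(dir, "groups_DS1.tsv"), "DS1")
  expect_equal(back$counts, ds$counts, tolerance = 1e-12)
  expect_equal(back$groups, ds$groups)

  edges <- read_edge_list(file.path(dir, "edges_stringdb.tsv"))
  orig <- sim$interactome$edges
  expect_equal(nrow(edges), sum(orig$source == "stringdb"))

  tracks <- read_tracks(file.path(dir, "tracks.csv"))
  expect_equal(nrow(tracks), nrow(sim$screen$tracks))
  expect_equal(tracks$x, sim$screen$tracks$x, tolerance = 1e-12)

  ann <- read_gmt(file.path(dir, "terms.gmt"))
  expect_equal(lapply(ann$sets, sort),
               lapply(sim$terms$annotation$sets, sort))

  dag <- read_obo_dag(file.path(dir, "terms.obo"))
  expect_equal(dag$parents[order(names(dag$parents))],
               sim$terms$dag$parents[order(names(sim$terms$dag$parents))])
})
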