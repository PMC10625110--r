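test_that("scatter distance matches geometry and the pairwise oracle", {
  expect_equal(scatter_distance(rbind(c(0, 0), c(2, 0))), 1)
  expect_equal(scatter_distance(matrix(c(3, 4), ncol = 2)), 0)
  expect_error(scatter_distance(matrix(numeric(0), ncol = 2)), "empty")
  set.seed(10)
  xy <- matrix(rnorm(100, sd = 20), ncol = 2)
  expect_equal(scatter_distance(xy, "pairwise"),
               double_loop_pairwise(xy))
  # mean pairwise distance dominates mean distance to the centroid
  expect_gte(scatter_distance(xy, "pairwise"), scatter_distance(xy))
})

test_that("log-FC series reflect exact scatter ratios", {
  tr2 <- toy_tracks(ratio = 2)
  s <- migration_series(tr2, "WT", "DMOG", "INHX")
  expect_equal(s$logfc, rep(1, 13), tolerance = 1e-12)
  expect_equal(s$auc, 48, tolerance = 1e-9)
  s1 <- migration_series(toy_tracks(ratio = 1), "WT", "DMOG", "INHX")
  expect_equal(s1$logfc, rep(0, 13), tolerance = 1e-12)
  expect_equal(s1$auc, 0, tolerance = 1e-12)
  # missing control timepoints are named
  broken <- tr2[!(tr2$inhibitor == "UNTREATED" & tr2$time_h == 24), ]
  expect_error(migration_series(broken, "WT", "DMOG", "INHX"), "24")
})

test_that("planted suppression is recovered from generated tracks", {
  cfg <- emt_config(seed = 21, n_inhibitors = 12, n_kinases = 8,
                    n_replicates = 3, cells_per_well = 20)
  sim <- simulate_screen_tracks(cfg)
  ind <- sim$truth$inhibitor[sim$truth$category ==
                               "independent_inhibitor"][1]
  for (gt in c("WT", "KD")) {
    s <- migration_series(sim$tracks, gt, "DMOG", ind)
    # planted factor 0.4 halves late scatter: log-FC near -1 at 48 h
    expect_lt(s$logfc[13], -0.6)
    expect_lt(s$auc, -10)
  }
})

test_that("trapezoidal AUC is exact for constant and linear series", {
  grid <- seq(0, 48, 4)
  expect_equal(auc_trapezoid(grid, rep(1, 13)), 48, tolerance = 1e-9)
  expect_equal(auc_trapezoid(grid, grid / 24), 48, tolerance = 1e-9)
  expect_equal(auc_trapezoid(grid, rep(0, 13)), 0)
  # linearity: auc(a f + b g) = a auc(f) + b auc(g)
  set.seed(3)
  f <- rnorm(13); g <- rnorm(13)
  expect_equal(auc_trapezoid(grid, 2.5 * f - 1.5 * g),
               2.5 * auc_trapezoid(grid, f) - 1.5 * auc_trapezoid(grid, g))
  expect_error(auc_trapezoid(c(0, 4, 4), c(1, 1, 1)), "increasing")
  expect_error(auc_trapezoid(0, 1), "grid")
})

test_that("quantile classification matches the rule oracle on a toy panel", {
  aucs <- c(-10, -8, -6, -4, -2, 0, 2, 4)
  inh <- paste0("I", 1:8)
  panel <- function(auc_wt, auc_kd, inducer = "DMOG") {
    rbind(data.frame(genotype = "WT", inducer = inducer, inhibitor = inh,
                     auc = auc_wt, stringsAsFactors = FALSE),
          data.frame(genotype = "KD", inducer = inducer, inhibitor = inh,
                     auc = auc_kd, stringsAsFactors = FALSE))
  }
  cls <- classify_inhibitors(panel(aucs, aucs))
  # q25 = -6.5: I1 (-10) and I2 (-8) fall below it in both genotypes
  expect_equal(cls$thresholds$q25_WT, -6.5)
  expect_equal(cls$thresholds$q75_WT, 0.5)
  expect_equal(cls$final$category[cls$final$inhibitor == "I1"],
               "independent_inhibitor")
  expect_identical(
    setNames(cls$per_inducer$category, cls$per_inducer$inhibitor)[inh],
    setNames(oracle_classify(aucs, aucs), inh))

  # raising I1's KD AUC above q25_KD turns it adaptor-dependent
  kd2 <- aucs; kd2[1] <- 0
  cls2 <- classify_inhibitors(panel(aucs, kd2))
  expect_equal(cls2$final$category[cls2$final$inhibitor == "I1"],
               "dependent_inhibitor")
  expect_identical(
    setNames(cls2$per_inducer$category, cls2$per_inducer$inhibitor)[inh],
    setNames(oracle_classify(aucs, kd2), inh))

  # an inhibitor at the WT median whose KD AUC tops the KD panel
  wt3 <- aucs; kd3 <- aucs
  wt3[5] <- median(aucs); kd3[5] <- max(aucs) + 10
  cls3 <- classify_inhibitors(panel(wt3, kd3))
  expect_equal(cls3$final$category[cls3$final$inhibitor == "I5"],
               "dependent_activator")
  expect_identical(
    setNames(cls3$per_inducer$category, cls3$per_inducer$inhibitor)[inh],
    setNames(oracle_classify(wt3, kd3), inh))
})

test_that("classification respects invariances and the cross-inducer rule", {
  set.seed(8)
  inh <- sprintf("I%02d", 1:20)
  base <- data.frame(
    genotype = rep(c("WT", "KD"), each = 40),
    inducer = rep(rep(c("DMOG", "TGFB"), each = 20), 2),
    inhibitor = rep(inh, 4),
    auc = rnorm(80, sd = 10), stringsAsFactors = FALSE)
  cls <- classify_inhibitors(base)
  # invariant to inhibitor row order
  shuf <- base[sample(nrow(base)), ]
  cls_shuf <- classify_inhibitors(shuf)
  expect_equal(cls$final[order(cls$final$inhibitor), ],
               cls_shuf$final[order(cls_shuf$final$inhibitor), ])
  # invariant to adding a constant to one genotype's panel
  shifted <- base
  shifted$auc[shifted$genotype == "KD"] <-
    shifted$auc[shifted$genotype == "KD"] + 100
  expect_equal(classify_inhibitors(shifted)$final, cls$final)
  # per-inducer categories are a partition: exactly one per inhibitor
  expect_equal(nrow(cls$per_inducer), 40)
  expect_false(any(duplicated(
    cls$per_inducer[c("inhibitor", "inducer")])))
  # final category only when both inducers agree
  per <- split(cls$per_inducer$category, cls$per_inducer$inhibitor)
  for (i in inh) {
    want <- if (length(unique(per[[i]])) == 1) per[[i]][1] else
      "unclassified"
    expect_equal(cls$final$category[cls$final$inhibitor == i], want)
  }
  # panel mismatch errors name the missing inhibitor
  expect_error(classify_inhibitors(base[-1, ]), "I01")
})

test_that("kinase family summaries count distinct kinases per category", {
  cls <- structure(list(
    final = data.frame(
      inhibitor = c("A", "B", "C", "D"),
      category = c("dependent_inhibitor", "dependent_inhibitor",
                   "dependent_activator", "unclassified"),
      stringsAsFactors = FALSE)), class = "screen_classification")
  ik <- data.frame(inhibitor = c("A", "B", "C", "C"),
                   kinase = c("k1", "k2", "k3", "k4"),
                   stringsAsFactors = FALSE)
  kf <- data.frame(kinase = c("k1", "k2", "k3", "k4"),
                   family = c("TK", "TK", "AGC", "CAMK"),
                   stringsAsFactors = FALSE)
  s <- summarize_kinases(cls, ik, kf)
  fc <- s$family_counts
  expect_equal(fc$n_kinases[fc$category == "dependent_inhibitor" &
                              fc$family == "TK"], 2)
  # inhibitor C targets two families and contributes to both
  expect_equal(fc$n_kinases[fc$category == "dependent_activator" &
                              fc$family == "AGC"], 1)
  expect_equal(fc$n_kinases[fc$category == "dependent_activator" &
                              fc$family == "CAMK"], 1)
  expect_equal(unname(s$dependent_split),
               c(2, 2))
  expect_equal(s$unannotated, "D")
  # empty classification: all-zero table
  cls0 <- structure(list(final = data.frame(
    inhibitor = character(0), category = character(0),
    stringsAsFactors = FALSE)), class = "screen_classification")
  s0 <- summarize_kinases(cls0, ik, kf)
  expect_true(all(s0$family_counts$n_kinases == 0))
})

test_that("tumor volume follows the ellipsoid formula with axis swap", {
  expect_equal(tumor_volume(10, 5), 125)
  expect_equal(tumor_volume(2, 2), 4)
  # swap makes L = 10, W = 5: same volume as the unswapped measurement
  expect_warning(v <- tumor_volume(5, 10), "swap")
  expect_equal(v, 125)
  expect_error(tumor_volume(0, 1), "positive")
  expect_equal(tumor_volume(c(10, 2), c(5, 2)), c(125, 4))
})
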