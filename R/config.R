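#' Configuration for the synthetic EMT pipeline generator
#'
#' Bundles every tunable of the synthetic-data module into one validated
#' object. The same configuration object drives all four generators
#' ([simulate_count_datasets()], [simulate_interactome()],
#' [simulate_screen_tracks()], [simulate_term_annotation()]), and the seed
#' fully determines every generated file.
#'
#' The defaults describe the emulated study: five RNA-seq datasets of
#' EMT-induced versus control cells with a planted direction-consistent DEG
#' signature; an interaction network in which a handful of hub genes are
#' each embedded in several disjoint cliques; a 188-inhibitor /
#' 130-kinase time-lapse scattering screen sampled every 4 h over 48 h in
#' wild-type (WT) and adaptor-knockdown (KD) cells under two EMT inducers;
#' and a 7-branch term ontology with branch-coherent gene sets.
#'
#' @param seed integer; root seed, fully determines all generator output.
#' @param n_datasets number of count datasets (emulated studies).
#' @param n_genes genes per dataset (shared gene universe).
#' @param n_samples_per_group samples per group (control / treated).
#' @param nb_mean median negative-binomial mean count per gene; gene-wise
#'   means are drawn log-normally around it.
#' @param nb_dispersion shared NB dispersion (variance = mu + dispersion *
#'   mu^2).
#' @param n_consistent_degs planted DEGs carrying the effect in a
#'   `consistency_fraction` of datasets.
#' @param consistency_fraction fraction of datasets (rounded up) in which a
#'   planted DEG carries the effect; in `[0, 1]`.
#' @param n_decoy_degs planted decoy DEGs carrying the effect in only a
#'   `decoy_fraction` of datasets; used to score the specificity of the
#'   consistency filter.
#' @param decoy_fraction fraction of datasets in which decoys carry the
#'   effect; in `[0, 1]`.
#' @param planted_log2fc absolute log2 fold change planted on DEGs (half
#'   up, half down).
#' @param n_hubs planted hub genes in the interactome.
#' @param n_inhibitors size of the inhibitor panel.
#' @param n_kinases number of distinct target kinases.
#' @param n_timepoints points on the 4 h imaging grid starting at 0 h
#'   (13 gives 0--48 h).
#' @param n_replicates replicate wells per condition.
#' @param cells_per_well cells observed per well and timepoint.
#' @param scatter_noise_sd i.i.d. Gaussian noise SD added to each cell
#'   coordinate, in micrometres.
#' @param n_terms number of annotation terms in the generated GMT.
#' @param n_term_clusters branches (depth-1 subtrees) of the term DAG;
#'   terms within a branch share most member genes.
#'
#' @return An object of class `emt_config` (a validated named list).
#' @examples
#' cfg <- emt_config(seed = 1, n_genes = 200, n_consistent_degs = 20,
#'                   n_decoy_degs = 20)
#' cfg$n_datasets
#' @export
emt_config <- function(seed = 1L,
                       n_datasets = 5L,
                       n_genes = 1000L,
                       n_samples_per_group = 6L,
                       nb_mean = 100,
                       nb_dispersion = 0.1,
                       n_consistent_degs = 100L,
                       consistency_fraction = 1.0,
                       n_decoy_degs = 100L,
                       decoy_fraction = 0.6,
                       planted_log2fc = 2,
                       n_hubs = 5L,
                       n_inhibitors = 188L,
                       n_kinases = 130L,
                       n_timepoints = 13L,
                       n_replicates = 3L,
                       cells_per_well = 20L,
                       scatter_noise_sd = 5,
                       n_terms = 70L,
                       n_term_clusters = 7L) {
  cfg <- list(
    seed = as.integer(seed),
    n_datasets = as.integer(n_datasets),
    n_genes = as.integer(n_genes),
    n_samples_per_group = as.integer(n_samples_per_group),
    nb_mean = as.numeric(nb_mean),
    nb_dispersion = as.numeric(nb_dispersion),
    n_consistent_degs = as.integer(n_consistent_degs),
    consistency_fraction = as.numeric(consistency_fraction),
    n_decoy_degs = as.integer(n_decoy_degs),
    decoy_fraction = as.numeric(decoy_fraction),
    planted_log2fc = as.numeric(planted_log2fc),
    n_hubs = as.integer(n_hubs),
    n_inhibitors = as.integer(n_inhibitors),
    n_kinases = as.integer(n_kinases),
    n_timepoints = as.integer(n_timepoints),
    n_replicates = as.integer(n_replicates),
    cells_per_well = as.integer(cells_per_well),
    scatter_noise_sd = as.numeric(scatter_noise_sd),
    n_terms = as.integer(n_terms),
    n_term_clusters = as.integer(n_term_clusters)
  )
  class(cfg) <- "emt_config"
  validate_emt_config(cfg)
  cfg
}

validate_emt_config <- function(cfg) {
  stopifnot(inherits(cfg, "emt_config"))
  pos <- c("n_datasets", "n_genes", "n_samples_per_group", "nb_mean",
           "nb_dispersion", "n_hubs", "n_inhibitors", "n_kinases",
           "n_replicates", "cells_per_well", "scatter_noise_sd",
           "n_terms", "n_term_clusters")
  for (f in pos) {
    if (is.na(cfg[[f]]) || cfg[[f]] <= 0) {
      stop("configuration error: '", f, "' must be positive", call. = FALSE)
    }
  }
  for (f in c("n_consistent_degs", "n_decoy_degs")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0) {
      stop("configuration error: '", f, "' must be non-negative",
           call. = FALSE)
    }
  }
  for (f in c("consistency_fraction", "decoy_fraction")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("configuration error: '", f, "' must lie in [0, 1]",
           call. = FALSE)
    }
  }
  if (cfg$n_consistent_degs + cfg$n_decoy_degs > cfg$n_genes) {
    stop("configuration error: planted DEGs (consistent + decoy) exceed ",
         "n_genes", call. = FALSE)
  }
  if (cfg$n_samples_per_group < 2) {
    stop("configuration error: need >= 2 samples per group", call. = FALSE)
  }
  # the imaging grid is fixed at 4 h steps from 0 h; only its length varies
  if (cfg$n_timepoints < 2) {
    stop("configuration error: n_timepoints inconsistent with the 4 h ",
         "grid (need >= 2 points)", call. = FALSE)
  }
  if (cfg$n_term_clusters > cfg$n_terms) {
    stop("configuration error: n_term_clusters > n_terms", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.emt_config <- function(x, ...) {
  cat("Synthetic EMT pipeline configuration (seed ", x$seed, ")\n", sep = "")
  cat("  expression : ", x$n_datasets, " datasets x ", x$n_genes,
      " genes, ", x$n_samples_per_group, "/group; ",
      x$n_consistent_degs, " DEGs @", x$consistency_fraction,
      ", ", x$n_decoy_degs, " decoys @", x$decoy_fraction,
      ", |log2FC| = ", x$planted_log2fc, "\n", sep = "")
  cat("  interactome: ", x$n_hubs, " planted hubs\n", sep = "")
  cat("  screen     : ", x$n_inhibitors, " inhibitors / ", x$n_kinases,
      " kinases, ", x$n_timepoints, " timepoints (4 h grid), ",
      x$n_replicates, " replicates x ", x$cells_per_well, " cells\n",
      sep = "")
  cat("  ontology   : ", x$n_terms, " terms in ", x$n_term_clusters,
      " branches\n", sep = "")
  invisible(x)
}

# Time grid implied by the configuration: 0 h upward in 4 h steps.
time_grid <- function(cfg) seq(0, by = 4, length.out = cfg$n_timepoints)

# Gene universe shared by all generators.
gene_universe <- function(cfg) sprintf("GENE%04d", seq_len(cfg$n_genes))

# Planted DEG identities are drawn once from a dedicated RNG stream so that
# the count generator and the interactome generator agree on them without
# sharing state.
# Independent RNG stream k derived from the root seed (kept below 2^31).
sim_seed <- function(cfg, k) (as.numeric(cfg$seed) * 7 + k) %% 2147483647

planted_genes <- function(cfg) {
  genes <- gene_universe(cfg)
  n_pl <- cfg$n_consistent_degs + cfg$n_decoy_degs
  old <- .Random.seed_guard(sim_seed(cfg, 1))
  on.exit(old(), add = TRUE)
  idx <- sample.int(cfg$n_genes, n_pl)
  role <- rep(c("consistent", "decoy"),
              c(cfg$n_consistent_degs, cfg$n_decoy_degs))
  direction <- rep_len(c("up", "down"), n_pl)
  data.frame(gene = genes[idx], role = role, direction = direction,
             stringsAsFactors = FALSE)
}

# Save/set/restore RNG state; returns a restore closure.
.Random.seed_guard <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}
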