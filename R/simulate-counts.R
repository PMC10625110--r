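#' Simulate negative-binomial count datasets with planted consistent DEGs
#'
#' Emulates a collection of independent two-group RNA-seq studies of cells
#' undergoing EMT. Gene-wise means are drawn log-normally around
#' `nb_mean` independently per dataset; counts are negative-binomial with
#' shared dispersion `nb_dispersion`. Each planted DEG carries
#' `planted_log2fc` (up or down) in the treated group of a
#' `consistency_fraction` of the datasets (rounded up) and no effect in the
#' remainder; decoy DEGs carry the effect in only a `decoy_fraction` of
#' datasets. Null genes have no group effect anywhere.
#'
#' @param config an [emt_config()] object.
#' @return A list with elements:
#'   \describe{
#'     \item{datasets}{list of `count_dataset` objects (fields
#'       `dataset_id`, `counts` (genes x samples integer matrix),
#'       `groups` (named character, `control`/`treated`)).}
#'     \item{truth}{data.frame with one row per gene: `gene`, `role`
#'       (`consistent`/`decoy`/`null`), `direction` (`up`/`down`/`null`)
#'       and one logical column `in_<dataset_id>` per dataset marking where
#'       the effect was planted.}
#'   }
#' @examples
#' sim <- simulate_count_datasets(emt_config(seed = 1, n_genes = 100,
#'   n_consistent_degs = 10, n_decoy_degs = 10))
#' dim(sim$datasets[[1]]$counts)
#' @export
simulate_count_datasets <- function(config) {
  validate_emt_config(config)
  restore <- .Random.seed_guard(sim_seed(config, 2))
  on.exit(restore(), add = TRUE)

  genes <- gene_universe(config)
  pl <- planted_genes(config)
  K <- config$n_datasets
  ns <- config$n_samples_per_group
  ds_ids <- sprintf("DS%d", seq_len(K))

  # which datasets carry each planted gene's effect
  n_carry <- ifelse(pl$role == "consistent",
                    ceiling(config$consistency_fraction * K),
                    ceiling(config$decoy_fraction * K))
  carries <- matrix(FALSE, nrow = nrow(pl), ncol = K)
  for (i in seq_len(nrow(pl))) {
    if (n_carry[i] > 0) carries[i, sample.int(K, n_carry[i])] <- TRUE
  }

  truth <- data.frame(gene = genes, role = "null", direction = "null",
                      stringsAsFactors = FALSE)
  pidx <- match(pl$gene, genes)
  truth$role[pidx] <- pl$role
  truth$direction[pidx] <- pl$direction
  for (k in seq_len(K)) {
    col <- logical(config$n_genes)
    col[pidx] <- carries[, k]
    truth[[paste0("in_", ds_ids[k])]] <- col
  }

  size <- 1 / config$nb_dispersion
  fc <- 2^config$planted_log2fc
  datasets <- vector("list", K)
  for (k in seq_len(K)) {
    mu <- exp(stats::rnorm(config$n_genes, log(config$nb_mean), 1))
    mu_trt <- mu
    eff <- pidx[carries[, k]]
    dirn <- truth$direction[eff]
    mu_trt[eff] <- mu[eff] * ifelse(dirn == "up", fc, 1 / fc)
    ctrl <- matrix(stats::rnbinom(config$n_genes * ns, mu = mu, size = size),
                   nrow = config$n_genes)
    trt <- matrix(stats::rnbinom(config$n_genes * ns, mu = mu_trt,
                                 size = size),
                  nrow = config$n_genes)
    counts <- cbind(ctrl, trt)
    rownames(counts) <- genes
    colnames(counts) <- c(sprintf("%s_ctrl_%d", ds_ids[k], seq_len(ns)),
                          sprintf("%s_trt_%d", ds_ids[k], seq_len(ns)))
    groups <- stats::setNames(rep(c("control", "treated"), each = ns),
                              colnames(counts))
    datasets[[k]] <- new_count_dataset(ds_ids[k], counts, groups)
  }
  names(datasets) <- ds_ids
  list(datasets = datasets, truth = truth)
}

new_count_dataset <- function(dataset_id, counts, groups) {
  if (anyDuplicated(rownames(counts))) {
    stop("gene ids must be unique in dataset '", dataset_id, "'",
         call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("counts must be non-negative in dataset '", dataset_id, "'",
         call. = FALSE)
  }
  groups <- groups[colnames(counts)]
  if (anyNA(groups) || !all(groups %in% c("control", "treated"))) {
    stop("every sample of '", dataset_id,
         "' needs a group label in {control, treated}", call. = FALSE)
  }
  if (any(table(factor(groups, c("control", "treated"))) < 2)) {
    stop("dataset '", dataset_id, "' needs >= 2 samples per group",
         call. = FALSE)
  }
  structure(list(dataset_id = dataset_id, counts = counts, groups = groups),
            class = "count_dataset")
}

#' @export
print.count_dataset <- function(x, ...) {
  cat("count_dataset '", x$dataset_id, "': ", nrow(x$counts), " genes x ",
      ncol(x$counts), " samples (",
      sum(x$groups == "control"), " control / ",
      sum(x$groups == "treated"), " treated)\n", sep = "")
  invisible(x)
}
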