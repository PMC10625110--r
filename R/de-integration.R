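#' Counts-per-million normalization
#'
#' Scales each sample (column) to a library size of one million.
#'
#' @param x a `count_dataset` or a non-negative numeric matrix.
#' @return Numeric matrix of the same shape; every column sums to `1e6`.
#' @examples
#' normalize_cpm(matrix(c(10, 90), ncol = 1))
#' @export
normalize_cpm <- function(x) {
  mat <- if (inherits(x, "count_dataset")) x$counts else x
  cs <- colSums(mat)
  if (any(cs == 0)) {
    bad <- colnames(mat)[cs == 0]
    if (is.null(bad)) bad <- which(cs == 0)
    stop("degenerate input: zero library size in sample(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sweep(mat, 2, cs, "/") * 1e6
}

#' Per-dataset two-group differential expression
#'
#' A light-weight DE engine for the consistency integration: per-gene
#' log2 fold change of group means on the `log2(CPM + 1)` scale, two-sided
#' Welch t-test p-values on the same scale, and Benjamini-Hochberg
#' adjustment over all genes. Externally computed DE tables (e.g. DESeq2
#' results) can be supplied instead via [read_de_table()]; the bespoke
#' step of the pipeline is the integration rule, not the per-dataset test.
#'
#' @param dataset a `count_dataset`.
#' @return A `de_table` (data.frame `gene`, `log2FC`, `pvalue`, `padj`,
#'   attribute `dataset_id`). `log2FC` is treated minus control.
#' @examples
#' sim <- simulate_count_datasets(emt_config(seed = 1, n_genes = 50,
#'   n_consistent_degs = 5, n_decoy_degs = 5))
#' head(simple_de(sim$datasets[[1]]))
#' @export
simple_de <- function(dataset) {
  stopifnot(inherits(dataset, "count_dataset"))
  lg <- log2(normalize_cpm(dataset) + 1)
  ctrl <- lg[, dataset$groups == "control", drop = FALSE]
  trt <- lg[, dataset$groups == "treated", drop = FALSE]
  n1 <- ncol(ctrl); n2 <- ncol(trt)
  if (n1 < 2 || n2 < 2) {
    stop("each group needs >= 2 samples for the Welch test", call. = FALSE)
  }
  m1 <- rowMeans(ctrl); m2 <- rowMeans(trt)
  v1 <- rowSums((ctrl - m1)^2) / (n1 - 1)
  v2 <- rowSums((trt - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[se2 == 0] <- ifelse(m2[se2 == 0] == m1[se2 == 0], 1, 0)
  new_de_table(data.frame(gene = rownames(lg), log2FC = m2 - m1,
                          pvalue = p,
                          padj = stats::p.adjust(p, method = "BH"),
                          row.names = NULL, stringsAsFactors = FALSE),
               dataset$dataset_id)
}

#' Cross-dataset direction-consistency integration
#'
#' The vote-counting meta-analysis that defines the common EMT signature:
#' a gene is retained as consistently *up* if it is significantly
#' upregulated (`padj < alpha`, `log2FC > 0`) in at least `min_fraction`
#' of the supplied datasets and is significantly downregulated in none
#' (the opposite-direction veto); symmetrically for *down*. The
#' denominator is always the number of supplied tables — a gene absent
#' from a dataset counts as unsupported there.
#'
#' @param tables list of `de_table` objects (>= 2).
#' @param min_fraction minimum supporting fraction of datasets, in
#'   `(0, 1]`; the headline analysis uses 0.8 ("at least 80% of the
#'   datasets").
#' @param alpha per-dataset adjusted-p significance gate.
#' @return A `consensus_degs` object: data.frame with columns `gene`,
#'   `direction` (`up`/`down`), `support_count`, `support_fraction`,
#'   sorted by direction then gene; attributes `n_datasets`,
#'   `min_fraction`, `alpha`, `dataset_ids`.
#' @examples
#' sim <- simulate_count_datasets(emt_config(seed = 1, n_genes = 200,
#'   n_consistent_degs = 20, n_decoy_degs = 0))
#' tabs <- lapply(sim$datasets, simple_de)
#' integrate_consistency(tabs, min_fraction = 0.8)
#' @export
integrate_consistency <- function(tables, min_fraction = 0.8,
                                  alpha = 0.05) {
  if (length(tables) < 2) {
    stop("need at least 2 DE tables to integrate", call. = FALSE)
  }
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    stop("parameter error: min_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop("parameter error: alpha must lie in (0, 1]", call. = FALSE)
  }
  n <- length(tables)
  genes <- sort(unique(unlist(lapply(tables, function(t) t$gene))))
  up <- matrix(FALSE, length(genes), n)
  down <- matrix(FALSE, length(genes), n)
  for (k in seq_len(n)) {
    t <- tables[[k]]
    sig <- !is.na(t$padj) & t$padj < alpha
    idx <- match(t$gene, genes)
    up[idx[sig & t$log2FC > 0], k] <- TRUE
    down[idx[sig & t$log2FC < 0], k] <- TRUE
  }
  n_up <- rowSums(up)
  n_down <- rowSums(down)
  keep_up <- n_up / n >= min_fraction & n_down == 0
  keep_down <- n_down / n >= min_fraction & n_up == 0
  res <- rbind(
    data.frame(gene = genes[keep_up],
               direction = rep("up", sum(keep_up)),
               support_count = n_up[keep_up],
               stringsAsFactors = FALSE),
    data.frame(gene = genes[keep_down],
               direction = rep("down", sum(keep_down)),
               support_count = n_down[keep_down],
               stringsAsFactors = FALSE))
  res$support_fraction <- res$support_count / n
  res <- res[order(res$direction, res$gene), ]
  rownames(res) <- NULL
  ids <- vapply(tables, function(t) {
    id <- attr(t, "dataset_id")
    if (is.null(id)) NA_character_ else id
  }, character(1))
  structure(res, n_datasets = n, min_fraction = min_fraction,
            alpha = alpha, dataset_ids = ids,
            class = c("consensus_degs", "data.frame"))
}

#' @export
print.consensus_degs <- function(x, ...) {
  cat("consensus_degs: ", sum(x$direction == "up"), " up / ",
      sum(x$direction == "down"), " down over ",
      attr(x, "n_datasets"), " datasets (min_fraction ",
      attr(x, "min_fraction"), ", alpha ", attr(x, "alpha"), ")\n",
      sep = "")
  if (nrow(x)) print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... ", nrow(x) - 10, " more rows\n", sep = "")
  invisible(x)
}

#' @rdname integrate_consistency
#' @param consensus a `consensus_degs` object.
#' @param path output TSV path; a JSON run manifest is written alongside
#'   with suffix `.manifest.json`.
#' @export
write_consensus <- function(consensus, path) {
  utils::write.table(as.data.frame(consensus), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_datasets = attr(consensus, "n_datasets"),
         min_fraction = attr(consensus, "min_fraction"),
         alpha = attr(consensus, "alpha"),
         dataset_ids = attr(consensus, "dataset_ids"),
         n_up = sum(consensus$direction == "up"),
         n_down = sum(consensus$direction == "down")),
    paste0(path, ".manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
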