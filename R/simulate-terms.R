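#' Simulate a term annotation (GMT) and a shallow term DAG
#'
#' Emulates a GO-like functional annotation: `n_terms` gene sets arranged
#' under `n_term_clusters` depth-1 branches of a rooted is_a DAG. Terms
#' within a branch share a branch core of genes (>= 50% of each member
#' set), while sets from different branches are disjoint, so both the
#' shared-gene combined coefficient and Wang semantic similarity separate
#' the branches cleanly. Branch cores are drawn from the planted DEGs of
#' the count generator so that a consensus DEG query is genuinely enriched
#' in the generated terms.
#'
#' @param config an [emt_config()] object.
#' @return A list with:
#'   \describe{
#'     \item{annotation}{a `term_annotation` object (see [read_gmt()]):
#'       `sets` (named list of gene vectors), `names` (term id -> label),
#'       `universe`.}
#'     \item{dag}{a `term_dag` object (see [read_obo_dag()]): `parents`
#'       (named list, child -> parent ids), `root`.}
#'     \item{truth}{data.frame `term`, `cluster` (planted branch id).}
#'   }
#' @examples
#' sim <- simulate_term_annotation(emt_config(seed = 1, n_terms = 14))
#' length(sim$annotation$sets)
#' @export
simulate_term_annotation <- function(config) {
  validate_emt_config(config)
  restore <- .Random.seed_guard(sim_seed(config, 5))
  on.exit(restore(), add = TRUE)

  genes <- gene_universe(config)
  pl <- planted_genes(config)
  B <- config$n_term_clusters
  n_terms <- config$n_terms

  core_size <- 20L
  peri_size <- 30L
  pool_need <- B * core_size
  # cores preferentially from planted DEGs so DEG queries enrich
  core_pool <- pl$gene
  if (length(core_pool) < pool_need) {
    core_pool <- c(core_pool,
                   sample(setdiff(genes, core_pool),
                          pool_need - length(core_pool)))
  }
  core_pool <- sample(core_pool, pool_need)
  peri_pool <- sample(setdiff(genes, core_pool),
                      min(B * peri_size, length(setdiff(genes, core_pool))))
  peri_per_branch <- length(peri_pool) %/% B

  term_ids <- sprintf("T:%07d", seq_len(n_terms))
  branch_ids <- sprintf("T:%07d", n_terms + seq_len(B))
  root_id <- sprintf("T:%07d", n_terms + B + 1L)
  branch_of <- rep_len(seq_len(B), n_terms)
  branch_of <- sort(branch_of)

  topics <- c("signaling cascade", "stress response", "cell division",
              "metabolic process", "developmental process",
              "organismal process", "macromolecule modification",
              "transport regulation", "adhesion program",
              "chromatin organization")
  sets <- vector("list", n_terms)
  names(sets) <- term_ids
  labels <- character(n_terms)
  parents <- vector("list", n_terms + B + 1L)
  names(parents) <- c(term_ids, branch_ids, root_id)
  for (b in seq_len(B)) parents[[branch_ids[b]]] <- root_id
  parents[[root_id]] <- character(0)

  for (i in seq_len(n_terms)) {
    b <- branch_of[i]
    core <- core_pool[(b - 1L) * core_size + seq_len(core_size)]
    peri <- peri_pool[(b - 1L) * peri_per_branch + seq_len(peri_per_branch)]
    extra <- sample(peri, min(5L, length(peri)))
    sets[[i]] <- sort(unique(c(core, extra)))
    topic <- topics[(b - 1L) %% length(topics) + 1L]
    labels[i] <- paste(topic, "term", i)
    # some terms nest under an earlier sibling for a two-level branch
    prev <- which(branch_of[seq_len(i - 1L)] == b)
    if (length(prev) && stats::runif(1) < 0.3) {
      parents[[term_ids[i]]] <- term_ids[max(prev)]
    } else {
      parents[[term_ids[i]]] <- branch_ids[b]
    }
  }

  annotation <- new_term_annotation(
    sets = sets,
    names = stats::setNames(c(labels,
                              paste("branch", seq_len(B), "root"),
                              "root"),
                            c(term_ids, branch_ids, root_id)),
    universe = genes)
  dag <- new_term_dag(parents)
  truth <- data.frame(term = term_ids, cluster = branch_of,
                      stringsAsFactors = FALSE)
  list(annotation = annotation, dag = dag, truth = truth)
}
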