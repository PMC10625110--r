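#' @importFrom data.table fread fwrite :=
NULL

# ---- count datasets ---------------------------------------------------------

#' Write / read a count dataset as TSV
#'
#' The counts file has the gene id in the first column (`gene`) and one
#' column per sample; the companion groups file maps `sample` to `group`
#' (`control` / `treated`).
#'
#' @param dataset a `count_dataset` object.
#' @param counts_path,groups_path file paths.
#' @return `write_count_dataset()` returns the paths invisibly;
#'   `read_count_dataset()` returns a `count_dataset`.
#' @export
write_count_dataset <- function(dataset, counts_path, groups_path) {
  df <- data.frame(gene = rownames(dataset$counts), dataset$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(dataset$groups), group = dataset$groups,
               stringsAsFactors = FALSE),
    groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts_path, groups_path))
}

#' @rdname write_count_dataset
#' @param dataset_id id recorded on the object read back.
#' @export
read_count_dataset <- function(counts_path, groups_path, dataset_id = NULL) {
  df <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (colnames(df)[1] != "gene") {
    stop("format error: counts file must have 'gene' as first column",
         call. = FALSE)
  }
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$gene
  gr <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% colnames(gr))) {
    stop("format error: groups file needs columns 'sample' and 'group'",
         call. = FALSE)
  }
  if (is.null(dataset_id)) {
    dataset_id <- sub("\\.[^.]*$", "", basename(counts_path))
  }
  new_count_dataset(dataset_id, counts,
                    stats::setNames(gr$group, gr$sample))
}

# ---- DE tables --------------------------------------------------------------

#' Read a precomputed differential-expression table
#'
#' Lets externally computed per-dataset DE results (for example DESeq2
#' output reshaped to TSV) enter the consistency integration. Required
#' columns: `gene`, `log2FC`, `pvalue`, `padj` (header required).
#'
#' @param path TSV path.
#' @param dataset_id id stored on the returned table (defaults to the file
#'   name).
#' @return A `de_table`: data.frame with columns `gene`, `log2FC`,
#'   `pvalue`, `padj` and attribute `dataset_id`.
#' @export
read_de_table <- function(path, dataset_id = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene", "log2FC", "pvalue", "padj")
  missing <- setdiff(needed, colnames(df))
  if (length(missing)) {
    stop("format error: missing column(s) ",
         paste(sQuote(missing), collapse = ", "), " in ", path,
         call. = FALSE)
  }
  if (is.null(dataset_id)) dataset_id <- sub("\\.[^.]*$", "", basename(path))
  new_de_table(df[needed], dataset_id)
}

new_de_table <- function(df, dataset_id) {
  if (anyDuplicated(df$gene)) {
    stop("validation error: duplicated gene id(s) in DE table '",
         dataset_id, "': ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "),
         call. = FALSE)
  }
  for (col in c("pvalue", "padj")) {
    bad <- !is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 1)
    if (any(bad)) {
      stop("validation error: ", col, " outside [0, 1] for gene(s) ",
           paste(utils::head(df$gene[bad], 5), collapse = ", "),
           call. = FALSE)
    }
  }
  attr(df, "dataset_id") <- dataset_id
  class(df) <- c("de_table", "data.frame")
  df
}

#' @export
write_de_table <- function(de, path) {
  utils::write.table(as.data.frame(de)[c("gene", "log2FC", "pvalue",
                                         "padj")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- edge lists -------------------------------------------------------------

#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges[c("node_a", "node_b", "source")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# Three-column edge TSV (node_a, node_b, source), no header; lines
# starting with '#' are comments.
read_edge_list <- function(path, source_default = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf < 2)) {
    bad <- which(keep)[which(nf < 2)[1]]
    stop("format error: line ", bad, " of ", path,
         " has fewer than 2 tab-separated fields", call. = FALSE)
  }
  src <- vapply(rows, function(r) {
    if (length(r) >= 3) r[3]
    else if (!is.null(source_default)) source_default
    else stop("format error: missing source column in ", path,
              call. = FALSE)
  }, character(1))
  data.frame(node_a = vapply(rows, `[`, character(1), 1),
             node_b = vapply(rows, `[`, character(1), 2),
             source = src, stringsAsFactors = FALSE)
}

# ---- cell tracks ------------------------------------------------------------

#' Read / write time-lapse cell track tables
#'
#' CSV with columns `genotype`, `inducer`, `inhibitor`, `replicate`,
#' `time_h`, `cell_id`, `x`, `y` (coordinates in micrometres; `UNTREATED`
#' in `inhibitor` marks the matched control wells).
#'
#' @param tracks data.frame of cell observations.
#' @param path CSV path.
#' @export
write_tracks <- function(tracks, path) {
  data.table::fwrite(tracks, path)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  tracks <- data.table::fread(path, data.table = FALSE)
  needed <- c("genotype", "inducer", "inhibitor", "replicate", "time_h",
              "cell_id", "x", "y")
  missing <- setdiff(needed, colnames(tracks))
  if (length(missing)) {
    stop("format error: track file missing column(s) ",
         paste(sQuote(missing), collapse = ", "), call. = FALSE)
  }
  tracks
}

# ---- term annotation (GMT) --------------------------------------------------

#' Construct a term annotation or term DAG programmatically
#'
#' `new_term_annotation()` validates a named list of gene sets against a
#' universe; `new_term_dag()` validates a child -> parents list as a
#' rooted acyclic is_a hierarchy (single root, every term reaching it)
#' and records per-term depth. [read_gmt()] and [read_obo_dag()] are the
#' file-based counterparts.
#'
#' @param sets named list of character gene vectors (empty sets dropped).
#' @param names optional named character of term labels.
#' @param universe optional gene universe (default: union of the sets).
#' @return A `term_annotation` or `term_dag` object.
#' @examples
#' dag <- new_term_dag(list(R = character(0), A = "R", B = "A"))
#' dag$depth
#' @export
new_term_annotation <- function(sets, names = NULL, universe = NULL) {
  stopifnot(is.list(sets), !is.null(base::names(sets)))
  empty <- lengths(sets) == 0
  if (any(empty)) sets <- sets[!empty]
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  if (is.null(names)) {
    names <- stats::setNames(base::names(sets), base::names(sets))
  }
  outside <- setdiff(unlist(sets), universe)
  if (length(outside)) {
    stop("term annotation: member genes outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(sets = sets, names = names, universe = universe),
            class = "term_annotation")
}

#' @export
print.term_annotation <- function(x, ...) {
  cat("term_annotation: ", length(x$sets), " terms over ",
      length(x$universe), " genes (set sizes ",
      min(lengths(x$sets)), "-", max(lengths(x$sets)), ")\n", sep = "")
  invisible(x)
}

#' Read / write gene-set annotations in GMT format
#'
#' Standard tab-separated GMT: term id, description, then member genes.
#'
#' @param path GMT file path.
#' @param universe optional gene universe; defaults to the union of all
#'   member sets.
#' @return A `term_annotation` object with fields `sets` (named list of
#'   character vectors), `names` (term id -> description) and `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(rows) < 3
  if (any(short)) {
    stop("format error: GMT line ", which(short)[1],
         " has fewer than 3 fields", call. = FALSE)
  }
  ids <- vapply(rows, `[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("format error: duplicated term id in GMT: ",
         ids[duplicated(ids)][1], call. = FALSE)
  }
  sets <- lapply(rows, function(r) unique(r[-(1:2)]))
  names(sets) <- ids
  new_term_annotation(sets,
                      names = stats::setNames(
                        vapply(rows, `[`, character(1), 2), ids),
                      universe = universe)
}

#' @rdname read_gmt
#' @param annotation a `term_annotation`.
#' @export
write_gmt <- function(annotation, path) {
  lines <- vapply(names(annotation$sets), function(id) {
    paste(c(id, unname(annotation$names[id]), annotation$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- term DAG (OBO subset) --------------------------------------------------

#' @rdname new_term_annotation
#' @param parents named list mapping each term id to the character vector
#'   of its parent ids (the root has `character(0)`).
#' @export
new_term_dag <- function(parents) {
  stopifnot(is.list(parents), !is.null(names(parents)))
  ids <- names(parents)
  roots <- ids[lengths(parents) == 0]
  if (length(roots) != 1) {
    stop("term DAG must have exactly one root, found ", length(roots),
         call. = FALSE)
  }
  unknown <- setdiff(unlist(parents), ids)
  if (length(unknown)) {
    stop("term DAG references unknown parent(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  # acyclicity + reachability of the root via iterative depth assignment
  depth <- stats::setNames(rep(NA_real_, length(ids)), ids)
  depth[roots] <- 0
  for (iter in seq_len(length(ids) + 1L)) {
    changed <- FALSE
    for (id in ids[is.na(depth)]) {
      pd <- depth[parents[[id]]]
      if (all(!is.na(pd))) {
        depth[id] <- max(pd) + 1
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (anyNA(depth)) {
    stop("term DAG is cyclic or disconnected at: ",
         paste(utils::head(ids[is.na(depth)], 5), collapse = ", "),
         call. = FALSE)
  }
  structure(list(parents = parents, root = roots, depth = depth),
            class = "term_dag")
}

#' @export
print.term_dag <- function(x, ...) {
  cat("term_dag: ", length(x$parents), " terms, root ", x$root,
      ", max depth ", max(x$depth), "\n", sep = "")
  invisible(x)
}

#' Read / write a rooted is_a term DAG in OBO-subset format
#'
#' Parses only `[Term]` stanzas with `id:`, `name:` and `is_a:` lines —
#' the subset needed for Wang semantic similarity over an ontology-like
#' hierarchy.
#'
#' @param path OBO file path.
#' @return A `term_dag` with `parents` (named list child -> parents),
#'   `root` and per-term `depth`.
#' @export
read_obo_dag <- function(path) {
  lines <- readLines(path)
  parents <- list()
  labels <- character(0)
  cur <- NULL
  flush <- function(cur) {
    if (!is.null(cur) && !is.null(cur$id)) {
      parents[[cur$id]] <<- cur$is_a
      labels[cur$id] <<- if (is.null(cur$name)) cur$id else cur$name
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush(cur)
      cur <- list(is_a = character(0))
    } else if (!is.null(cur)) {
      if (startsWith(ln, "id:")) {
        cur$id <- trimws(sub("^id:", "", ln))
      } else if (startsWith(ln, "name:")) {
        cur$name <- trimws(sub("^name:", "", ln))
      } else if (startsWith(ln, "is_a:")) {
        tgt <- trimws(sub("^is_a:", "", ln))
        tgt <- trimws(sub("!.*$", "", tgt))   # strip trailing label
        cur$is_a <- c(cur$is_a, tgt)
      }
    }
  }
  flush(cur)
  dag <- new_term_dag(parents)
  dag$labels <- labels
  dag
}

#' @rdname read_obo_dag
#' @param dag a `term_dag`.
#' @param labels optional named character of term labels.
#' @export
write_obo_dag <- function(dag, path, labels = NULL) {
  ids <- names(dag$parents)
  ids <- ids[order(dag$depth[ids], ids)]
  out <- c("format-version: 1.2", "")
  for (id in ids) {
    nm <- if (!is.null(labels) && !is.na(labels[id])) labels[id] else id
    pa <- dag$parents[[id]]
    out <- c(out, "[Term]", paste0("id: ", id), paste0("name: ", nm),
             if (length(pa)) paste0("is_a: ", pa), "")
  }
  writeLines(out, path)
  invisible(path)
}

# ---- one-call generator -----------------------------------------------------

#' Generate every synthetic pipeline input into a directory
#'
#' Runs all four generators of the synthetic-data module for one
#' configuration and writes their outputs (counts + groups TSVs per
#' dataset, three per-source edge-list TSVs, the cell-track CSV, the
#' annotation TSVs, the GMT and OBO files) plus the planted truth tables
#' under `out_dir/truth/`. Output is byte-identical for a fixed seed.
#'
#' @param config an [emt_config()] object.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the full in-memory simulation: list with `counts`,
#'   `interactome`, `screen`, `terms` (each the corresponding generator's
#'   return value) and `files` (named character of written paths).
#' @export
simulate_emt_inputs <- function(config, out_dir) {
  validate_emt_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)

  counts <- simulate_count_datasets(config)
  interactome <- simulate_interactome(config)
  screen <- simulate_screen_tracks(config)
  terms <- simulate_term_annotation(config)

  files <- character(0)
  for (ds in counts$datasets) {
    cp <- file.path(out_dir, paste0("counts_", ds$dataset_id, ".tsv"))
    gp <- file.path(out_dir, paste0("groups_", ds$dataset_id, ".tsv"))
    write_count_dataset(ds, cp, gp)
    files[paste0("counts_", ds$dataset_id)] <- cp
    files[paste0("groups_", ds$dataset_id)] <- gp
  }
  for (src in unique(interactome$edges$source)) {
    ep <- file.path(out_dir, paste0("edges_", src, ".tsv"))
    write_edge_list(interactome$edges[interactome$edges$source == src, ],
                    ep)
    files[paste0("edges_", src)] <- ep
  }
  files["tracks"] <- file.path(out_dir, "tracks.csv")
  write_tracks(screen$tracks, files["tracks"])
  files["inhibitor_kinase"] <- file.path(out_dir, "inhibitor_kinase.tsv")
  utils::write.table(screen$inhibitor_kinase, files["inhibitor_kinase"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files["kinase_family"] <- file.path(out_dir, "kinase_family.tsv")
  utils::write.table(screen$kinase_family, files["kinase_family"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files["gmt"] <- file.path(out_dir, "terms.gmt")
  write_gmt(terms$annotation, files["gmt"])
  files["obo"] <- file.path(out_dir, "terms.obo")
  write_obo_dag(terms$dag, files["obo"], labels = terms$annotation$names)

  truths <- list(genes = counts$truth, hubs = interactome$truth,
                 inhibitors = screen$truth, terms = terms$truth)
  for (nm in names(truths)) {
    tp <- file.path(out_dir, "truth", paste0(nm, ".tsv"))
    utils::write.table(truths[[nm]], tp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files[paste0("truth_", nm)] <- tp
  }
  manifest <- list(seed = config$seed,
                   config = unclass(config),
                   files = as.list(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(counts = counts, interactome = interactome,
                 screen = screen, terms = terms, files = files))
}
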