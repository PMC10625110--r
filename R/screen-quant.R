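#' Scatter distance of a cell population at one timepoint
#'
#' Quantifies how dispersed the cells of a well are. The default
#' `centroid` method is the mean Euclidean distance of the cells to their
#' population centroid; `pairwise` is the mean distance over all
#' unordered cell pairs. A single cell has scatter 0 under the centroid
#' method.
#'
#' @param xy two-column numeric matrix (or data.frame) of cell
#'   coordinates in micrometres.
#' @param method `"centroid"` (default) or `"pairwise"`.
#' @return Scatter distance in micrometres.
#' @examples
#' scatter_distance(rbind(c(0, 0), c(2, 0)))   # 1
#' @export
scatter_distance <- function(xy, method = c("centroid", "pairwise")) {
  method <- match.arg(method)
  xy <- as.matrix(xy)
  if (nrow(xy) == 0) stop("empty cell set", call. = FALSE)
  if (method == "centroid") {
    ctr <- colMeans(xy)
    mean(sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2))
  } else {
    if (nrow(xy) < 2) {
      stop("pairwise scatter needs >= 2 cells", call. = FALSE)
    }
    mean(stats::dist(xy))
  }
}

# Per-well, per-replicate, per-timepoint scatter distances.
scatter_table <- function(tracks, method = c("centroid", "pairwise")) {
  method <- match.arg(method)
  dt <- data.table::as.data.table(tracks)
  if (method == "centroid") {
    res <- dt[, {
      cx <- mean(x); cy <- mean(y)
      list(distance = mean(sqrt((x - cx)^2 + (y - cy)^2)))
    }, by = c("genotype", "inducer", "inhibitor", "replicate", "time_h")]
  } else {
    res <- dt[, list(distance = mean(stats::dist(cbind(x, y)))),
              by = c("genotype", "inducer", "inhibitor", "replicate",
                     "time_h")]
  }
  data.table::setorder(res, genotype, inducer, inhibitor, replicate,
                       time_h)
  data.table::setDF(res)
}

#' Migration log-fold-change series for one well
#'
#' For one (genotype, inducer, inhibitor) condition, computes the scatter
#' distance per replicate and timepoint, the log2 ratio of each treated
#' replicate against the mean matched untreated control at the same
#' genotype, inducer and timepoint, the replicate-averaged log-FC series,
#' and its trapezoidal AUC. Distances below `eps` micrometres are floored
#' before the ratio and the well is flagged.
#'
#' @param tracks cell-track data.frame (see [read_tracks()]).
#' @param genotype,inducer,inhibitor the well key.
#' @param method scatter statistic, see [scatter_distance()].
#' @param eps distance floor (micrometres) guarding the log ratio.
#' @param control label of untreated control wells in `inhibitor`.
#' @return A `migration_series` list: `genotype`, `inducer`, `inhibitor`,
#'   `time_h`, `logfc` (replicate-averaged), `per_replicate` (matrix
#'   replicate x time), `auc`, `floored` (logical).
#' @export
migration_series <- function(tracks, genotype, inducer, inhibitor,
                             method = c("centroid", "pairwise"),
                             eps = 1e-6, control = "UNTREATED") {
  method <- match.arg(method)
  sel <- tracks$genotype == genotype & tracks$inducer == inducer &
    tracks$inhibitor %in% c(inhibitor, control)
  st <- scatter_table(tracks[sel, , drop = FALSE], method = method)
  build_series(st, genotype, inducer, inhibitor, eps = eps,
               control = control)
}

# Shared series builder operating on a precomputed scatter table.
build_series <- function(st, genotype, inducer, inhibitor, eps = 1e-6,
                         control = "UNTREATED") {
  trt <- st[st$genotype == genotype & st$inducer == inducer &
              st$inhibitor == inhibitor, , drop = FALSE]
  ctl <- st[st$genotype == genotype & st$inducer == inducer &
              st$inhibitor == control, , drop = FALSE]
  if (!nrow(trt)) {
    stop("no observations for well ", genotype, "/", inducer, "/",
         inhibitor, call. = FALSE)
  }
  grid <- sort(unique(trt$time_h))
  ctl_mean <- tapply(ctl$distance, ctl$time_h, mean)
  missing <- setdiff(as.character(grid), names(ctl_mean))
  if (length(missing)) {
    stop("missing control timepoint(s) ", paste(missing, collapse = ", "),
         " h for well ", genotype, "/", inducer, "/", inhibitor,
         call. = FALSE)
  }
  floored <- any(trt$distance < eps) || any(ctl_mean[as.character(grid)] < eps)
  reps <- sort(unique(trt$replicate))
  per_rep <- matrix(NA_real_, length(reps), length(grid),
                    dimnames = list(reps, grid))
  for (i in seq_along(reps)) {
    ri <- trt[trt$replicate == reps[i], , drop = FALSE]
    d_t <- pmax(ri$distance[match(grid, ri$time_h)], eps)
    d_c <- pmax(ctl_mean[as.character(grid)], eps)
    per_rep[i, ] <- log2(d_t / d_c)
  }
  logfc <- colMeans(per_rep, na.rm = TRUE)
  structure(list(genotype = genotype, inducer = inducer,
                 inhibitor = inhibitor, time_h = grid,
                 logfc = unname(logfc), per_replicate = per_rep,
                 auc = auc_trapezoid(grid, unname(logfc)),
                 floored = floored),
            class = "migration_series")
}

#' @export
print.migration_series <- function(x, ...) {
  cat("migration_series ", x$genotype, "/", x$inducer, "/", x$inhibitor,
      ": ", length(x$time_h), " timepoints, AUC ", round(x$auc, 2),
      if (x$floored) " [distance floored]", "\n", sep = "")
  invisible(x)
}

#' Trapezoidal area under a log-fold-change time course
#'
#' Signed trapezoidal integral over the imaging grid, in
#' log2-units x hours. Exact for piecewise-linear trajectories.
#'
#' @param time_h strictly increasing time grid (hours).
#' @param value values on the grid.
#' @return The signed integral.
#' @examples
#' auc_trapezoid(seq(0, 48, 4), rep(1, 13))     # 48
#' auc_trapezoid(seq(0, 48, 4), seq(0, 48, 4) / 24)  # 48
#' @export
auc_trapezoid <- function(time_h, value) {
  if (length(time_h) < 2) stop("need >= 2 grid points", call. = FALSE)
  if (length(time_h) != length(value)) {
    stop("time and value lengths differ", call. = FALSE)
  }
  dt <- diff(time_h)
  if (any(dt <= 0)) {
    stop("time grid must be strictly increasing", call. = FALSE)
  }
  sum(dt * (value[-1] + value[-length(value)]) / 2)
}

#' Quantify a full scattering screen into per-well AUCs
#'
#' Computes the scatter distance for every well and timepoint, the
#' replicate-averaged log-FC series against the matched untreated control
#' of each genotype x inducer, and its AUC, for every inhibitor on the
#' panel.
#'
#' @inheritParams migration_series
#' @return A `screen_auc` data.frame: `genotype`, `inducer`, `inhibitor`,
#'   `auc`, `floored`; attribute `logfc_matrix` holds one
#'   time x inhibitor log-FC matrix per genotype x inducer (heatmap-ready).
#' @export
quantify_screen <- function(tracks, method = c("centroid", "pairwise"),
                            eps = 1e-6, control = "UNTREATED") {
  method <- match.arg(method)
  st <- scatter_table(tracks, method = method)
  conds <- unique(st[st$inhibitor != control,
                     c("genotype", "inducer", "inhibitor")])
  rows <- vector("list", nrow(conds))
  mats <- list()
  for (i in seq_len(nrow(conds))) {
    s <- build_series(st, conds$genotype[i], conds$inducer[i],
                      conds$inhibitor[i], eps = eps, control = control)
    rows[[i]] <- data.frame(genotype = s$genotype, inducer = s$inducer,
                            inhibitor = s$inhibitor, auc = s$auc,
                            floored = s$floored, stringsAsFactors = FALSE)
    key <- paste(s$genotype, s$inducer, sep = "_")
    mats[[key]] <- cbind(mats[[key]],
                         stats::setNames(list(s$logfc), s$inhibitor)[[1]])
    colnames(mats[[key]])[ncol(mats[[key]])] <- s$inhibitor
    rownames(mats[[key]]) <- s$time_h
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$genotype, res$inducer, res$inhibitor), ]
  rownames(res) <- NULL
  structure(res, logfc_matrix = mats,
            class = c("screen_auc", "data.frame"))
}

#' Classify inhibitors by the quantile rules of the dependence screen
#'
#' Applies the percentile criteria comparing wild-type (WT) and
#' adaptor-knockdown (KD) AUC panels, separately per inducer, then
#' intersects across inducers:
#' \enumerate{
#'   \item AUC <= 25th percentile in WT and in KD: adaptor-*independent*
#'     EMT inhibitor.
#'   \item AUC <= 25th percentile in WT but > 25th percentile in KD:
#'     adaptor-*dependent* EMT inhibitor.
#'   \item AUC < 75th percentile in WT but >= 75th percentile in KD:
#'     adaptor-*dependent* EMT activator.
#' }
#' Criteria are applied in order with first match winning; anything else
#' is `unclassified`. Percentiles are computed within each
#' genotype x inducer AUC distribution by linear interpolation between
#' closest ranks, over the inhibitor panel only (controls excluded). The
#' final category of an inhibitor is its per-inducer category if that
#' category agrees under both inducers, else `unclassified`.
#'
#' @param auc a `screen_auc` data.frame (from [quantify_screen()]) or any
#'   data.frame with columns `genotype` (`WT`/`KD`), `inducer`,
#'   `inhibitor`, `auc`.
#' @param probs the two percentile probabilities (default 0.25 and 0.75).
#' @return A `screen_classification` list: `per_inducer` (data.frame
#'   `inhibitor`, `inducer`, `category`), `final` (data.frame
#'   `inhibitor`, `category`), `thresholds` (data.frame `inducer`,
#'   `q25_WT`, `q75_WT`, `q25_KD`, `q75_KD`).
#' @examples
#' pan <- expand.grid(genotype = c("WT", "KD"), inducer = "DMOG",
#'                    inhibitor = paste0("I", 1:8),
#'                    stringsAsFactors = FALSE)
#' pan$auc <- rep(c(-10, -8, -6, -4, -2, 0, 2, 4), each = 2)
#' classify_inhibitors(pan)
#' @export
classify_inhibitors <- function(auc, probs = c(0.25, 0.75)) {
  stopifnot(all(c("genotype", "inducer", "inhibitor", "auc") %in%
                  colnames(auc)))
  df <- as.data.frame(auc)[c("genotype", "inducer", "inhibitor", "auc")]
  inducers <- sort(unique(df$inducer))
  per <- list()
  thresholds <- list()
  for (ind in inducers) {
    wt <- df[df$genotype == "WT" & df$inducer == ind, , drop = FALSE]
    kd <- df[df$genotype == "KD" & df$inducer == ind, , drop = FALSE]
    panel <- sort(unique(c(wt$inhibitor, kd$inhibitor)))
    miss <- c(setdiff(panel, wt$inhibitor), setdiff(panel, kd$inhibitor))
    if (length(miss)) {
      stop("panel mismatch under inducer ", ind,
           ": inhibitor(s) missing in one genotype: ",
           paste(unique(miss), collapse = ", "), call. = FALSE)
    }
    a_wt <- wt$auc[match(panel, wt$inhibitor)]
    a_kd <- kd$auc[match(panel, kd$inhibitor)]
    if (length(unique(a_wt)) < 2 || length(unique(a_kd)) < 2) {
      stop("degenerate AUC panel under inducer ", ind,
           ": need >= 2 distinct values per genotype", call. = FALSE)
    }
    q_wt <- stats::quantile(a_wt, probs, type = 7, names = FALSE)
    q_kd <- stats::quantile(a_kd, probs, type = 7, names = FALSE)
    cat_i <- ifelse(a_wt <= q_wt[1] & a_kd <= q_kd[1],
                    "independent_inhibitor",
             ifelse(a_wt <= q_wt[1] & a_kd > q_kd[1],
                    "dependent_inhibitor",
             ifelse(a_wt < q_wt[2] & a_kd >= q_kd[2],
                    "dependent_activator", "unclassified")))
    per[[ind]] <- data.frame(inhibitor = panel, inducer = ind,
                             category = cat_i, stringsAsFactors = FALSE)
    thresholds[[ind]] <- data.frame(inducer = ind,
                                    q25_WT = q_wt[1], q75_WT = q_wt[2],
                                    q25_KD = q_kd[1], q75_KD = q_kd[2],
                                    stringsAsFactors = FALSE)
  }
  per_inducer <- do.call(rbind, per)
  rownames(per_inducer) <- NULL
  wide <- split(per_inducer$category, per_inducer$inhibitor)
  final <- data.frame(
    inhibitor = names(wide),
    category = vapply(wide, function(cats) {
      if (length(cats) == length(inducers) && length(unique(cats)) == 1)
        cats[1] else "unclassified"
    }, character(1)),
    stringsAsFactors = FALSE)
  rownames(final) <- NULL
  structure(list(per_inducer = per_inducer, final = final,
                 thresholds = do.call(rbind, thresholds)),
            class = "screen_classification")
}

#' @export
print.screen_classification <- function(x, ...) {
  tab <- table(factor(x$final$category,
                      c("independent_inhibitor", "dependent_inhibitor",
                        "dependent_activator", "unclassified")))
  cat("screen_classification over ", nrow(x$final),
      " inhibitors (final, cross-inducer):\n", sep = "")
  print(tab)
  invisible(x)
}

#' Summarize classified inhibitors by target kinase family
#'
#' Maps classified inhibitors to their target kinases and kinase
#' families, counting distinct kinases per category x family (an
#' inhibitor with targets in several families contributes to each).
#' Also reports the promote/attenuate split: adaptor-dependent EMT
#' inhibitors act on EMT-promoting kinases, adaptor-dependent activators
#' on EMT-attenuating kinases.
#'
#' @param classification a `screen_classification`.
#' @param inhibitor_kinase data.frame `inhibitor`, `kinase`.
#' @param kinase_family data.frame `kinase`, `family`.
#' @return A list: `family_counts` (data.frame `category`, `family`,
#'   `n_kinases`), `dependent_split` (named counts of distinct kinases
#'   behind dependent inhibitors / activators), `unannotated` (inhibitor
#'   ids without kinase annotation).
#' @export
summarize_kinases <- function(classification, inhibitor_kinase,
                              kinase_family) {
  stopifnot(inherits(classification, "screen_classification"))
  final <- classification$final
  ann <- merge(final, inhibitor_kinase, by = "inhibitor", all.x = TRUE)
  unannotated <- unique(ann$inhibitor[is.na(ann$kinase)])
  ann <- merge(ann[!is.na(ann$kinase), , drop = FALSE], kinase_family,
               by = "kinase", all.x = TRUE)
  ann$family[is.na(ann$family)] <- "unannotated"
  classified <- ann[ann$category != "unclassified", , drop = FALSE]
  cats <- c("independent_inhibitor", "dependent_inhibitor",
            "dependent_activator")
  fams <- sort(unique(kinase_family$family))
  grid <- expand.grid(category = cats, family = fams,
                      stringsAsFactors = FALSE)
  grid$n_kinases <- mapply(function(cat, fam) {
    length(unique(classified$kinase[classified$category == cat &
                                      classified$family == fam]))
  }, grid$category, grid$family)
  split <- c(
    promoting = length(unique(
      classified$kinase[classified$category == "dependent_inhibitor"])),
    attenuating = length(unique(
      classified$kinase[classified$category == "dependent_activator"])))
  list(family_counts = grid[order(grid$category, grid$family), ],
       dependent_split = split, unannotated = unannotated)
}

#' Ellipsoid tumor volume from caliper measurements
#'
#' `V = 0.5 * L * W^2` in cubic millimetres. If width exceeds length the
#' two are swapped with a warning (calipers record the larger axis as
#' length).
#'
#' @param length_mm,width_mm caliper measurements in millimetres.
#' @return Volume(s) in mm^3.
#' @examples
#' tumor_volume(10, 5)   # 125
#' @export
tumor_volume <- function(length_mm, width_mm) {
  if (any(length_mm <= 0) || any(width_mm <= 0)) {
    stop("tumor dimensions must be positive", call. = FALSE)
  }
  swap <- width_mm > length_mm
  if (any(swap)) {
    warning("width > length for ", sum(swap),
            " measurement(s); swapping", call. = FALSE)
    tmp <- length_mm[swap]
    length_mm[swap] <- width_mm[swap]
    width_mm[swap] <- tmp
  }
  0.5 * length_mm * width_mm^2
}
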