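#' Simulate a time-lapse kinase-inhibitor scattering screen
#'
#' Emulates live imaging of EMT-induced cell scattering in wild-type (WT)
#' and adaptor-knockdown (KD) cells across an inhibitor panel under two
#' EMT inducers (DMOG, TGFB), sampled on the 4 h grid. Cell positions in a
#' well are isotropic Gaussian around the well centre with the per-axis SD
#' chosen so that the expected scatter distance (mean distance to the
#' population centroid) follows a planted linear time course
#' `d0 + f * rate * t`; i.i.d. Gaussian noise of SD `scatter_noise_sd`
#' is added to every coordinate.
#'
#' Planted inhibitor classes (10 per class on the default panel) modulate
#' the scatter growth factor `f`:
#' \describe{
#'   \item{independent_inhibitor}{`f = 0.4` in both genotypes: suppresses
#'     scattering regardless of the adaptor.}
#'   \item{dependent_inhibitor}{`f = 0.4` in WT only; the suppression is
#'     lost upon knockdown (`f = 1` in KD).}
#'   \item{dependent_activator}{`f = 1.8` in KD only: scattering increases
#'     when the knockdown restores the targeted kinase's braking role.}
#' }
#' Unplanted inhibitors receive a mild idiosyncratic factor (log-normal,
#' shared across genotypes and inducers) so the panel-wide AUC
#' distribution has realistic spread for the quantile rules.
#'
#' @param config an [emt_config()] object.
#' @return A list with:
#'   \describe{
#'     \item{tracks}{data.frame (also data.table) with columns `genotype`,
#'       `inducer`, `inhibitor` (`UNTREATED` marks control wells),
#'       `replicate`, `time_h`, `cell_id`, `x`, `y` (micrometres).}
#'     \item{inhibitor_kinase}{data.frame `inhibitor`, `kinase`.}
#'     \item{kinase_family}{data.frame `kinase`, `family`.}
#'     \item{truth}{data.frame `inhibitor`, `category` (planted final
#'       category; `unclassified` for nulls).}
#'   }
#' @examples
#' sim <- simulate_screen_tracks(emt_config(seed = 1, n_inhibitors = 12,
#'   n_kinases = 8, n_replicates = 2, cells_per_well = 5))
#' head(sim$tracks)
#' @export
simulate_screen_tracks <- function(config) {
  validate_emt_config(config)
  restore <- .Random.seed_guard(sim_seed(config, 4))
  on.exit(restore(), add = TRUE)

  n_inh <- config$n_inhibitors
  inhibitors <- sprintf("INH%03d", seq_len(n_inh))
  n_per_class <- min(10L, n_inh %/% 6L)
  classes <- c("independent_inhibitor", "dependent_inhibitor",
               "dependent_activator")
  planted_idx <- sample.int(n_inh, 3L * n_per_class)
  category <- rep("unclassified", n_inh)
  category[planted_idx] <- rep(classes, each = n_per_class)

  # idiosyncratic scatter-growth factor, shared across genotype and inducer
  f0 <- exp(stats::rnorm(n_inh, 0, 0.2))
  f_wt <- f0
  f_kd <- f0
  f_wt[category == "independent_inhibitor"] <- 0.4
  f_kd[category == "independent_inhibitor"] <- 0.4
  f_wt[category == "dependent_inhibitor"] <- 0.4
  f_kd[category == "dependent_inhibitor"] <- 1.0
  f_wt[category == "dependent_activator"] <- 1.0
  f_kd[category == "dependent_activator"] <- 1.8

  d0 <- 20                                  # baseline scatter at 0 h (um)
  rate <- c(DMOG = 2.0, TGFB = 2.2)          # um/h scatter growth, untreated
  grid <- time_grid(config)

  wells <- data.table::CJ(genotype = c("WT", "KD"),
                          inducer = c("DMOG", "TGFB"),
                          inhibitor = c("UNTREATED", inhibitors),
                          replicate = seq_len(config$n_replicates),
                          time_h = grid,
                          cell_id = seq_len(config$cells_per_well))
  fac <- data.table::data.table(
    inhibitor = rep(c("UNTREATED", inhibitors), 2),
    genotype = rep(c("WT", "KD"), each = n_inh + 1L),
    f = c(1, f_wt, 1, f_kd))
  tracks <- fac[wells, on = c("inhibitor", "genotype")]
  d_target <- d0 + tracks$f * rate[tracks$inducer] * tracks$time_h
  # per-axis SD so that E[distance to centroid] ~ d_target (Rayleigh mean)
  sigma <- sqrt((d_target * sqrt(2 / pi))^2 + config$scatter_noise_sd^2)
  n <- nrow(tracks)
  tracks[, c("x", "y") := list(stats::rnorm(n, 0, sigma),
                               stats::rnorm(n, 0, sigma))]
  tracks[, c("f") := NULL]
  data.table::setcolorder(tracks, c("genotype", "inducer", "inhibitor",
                                    "replicate", "time_h", "cell_id",
                                    "x", "y"))
  data.table::setorder(tracks, genotype, inducer, inhibitor, replicate,
                       time_h, cell_id)

  kinases <- sprintf("KIN%03d", seq_len(config$n_kinases))
  # every kinase targeted at least once; surplus inhibitors re-drawn
  k1 <- c(kinases[seq_len(min(n_inh, config$n_kinases))],
          sample(kinases, max(0L, n_inh - config$n_kinases),
                 replace = TRUE))
  k1 <- sample(k1)                           # decouple id order from targets
  inhibitor_kinase <- data.frame(inhibitor = inhibitors, kinase = k1,
                                 stringsAsFactors = FALSE)
  dual <- which(stats::runif(n_inh) < 0.15)
  if (length(dual)) {
    k2 <- vapply(k1[dual],
                 function(k) sample(setdiff(kinases, k), 1), character(1))
    inhibitor_kinase <- rbind(
      inhibitor_kinase,
      data.frame(inhibitor = inhibitors[dual], kinase = k2,
                 stringsAsFactors = FALSE))
  }
  inhibitor_kinase <-
    inhibitor_kinase[order(inhibitor_kinase$inhibitor,
                           inhibitor_kinase$kinase), , drop = FALSE]
  rownames(inhibitor_kinase) <- NULL

  families <- c("TK", "TKL", "AGC", "CAMK", "CMGC", "STE", "CK1")
  kinase_family <- data.frame(
    kinase = kinases,
    family = sample(families, config$n_kinases, replace = TRUE,
                    prob = c(0.3, 0.12, 0.15, 0.15, 0.13, 0.1, 0.05)),
    stringsAsFactors = FALSE)

  truth <- data.frame(inhibitor = inhibitors, category = category,
                      stringsAsFactors = FALSE)
  list(tracks = data.table::setDF(tracks), inhibitor_kinase = inhibitor_kinase,
       kinase_family = kinase_family, truth = truth)
}
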