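DEFAULT_SUBSTRATES <- c("xylan", "arabinoxylan", "galactomannan", "pectin",
                        "beta_glucan", "cellulose", "lignin")
LABILE <- c("xylan", "arabinoxylan", "galactomannan", "pectin")
RECALCITRANT <- c("beta_glucan", "cellulose", "lignin")
DEFAULT_SPECIES <- c("Stenotrophomonas", "Bacillus", "Paenibacillus",
                     "Microbacterium", "Cellulomonas", "Rhodococcus")

# Default mean phenotype displacement per transfer, emulating the
# qualitative structure of the experiment: the monoculture (MC) takes a
# short path; the reset polyculture (RP) moves steadily toward labile
# substrates; the dynamic polyculture (DP) first tracks labile substrates,
# then pivots toward recalcitrant substrates mid-experiment (the
# species-sorting-driven change of direction).
default_trajectory_effects <- function(transfers, substrates) {
  p <- length(substrates)
  mk <- function() matrix(0, length(transfers), p,
                          dimnames = list(transfers, substrates))
  lab <- intersect(LABILE, substrates)
  rec <- intersect(RECALCITRANT, substrates)
  MC <- RP <- DP <- mk()
  for (i in seq_along(transfers)) {
    t <- transfers[i]
    MC[i, intersect(c("xylan", "arabinoxylan"), substrates)] <- 0.022 * t
    RP[i, intersect(c("xylan", "arabinoxylan", "pectin"), substrates)] <-
      0.065 * t
    RP[i, intersect("galactomannan", substrates)] <- 0.02 * t
    DP[i, intersect(c("xylan", "arabinoxylan"), substrates)] <-
      0.05 * min(t, 8)
    DP[i, rec] <- 0.09 * max(t - 8, 0)
    DP[i, intersect("lignin", substrates)] <- 0.06 * max(t - 8, 0)
  }
  list(MC = MC, RP = RP, DP = DP)
}

default_hotspot_weights <- function(treatments, locus_pool_size) {
  if (locus_pool_size == 1) {
    return(matrix(1, length(treatments), 1,
                  dimnames = list(treatments, "tctE")))
  }
  loci <- c("tctE", sprintf("locus_%03d", seq_len(locus_pool_size - 1)))
  w <- matrix(1 / (locus_pool_size - 1), length(treatments),
              locus_pool_size, dimnames = list(treatments, loci))
  # focal hotspot emulating a carbon-metabolism regulator mutated in
  # several DP and MC replicates but rarely in RP
  hot <- c(MC = 0.24, RP = 0.12, DP = 0.36)[treatments]
  hot[is.na(hot)] <- 0.2
  w[, "tctE"] <- hot
  for (i in seq_along(treatments)) {
    w[i, -1] <- (1 - hot[i]) / (locus_pool_size - 1)
  }
  w
}

default_growth_rates <- function() {
  data.frame(
    treatment = rep(c("ancestor", "MC", "RP", "DP"), each = 2),
    condition = rep(c("alone", "with_community"), 4),
    mean = c(4.6, 5.3, 4.6, 5.4, 4.6, 6.5, 4.6, 5.5),
    sd = 0.25,
    stringsAsFactors = FALSE)
}

#' Configuration of the synthetic experiment
#'
#' Bundles every parameter of the synthetic-data generators, defaulting
#' to the design of the compost-community selection experiment the
#' pipeline analyzes: three treatments (monoculture MC with 12
#' replicates, reset polyculture RP and dynamic polyculture DP with 6
#' each), phenotypes assayed at transfers 0 (ancestor), 4, 8, 12 and 16
#' on seven lignocellulose substrates, one sequenced clone per replicate
#' with on average 1.375 mutations (33 mutations over 24 clones, 66.6%
#' non-synonymous) drawn over a locus pool with treatment-specific
#' hotspot weights, a six-species community time series with species
#' sorting and an optional reinvasion scenario, and 6-day growth cycles
#' started from 10^6 CFU/mL.
#'
#' @param n_replicates_per_treatment single integer or per-treatment
#'   named/positional vector (default `c(MC = 12, RP = 6, DP = 6)`).
#' @param treatments treatment labels.
#' @param transfers ordered integer time levels (0 = ancestor).
#' @param substrates substrate labels for the multivariate phenotype.
#' @param baseline per-substrate ancestral respiration level.
#' @param trajectory_effects named list (per treatment) of
#'   `length(transfers) x length(substrates)` matrices of mean phenotype
#'   displacement from baseline at each transfer.
#' @param replicate_sd SD of the additive per-replicate scalar effect.
#' @param residual_sd SD of the per-measurement Gaussian noise.
#' @param mutation_rate_lambda expected mutations per clone (Poisson).
#' @param locus_pool_size number of mutable loci.
#' @param hotspot_weights treatments x loci matrix of sampling weights
#'   (rows normalizable).
#' @param nonsyn_fraction probability a mutation is non-synonymous.
#' @param species community species labels.
#' @param sorting_drift_sd SD of the per-transfer log-abundance random
#'   walk (species sorting).
#' @param reinvasion_scenario if `TRUE`, one designated species crashes
#'   to near-zero mid-series and then recovers in half (rounded up) of
#'   the replicates.
#' @param reinvasion_species species subject to the reinvasion scenario.
#' @param growth_rates data.frame (`treatment`, `condition`, `mean`,
#'   `sd`): mean Malthusian parameter and lognormal noise per cell.
#' @param n_growth_replicates populations per treatment x condition cell.
#' @param start_density initial density (CFU/mL) of growth assays.
#' @param duration growth-cycle length in days.
#' @param seed integer master seed; each generator uses an independent
#'   stream derived from it by a fixed offset.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_replicates_per_treatment = c(MC = 12, RP = 6,
                                                      DP = 6),
                       treatments = c("MC", "RP", "DP"),
                       transfers = c(0, 4, 8, 12, 16),
                       substrates = DEFAULT_SUBSTRATES,
                       baseline = NULL,
                       trajectory_effects = NULL,
                       replicate_sd = 0.10,
                       residual_sd = 0.15,
                       mutation_rate_lambda = 33 / 24,
                       locus_pool_size = 60,
                       hotspot_weights = NULL,
                       nonsyn_fraction = 0.666,
                       species = DEFAULT_SPECIES,
                       sorting_drift_sd = 0.6,
                       reinvasion_scenario = TRUE,
                       reinvasion_species = "Bacillus",
                       growth_rates = default_growth_rates(),
                       n_growth_replicates = 6,
                       start_density = 1e6,
                       duration = 6,
                       seed = 1) {
  if (length(treatments) < 1) stop("empty treatments", call. = FALSE)
  if (length(substrates) < 1) stop("empty substrates", call. = FALSE)
  if (length(transfers) < 1) stop("empty transfers", call. = FALSE)
  if (is.null(names(n_replicates_per_treatment)) &&
      length(n_replicates_per_treatment) == 1) {
    n_replicates_per_treatment <- stats::setNames(
      rep(n_replicates_per_treatment, length(treatments)), treatments)
  }
  if (is.null(names(n_replicates_per_treatment))) {
    names(n_replicates_per_treatment) <- treatments
  }
  if (!all(treatments %in% names(n_replicates_per_treatment))) {
    stop("n_replicates_per_treatment must cover every treatment",
         call. = FALSE)
  }
  n_replicates_per_treatment <-
    n_replicates_per_treatment[treatments]
  if (any(n_replicates_per_treatment < 1)) {
    stop("replicate counts must be positive", call. = FALSE)
  }
  if (is.null(baseline)) {
    baseline <- stats::setNames(
      ifelse(substrates %in% RECALCITRANT, 0.6, 1.2), substrates)
  }
  if (is.null(trajectory_effects)) {
    trajectory_effects <- default_trajectory_effects(transfers, substrates)
    trajectory_effects <- trajectory_effects[
      intersect(names(trajectory_effects), treatments)]
    for (tr in setdiff(treatments, names(trajectory_effects))) {
      trajectory_effects[[tr]] <- matrix(0, length(transfers),
                                         length(substrates),
                                         dimnames = list(transfers,
                                                         substrates))
    }
    trajectory_effects <- trajectory_effects[treatments]
  }
  for (tr in treatments) {
    eff <- trajectory_effects[[tr]]
    if (is.null(eff) || !all(dim(eff) == c(length(transfers),
                                           length(substrates)))) {
      stop("trajectory_effects[['", tr, "']] must be a ",
           length(transfers), " x ", length(substrates), " matrix",
           call. = FALSE)
    }
  }
  if (replicate_sd < 0 || residual_sd < 0 || sorting_drift_sd < 0) {
    stop("sd parameters must be >= 0", call. = FALSE)
  }
  if (mutation_rate_lambda < 0) stop("mutation_rate_lambda must be >= 0",
                                     call. = FALSE)
  if (locus_pool_size < 1) stop("locus_pool_size must be >= 1",
                                call. = FALSE)
  if (nonsyn_fraction < 0 || nonsyn_fraction > 1) {
    stop("nonsyn_fraction must be in [0, 1]", call. = FALSE)
  }
  if (is.null(hotspot_weights)) {
    hotspot_weights <- default_hotspot_weights(treatments, locus_pool_size)
  }
  if (!is.matrix(hotspot_weights) ||
      nrow(hotspot_weights) != length(treatments) ||
      ncol(hotspot_weights) != locus_pool_size) {
    stop("hotspot_weights must be a treatments x locus_pool_size matrix",
         call. = FALSE)
  }
  if (any(hotspot_weights < 0) || any(rowSums(hotspot_weights) <= 0)) {
    stop("hotspot_weights rows must be nonnegative and normalizable",
         call. = FALSE)
  }
  need <- expand.grid(treatment = unique(growth_rates$treatment),
                      condition = unique(growth_rates$condition))
  have <- paste(growth_rates$treatment, growth_rates$condition)
  if (!all(paste(need$treatment, need$condition) %in% have)) {
    stop("growth_rates must specify every treatment x condition cell",
         call. = FALSE)
  }
  if (start_density <= 0) stop("start_density must be positive",
                               call. = FALSE)
  structure(list(
    n_replicates_per_treatment = n_replicates_per_treatment,
    treatments = treatments, transfers = transfers,
    substrates = substrates, baseline = baseline,
    trajectory_effects = trajectory_effects,
    replicate_sd = replicate_sd, residual_sd = residual_sd,
    mutation_rate_lambda = mutation_rate_lambda,
    locus_pool_size = locus_pool_size,
    hotspot_weights = hotspot_weights,
    nonsyn_fraction = nonsyn_fraction,
    species = species, sorting_drift_sd = sorting_drift_sd,
    reinvasion_scenario = reinvasion_scenario,
    reinvasion_species = reinvasion_species,
    growth_rates = growth_rates,
    n_growth_replicates = n_growth_replicates,
    start_density = start_density, duration = duration,
    seed = as.integer(seed)), class = "sim_config")
}

# Fixed per-generator seed offsets: adding one generator to a pipeline
# never perturbs another generator's draws.
SEED_OFFSETS <- c(phenotypes = 101L, mutations = 211L, community = 307L,
                  growth = 401L)

#' Simulate the multivariate substrate-use phenotype table
#'
#' One respiration record per replicate x treatment x transfer x
#' substrate: `value = baseline + treatment displacement at the transfer
#' + replicate effect + residual noise`, truncated at zero (respiration
#' is nonnegative). The replicate effect is a single additive scalar per
#' replicate, shared across substrates and transfers.
#'
#' @param config a [sim_config()].
#' @return tidy data.frame (`replicate_id`, `treatment`, `transfer`,
#'   `substrate`, `value`).
#' @export
simulate_phenotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + SEED_OFFSETS[["phenotypes"]], {
    rows <- list()
    for (tr in config$treatments) {
      nrep <- config$n_replicates_per_treatment[[tr]]
      rep_eff <- stats::rnorm(nrep, 0, config$replicate_sd)
      for (r in seq_len(nrep)) {
        rid <- sprintf("%s_%02d", tr, r)
        for (ti in seq_along(config$transfers)) {
          mu <- config$baseline +
            config$trajectory_effects[[tr]][ti, ] + rep_eff[r]
          val <- pmax(0, mu + stats::rnorm(length(config$substrates), 0,
                                           config$residual_sd))
          rows[[length(rows) + 1L]] <- data.frame(
            replicate_id = rid, treatment = tr,
            transfer = config$transfers[ti],
            substrate = config$substrates,
            value = unname(val), stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate clone mutation profiles
#'
#' One sequenced clone per replicate. Each clone acquires
#' `Poisson(mutation_rate_lambda)` mutations at loci sampled without
#' replacement from the locus pool with its treatment's hotspot weights;
#' each mutation is non-synonymous with probability `nonsyn_fraction`,
#' otherwise synonymous, indel or intergenic with equal probability.
#'
#' @param config a [sim_config()].
#' @return a [mutation_profiles()] object.
#' @export
simulate_mutations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  loci <- colnames(config$hotspot_weights)
  if (is.null(loci)) loci <- sprintf("locus_%03d",
                                     seq_len(config$locus_pool_size))
  with_seed(config$seed + SEED_OFFSETS[["mutations"]], {
    clones <- list(); muts <- list()
    for (tr in config$treatments) {
      w <- config$hotspot_weights[match(tr, config$treatments), ]
      nrep <- config$n_replicates_per_treatment[[tr]]
      for (r in seq_len(nrep)) {
        cid <- sprintf("%s_%02d", tr, r)
        clones[[length(clones) + 1L]] <- data.frame(
          clone_id = cid, treatment = tr, stringsAsFactors = FALSE)
        k <- min(stats::rpois(1, config$mutation_rate_lambda),
                 config$locus_pool_size)
        if (k > 0) {
          hit <- sample(loci, k, replace = FALSE, prob = w)
          cls <- ifelse(
            stats::runif(k) < config$nonsyn_fraction, "nonsynonymous",
            sample(c("synonymous", "indel", "intergenic"), k,
                   replace = TRUE))
          muts[[length(muts) + 1L]] <- data.frame(
            clone_id = cid, treatment = tr, locus_tag = hit,
            mutation_class = cls, stringsAsFactors = FALSE)
        }
      }
    }
    mutation_profiles(
      do.call(rbind, clones),
      if (length(muts)) do.call(rbind, muts) else
        data.frame(clone_id = character(), locus_tag = character(),
                   mutation_class = character(), stringsAsFactors = FALSE))
  })
}

#' Simulate the community relative-abundance time series
#'
#' Species sorting as a phenomenological log-abundance random walk: per
#' replicate, each species' log-abundance drifts with SD
#' `sorting_drift_sd` per transfer and compositions are
#' softmax-normalized, so every (replicate, transfer) row sums to 1.
#' Under the reinvasion scenario the designated species is forced to
#' near-zero relative abundance over the middle transfers and recovers by
#' the final transfer in the first `ceiling(n/2)` replicates.
#'
#' @param config a [sim_config()]; replicates are those of the dynamic
#'   polyculture (`DP`) treatment when present, otherwise of the first
#'   treatment.
#' @return data.frame (`replicate_id`, `transfer`, `species`,
#'   `rel_abundance`).
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sp <- config$species
  if (length(sp) < 2) stop("need >= 2 species", call. = FALSE)
  tr <- if ("DP" %in% config$treatments) "DP" else config$treatments[1]
  nrep <- config$n_replicates_per_treatment[[tr]]
  transfers <- config$transfers
  k <- length(transfers)
  reinvaders <- if (config$reinvasion_scenario) {
    seq_len(ceiling(nrep / 2))
  } else integer(0)
  mid <- if (k > 2) seq(2, k - 1) else integer(0)
  with_seed(config$seed + SEED_OFFSETS[["community"]], {
    rows <- list()
    for (r in seq_len(nrep)) {
      x <- rep(0, length(sp))                 # equal initial composition
      for (ti in seq_len(k)) {
        if (ti > 1) x <- x + stats::rnorm(length(sp), 0,
                                          config$sorting_drift_sd)
        rel <- exp(x - max(x)); rel <- rel / sum(rel)
        if (r %in% reinvaders && ti %in% mid &&
            config$reinvasion_species %in% sp) {
          i <- match(config$reinvasion_species, sp)
          rel[i] <- 1e-4
          rel <- rel / sum(rel)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          replicate_id = sprintf("%s_%02d", tr, r),
          transfer = transfers[ti], species = sp,
          rel_abundance = rel, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate growth-assay density records
#'
#' Exponential growth over one cycle: every population starts at
#' `start_density` and ends at `start_density * exp(m + noise)` where `m`
#' is the configured mean Malthusian parameter of its treatment x
#' condition cell and the noise is `Normal(0, sd)` on the log scale, so
#' [malthusian()] recovers `m` in expectation (exactly when `sd = 0`).
#'
#' @param config a [sim_config()].
#' @return data.frame (`population_id`, `treatment`, `condition`, `n0`,
#'   `nf`, `duration`).
#' @export
simulate_growth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gr <- config$growth_rates
  with_seed(config$seed + SEED_OFFSETS[["growth"]], {
    rows <- list()
    for (i in seq_len(nrow(gr))) {
      for (r in seq_len(config$n_growth_replicates)) {
        m <- gr$mean[i] + stats::rnorm(1, 0, gr$sd[i])
        rows[[length(rows) + 1L]] <- data.frame(
          population_id = sprintf("%s_%s_%02d", gr$treatment[i],
                                  gr$condition[i], r),
          treatment = gr$treatment[i], condition = gr$condition[i],
          n0 = config$start_density,
          nf = config$start_density * exp(m),
          duration = config$duration, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
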