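perm_test_summary <- function(x) {
  out <- list(statistic = x$statistic_name, observed = x$observed,
              Z = x$Z, p = x$p, n_permutations = x$n_permutations,
              seed = x$seed)
  if (!is.null(x$df)) out$df <- as.numeric(x$df)
  out
}

#' Pipeline configuration
#'
#' Input tables (in-memory data.frames or file paths), permutation
#' counts, seed and analysis flags for [run_full_pipeline()]. A seed is
#' mandatory: no stage is allowed to be silently nondeterministic.
#'
#' @param phenotypes phenotype table or CSV path (optional).
#' @param mutations [mutation_profiles()] object or TSV path (optional).
#' @param abundance abundance table or TSV path (optional).
#' @param growth growth table or CSV path (optional).
#' @param n_permutations_trajectory permutations for the trajectory tests.
#' @param n_permutations_parallelism permutations for the parallelism
#'   tests.
#' @param seed integer seed applied to every permutation procedure.
#' @param scale scale substrates to unit variance in the trajectory
#'   analysis.
#' @param per_day report per-day Malthusian rates.
#' @param classes mutation-class filter for the Jaccard analysis.
#' @param scheme permutation scheme for the parallelism tests.
#' @param empty_union Jaccard convention for two mutation-free clones.
#' @param abundance_species,abundance_substrate species and substrate for
#'   the endpoint abundance-phenotype regression.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(phenotypes = NULL, mutations = NULL,
                            abundance = NULL, growth = NULL,
                            n_permutations_trajectory = 999,
                            n_permutations_parallelism = 10000,
                            seed,
                            scale = FALSE, per_day = FALSE,
                            classes = "nonsynonymous",
                            scheme = "clone_labels",
                            empty_union = "one",
                            abundance_species = "Bacillus",
                            abundance_substrate = "cellulose") {
  if (missing(seed)) stop("a seed is mandatory for any permutation or ",
                          "simulation run", call. = FALSE)
  structure(list(phenotypes = phenotypes, mutations = mutations,
                 abundance = abundance, growth = growth,
                 n_permutations_trajectory = n_permutations_trajectory,
                 n_permutations_parallelism = n_permutations_parallelism,
                 seed = as.integer(seed), scale = scale,
                 per_day = per_day, classes = classes, scheme = scheme,
                 empty_union = empty_union,
                 abundance_species = abundance_species,
                 abundance_substrate = abundance_substrate),
            class = "pipeline_config")
}

resolve_input <- function(x, reader, stage) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) {
      stop("stage '", stage, "': input file not found: ", x,
           call. = FALSE)
    }
    return(reader(x))
  }
  x
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage for which an input is configured — phenotypic
#' trajectory analysis, mutational parallelism, community-phenotype
#' covariance, growth statistics — and returns a single report carrying
#' every statistic together with the seed and permutation count that
#' produced it. Identical configuration and seed give an identical
#' report.
#'
#' @param config a [pipeline_config()].
#' @return nested list of class `pipeline_report`.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(settings = list(
    seed = config$seed,
    n_permutations_trajectory = config$n_permutations_trajectory,
    n_permutations_parallelism = config$n_permutations_parallelism,
    scale = config$scale, per_day = config$per_day,
    classes = config$classes, scheme = config$scheme,
    empty_union = config$empty_union,
    package_version = as.character(utils::packageVersion("ecoevo"))))

  phen <- run_stage("phenotypes",
                    resolve_input(config$phenotypes, read_phenotypes,
                                  "phenotypes"))
  if (!is.null(phen)) {
    report$trajectory <- run_stage("trajectory", {
      fit <- fit_factorial_model(phen, scale = config$scale)
      traj <- build_trajectories(fit)
      ord <- pca_of_fitted(fit)
      inter <- rrpp_interaction_test(
        phen, config$n_permutations_trajectory, seed = config$seed,
        scale = config$scale)
      pw <- lapply(c(distance = "distance", angle = "angle",
                     shape = "shape"), function(at) {
        lapply(pairwise_trajectory_tests(
          phen, attribute = at,
          n_permutations = config$n_permutations_trajectory,
          seed = config$seed, scale = config$scale), perm_test_summary)
      })
      list(interaction = perm_test_summary(inter),
           path_length = as.list(traj$path_length),
           pairwise = pw,
           pca_proportions = as.numeric(ord$proportions))
    })
  }

  prof <- run_stage("parallelism",
                    resolve_input(config$mutations, read_mutations,
                                  "parallelism"))
  if (!is.null(prof)) {
    report$parallelism <- run_stage("parallelism", {
      J <- similarity_matrix(prof, classes = config$classes,
                             empty_union = config$empty_union)
      trts <- prof$clones$treatment
      pa <- parallelism_perm_anova(
        J, trts, n_permutations = config$n_permutations_parallelism,
        seed = config$seed, scheme = config$scheme)
      ct <- pairwise_treatment_contrasts(
        J, trts, n_permutations = config$n_permutations_parallelism,
        seed = config$seed, scheme = config$scheme)
      counts_all <- mutation_count_anova(prof, "all")
      counts_ns <- mutation_count_anova(prof, "nonsynonymous")
      list(perm_anova = perm_test_summary(pa),
           contrasts = lapply(ct, perm_test_summary),
           mutation_counts = list(
             all = counts_all[c("F", "df1", "df2", "p")],
             nonsynonymous = counts_ns[c("F", "df1", "df2", "p")]))
    })
  }

  abun <- run_stage("community",
                    resolve_input(config$abundance, read_abundance,
                                  "community"))
  if (!is.null(abun)) {
    report$community <- run_stage("community", {
      transfers <- sort(unique(abun$transfer))
      transfers <- transfers[transfers > 0]
      comm_d <- dissimilarity_over_time(abun, transfers)
      out <- list(mean_dissimilarity_by_transfer = tapply(
        comm_d$dissimilarity, comm_d$transfer, mean))
      if (!is.null(phen)) {
        dp <- phen[phen$replicate_id %in% abun$replicate_id, ]
        phen_d <- dissimilarity_over_time(dp, transfers)
        cov_reg <- covariance_regression(phen_d, comm_d)
        out$covariance <- cov_reg[c("R_squared", "F", "df", "p")]
        final_t <- max(abun$transfer)
        sp <- abun[abun$species == config$abundance_species &
                     abun$transfer == final_t, ]
        ph <- dp[dp$substrate == config$abundance_substrate &
                   dp$transfer == final_t, ]
        m <- match(sp$replicate_id, ph$replicate_id)
        if (nrow(sp) >= 3 && !anyNA(m)) {
          ar <- abundance_phenotype_regression(sp$rel_abundance,
                                               ph$value[m])
          out$abundance_phenotype <- ar[c("R_squared", "F", "df", "p")]
        }
      }
      out
    })
  }

  grow <- run_stage("growth",
                    resolve_input(config$growth, read_growth, "growth"))
  if (!is.null(grow)) {
    report$growth <- run_stage("growth", {
      ga <- growth_interaction_anova(grow, per_day = config$per_day)
      comp <- grow[grow$condition == "with_community", ]
      out <- list(interaction = list(F = ga$F, df = as.numeric(ga$df),
                                     p = ga$p))
      if (nrow(comp) && length(unique(comp$treatment)) >= 2) {
        rates <- growth_rates(comp, per_day = config$per_day)
        ca <- competition_oneway_anova(rates$rate, rates$treatment)
        out$competition <- list(F = ca$F, df = as.numeric(ca$df),
                                p = ca$p, tukey = ca$tukey)
      }
      out
    })
  }
  structure(report, class = "pipeline_report")
}

#' Write a pipeline report as JSON
#'
#' @param report a `pipeline_report` from [run_full_pipeline()].
#' @param path output JSON path.
#' @export
write_report <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
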