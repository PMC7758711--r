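#!/usr/bin/env Rscript
# Phenotypic trajectory analysis of substrate-use evolution: does the path
# the multivariate phenotype takes through substrate space differ between
# community treatments? Tests the treatment x time interaction by residual
# randomization (RRPP), then compares path length, direction and shape
# pairwise between treatments, and ordinates the fitted values by PCA.

library(ecoevo)

seed <- 20201221L
phen <- read_phenotypes("results/data/phenotypes.csv")
dir.create("results", showWarnings = FALSE)

fit <- suppressWarnings(fit_factorial_model(phen))
traj <- build_trajectories(fit)
print(traj)

inter <- suppressWarnings(
  rrpp_interaction_test(phen, n_permutations = 999, seed = seed))
cat("\nTreatment x time interaction (RRPP permutational MANOVA):\n")
print(inter)

rows <- list()
for (at in c("distance", "angle", "shape")) {
  pw <- suppressWarnings(pairwise_trajectory_tests(
    phen, attribute = at, n_permutations = 999, seed = seed))
  cat("\nPairwise", at, "tests:\n")
  for (pr in names(pw)) {
    cat(sprintf("  %-6s observed = %7.4f  Z = %6.2f  p = %.3f\n",
                pr, pw[[pr]]$observed, pw[[pr]]$Z, pw[[pr]]$p))
    rows[[length(rows) + 1L]] <- data.frame(
      attribute = at, pair = pr, observed = pw[[pr]]$observed,
      Z = pw[[pr]]$Z, p = pw[[pr]]$p,
      n_permutations = pw[[pr]]$n_permutations, seed = seed)
  }
}
write.table(do.call(rbind, rows), "results/trajectory_tests.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

ord <- pca_of_fitted(fit)
cat("\n")
print(ord)
scores <- data.frame(fit$meta, ord$scores[, 1:3])
write.csv(scores, "results/ordination_scores.csv", row.names = FALSE)
cat("wrote results/trajectory_tests.tsv and results/ordination_scores.csv\n")
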