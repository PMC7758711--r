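#!/usr/bin/env Rscript
# Genomic parallelism: do clones from the same (or particular pairs of)
# treatments share mutated loci more than expected? Builds the Jaccard
# similarity matrix over non-synonymous mutation profiles, tests the
# effect of treatment comparison by permutational ANOVA, contrasts
# treatment pairs, and compares per-clone mutation counts with Welch's
# ANOVA.

library(ecoevo)

seed <- 20201221L
prof <- read_mutations("results/data/mutations.tsv")
dir.create("results", showWarnings = FALSE)
print(prof)

J <- similarity_matrix(prof, classes = "nonsynonymous")
write.table(data.frame(clone_id = rownames(J), J, check.names = FALSE),
            "results/jaccard_matrix.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

pa <- parallelism_perm_anova(J, prof$clones$treatment,
                             n_permutations = 10000, seed = seed)
cat("\nPermutational ANOVA of treatment comparison on Jaccard similarity:\n")
print(pa)

ct <- pairwise_treatment_contrasts(J, prof$clones$treatment,
                                   n_permutations = 10000, seed = seed)
cat("\nPairwise contrasts (between- vs within-treatment similarity):\n")
for (pr in names(ct)) {
  cat(sprintf("  %-6s t = %6.3f  p = %.3f\n", pr, ct[[pr]]$observed,
              ct[[pr]]$p))
}

cat("\nPer-clone mutation counts (Welch's ANOVA):\n")
for (cl in list("all", "nonsynonymous")) {
  mc <- mutation_count_anova(prof, cl)
  cat(sprintf("  %-14s F(%d, %.2f) = %.4f, p = %.4f\n",
              paste(cl, collapse = "+"), mc$df1, mc$df2, mc$F, mc$p))
}

res <- data.frame(
  test = c("perm_anova", paste0("contrast_", names(ct))),
  statistic = c(pa$observed, vapply(ct, `[[`, numeric(1), "observed")),
  Z = c(pa$Z, vapply(ct, `[[`, numeric(1), "Z")),
  p = c(pa$p, vapply(ct, `[[`, numeric(1), "p")),
  n_permutations = 10000, seed = seed)
write.table(res, "results/parallelism_tests.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nwrote results/jaccard_matrix.tsv and results/parallelism_tests.tsv\n")
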