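#!/usr/bin/env Rscript
# Generate the synthetic experiment at the study conditions: 12 monoculture
# (MC), 6 reset-polyculture (RP) and 6 dynamic-polyculture (DP) replicate
# populations, phenotyped on seven lignocellulose substrates at transfers
# 0-16, one sequenced clone per population, a six-species DP community
# series with a Bacillus reinvasion in half the replicates, and 6-day
# growth assays. Writes the four input tables that the downstream analysis
# scripts consume.

library(ecoevo)

seed <- 20201221L
out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)

phen <- simulate_phenotypes(cfg)
write_phenotypes(phen, file.path(out_dir, "phenotypes.csv"))

prof <- simulate_mutations(cfg)
write_mutations(prof, file.path(out_dir, "mutations.tsv"))

abund <- simulate_community(cfg)
write_abundance(abund, file.path(out_dir, "abundance.tsv"))

growth <- simulate_growth(cfg)
write_growth(growth, file.path(out_dir, "growth.csv"))

cat("Simulated experiment (seed ", seed, "):\n", sep = "")
cat("  phenotype records: ", nrow(phen), " (",
    length(unique(phen$replicate_id)), " populations x ",
    length(cfg$transfers), " transfers x ", length(cfg$substrates),
    " substrates)\n", sep = "")
cat("  sequenced clones:  ", nrow(prof$clones), ", carrying ",
    nrow(prof$mutations), " mutations (",
    round(100 * mean(prof$mutations$mutation_class == "nonsynonymous"), 1),
    "% non-synonymous)\n", sep = "")
cat("  community records: ", nrow(abund), "\n", sep = "")
cat("  growth records:    ", nrow(growth), "\n", sep = "")
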