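#!/usr/bin/env Rscript
# Community-phenotype covariance: does divergence of the focal species'
# evolved metabolism between replicate communities track divergence of
# community composition, increasingly over time? Bray-Curtis dissimilarity
# of both profiles per replicate pair and transfer, the dissimilarity x
# time interaction regression, and the endpoint regression of cellulose
# respiration on final Bacillus relative abundance.

library(ecoevo)

abund <- read_abundance("results/data/abundance.tsv")
phen <- read_phenotypes("results/data/phenotypes.csv")
dir.create("results", showWarnings = FALSE)

transfers <- sort(unique(abund$transfer))
transfers <- transfers[transfers > 0]
comm_d <- dissimilarity_over_time(abund, transfers)
dp_phen <- phen[phen$replicate_id %in% abund$replicate_id, ]
phen_d <- dissimilarity_over_time(dp_phen, transfers)

both <- merge(comm_d, phen_d, by = c("rep_a", "rep_b", "transfer"),
              suffixes = c("_community", "_phenotype"))
write.table(both, "results/dissimilarity.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("Mean Bray-Curtis dissimilarity between replicate communities:\n")
print(round(tapply(comm_d$dissimilarity, comm_d$transfer, mean), 3))

cov_reg <- covariance_regression(phen_d, comm_d)
cat("\nPhenotype divergence ~ community divergence x time:\n")
print(cov_reg)

final_t <- max(abund$transfer)
bac <- abund[abund$species == "Bacillus" & abund$transfer == final_t, ]
cel <- dp_phen[dp_phen$substrate == "cellulose" &
                 dp_phen$transfer == final_t, ]
cel <- cel[match(bac$replicate_id, cel$replicate_id), ]
ar <- abundance_phenotype_regression(bac$rel_abundance, cel$value)
cat("\nEndpoint cellulose respiration ~ final Bacillus abundance:\n")
print(ar)
cat("\nwrote results/dissimilarity.tsv\n")
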