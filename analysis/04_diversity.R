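#!/usr/bin/env Rscript
# Stage 4: synapse-diversity maps.
#
# Shannon diversity (nats) of each animal x subregion subtype composition,
# contrasted between genotypes per (age, subregion) with the Bayesian
# effect-size test and BH correction over subregions within each age.

suppressPackageStartupMessages(library(synwaves))

cohort <- read_cohort("scratch/cohort")
dir.create("results", showWarnings = FALSE)

dmap <- compare_diversity(cohort, n_draws = 4000L, seed = 401L)
write.table(dmap, "scratch/diversity_map.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

summary_by_age <- do.call(rbind, lapply(split(dmap, dmap$age), function(b) {
  data.frame(age = b$age[1],
             mean_h_control = mean(b$h_control),
             mean_h_mutant = mean(b$h_mutant),
             n_reduced = sum(b$significant & b$d < 0),
             n_increased = sum(b$significant & b$d > 0))
}))
summary_by_age <- summary_by_age[order(summary_by_age$age), ]
write.table(format(summary_by_age, digits = 4),
            "results/04_diversity_by_age.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("Subregions with significantly changed synapse diversity (of 131):\n")
print(summary_by_age, row.names = FALSE, digits = 3)
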