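#!/usr/bin/env Rscript
# Stage 5: similarity matrices, similarity ratio and small-world networks.
#
# Per-animal subregion similarity matrices (Pearson correlation of pooled-
# standardized subtype densities), the between/within main-region similarity
# ratio, and small-worldness of the top-k similarity graphs with degree-
# preserving rewired references; genotype contrasts per age with BH over
# ages.

suppressPackageStartupMessages(library(synwaves))

cohort <- read_cohort("scratch/cohort")
dir.create("results", showWarnings = FALSE)

sim <- cohort_similarity(cohort, k = 12L, n_random = 20L, seed = 501L)
write.table(sim$per_animal, "results/05_network_per_animal.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

sr <- compare_network_statistic(sim$per_animal, "s_ratio", seed = 502L)
sw <- compare_network_statistic(sim$per_animal, "sigma", seed = 503L)
write.table(format(sr, digits = 4), "results/05_s_ratio_contrast.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(format(sw, digits = 4), "results/05_small_worldness_contrast.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

# one group-average similarity matrix as an exemplar (scratch: large)
write.table(round(sim$group_matrices[["control.14"]], 4),
            "scratch/similarity_control_P14.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("Similarity-ratio contrast (mutant - control, Cohen's d by age):\n")
print(sr, row.names = FALSE, digits = 3)
cat("Small-worldness contrast (mutant - control, Cohen's d by age):\n")
print(sw, row.names = FALSE, digits = 3)
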