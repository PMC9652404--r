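#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Two genotypes (control, mutant) x 9 postnatal ages (P1, P7 ... P56),
# 8 animals per group per age, 131 atlas subregions in 12 main regions,
# 37 synapse subtypes. The mutant carries two "phenotype waves" -- transient
# homogenization of regional subtype composition (effect size d = 2 in
# between-animal SD units) at P7-P21 and P35-P42 -- while total synapse
# density is preserved everywhere. Ground truth is recorded per
# (age, subregion, subtype). A second cohort with the phenotype confined to
# the short-protein-lifetime (SPL) subtypes is built in stage 3 for the
# subtype-ranking and SPL-vs-LPL analyses.

suppressPackageStartupMessages(library(synwaves))

seed <- 101L
cfg <- cohort_config(seed = seed, wave_windows = list(
  wave_window(7, 21, subregions = 1:131, d = 2, mode = "homogenize"),
  wave_window(35, 42, subregions = 1:131, d = 2, mode = "homogenize")))
cohort <- generate_cohort(cfg)

dir.create("scratch", showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)
write_cohort(cohort, "scratch/cohort")

# small summary of the designed truth for downstream stages and the reader
truth_by_age <- aggregate(d_true ~ age, cohort$truth,
                          function(x) round(mean(abs(x)), 3))
names(truth_by_age)[2] <- "mean_abs_d_true"
truth_by_age$n_cells <- as.vector(table(factor(cohort$truth$age,
                                               levels = truth_by_age$age)))
write.table(truth_by_age, "results/01_truth_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

# designed null on total synapse number: per-animal whole-brain totals
totals <- sapply(c("control", "mutant"), function(g) {
  arr <- cohort$densities[[g]]
  mean(apply(arr, c(1, 4), sum))
})
cat("Cohort written to scratch/cohort (",
    length(cfg$ages), "ages x", cfg$n_control + cfg$n_mutant, "animals x",
    cfg$n_subregions, "subregions x", cfg$n_subtypes, "subtypes )\n")
cat(sprintf("Mean whole-brain total density: control %.3f, mutant %.3f\n",
            totals["control"], totals["mutant"]))
cat("Truth cells per age:\n")
print(truth_by_age, row.names = FALSE)
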