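#!/usr/bin/env Rscript
# Stage 3: Bayesian effect-size maps and phenotype-wave detection.
#
# Computes the type-level mutant-vs-control Cohen's d map (posterior mode,
# two-sided posterior significance, BH over subregions within each age x
# parameter family), the fraction of affected subregions per age, the
# detected waves, a subtype-level map for ranking, and the SPL-vs-LPL
# contrast at the first wave's peak age.

suppressPackageStartupMessages(library(synwaves))

cohort <- read_cohort("scratch/cohort")
scheme <- read_subtype_scheme()
dir.create("results", showWarnings = FALSE)

map_type <- effectsize_map(cohort, level = "type", n_draws = 4000L,
                           seed = 301L)
write.table(map_type, "scratch/effectsize_map_type.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

frac <- fraction_affected(map_type)
waves <- detect_waves(frac$fraction, frac$age, threshold = 0.25)
write.table(frac, "results/03_fraction_affected.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(waves, "results/03_waves.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("Fraction of subregions with a significant type-density phenotype:\n")
print(frac, row.names = FALSE, digits = 3)
cat("Detected phenotype waves:\n")
print(waves, row.names = FALSE)

# A second cohort carries the phenotype only on the SPL subtypes (density
# shifted by d = 2 toward SPL in the same windows, the mass drawn
# proportionally from all non-SPL subtypes so no subregion's donors are
# exhausted): the substrate for the subtype ranking and the SPL-vs-LPL map.
scheme_spl <- scheme$spl
donors <- setdiff(1:37, scheme_spl)
cfg_spl <- cohort_config(seed = 102L, wave_windows = list(
  wave_window(7, 21, subregions = 1:131, subtypes = scheme_spl, d = 2,
              mode = "shift", donors = donors),
  wave_window(35, 42, subregions = 1:131, subtypes = scheme_spl, d = 2,
              mode = "shift", donors = donors)))
cohort_spl <- generate_cohort(cfg_spl)

map_sub <- effectsize_map(cohort_spl, level = "subtype", n_draws = 2000L,
                          seed = 302L)
write.table(map_sub, "scratch/effectsize_map_subtype.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
ranking <- rank_subtypes(map_sub, scheme, psd95_only = TRUE)
write.table(ranking, "results/03_subtype_ranking.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("Top affected PSD95-expressing subtypes (significant subregions, all ages):\n")
print(head(ranking, 8), row.names = FALSE)
cat(sprintf("SPL subtypes in the top 6 of the ranking: %d of 6\n",
            sum(head(ranking$subtype, 6) %in% scheme_spl)))

# SPL vs LPL contrast at the first wave peak (P14)
ai <- which(cohort_spl$config$ages == 14L)
pdfs_for <- function(subtypes) {
  lapply(seq_len(cohort_spl$config$n_subregions), function(r) {
    lapply(subtypes, function(s) {
      bayes_effectsize(cohort_spl$densities$mutant[, r, s, ai],
                       cohort_spl$densities$control[, r, s, ai],
                       n_draws = 2000L,
                       seed = child_seed(303L, paste(r, s)))
    })
  })
}
spl_lpl <- compare_spl_lpl(pdfs_for(scheme$spl), pdfs_for(scheme$lpl),
                           ages = rep(14L, cohort_spl$config$n_subregions),
                           seed = 304L)
write.table(spl_lpl, "scratch/03_spl_lpl_P14.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("P14 SPL-LPL contrast: %d/131 subregions SPL-dominant (d > 0, adj. P < 0.05), %d/131 LPL-dominant\n",
            sum(spl_lpl$d_spl_lpl > 0 & spl_lpl$p_adj < 0.05),
            sum(spl_lpl$d_spl_lpl < 0 & spl_lpl$p_adj < 0.05)))
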