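#' Write a synthetic cohort to a directory
#'
#' Writes the tidy density table (`cohort.tsv`, one row per animal x
#' subregion x subtype), the ground-truth sidecar (`truth.json`), the region
#' hierarchy (`hierarchy.tsv`) and the generating configuration
#' (`config.yaml`).
#'
#' @param cohort a `syn_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "syn_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort_table(cohort), file.path(dir, "cohort.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       digits = NA)
  utils::write.table(cohort$hierarchy, file.path(dir, "hierarchy.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- cohort$config
  yaml::write_yaml(list(
    n_subregions = cfg$n_subregions, ages = cfg$ages,
    n_control = cfg$n_control, n_mutant = cfg$n_mutant,
    n_subtypes = cfg$n_subtypes, noise_cv = cfg$noise_cv, seed = cfg$seed,
    wave_windows = lapply(cfg$wave_windows, unclass)),
    file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a cohort density table back into array form
#'
#' Rebuilds the `densities` arrays of a `syn_cohort` from a directory written
#' by [write_cohort()] (the configuration's composition matrices are not
#' round-tripped; statistics modules only need densities, hierarchy and
#' truth).
#'
#' @param dir directory written by [write_cohort()].
#' @return A list of class `syn_cohort` with `densities`, `truth`,
#'   `hierarchy` and a minimal `config` (`ages`, group sizes, counts).
#' @export
read_cohort <- function(dir) {
  tab <- utils::read.delim(file.path(dir, "cohort.tsv"))
  hier <- utils::read.delim(file.path(dir, "hierarchy.tsv"))
  truth <- as.data.frame(jsonlite::read_json(file.path(dir, "truth.json"),
                                             simplifyVector = TRUE))
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  ages <- sort(unique(tab$age))
  R <- max(tab$subregion); S <- max(tab$subtype)
  dens <- list()
  for (g in c("control", "mutant")) {
    sub <- tab[tab$genotype == g, ]
    animals <- sort(unique(sub$animal))
    arr <- array(NA_real_, dim = c(length(animals), R, S, length(ages)),
                 dimnames = list(NULL, NULL, NULL, as.character(ages)))
    ai <- match(sub$animal, animals)
    gi <- match(sub$age, ages)
    arr[cbind(ai, sub$subregion, sub$subtype, gi)] <- sub$density
    dens[[g]] <- arr
  }
  structure(list(densities = dens, truth = truth,
                 config = list(ages = as.integer(ages),
                               n_subregions = R, n_subtypes = S,
                               n_control = dim(dens$control)[1],
                               n_mutant = dim(dens$mutant)[1],
                               noise_cv = cfg$noise_cv, seed = cfg$seed,
                               wave_windows = cfg$wave_windows),
                 hierarchy = hier),
            class = "syn_cohort")
}
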