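#' Run the full analysis pipeline
#'
#' Orchestrates the stages end-to-end on a synthetic cohort: cohort
#' generation, type-level effect-size mapping with wave detection, diversity
#' comparison, similarity/network statistics, and the grid-based synaptic
#' response simulation with genotype comparison. Stage outputs are written as
#' tidy delimited tables under `out_dir`, and a JSON manifest records the
#' seed, package version, stage parameters and MD5 digests of every output
#' so a run is reproducible from the manifest alone.
#'
#' @param config list with elements `cohort` (a [cohort_config()]), optional
#'   `stages` (subset of `"cohort"`, `"effectsize"`, `"diversity"`,
#'   `"network"`, `"ephys"`), optional `n_draws`, `alpha`,
#'   `wave_threshold`, `patterns`, `genotype_effect`.
#' @param out_dir output directory.
#' @param seed master seed for every stage's randomness.
#' @return The manifest (list), invisibly; written to `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  stages_all <- c("cohort", "effectsize", "diversity", "network", "ephys")
  stages <- config$stages %||% stages_all
  if (!all(stages %in% stages_all)) {
    stop("unknown stage: ", paste(setdiff(stages, stages_all), collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_draws <- config$n_draws %||% 4000L
  alpha <- config$alpha %||% 0.05
  outputs <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    outputs[[name]] <<- path
    path
  }

  cohort <- NULL
  if ("cohort" %in% stages) {
    cfg <- config$cohort
    stopifnot(inherits(cfg, "cohort_config"))
    cfg$seed <- as.integer(seed)
    cohort <- generate_cohort(cfg)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    for (f in c("cohort.tsv", "truth.json", "hierarchy.tsv", "config.yaml")) {
      outputs[[file.path("cohort", f)]] <- file.path(out_dir, "cohort", f)
    }
  }
  if (any(c("effectsize", "diversity", "network") %in% stages) &&
      is.null(cohort)) {
    cohort <- read_cohort(file.path(out_dir, "cohort"))
  }
  if ("effectsize" %in% stages) {
    map <- effectsize_map(cohort, level = "type", n_draws = n_draws,
                          seed = child_seed(seed, "effectsize"), alpha = alpha)
    emit(map, "effectsize_map.tsv")
    frac <- fraction_affected(map)
    emit(frac, "fraction_affected.tsv")
    waves <- detect_waves(frac$fraction, frac$age,
                          threshold = config$wave_threshold %||% 0.25)
    emit(waves, "waves.tsv")
  }
  if ("diversity" %in% stages) {
    emit(compare_diversity(cohort, n_draws = n_draws,
                           seed = child_seed(seed, "diversity"),
                           alpha = alpha),
         "diversity_map.tsv")
  }
  if ("network" %in% stages) {
    sim <- cohort_similarity(cohort, seed = child_seed(seed, "network"))
    emit(sim$per_animal, "network_per_animal.tsv")
    emit(compare_network_statistic(sim$per_animal, "s_ratio",
                                   seed = child_seed(seed, "network-sr")),
         "s_ratio_contrast.tsv")
    emit(compare_network_statistic(sim$per_animal, "sigma",
                                   seed = child_seed(seed, "network-sw")),
         "small_worldness_contrast.tsv")
  }
  if ("ephys" %in% stages) {
    grids <- generate_intensity_grids(
      genotype_effect = config$genotype_effect %||% c("7" = -0.25, "35" = -0.25),
      seed = child_seed(seed, "ephys"))
    prof <- normalize_grids(grids)
    patterns <- config$patterns %||%
      c("theta_burst", "theta_train", "gamma_burst", "gamma_train")
    params <- config$synapse_params %||% synapse_params()
    comps <- list()
    for (a in unique(prof$age)) {
      gc_ <- build_synapse_grid(prof[prof$genotype == "control" &
                                       prof$age == a, ])
      gm_ <- build_synapse_grid(prof[prof$genotype == "mutant" &
                                       prof$age == a, ])
      for (pn in patterns) {
        pat <- make_pattern(pn)
        cmp <- compare_genotypes(simulate_grid(params, gc_, pat),
                                 simulate_grid(params, gm_, pat))
        cmp$age <- a; cmp$pattern <- pn
        comps[[paste(a, pn)]] <- cmp
      }
    }
    emit(adjust_comparisons(do.call(rbind, comps), alpha = alpha),
         "ephys_contrasts.tsv")
  }

  manifest <- list(
    package = "synwaves",
    version = as.character(utils::packageVersion("synwaves")),
    seed = as.integer(seed), stages = stages,
    parameters = list(n_draws = n_draws, alpha = alpha),
    outputs = lapply(outputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Fraction of significantly affected subregions per age
#'
#' A subregion counts as affected at an age if any parameter of the
#' effect-size map is significant there after correction.
#'
#' @param map an [effectsize_map()].
#' @return Data frame with columns `age`, `fraction`.
#' @export
fraction_affected <- function(map) {
  ages <- sort(unique(map$age))
  frac <- vapply(ages, function(a) {
    sub <- map[map$age == a, ]
    affected <- tapply(sub$significant, sub$subregion, any)
    mean(affected)
  }, numeric(1))
  data.frame(age = ages, fraction = frac)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
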