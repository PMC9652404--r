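#' Configure a synthetic synaptome cohort
#'
#' Defines the study conditions for a simulated two-genotype developmental
#' cohort: subregion atlas and hierarchy, sampled ages, group sizes, baseline
#' subtype composition per subregion, total puncta density, between-animal
#' noise, and "phenotype waves" — age-windows in which the mutant group's
#' subtype composition is perturbed with a known effect size while the total
#' synapse density is left unchanged (the designed null on synapse number).
#'
#' @param n_subregions number of atlas subregions (default 131).
#' @param hierarchy data frame with columns `subregion`, `main_region`; by
#'   default 131 subregions partitioned into 12 near-equal main regions.
#' @param ages ordered postnatal days sampled (default P1 and weekly P7-P56).
#' @param n_control,n_mutant animals per genotype per age.
#' @param n_subtypes number of synapse subtypes (default 37).
#' @param baseline_composition matrix (`n_subregions` x `n_subtypes`) of
#'   subtype proportions, rows summing to 1. By default drawn once (seeded)
#'   with a main-region block structure: subregions of one main region share a
#'   composition archetype plus subregion-level jitter.
#' @param total_density per-subregion total puncta density (puncta / um^2);
#'   scalar or length-`n_subregions` vector.
#' @param wave_windows list of [wave_window()] perturbations.
#' @param noise_cv between-animal coefficient of variation of subtype
#'   densities (default 0.15).
#' @param seed master RNG seed; all stages derive named child streams from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subregions = 131L,
                          hierarchy = default_hierarchy(n_subregions),
                          ages = c(1L, seq(7L, 56L, by = 7L)),
                          n_control = 8L, n_mutant = 8L,
                          n_subtypes = 37L,
                          baseline_composition = NULL,
                          total_density = 1.0,
                          wave_windows = list(),
                          noise_cv = 0.15,
                          seed = 1L) {
  stopifnot(n_subregions >= 2L, n_subtypes >= 2L,
            n_control >= 2L, n_mutant >= 2L,
            noise_cv > 0, all(diff(ages) > 0),
            nrow(hierarchy) == n_subregions,
            all(c("subregion", "main_region") %in% names(hierarchy)))
  if (length(total_density) == 1L) {
    total_density <- rep(total_density, n_subregions)
  }
  if (any(total_density <= 0)) stop("negative densities requested")
  if (is.null(baseline_composition)) {
    baseline_composition <- default_composition(hierarchy, n_subtypes,
                                                child_seed(seed, "baseline"))
  }
  stopifnot(nrow(baseline_composition) == n_subregions,
            ncol(baseline_composition) == n_subtypes)
  if (any(baseline_composition < 0)) stop("negative densities requested")
  if (max(abs(rowSums(baseline_composition) - 1)) > 1e-8) {
    stop("subtype proportions must sum to 1 per subregion")
  }
  for (w in wave_windows) stopifnot(inherits(w, "wave_window"))
  structure(
    list(n_subregions = as.integer(n_subregions), hierarchy = hierarchy,
         ages = as.integer(ages), n_control = as.integer(n_control),
         n_mutant = as.integer(n_mutant), n_subtypes = as.integer(n_subtypes),
         baseline_composition = baseline_composition,
         total_density = total_density, wave_windows = wave_windows,
         noise_cv = noise_cv, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Define a phenotype wave
#'
#' A wave perturbs the mutant group's subtype composition in an age-window in
#' a set of subregions, leaving the total density unchanged. Two modes:
#' `"shift"` adds `d` between-animal SDs of density to each affected subtype
#' and removes the same total mass from donor subtypes (by default the type-2
#' subtypes outside the affected set, echoing a loss of SAP102-only synapses
#' compensated by PSD95-expressing ones); `"homogenize"` pulls the affected
#' subregions' compositions toward their shared, region-identity-free
#' composition (the default baseline's global maturation gradient; the
#' grand-mean composition when a user-supplied baseline carries no shared
#' component), with a strength calibrated so the mean absolute standardized
#' subtype shift is `d` — a delayed-differentiation phenotype that raises
#' between-region similarity.
#'
#' @param age_start,age_end inclusive postnatal-day window.
#' @param subregions affected subregion ids (indices into the atlas).
#' @param subtypes affected subtype labels (`"shift"` mode only).
#' @param d injected effect size in between-animal SD units.
#' @param mode `"shift"` or `"homogenize"`.
#' @param donors optional donor subtype labels for `"shift"` mode.
#' @return An object of class `wave_window`.
#' @export
wave_window <- function(age_start, age_end, subregions, subtypes = NULL,
                        d = 1, mode = c("shift", "homogenize"),
                        donors = NULL) {
  mode <- match.arg(mode)
  stopifnot(age_start <= age_end, length(subregions) >= 1L)
  if (mode == "shift" && length(subtypes) < 1L) {
    stop("shift-mode waves need affected subtypes")
  }
  structure(list(age_start = age_start, age_end = age_end,
                 subregions = as.integer(subregions),
                 subtypes = if (is.null(subtypes)) NULL else as.integer(subtypes),
                 d = d, mode = mode,
                 donors = if (is.null(donors)) NULL else as.integer(donors)),
            class = "wave_window")
}

#' Default region hierarchy
#'
#' Partitions `n_subregions` subregions into 12 near-equal main regions named
#' after the major mouse brain divisions. Any two-column
#' (`subregion`, `main_region`) mapping can be used instead.
#'
#' @param n_subregions number of subregions (default 131).
#' @param n_main number of main regions (default 12).
#' @return Data frame with columns `subregion` (integer id), `subregion_name`,
#'   `main_region`.
#' @export
default_hierarchy <- function(n_subregions = 131L, n_main = 12L) {
  mains <- c("Isocortex", "OLF", "HPF", "CTXsp", "STR", "PAL",
             "TH", "HY", "MB", "P", "MY", "CB")[seq_len(n_main)]
  sizes <- rep(n_subregions %/% n_main, n_main)
  sizes[seq_len(n_subregions %% n_main)] <- sizes[seq_len(n_subregions %% n_main)] + 1L
  main_of <- rep(mains, times = sizes)
  idx <- unlist(lapply(sizes, seq_len))
  data.frame(subregion = seq_len(n_subregions),
             subregion_name = paste0(main_of, "_", sprintf("%02d", idx)),
             main_region = main_of)
}

# Baseline composition with the structure of a differentiated brain:
# log-composition of subregion r is a shared base plus a common maturation
# gradient with positive subregion-specific loading (all regions express it,
# to varying degree), a main-region-specific deviation (regional identity)
# and subregion-level jitter. The shared part (base + gradient) is attached
# as attribute "shared_composition": it is the target of homogenize-mode
# waves, which suppress regional identity while preserving the global
# gradient (a delayed-differentiation phenotype).
default_composition <- function(hierarchy, n_subtypes, seed,
                                gradient_sd = 0.4, block_sd = 0.5,
                                jitter_sd = 0.15, alpha = 2) {
  with_seed(seed, {
    mains <- unique(hierarchy$main_region)
    base <- stats::rgamma(n_subtypes, shape = alpha)
    base <- log(base / sum(base))
    v <- stats::rnorm(n_subtypes, 0, gradient_sd)
    v <- v - mean(v)
    u <- stats::runif(nrow(hierarchy), 0.5, 1.5)
    blockdev <- matrix(stats::rnorm(length(mains) * n_subtypes, 0, block_sd),
                       length(mains), n_subtypes,
                       dimnames = list(mains, NULL))
    softmax <- function(x) {
      e <- exp(x - max(x))
      e / sum(e)
    }
    shared <- t(vapply(seq_len(nrow(hierarchy)), function(r) {
      softmax(base + u[r] * v)
    }, numeric(n_subtypes)))
    comp <- t(vapply(seq_len(nrow(hierarchy)), function(r) {
      softmax(base + u[r] * v + blockdev[hierarchy$main_region[r], ] +
                stats::rnorm(n_subtypes, 0, jitter_sd))
    }, numeric(n_subtypes)))
    attr(comp, "shared_composition") <- shared
    comp
  })
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws per-animal, per-subregion subtype densities log-normally around
#' genotype/age group means. Control means are the baseline composition scaled
#' by the total density; mutant means are perturbed only inside the configured
#' phenotype waves, using the control group's absolute between-animal SD so
#' that an injected effect of size `d` has true (pooled-SD) Cohen's d exactly
#' `d`. Total density is preserved in expectation everywhere.
#'
#' @param config a [cohort_config()].
#' @return A list of class `syn_cohort` with elements:
#'   \describe{
#'     \item{densities}{list of two 4-d arrays (`control`, `mutant`) with
#'       dimensions animal x subregion x subtype x age.}
#'     \item{truth}{data frame (`age`, `subregion`, `subtype`, `d_true`) of
#'       nonzero injected effects; empty outside wave windows.}
#'     \item{config, hierarchy}{as configured.}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  R <- config$n_subregions; S <- config$n_subtypes
  ages <- config$ages; cv <- config$noise_cv
  mu_c <- config$baseline_composition * config$total_density  # R x S
  sigma <- cv * mu_c
  if (any(mu_c <= 0)) stop("negative densities requested")
  gbar_comp <- colMeans(config$baseline_composition)

  truth <- list()
  mu_m_by_age <- list()
  for (a in ages) {
    mu_m <- mu_c
    for (w in config$wave_windows) {
      if (a < w$age_start || a > w$age_end) next
      for (r in w$subregions) {
        if (w$mode == "shift") {
          aff <- w$subtypes
          delta <- w$d * sigma[r, aff]
          donors <- w$donors
          if (is.null(donors)) donors <- setdiff(12:18, aff)
          stopifnot(length(donors) >= 1L, !any(donors %in% aff))
          mu_m[r, aff] <- mu_m[r, aff] + delta
          take <- sum(delta) * mu_c[r, donors] / sum(mu_c[r, donors])
          mu_m[r, donors] <- mu_m[r, donors] - take
        } else {
          shared <- attr(config$baseline_composition, "shared_composition")
          target_comp <- if (is.null(shared)) gbar_comp else shared[r, ]
          target <- target_comp * config$total_density[r]
          g <- (target - mu_c[r, ]) / sigma[r, ]
          wgt <- min(1, w$d / mean(abs(g)))
          mu_m[r, ] <- mu_c[r, ] + wgt * (target - mu_c[r, ])
        }
      }
      if (any(mu_m < 0)) stop("negative densities requested")
    }
    mu_m_by_age[[as.character(a)]] <- mu_m
    d_true <- (mu_m - mu_c) / sigma
    nz <- which(abs(d_true) > 1e-12, arr.ind = TRUE)
    if (nrow(nz) > 0) {
      truth[[as.character(a)]] <- data.frame(
        age = a, subregion = nz[, 1], subtype = nz[, 2],
        d_true = d_true[nz])
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(age = integer(), subregion = integer(),
               subtype = integer(), d_true = numeric())
  rownames(truth) <- NULL

  draw_group <- function(n, mu_fun, seed) {
    arr <- array(NA_real_, dim = c(n, R, S, length(ages)),
                 dimnames = list(NULL, NULL, NULL, as.character(ages)))
    with_seed(seed, {
      for (ai in seq_along(ages)) {
        mu <- mu_fun(ages[ai])          # R x S means
        sd_abs <- sigma                 # control-referenced absolute SD
        cv_eff <- sd_abs / mu
        sdlog <- sqrt(log(1 + cv_eff^2))
        meanlog <- log(mu) - sdlog^2 / 2
        for (i in seq_len(n)) {
          arr[i, , , ai] <- stats::rlnorm(R * S, meanlog, sdlog)
        }
      }
    })
    arr
  }
  control <- draw_group(config$n_control, function(a) mu_c,
                        child_seed(config$seed, "cohort-control"))
  mutant <- draw_group(config$n_mutant,
                       function(a) mu_m_by_age[[as.character(a)]],
                       child_seed(config$seed, "cohort-mutant"))
  structure(list(densities = list(control = control, mutant = mutant),
                 truth = truth, config = config,
                 hierarchy = config$hierarchy),
            class = "syn_cohort")
}

#' Tidy long table of a synthetic cohort
#'
#' @param cohort a `syn_cohort`.
#' @return Data frame with one row per animal x subregion x subtype:
#'   columns `animal`, `genotype`, `age`, `subregion`, `subtype`, `density`.
#' @export
cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "syn_cohort"))
  out <- list()
  for (g in c("control", "mutant")) {
    arr <- cohort$densities[[g]]
    dm <- dim(arr)
    grid <- expand.grid(animal = seq_len(dm[1]), subregion = seq_len(dm[2]),
                        subtype = seq_len(dm[3]), age_i = seq_len(dm[4]))
    out[[g]] <- data.frame(
      animal = paste0(toupper(substr(g, 1, 1)), sprintf("%02d", grid$animal)),
      genotype = g,
      age = cohort$config$ages[grid$age_i],
      subregion = grid$subregion,
      subtype = grid$subtype,
      density = as.vector(arr))
  }
  res <- rbind(out$control, out$mutant)
  res[order(res$genotype, res$animal, res$age, res$subregion, res$subtype), ,
      drop = FALSE]
}

#' Sample a synthetic puncta table for one subregion
#'
#' Given a subregion's subtype density profile, draws individual puncta with
#' channel intensities and morphological features scattered around the
#' scheme's subtype centroids, carrying a hidden true subtype label. Subtype
#' counts are multinomial with probabilities proportional to the profile
#' densities.
#'
#' @param profile data frame with columns `subtype`, `density` (one subregion).
#' @param n_puncta number of puncta to draw.
#' @param scheme a [subtype_scheme()] supplying the feature centroids.
#' @param noise_sd feature noise as a fraction of each feature's robust scale
#'   (morphology) or of the centroid intensity (channels); 0 gives puncta
#'   exactly at their centroids.
#' @param subregion subregion id stamped on the output.
#' @param seed RNG seed.
#' @return Data frame with columns `punctum`, `subregion`, `intensity_psd95`,
#'   `intensity_sap102`, `size`, `circularity`, `aspect`, `true_subtype`.
#' @export
generate_puncta_table <- function(profile, n_puncta, scheme = subtype_scheme(),
                                  noise_sd = 0.05, subregion = 1L,
                                  seed = NULL) {
  stopifnot(all(c("subtype", "density") %in% names(profile)),
            all(profile$density >= 0))
  present <- profile$subtype[profile$density > 0]
  if (n_puncta < 1L && length(present) > 0L) {
    stop("n_puncta must be positive for a nonempty profile")
  }
  if (!all(present %in% scheme$centroids$subtype)) {
    stop("centroids missing for some subtypes present in the profile")
  }
  with_seed(seed, {
    p <- profile$density / sum(profile$density)
    labels <- sample(profile$subtype, n_puncta, replace = TRUE, prob = p)
    cen <- scheme$centroids[match(labels, scheme$centroids$subtype), ]
    n <- n_puncta
    jitter_abs <- function(x, scale) x + stats::rnorm(n, 0, noise_sd * scale)
    out <- data.frame(
      punctum = seq_len(n),
      subregion = subregion,
      intensity_psd95 = pmax(0, cen$intensity_psd95 +
                               stats::rnorm(n, 0, noise_sd * cen$intensity_psd95)),
      intensity_sap102 = pmax(0, cen$intensity_sap102 +
                                stats::rnorm(n, 0, noise_sd * cen$intensity_sap102)),
      size = pmax(1e-6, jitter_abs(cen$size, scheme$scale["size"])),
      circularity = jitter_abs(cen$circularity, scheme$scale["circularity"]),
      aspect = jitter_abs(cen$aspect, scheme$scale["aspect"]),
      true_subtype = labels)
    rownames(out) <- NULL
    out
  })
}

#' Generate synthetic PSD95/SAP102 intensity grids for CA1 stratum radiatum
#'
#' Emulates per-individual mean fluorescence intensity over 4 radial x 10
#' tangential bins of CA1sr for each protein, genotype and age: smooth spatial
#' gradients, intensity increasing monotonically with age, an optional
#' genotype effect, and log-normal individual variation. All values are
#' strictly positive so geometric means exist.
#'
#' @param ages simulated postnatal days (default P1, P7, P28, P35, P56).
#' @param n_control,n_mutant individuals per genotype (defaults 5 and 4).
#' @param genotype_effect multiplicative mutant offset; a single number applied
#'   at all ages, or a named vector keyed by age (e.g. `c("7" = -0.2)`) for
#'   age-restricted phenotypes. 0 gives identical expected grids.
#' @param noise_cv individual-level coefficient of variation.
#' @param seed RNG seed.
#' @return Data frame with columns `protein`, `genotype`, `age`, `individual`,
#'   `radial` (1-4), `tangential` (1-10), `intensity`.
#' @export
generate_intensity_grids <- function(ages = c(1L, 7L, 28L, 35L, 56L),
                                     n_control = 5L, n_mutant = 4L,
                                     genotype_effect = 0,
                                     noise_cv = 0.05, seed = 1L) {
  stopifnot(all(ages >= 0), n_control >= 1L, n_mutant >= 1L, noise_cv >= 0)
  offset_at <- function(a) {
    if (length(genotype_effect) == 1L && is.null(names(genotype_effect))) {
      return(genotype_effect)
    }
    v <- genotype_effect[as.character(a)]
    if (is.na(v)) 0 else unname(v)
  }
  base_surface <- function(protein) {
    rad <- if (protein == "PSD95") 1.30 - 0.12 * (0:3) else 1.20 - 0.09 * (0:3)
    tan <- if (protein == "PSD95") 1.25 - 0.05 * (0:9) else 1.15 - 0.04 * (0:9)
    outer(rad, tan)
  }
  rows <- list()
  with_seed(child_seed(seed, "grids"), {
    for (protein in c("PSD95", "SAP102")) {
      surf <- base_surface(protein)
      for (a in ages) {
        age_factor <- 0.4 + 0.6 * a / 56
        for (g in c("control", "mutant")) {
          n_ind <- if (g == "control") n_control else n_mutant
          geno <- if (g == "mutant") 1 + offset_at(a) else 1
          mu <- 100 * age_factor * geno * surf
          if (any(mu <= 0)) stop("non-positive intensity requested")
          for (i in seq_len(n_ind)) {
            noise <- if (noise_cv > 0) {
              sdlog <- sqrt(log(1 + noise_cv^2))
              matrix(stats::rlnorm(40, -sdlog^2 / 2, sdlog), 4, 10)
            } else matrix(1, 4, 10)
            vals <- mu * noise
            rows[[length(rows) + 1L]] <- data.frame(
              protein = protein, genotype = g, age = a, individual = i,
              radial = rep(1:4, times = 10),
              tangential = rep(1:10, each = 4),
              intensity = as.vector(vals))
          }
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
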