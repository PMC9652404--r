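#' Cohen's d with pooled standard deviation
#'
#' Effect size of the mutant-vs-control difference in a synaptome parameter:
#' `d = (mean(mutant) - mean(control)) / s`, with `s` the pooled standard
#' deviation `sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#'
#' @param mutant,control numeric vectors of per-animal parameter values
#'   (mutant is the first group; a positive `d` means the mutant mean is
#'   larger). Both need `n >= 2`.
#' @return Cohen's d (unitless scalar).
#' @export
cohen_d <- function(mutant, control) {
  n1 <- length(mutant); n2 <- length(control)
  if (n1 < 2 || n2 < 2) stop("need at least 2 values per group")
  s <- sqrt(((n1 - 1) * stats::var(mutant) + (n2 - 1) * stats::var(control)) /
              (n1 + n2 - 2))
  if (s == 0) stop("zero pooled standard deviation: effect size undefined")
  (mean(mutant) - mean(control)) / s
}

#' Bayesian Monte-Carlo effect-size estimation
#'
#' Infers the posterior distribution of Cohen's d by Monte-Carlo upscaling of
#' the two samples under a normal observation model with the noninformative
#' reference prior: per group, the posterior of the variance is
#' `(n-1) s^2 / chisq(n-1)` and the posterior of the mean is the location-scale
#' t-distribution `mean + (sigma / sqrt(n)) N(0,1)`. Each joint draw yields a
#' Cohen's d draw via the pooled SD; the reported effect size is the mode of a
#' Gaussian kernel density over the draws (Silverman bandwidth), and the
#' two-sided significance is `P = 2 min(Pr(d < 0), Pr(d > 0))`.
#'
#' @param mutant,control numeric vectors of per-animal values (`n >= 2` each).
#' @param n_draws number of Monte-Carlo draws (default 20000); fewer than
#'   1000 gives an unstable mode and raises a warning.
#' @param seed optional RNG seed (restores the caller's RNG state).
#' @return A list of class `effectsize_pdf`: `draws`, `mode`, `p` (two-sided
#'   posterior significance), `expectation`, `spread` (SD of the draws),
#'   `n1`, `n2`, and the analytic `d` of [cohen_d()] (NA when degenerate).
#' @export
bayes_effectsize <- function(mutant, control, n_draws = 20000L, seed = NULL) {
  n1 <- length(mutant); n2 <- length(control)
  if (n1 < 2 || n2 < 2) stop("need at least 2 values per group")
  if (n_draws < 1000) warning("fewer than 1000 draws: mode estimate unstable")
  m1 <- mean(mutant); m2 <- mean(control)
  v1 <- stats::var(mutant); v2 <- stats::var(control)
  if (v1 == 0 && v2 == 0) {
    if (m1 == m2) {
      return(structure(list(draws = rep(0, n_draws), mode = 0, p = 1,
                            expectation = 0, spread = 0, n1 = n1, n2 = n2,
                            d = NA_real_),
                       class = "effectsize_pdf"))
    }
    stop("zero pooled standard deviation: effect size undefined")
  }
  draws <- with_seed(seed, {
    sig1 <- sqrt((n1 - 1) * v1 / stats::rchisq(n_draws, n1 - 1))
    sig2 <- sqrt((n2 - 1) * v2 / stats::rchisq(n_draws, n2 - 1))
    mu1 <- m1 + sig1 / sqrt(n1) * stats::rnorm(n_draws)
    mu2 <- m2 + sig2 / sqrt(n2) * stats::rnorm(n_draws)
    sp <- sqrt(((n1 - 1) * sig1^2 + (n2 - 1) * sig2^2) / (n1 + n2 - 2))
    (mu1 - mu2) / sp
  })
  dens <- stats::density(draws, bw = "nrd0")
  p_neg <- mean(draws < 0)
  structure(list(draws = draws,
                 mode = dens$x[which.max(dens$y)],
                 p = min(1, 2 * min(p_neg, 1 - p_neg)),
                 expectation = mean(draws),
                 spread = stats::sd(draws),
                 n1 = n1, n2 = n2,
                 d = cohen_d(mutant, control)),
            class = "effectsize_pdf")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment; monotone, capped at 1,
#' input order preserved.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Genotype effect-size map across subregions and ages
#'
#' For every (age, subregion, parameter) cell, runs [bayes_effectsize()] on
#' the per-animal parameter values of the two genotypes and adjusts the
#' two-sided posterior significances with Benjamini-Hochberg over all
#' subregions within each age x parameter family.
#'
#' @param cohort a `syn_cohort` from [generate_cohort()].
#' @param level `"type"` (densities of the 3 types; default) or `"subtype"`
#'   (densities of the 37 subtypes).
#' @param n_draws Monte-Carlo draws per cell.
#' @param seed master seed; each cell draws from its own child stream.
#' @param alpha significance level applied to the adjusted p-values.
#' @param scheme a [subtype_scheme()] (used to sum subtype densities per type).
#' @return Data frame of class `effectsize_map` with columns `age`,
#'   `subregion`, `parameter`, `d` (posterior mode), `expectation`, `spread`,
#'   `p`, `p_adj`, `significant`.
#' @export
effectsize_map <- function(cohort, level = c("type", "subtype"),
                           n_draws = 4000L, seed = 1L, alpha = 0.05,
                           scheme = subtype_scheme()) {
  stopifnot(inherits(cohort, "syn_cohort"))
  level <- match.arg(level)
  ages <- cohort$config$ages
  R <- cohort$config$n_subregions
  S <- cohort$config$n_subtypes
  # type ranges clipped to the cohort's subtype count (small test cohorts)
  type_sel <- lapply(scheme$type_ranges, function(rng) rng[rng <= S])
  type_sel <- type_sel[vapply(type_sel, length, integer(1)) > 0]
  group_values <- function(arr, ai) {
    # animal x subregion x parameter matrix for one age
    x <- arr[, , , ai, drop = FALSE]
    dim(x) <- dim(arr)[1:3]
    if (level == "subtype") return(x)
    out <- array(0, dim = c(dim(x)[1], dim(x)[2], length(type_sel)))
    for (tp in seq_along(type_sel)) {
      out[, , tp] <- apply(x[, , type_sel[[tp]], drop = FALSE], c(1, 2), sum)
    }
    out
  }
  rows <- vector("list", length(ages))
  for (ai in seq_along(ages)) {
    ctrl <- group_values(cohort$densities$control, ai)
    mut <- group_values(cohort$densities$mutant, ai)
    n_par <- dim(ctrl)[3]
    res <- expand.grid(subregion = seq_len(R), parameter = seq_len(n_par))
    res$age <- ages[ai]
    stats_mat <- matrix(NA_real_, nrow(res), 4)
    for (k in seq_len(nrow(res))) {
      r <- res$subregion[k]; ppar <- res$parameter[k]
      fit <- bayes_effectsize(
        mut[, r, ppar], ctrl[, r, ppar], n_draws = n_draws,
        seed = child_seed(seed, paste0("map-", ages[ai], "-", r, "-", ppar)))
      stats_mat[k, ] <- c(fit$mode, fit$expectation, fit$spread, fit$p)
    }
    res$d <- stats_mat[, 1]; res$expectation <- stats_mat[, 2]
    res$spread <- stats_mat[, 3]; res$p <- stats_mat[, 4]
    res$p_adj <- NA_real_
    for (pp in seq_len(n_par)) {
      sel <- res$parameter == pp
      res$p_adj[sel] <- bh_adjust(res$p[sel])
    }
    rows[[ai]] <- res
  }
  out <- do.call(rbind, rows)
  out$parameter <- if (level == "type") {
    paste0("type", names(type_sel)[out$parameter])
  } else paste0("subtype", out$parameter)
  out$significant <- out$p_adj < alpha
  out <- out[, c("age", "subregion", "parameter", "d", "expectation",
                 "spread", "p", "p_adj", "significant")]
  class(out) <- c("effectsize_map", class(out))
  out
}

#' Contrast of mutant effect sizes between SPL and LPL subtypes
#'
#' Pools the posterior effect-size draws of the short-protein-lifetime (SPL)
#' and long-protein-lifetime (LPL) subtype sets per subregion and computes
#' `d_SPL-LPL = (E[f_SPL] - E[f_LPL]) / sqrt((s^2[f_SPL] + s^2[f_LPL]) / 2)`,
#' with two-sided significance from the difference of paired draws from the
#' two PDFs and Benjamini-Hochberg adjustment over all subregions within each
#' age.
#'
#' @param spl_pdfs,lpl_pdfs lists (one element per subregion) of lists of
#'   `effectsize_pdf` objects (one per member subtype).
#' @param ages optional age labels (same length as the pdf lists); used only
#'   to label output rows, one BH family per distinct age.
#' @param seed RNG seed for the draw pairing.
#' @return Data frame with columns `age`, `subregion`, `d_spl_lpl`, `p`,
#'   `p_adj`.
#' @export
compare_spl_lpl <- function(spl_pdfs, lpl_pdfs, ages = NULL, seed = 1L) {
  stopifnot(length(spl_pdfs) == length(lpl_pdfs), length(spl_pdfs) >= 1L)
  if (is.null(ages)) ages <- rep(NA_integer_, length(spl_pdfs))
  n <- length(spl_pdfs)
  out <- data.frame(age = ages, subregion = seq_len(n),
                    d_spl_lpl = NA_real_, p = NA_real_, p_adj = NA_real_)
  for (i in seq_len(n)) {
    f_spl <- unlist(lapply(spl_pdfs[[i]], function(f) f$draws))
    f_lpl <- unlist(lapply(lpl_pdfs[[i]], function(f) f$draws))
    if (!length(f_spl) || !length(f_lpl)) stop("empty PDF set for subregion ", i)
    e1 <- mean(f_spl); e2 <- mean(f_lpl)
    s1 <- stats::sd(f_spl); s2 <- stats::sd(f_lpl)
    if (s1 == 0 && s2 == 0) stop("zero spread in both PDFs")
    out$d_spl_lpl[i] <- (e1 - e2) / sqrt((s1^2 + s2^2) / 2)
    m <- min(length(f_spl), length(f_lpl))
    diffs <- with_seed(child_seed(seed, paste0("spl-lpl-", i)), {
      sample(f_spl, m) - sample(f_lpl, m)
    })
    p_neg <- mean(diffs < 0)
    out$p[i] <- min(1, 2 * min(p_neg, 1 - p_neg))
  }
  for (a in unique(out$age)) {
    sel <- if (is.na(a)) is.na(out$age) else !is.na(out$age) & out$age == a
    out$p_adj[sel] <- bh_adjust(out$p[sel])
  }
  out
}

#' Rank subtypes by the number of significantly affected subregions
#'
#' Counts, per subtype, the (age, subregion) cells of a subtype-level
#' effect-size map that are significant after correction, summed over all
#' ages — the basis for ranking which subtypes carry the phenotype.
#'
#' @param map a subtype-level [effectsize_map()].
#' @param scheme a [subtype_scheme()].
#' @param psd95_only restrict to the 30 PSD95-expressing subtypes (types 1
#'   and 3)?
#' @return Data frame with columns `subtype`, `n_significant`, sorted by
#'   decreasing count.
#' @export
rank_subtypes <- function(map, scheme = subtype_scheme(), psd95_only = FALSE) {
  stopifnot(all(grepl("^subtype", map$parameter)))
  sub <- as.integer(sub("^subtype", "", map$parameter))
  keep <- if (psd95_only) psd95_subtypes(scheme) else sort(unique(sub))
  counts <- vapply(keep, function(s) sum(map$significant[sub == s]),
                   integer(1))
  out <- data.frame(subtype = keep, n_significant = counts)
  out[order(-out$n_significant, out$subtype), , drop = FALSE]
}

#' Detect phenotype waves in a fraction-affected age series
#'
#' Returns the maximal contiguous age-windows in which the fraction of
#' significantly affected subregions exceeds a threshold.
#'
#' @param fraction_affected numeric vector of fractions in `[0, 1]`, one per
#'   age, in age order.
#' @param ages postnatal days corresponding to the fractions.
#' @param threshold detection threshold in `(0, 1)`.
#' @return Data frame with one row per wave: `age_start`, `age_end`.
#' @export
detect_waves <- function(fraction_affected, ages, threshold = 0.25) {
  stopifnot(length(fraction_affected) == length(ages), all(diff(ages) > 0))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  above <- fraction_affected > threshold
  if (!any(above)) {
    return(data.frame(age_start = integer(), age_end = integer()))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(age_start = ages[starts[keep]], age_end = ages[ends[keep]])
}
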