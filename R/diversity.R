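#' Shannon synapse-diversity index
#'
#' Shannon entropy (natural log) of a subtype composition vector:
#' `H = -sum(p_i log p_i)` with the convention `0 log 0 = 0`. Proportions are
#' renormalized when they deviate from unit sum by more than 1e-6 of rounding
#' slack; an all-zero vector is an error. `H` ranges from 0 (one subtype) to
#' `log(n)` (uniform over n subtypes).
#'
#' @param proportions nonnegative subtype proportions (or densities; scale
#'   invariant).
#' @return Diversity `H` in nats.
#' @export
diversity_index <- function(proportions) {
  if (any(proportions < 0)) stop("proportions must be nonnegative")
  total <- sum(proportions)
  if (total == 0) stop("all-zero composition has no diversity")
  p <- proportions / total
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Genotype comparison of synapse diversity across subregions
#'
#' Computes the Shannon diversity of each animal x subregion subtype
#' composition, then contrasts genotypes per (age, subregion) with
#' [bayes_effectsize()] and adjusts significances with Benjamini-Hochberg
#' over all subregions within each age.
#'
#' @param cohort a `syn_cohort`.
#' @param n_draws Monte-Carlo draws per contrast.
#' @param seed master seed (child stream per cell).
#' @param alpha significance level on adjusted p-values.
#' @return Data frame with columns `age`, `subregion`, `h_control`
#'   (group mean H), `h_mutant`, `d` (posterior mode), `p`, `p_adj`,
#'   `significant`.
#' @export
compare_diversity <- function(cohort, n_draws = 4000L, seed = 1L,
                              alpha = 0.05) {
  stopifnot(inherits(cohort, "syn_cohort"))
  ages <- cohort$config$ages
  R <- cohort$config$n_subregions
  h_of <- function(arr, ai) {
    # animals x subregions matrix of H values at one age
    n <- dim(arr)[1]
    out <- matrix(NA_real_, n, R)
    for (i in seq_len(n)) {
      for (r in seq_len(R)) out[i, r] <- diversity_index(arr[i, r, , ai])
    }
    out
  }
  rows <- vector("list", length(ages))
  for (ai in seq_along(ages)) {
    hc <- h_of(cohort$densities$control, ai)
    hm <- h_of(cohort$densities$mutant, ai)
    res <- data.frame(age = ages[ai], subregion = seq_len(R),
                      h_control = colMeans(hc), h_mutant = colMeans(hm),
                      d = NA_real_, p = NA_real_)
    for (r in seq_len(R)) {
      fit <- bayes_effectsize(
        hm[, r], hc[, r], n_draws = n_draws,
        seed = child_seed(seed, paste0("div-", ages[ai], "-", r)))
      res$d[r] <- fit$mode; res$p[r] <- fit$p
    }
    res$p_adj <- bh_adjust(res$p)
    rows[[ai]] <- res
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}
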