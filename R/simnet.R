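#' Standardize synaptome parameters across subregions
#'
#' Z-scores each parameter column (mean 0, sample-SD 1) across subregions.
#' Constant columns carry no between-region information and are dropped with
#' a message.
#'
#' @param features numeric matrix, subregions x parameters (>= 2 subregions).
#' @return The standardized matrix (possibly with fewer columns).
#' @export
standardize_parameters <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2) stop("need at least 2 subregions")
  sds <- apply(features, 2, stats::sd)
  if (any(sds == 0)) {
    message("dropping ", sum(sds == 0), " constant parameter column(s)")
    features <- features[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (ncol(features) == 0) stop("no informative parameter columns remain")
  scale(features)
}

#' Subregion-by-subregion synaptome similarity matrix
#'
#' Similarity between two subregions is the Pearson correlation of their
#' standardized parameter vectors; the matrix is symmetric with unit
#' diagonal, values in [-1, 1].
#'
#' @param features standardized subregion x parameter matrix
#'   (from [standardize_parameters()]).
#' @return Square similarity matrix with subregion row/column names.
#' @export
similarity_matrix <- function(features) {
  features <- as.matrix(features)
  if (any(apply(features, 1, stats::sd) == 0)) {
    stop("subregion with zero-variance feature vector")
  }
  s <- stats::cor(t(features))
  diag(s) <- 1
  s
}

#' Similarity ratio of a block-structured similarity matrix
#'
#' `S_ratio` is the mean similarity of subregion pairs from different main
#' regions divided by the mean similarity of pairs within the same main
#' region (off-diagonal pairs only). A high ratio means the synaptome is
#' homogeneous across the whole matrix; a low ratio means similarity is
#' concentrated within main regions. Main regions with a single subregion
#' contribute no within pairs and are skipped.
#'
#' @param s similarity matrix (subregions in row order of `hierarchy`).
#' @param hierarchy data frame with columns `subregion`, `main_region` in the
#'   matrix's row order.
#' @return A list of class `s_ratio`: `s_ratio`, `between_mean`,
#'   `within_mean`, `n_between`, `n_within`.
#' @export
similarity_ratio <- function(s, hierarchy) {
  n <- nrow(s)
  stopifnot(ncol(s) == n, nrow(hierarchy) == n)
  same <- outer(hierarchy$main_region, hierarchy$main_region, "==")
  off <- upper.tri(s)
  within <- s[off & same]
  between <- s[off & !same]
  if (!length(within)) stop("no within-main-region pairs in hierarchy")
  if (!length(between)) stop("no between-main-region pairs in hierarchy")
  structure(list(s_ratio = mean(between) / mean(within),
                 between_mean = mean(between), within_mean = mean(within),
                 n_between = length(between), n_within = length(within)),
            class = "s_ratio")
}

#' Build a subregion network from a similarity matrix
#'
#' Nodes are subregions; the default edge rule connects each node to its
#' top-`k` most similar neighbours (union over nodes), which keeps every node
#' connected to at least `k` others. Self-loops are excluded.
#'
#' @param s similarity matrix (n >= 3).
#' @param k neighbours kept per node (default 12: one more than the largest
#'   default main-region block, so every node gains at least one
#'   between-region edge and the graph stays connected).
#' @return An undirected [igraph::graph] with `n` vertices.
#' @export
build_graph <- function(s, k = 12L) {
  n <- nrow(s)
  stopifnot(n >= 3, k >= 1, k < n)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- order(s[i, -i], decreasing = TRUE)
    nbr <- seq_len(n)[-i][ord[seq_len(k)]]
    adj[i, nbr] <- TRUE
  }
  adj <- adj | t(adj)
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}

#' Small-worldness of a subregion network
#'
#' `sigma = (C / C_rand) / (L / L_rand)`, where `C` is the average (local)
#' clustering coefficient, `L` the characteristic path length, and the
#' reference values are means over `n_random` degree-preserving rewirings
#' (double-edge swaps, `10 |E|` swaps each). If the graph is disconnected,
#' `L` is computed on the largest component with a warning.
#'
#' @param g an undirected igraph graph.
#' @param n_random number of rewired reference graphs (>= 10).
#' @param seed RNG seed for the rewiring.
#' @return A list of class `small_worldness`: `sigma`, `clustering`,
#'   `path_length`, `c_rand`, `l_rand`.
#' @export
small_worldness <- function(g, n_random = 20L, seed = NULL) {
  if (n_random < 10) stop("need at least 10 reference graphs")
  comps <- igraph::components(g)
  if (comps$no > 1) {
    warning("graph disconnected; path length computed on largest component")
    if (max(comps$csize) < 0.8 * igraph::vcount(g)) {
      stop("largest component below 80% of nodes")
    }
  }
  cl_metrics <- function(gr) {
    co <- igraph::components(gr)
    big <- igraph::induced_subgraph(
      gr, which(co$membership == which.max(co$csize)))
    c(igraph::transitivity(gr, type = "localaverage", isolates = "zero"),
      igraph::mean_distance(big, directed = FALSE))
  }
  obs <- cl_metrics(g)
  rand <- with_seed(seed, {
    vapply(seq_len(n_random), function(i) {
      gr <- igraph::rewire(
        g, igraph::keeping_degseq(niter = 10 * igraph::ecount(g)))
      cl_metrics(gr)
    }, numeric(2))
  })
  c_rand <- mean(rand[1, ]); l_rand <- mean(rand[2, ])
  structure(list(sigma = (obs[1] / c_rand) / (obs[2] / l_rand),
                 clustering = obs[1], path_length = obs[2],
                 c_rand = c_rand, l_rand = l_rand),
            class = "small_worldness")
}

#' Per-animal similarity, S_ratio and small-worldness for a cohort
#'
#' For every genotype x age x animal, builds the subregion feature matrix of
#' subtype densities, standardizes it, computes the similarity matrix, its
#' similarity ratio against the cohort hierarchy, and the small-worldness of
#' the top-`k` similarity network. Group-level similarity matrices are the
#' means of the per-animal matrices.
#'
#' Parameters are standardized once over the whole cohort (each subtype
#' density z-scored over all animals, ages, genotypes and subregions), not
#' within each animal's matrix: a per-matrix z-score forces the mean
#' off-diagonal similarity toward `-1/(n-1)` regardless of how homogeneous
#' the brain is, which would make the similarity ratio insensitive to
#' genuine homogenization. With a pooled standardization, two subregions
#' sharing the cohort-wide expression pattern correlate positively, as in
#' the published similarity matrices.
#'
#' @param cohort a `syn_cohort`.
#' @param k neighbours per node for [build_graph()].
#' @param n_random reference rewirings for [small_worldness()].
#' @param seed master seed (child stream per animal).
#' @param network compute small-worldness too? (slowest part; default TRUE)
#' @return A list with `per_animal` (data frame: `genotype`, `age`, `animal`,
#'   `s_ratio`, `sigma`) and `group_matrices` (named list `genotype.age` of
#'   mean similarity matrices).
#' @export
cohort_similarity <- function(cohort, k = 12L, n_random = 20L, seed = 1L,
                              network = TRUE) {
  stopifnot(inherits(cohort, "syn_cohort"))
  ages <- cohort$config$ages
  k <- min(k, cohort$config$n_subregions - 1L)
  # pooled per-subtype standardization over the whole cohort
  S <- cohort$config$n_subtypes
  pooled <- lapply(seq_len(S), function(s) {
    c(cohort$densities$control[, , s, ], cohort$densities$mutant[, , s, ])
  })
  m_s <- vapply(pooled, mean, numeric(1))
  sd_s <- vapply(pooled, stats::sd, numeric(1))
  if (any(sd_s == 0)) stop("constant subtype density across the cohort")
  rows <- list()
  mats <- list()
  for (g in c("control", "mutant")) {
    arr <- cohort$densities[[g]]
    for (ai in seq_along(ages)) {
      acc <- 0
      n_animals <- dim(arr)[1]
      for (i in seq_len(n_animals)) {
        feats <- sweep(sweep(arr[i, , , ai], 2, m_s), 2, sd_s, "/")
        s <- similarity_matrix(feats)
        acc <- acc + s
        sr <- similarity_ratio(s, cohort$hierarchy)$s_ratio
        sig <- if (network) {
          small_worldness(build_graph(s, k = k), n_random = n_random,
                          seed = child_seed(seed,
                                            paste0(g, "-", ages[ai], "-", i)))$sigma
        } else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          genotype = g, age = ages[ai], animal = i,
          s_ratio = sr, sigma = sig)
      }
      mats[[paste0(g, ".", ages[ai])]] <- acc / n_animals
    }
  }
  list(per_animal = do.call(rbind, rows), group_matrices = mats)
}

#' Genotype contrast of a per-animal network statistic across ages
#'
#' Runs [bayes_effectsize()] on the per-animal values of `statistic`
#' (mutant vs control) at each age, with Benjamini-Hochberg adjustment over
#' ages.
#'
#' @param per_animal the `per_animal` data frame from [cohort_similarity()].
#' @param statistic `"s_ratio"` or `"sigma"`.
#' @param n_draws,seed,alpha as in [compare_diversity()].
#' @return Data frame with columns `age`, `d`, `p`, `p_adj`, `significant`.
#' @export
compare_network_statistic <- function(per_animal,
                                      statistic = c("s_ratio", "sigma"),
                                      n_draws = 20000L, seed = 1L,
                                      alpha = 0.05) {
  statistic <- match.arg(statistic)
  ages <- sort(unique(per_animal$age))
  out <- data.frame(age = ages, d = NA_real_, p = NA_real_)
  for (i in seq_along(ages)) {
    sel <- per_animal$age == ages[i]
    x_m <- per_animal[[statistic]][sel & per_animal$genotype == "mutant"]
    x_c <- per_animal[[statistic]][sel & per_animal$genotype == "control"]
    fit <- bayes_effectsize(x_m, x_c, n_draws = n_draws,
                            seed = child_seed(seed, paste0("net-", ages[i])))
    out$d[i] <- fit$mode; out$p[i] <- fit$p
  }
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < alpha
  out
}
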