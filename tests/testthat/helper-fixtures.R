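# Small cohort configurations used across tests; built in code, no files.

tiny_config <- function(seed = 1L, waves = list(), n_subregions = 8L,
                        n_subtypes = 10L, ages = c(7L, 14L),
                        n_control = 6L, n_mutant = 6L) {
  cohort_config(
    n_subregions = n_subregions,
    hierarchy = default_hierarchy(n_subregions, 2L),
    n_subtypes = n_subtypes,
    baseline_composition = matrix(1 / n_subtypes, n_subregions, n_subtypes),
    ages = ages, n_control = n_control, n_mutant = n_mutant,
    wave_windows = waves, seed = seed)
}

# Independent step-up BH oracle (literal definition, no p.adjust).
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (i in rev(seq_len(n))) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- running
  }
  pmin(adj, 1)
}

# Brute-force graph oracles on an adjacency matrix (undirected, no loops).
clustering_oracle <- function(adj) {
  n <- nrow(adj)
  local_c <- vapply(seq_len(n), function(i) {
    nbr <- which(adj[i, ] > 0)
    k <- length(nbr)
    if (k < 2) return(0)
    links <- sum(adj[nbr, nbr]) / 2
    2 * links / (k * (k - 1))
  }, numeric(1))
  mean(local_c)
}

path_length_oracle <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
    }
  }
  off <- d[upper.tri(d)]
  mean(off[is.finite(off)])
}

# Exhaustive pair enumeration for the similarity ratio.
s_ratio_oracle <- function(s, main_region) {
  n <- nrow(s)
  w <- c(); b <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (main_region[i] == main_region[j]) w <- c(w, s[i, j]) else b <- c(b, s[i, j])
    }
  }
  mean(b) / mean(w)
}

# Closed-form paired t statistic and two-sided p.
paired_t_oracle <- function(x, y) {
  d <- x - y
  t_stat <- mean(d) / (sd(d) / sqrt(length(d)))
  p <- 2 * pt(-abs(t_stat), df = length(d) - 1)
  list(t = t_stat, p = p)
}
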