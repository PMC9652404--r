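test_that("parameter standardization gives sample z-scores and drops constants", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(2, 4, 9))
  expect_message(z <- standardize_parameters(m), "constant")
  expect_equal(colnames(z), c("a", "c"))
  expect_equal(unname(z[, "a"]), (c(1, 2, 3) - 2) / 1)
  expect_equal(unname(colMeans(z)), c(0, 0))
  expect_equal(unname(apply(z, 2, sd)), c(1, 1))
  expect_error(standardize_parameters(m[1, , drop = FALSE]), "at least 2")
})

test_that("similarity matrices are symmetric correlations with unit diagonal", {
  set.seed(12)
  f <- matrix(rnorm(40), 8, 5)
  s <- similarity_matrix(f)
  expect_equal(s, t(s))
  expect_equal(unname(diag(s)), rep(1, 8))
  expect_true(all(s >= -1 & s <= 1))
  # duplicated subregion -> off-diagonal 1; negated -> -1
  f2 <- rbind(f[1, ], f[1, ], -f[1, ])
  s2 <- similarity_matrix(f2)
  expect_equal(s2[1, 2], 1)
  expect_equal(s2[1, 3], -1)
  # permutation invariance (up to the same permutation)
  perm <- sample(8)
  expect_equal(unname(similarity_matrix(f[perm, ])), unname(s[perm, perm]))
  expect_error(similarity_matrix(rbind(f[1, ], rep(2, 5))), "zero-variance")
})

test_that("similarity ratio matches pair enumeration on hand-built matrices", {
  hier <- data.frame(subregion = 1:4, main_region = c("A", "A", "B", "B"))
  # all off-diagonal equal -> ratio 1
  s_eq <- matrix(0.6, 4, 4); diag(s_eq) <- 1
  expect_equal(similarity_ratio(s_eq, hier)$s_ratio, 1)
  # perfect blocks: within 1, between 0 -> ratio 0
  s_blk <- matrix(0, 4, 4)
  s_blk[1:2, 1:2] <- 1; s_blk[3:4, 3:4] <- 1
  expect_equal(similarity_ratio(s_blk, hier)$s_ratio, 0)
  # generic matrix vs the enumeration oracle
  set.seed(13)
  f <- matrix(rnorm(4 * 6), 4, 6)
  s <- similarity_matrix(f)
  res <- similarity_ratio(s, hier)
  expect_equal(res$s_ratio, s_ratio_oracle(s, hier$main_region),
               tolerance = 1e-12)
  expect_equal(res$n_within, 2L)
  expect_equal(res$n_between, 4L)
  # singleton main regions leave no within pairs
  hier_bad <- data.frame(subregion = 1:4, main_region = c("A", "B", "C", "D"))
  expect_error(similarity_ratio(s, hier_bad), "within")
})

test_that("graph construction keeps top-k neighbours and block structure", {
  ones <- matrix(1, 5, 5)
  g <- build_graph(ones, k = 4L)
  expect_equal(igraph::ecount(g), choose(5, 2))  # complete
  set.seed(14)
  s3 <- similarity_matrix(matrix(rnorm(9), 3, 3))
  g3 <- build_graph(s3, k = 1L)
  expect_true(all(igraph::degree(g3) >= 1))
  # block matrix: within-block edges dominate
  blk <- matrix(0.1, 8, 8)
  blk[1:4, 1:4] <- 0.9; blk[5:8, 5:8] <- 0.9; diag(blk) <- 1
  gb <- build_graph(blk, k = 3L)
  adj <- as.matrix(igraph::as_adjacency_matrix(gb))
  within <- sum(adj[1:4, 1:4]) + sum(adj[5:8, 5:8])
  between <- sum(adj) - within
  expect_gt(within, between)
})

test_that("small-worldness components match brute force and behave", {
  # complete graph: C = C_rand = 1, L = L_rand = 1 -> sigma = 1
  gK <- igraph::make_full_graph(7)
  swK <- small_worldness(gK, n_random = 10L, seed = 15L)
  expect_equal(swK$sigma, 1)
  expect_equal(swK$clustering, 1)
  expect_equal(swK$path_length, 1)
  # C and L agree with adjacency-matrix oracles on small random graphs
  set.seed(16)
  for (i in 1:5) {
    adj <- matrix(0, 9, 9)
    adj[upper.tri(adj)] <- rbinom(36, 1, 0.45)
    adj <- adj + t(adj)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    co <- igraph::components(g)
    if (co$no > 1) next
    sw <- small_worldness(g, n_random = 10L, seed = 100L + i)
    expect_equal(sw$clustering, clustering_oracle(adj), tolerance = 1e-10)
    expect_equal(sw$path_length, path_length_oracle(adj), tolerance = 1e-10)
  }
  # rewired ring (Watts-Strogatz regime) is small-world: sigma > 1
  set.seed(17)
  ws <- igraph::sample_smallworld(1, 100, 5, 0.1)
  ws <- igraph::simplify(ws)
  expect_gt(small_worldness(ws, n_random = 10L, seed = 18L)$sigma, 1)
  # determinism
  s1 <- small_worldness(ws, n_random = 10L, seed = 19L)$sigma
  s2 <- small_worldness(ws, n_random = 10L, seed = 19L)$sigma
  expect_identical(s1, s2)
  expect_error(small_worldness(ws, n_random = 5L), "at least 10")
})

test_that("destroying block structure lowers small-worldness", {
  cfg <- cohort_config(n_subregions = 40L,
                       hierarchy = default_hierarchy(40L, 4L),
                       ages = 14L, n_control = 4L, n_mutant = 4L,
                       seed = 41L)
  ch <- generate_cohort(cfg)
  feats <- ch$densities$control[1, , , 1]
  s <- similarity_matrix(standardize_parameters(feats))
  sig_block <- small_worldness(build_graph(s, k = 11L), n_random = 10L,
                               seed = 42L)$sigma
  # shuffle subregion labels: same value distribution, no block structure
  set.seed(43)
  perm <- sample(40)
  s_shuf <- s
  s_shuf[upper.tri(s_shuf)] <- sample(s[upper.tri(s)])
  s_shuf[lower.tri(s_shuf)] <- t(s_shuf)[lower.tri(s_shuf)]
  sig_shuf <- small_worldness(build_graph(s_shuf, k = 11L), n_random = 10L,
                              seed = 44L)$sigma
  expect_gt(sig_block, sig_shuf)
})
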