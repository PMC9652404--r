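test_that("pooled-SD Cohen's d matches hand evaluation and its symmetries", {
  expect_equal(cohen_d(c(1, 2, 3), c(2, 3, 4)), -1)
  expect_equal(cohen_d(c(2, 3, 4), c(1, 2, 3)), 1)
  x <- c(1.2, 0.7, 1.9, 1.4); y <- c(0.3, 0.9, 0.5, 0.8)
  expect_equal(cohen_d(x, y), -cohen_d(y, x))
  expect_equal(cohen_d(x + 5, y + 5), cohen_d(x, y))
  expect_equal(cohen_d(3 * x, 3 * y), cohen_d(x, y))
  expect_equal(cohen_d(c(1, 2, 3), c(0, 1, 2)), 1)  # s1 = s2 = 1, means differ by 1
  expect_error(cohen_d(c(1, 1), c(1, 1)), "pooled")
  expect_error(cohen_d(1, c(1, 2)), "at least 2")
})

test_that("posterior effect size is calibrated, consistent and seeded", {
  set.seed(1)
  x <- rnorm(60)
  null_fit <- bayes_effectsize(x, x, n_draws = 20000L, seed = 2L)
  expect_lt(abs(null_fit$mode), 0.15)
  expect_gt(null_fit$p, 0.5)
  # true d = 1 at n = 50: mode within 0.2
  set.seed(3)
  m <- rnorm(50, 1); c0 <- rnorm(50, 0)
  fit <- bayes_effectsize(m, c0, n_draws = 20000L, seed = 4L)
  expect_lt(abs(fit$mode - 1), 0.2)
  expect_lt(fit$p, 0.01)
  # mode converges on the analytic d as n grows
  set.seed(5)
  m2 <- rnorm(200, 0.8); c2 <- rnorm(200)
  fit2 <- bayes_effectsize(m2, c2, n_draws = 20000L, seed = 6L)
  expect_lt(abs(fit2$mode - cohen_d(m2, c2)), 0.1)
  # determinism and the unstable-draws warning
  f1 <- bayes_effectsize(m, c0, n_draws = 5000L, seed = 7L)
  f2 <- bayes_effectsize(m, c0, n_draws = 5000L, seed = 7L)
  expect_identical(f1$draws, f2$draws)
  expect_warning(bayes_effectsize(m, c0, n_draws = 500L, seed = 1L),
                 "unstable")
  # degenerate equal-constant groups
  deg <- bayes_effectsize(rep(2, 4), rep(2, 4), seed = 1L)
  expect_equal(deg$mode, 0)
  expect_equal(deg$p, 1)
})

test_that("BH adjustment matches the step-up oracle and its contract", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.04, 0.5)), c(0.08, 0.5))
  set.seed(8)
  for (i in 1:5) {
    p <- runif(20)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    perm <- sample(20)
    expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  }
  expect_true(all(bh_adjust(runif(10)) <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("SPL-LPL contrast follows its closed form", {
  mk <- function(draws) structure(list(draws = draws), class = "effectsize_pdf")
  set.seed(9)
  base <- rnorm(20000)
  # identical PDFs -> 0
  same <- compare_spl_lpl(list(list(mk(base))), list(list(mk(base))), seed = 1L)
  expect_equal(same$d_spl_lpl, 0)
  # N(2,1) vs N(0,1) -> (2 - 0) / sqrt((1 + 1)/2) = 2, and the two-sided
  # tail mass of the difference of draws has closed form 2 Phi(-2/sqrt(2))
  spl <- rnorm(50000, 2, 1); lpl <- rnorm(50000, 0, 1)
  res <- compare_spl_lpl(list(list(mk(spl))), list(list(mk(lpl))), seed = 2L)
  expect_equal(res$d_spl_lpl, 2, tolerance = 0.05)
  expect_equal(res$p, 2 * pnorm(-2 / sqrt(2)), tolerance = 0.02)
  expect_error(compare_spl_lpl(list(list()), list(list(mk(base)))), "empty")
})

test_that("subtype ranking counts significant cells over all ages", {
  map <- data.frame(
    age = rep(c(7L, 14L, 21L), each = 2),
    subregion = 1L,
    parameter = rep(c("subtype6", "subtype2"), 3),
    significant = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  r <- rank_subtypes(map)
  expect_equal(r$n_significant[r$subtype == 6L], 3L)
  expect_equal(r$n_significant[r$subtype == 2L], 0L)
  # empty significance -> all zeros
  map$significant <- FALSE
  expect_true(all(rank_subtypes(map)$n_significant == 0L))
  # PSD95-only restriction returns the 30 type-1/3 subtypes
  full <- data.frame(age = 7L, subregion = 1L,
                     parameter = paste0("subtype", 1:37),
                     significant = TRUE)
  expect_equal(nrow(rank_subtypes(full, psd95_only = TRUE)), 30L)
  expect_false(any(12:18 %in% rank_subtypes(full, psd95_only = TRUE)$subtype))
})

test_that("wave detection returns maximal contiguous windows", {
  ages <- c(1L, 7L, 14L, 21L, 28L, 35L, 42L, 49L, 56L)
  expect_equal(nrow(detect_waves(rep(0, 9), ages)), 0L)
  humped <- c(0, .6, .7, 0, 0, .5, .6, 0, 0)
  w <- detect_waves(humped, ages, threshold = 0.25)
  expect_equal(w$age_start, c(7L, 35L))
  expect_equal(w$age_end, c(14L, 42L))
  single <- c(0, 0, .9, 0, 0, 0, 0, 0, 0)
  w1 <- detect_waves(single, ages, threshold = 0.25)
  expect_equal(unlist(w1), c(age_start = 14L, age_end = 14L))
  expect_error(detect_waves(humped, ages, threshold = 1.5), "threshold")
})

test_that("an SPL-skewed cohort yields an SPL-dominant contrast map", {
  sch <- subtype_scheme()
  donors <- setdiff(1:37, sch$spl)
  wave <- wave_window(14, 14, subregions = 1:5, subtypes = sch$spl, d = 3,
                      mode = "shift", donors = donors)
  cfg <- cohort_config(n_subregions = 10L,
                       hierarchy = default_hierarchy(10L, 2L), ages = 14L,
                       n_control = 8L, n_mutant = 8L, seed = 61L,
                       wave_windows = list(wave))
  ch <- generate_cohort(cfg)
  pdfs <- function(subs) {
    lapply(1:10, function(r) {
      lapply(subs, function(s) {
        bayes_effectsize(ch$densities$mutant[, r, s, 1],
                         ch$densities$control[, r, s, 1], n_draws = 2000L,
                         seed = child_seed(62L, paste(r, s)))
      })
    })
  }
  res <- compare_spl_lpl(pdfs(sch$spl), pdfs(sch$lpl), seed = 63L)
  # red-dominant where injected, flat elsewhere
  expect_true(all(res$d_spl_lpl[1:5] > 0))
  expect_gte(mean(res$p_adj[1:5] < 0.05), 0.6)
  expect_lt(mean(abs(res$d_spl_lpl[6:10])), 0.6)
})
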