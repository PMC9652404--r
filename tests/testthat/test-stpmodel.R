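test_that("stimulation patterns have 20 pulses with the named timings", {
  for (nm in c("theta_burst", "theta_train", "gamma_burst", "gamma_train")) {
    pat <- make_pattern(nm)
    expect_length(pat$times, 20L)
    expect_true(all(diff(pat$times) > 0))
  }
  expect_equal(make_pattern("gamma_train")$times[2], 25)    # 1/40 Hz
  expect_equal(make_pattern("theta_train")$times[2], 200)   # 1/5 Hz
  tb <- make_pattern("theta_burst")
  expect_equal(sum(diff(tb$times) > 100), 3L)  # 4 bursts -> 3 long gaps
  expect_error(make_pattern("theta_burst", burst_onset_hz = 30),
               "overlapping")
  expect_error(make_pattern("theta_burst", n_bursts = 3L), "20 spikes")
})

test_that("single responses and closed-form plasticity cases are exact", {
  p <- synapse_params()
  one <- structure(list(name = "one", times = 0), class = "spike_pattern")
  res <- simulate_synapse(p, scaling_factors(), one)
  expect_equal(res$amplitudes, 1)
  expect_equal(res$A_td, 1)
  expect_equal(res$A_tf, 1)
  # depression only, gap = tau_d * ln 2 -> second amplitude 1 - A_d / 2
  # (tau_d chosen so the gap is a whole number of 1 ms steps)
  pd <- synapse_params(A_d0 = 0.5, tau_d0 = 100 / log(2), A_f0 = 0, A_s0 = 0)
  gap <- 100
  two <- structure(list(name = "two", times = c(0, gap)),
                   class = "spike_pattern")
  res2 <- simulate_synapse(pd, scaling_factors(), two)
  expect_equal(res2$A_td[2], 1 - 0.5 / 2)
  expect_equal(res2$amplitudes[2], 1 - 0.5 / 2, tolerance = 1e-6)
  # infinite gap -> full recovery
  far <- structure(list(name = "far", times = c(0, 1e5)),
                   class = "spike_pattern")
  res3 <- simulate_synapse(pd, scaling_factors(), far)
  expect_equal(res3$amplitudes[2], 1, tolerance = 1e-12)
  # unsorted pattern rejected
  bad <- structure(list(name = "bad", times = c(10, 0)),
                   class = "spike_pattern")
  expect_error(simulate_synapse(pd, scaling_factors(), bad), "increasing")
})

test_that("facilitation saturates at 3.3 and zero scaling removes plasticity", {
  pf <- synapse_params(A_f0 = 1, A_d0 = 0, A_s0 = 0)
  hf <- structure(list(name = "hf", times = seq(0, by = 10, length.out = 20)),
                  class = "spike_pattern")
  res <- simulate_synapse(pf, scaling_factors(), hf)
  expect_identical(max(res$A_tf), 3.3)
  expect_true(all(res$A_tf >= 1 & res$A_tf <= 3.3))
  # all spatial factors at 0 (slow facilitation disabled): unit responses
  p0 <- synapse_params(A_d0 = 0.5, A_f0 = 0.5, A_s0 = 0)
  res0 <- simulate_synapse(p0, scaling_factors(0, 0, 0, 0),
                           make_pattern("gamma_train"))
  expect_equal(res0$A_td, rep(1, 20))
  expect_equal(res0$A_tf, rep(1, 20))
  # responses equal the unit response up to the small superposed tail of
  # the preceding EPSP (exp(-25/3) of the peak at 40 Hz)
  expect_equal(res0$amplitudes, rep(1, 20), tolerance = 1e-3)
})

test_that("simulator invariants hold: bounds, translation, monotonicity", {
  pat <- make_pattern("theta_burst")
  set.seed(20)
  for (i in 1:10) {
    p <- synapse_params(A_d0 = runif(1, 0, 1), tau_d0 = runif(1, 50, 500),
                        A_f0 = runif(1, 0, 1.5), tau_f0 = runif(1, 50, 500),
                        A_s0 = runif(1, 0, 0.3), tau_s0 = runif(1, 500, 2000))
    sc <- scaling_factors(runif(1), runif(1), runif(1), runif(1))
    res <- simulate_synapse(p, sc, pat)
    expect_true(all(res$A_td >= 0 & res$A_td <= 1))
    expect_true(all(res$A_tf >= 1 & res$A_tf <= 3.3))
    # time translation by a multiple of dt leaves the response unchanged
    shifted <- structure(list(name = "s", times = pat$times + 100),
                         class = "spike_pattern")
    expect_equal(simulate_synapse(p, sc, shifted)$amplitudes,
                 res$amplitudes, tolerance = 1e-12)
    # monotonicity of the summed response in A_f0 (up) and A_d0 (down)
    p_f <- p; p_f$A_f0 <- p$A_f0 + 0.3
    p_d <- p; p_d$A_d0 <- min(1, p$A_d0 + 0.3)
    expect_gte(simulate_synapse(p_f, sc, pat)$summed + 1e-9, res$summed)
    expect_lte(simulate_synapse(p_d, sc, pat)$summed - 1e-9, res$summed)
  }
})

test_that("EPSP tail kinetics and dt refinement are faithful", {
  p <- synapse_params()
  e <- simulate_epsp(p, dt = 0.1, t_max = 30)
  fit <- lm(log(v) ~ t, data = e[e$t >= 10, ])
  expect_equal(-1 / unname(coef(fit)[2]), 3.0, tolerance = 0.02)
  # halving dt changes per-spike maxima by < 1%
  pat <- make_pattern("theta_burst")
  a1 <- simulate_synapse(p, scaling_factors(), pat)$raw_amplitudes
  p05 <- synapse_params(dt = 0.5)
  a05 <- simulate_synapse(p05, scaling_factors(), pat)$raw_amplitudes
  expect_lt(max(abs(a1 - a05) / a05), 0.01)
})

test_that("grid normalization and construction follow the layout contract", {
  expect_equal(synwaves:::geometric_mean(c(1, 4)), 2)
  g <- generate_intensity_grids(ages = c(1L, 56L), noise_cv = 0.04, seed = 23L)
  prof <- normalize_grids(g)
  # normalized per (protein, direction) jointly over ages/genotypes: [0, 1]
  for (pr in c("PSD95", "SAP102")) {
    for (dir in c("radial", "tangential")) {
      v <- prof$value[prof$protein == pr & prof$direction == dir]
      expect_equal(range(v), c(0, 1))
    }
  }
  expect_equal(sum(prof$direction == "radial" & prof$protein == "PSD95" &
                     prof$genotype == "control" & prof$age == 1L), 4L)
  expect_equal(sum(prof$direction == "tangential" & prof$protein == "PSD95" &
                     prof$genotype == "control" & prof$age == 1L), 10L)
  grid <- build_synapse_grid(prof[prof$genotype == "control" &
                                    prof$age == 1L, ])
  expect_equal(nrow(grid), 121L)
  expect_true(all(grid$S_Ad >= 0 & grid$S_Ad <= 1))
  # lattice corners carry the boundary-bin profile values
  rad <- prof[prof$protein == "PSD95" & prof$direction == "radial" &
                prof$genotype == "control" & prof$age == 1L, ]
  rad <- rad[order(rad$bin), ]
  corner <- grid[grid$radial_pos == 0 & grid$tangential_pos == 0, ]
  expect_equal(corner$S_Td, rad$value[1])
  # constant profiles give constant factors
  prof_const <- prof[prof$genotype == "control" & prof$age == 1L, ]
  prof_const$value <- 0.5
  gc <- build_synapse_grid(prof_const)
  expect_true(all(gc$S_Ad == 0.5 & gc$S_Tf == 0.5))
  expect_error(build_synapse_grid(prof_const[prof_const$protein == "PSD95", ]),
               "missing profile")
  g$intensity[1] <- 0
  expect_error(normalize_grids(g), "non-positive")
})

test_that("paired genotype comparison matches the closed form", {
  p <- synapse_params()
  pat <- make_pattern("gamma_train")
  g <- generate_intensity_grids(ages = 7L, genotype_effect = -0.3,
                                noise_cv = 0.04, seed = 24L)
  prof <- normalize_grids(g)
  grid_c <- build_synapse_grid(prof[prof$genotype == "control" & prof$age == 7L, ])
  grid_m <- build_synapse_grid(prof[prof$genotype == "mutant" & prof$age == 7L, ])
  rc <- simulate_grid(p, grid_c, pat)
  rm_ <- simulate_grid(p, grid_m, pat)
  cmp <- compare_genotypes(rc, rm_)
  oracle <- paired_t_oracle(rm_$summed, rc$summed)
  expect_equal(cmp$t, oracle$t, tolerance = 1e-10)
  expect_equal(cmp$p, oracle$p, tolerance = 1e-10)
  # identical inputs: t = 0, p = 1, degenerate flag
  same <- compare_genotypes(rc, rc)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)
  # consistent permutation of positions leaves the statistic unchanged
  perm <- sample(nrow(rc))
  cmp_p <- compare_genotypes(rc[perm, ], rm_[perm, ])
  expect_equal(cmp_p$t, cmp$t)
  # constant shift: zero-variance differences flagged as degenerate
  shifted <- rc; shifted$summed <- rc$summed + 1
  deg <- compare_genotypes(rc, shifted)
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)
})

test_that("free-parameter fitting is self-consistent and respects the frozen set", {
  true_p <- synapse_params(A_d0 = 0.15, tau_d0 = 180, A_f0 = 0.3,
                           tau_f0 = 120, A_s0 = 0.05, tau_s0 = 900)
  targets <- burst_amplitudes(true_p)
  start <- synapse_params(A_d0 = 0.05, tau_d0 = 120, A_f0 = 0.5,
                          tau_f0 = 120, A_s0 = 0.05, tau_s0 = 900)
  fit <- fit_free_params(targets, mode = "knockout", start = start)
  expect_lt(max(abs(fit$fitted - targets) / targets), 0.05)
  # knockout mode freezes the slow facilitation and tau_f0
  expect_equal(fit$params$A_s0, start$A_s0)
  expect_equal(fit$params$tau_s0, start$tau_s0)
  expect_equal(fit$params$tau_f0, start$tau_f0)
  expect_error(fit_free_params(targets[1], bursts = 1L), "at least 2")
  expect_error(fit_free_params(c(0, 0), bursts = c(1L, 2L)), "amplitude")
})
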