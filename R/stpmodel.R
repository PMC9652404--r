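#' Short-term plasticity model parameters
#'
#' Parameter bundle of the CA1 stratum radiatum synaptic-response model: one
#' depressing component (`A_d0`, `tau_d0`), one fast facilitating component
#' (`A_f0`, `tau_f0`), one slow facilitating component (`A_s0`, `tau_s0`),
#' the bi-exponential EPSP time constants `tau1 = 3.0 ms` and `tau2 = 0.4 ms`
#' (fast AMPA-type kinetics), the facilitation cap of 3.3 times the unit
#' response, and the 1 ms time discretization. The amplitude/time-constant
#' defaults are placeholders meant to be re-fit with [fit_free_params()];
#' they produce moderate depression and facilitation at theta-burst rates.
#'
#' @param A_d0,tau_d0 depression amplitude (unitless) and time constant (ms).
#' @param A_f0,tau_f0 fast facilitation amplitude and time constant (ms).
#' @param A_s0,tau_s0 slow facilitation amplitude and time constant (ms).
#' @param tau1,tau2 EPSP rise/decay constants (ms); `tau1 > tau2 > 0`.
#' @param cap facilitation saturation (3.3 times the unit response).
#' @param dt simulation time step (ms).
#' @return A list of class `synapse_params`.
#' @export
synapse_params <- function(A_d0 = 0.12, tau_d0 = 150, A_f0 = 0.25,
                           tau_f0 = 100, A_s0 = 0.06, tau_s0 = 800,
                           tau1 = 3.0, tau2 = 0.4, cap = 3.3, dt = 1) {
  stopifnot(tau1 > tau2, tau2 > 0, A_d0 >= 0, A_f0 >= 0, A_s0 >= 0,
            tau_d0 >= 0, tau_f0 >= 0, tau_s0 > 0, dt > 0)
  structure(list(A_d0 = A_d0, tau_d0 = tau_d0, A_f0 = A_f0, tau_f0 = tau_f0,
                 A_s0 = A_s0, tau_s0 = tau_s0, tau1 = tau1, tau2 = tau2,
                 cap = cap, dt = dt),
            class = "synapse_params")
}

#' Spatial scaling factors for one synapse position
#'
#' Normalized intensity factors in [0, 1] scaling the plasticity parameters:
#' `S_Ad` (tangential PSD95) scales the depression amplitude, `S_Td` (radial
#' PSD95) the depression time constant, `S_Af` (tangential SAP102) the fast
#' facilitation amplitude, and `S_Tf` (radial SAP102) its time constant.
#' The slow facilitation component is spatially uniform.
#'
#' @param S_Ad,S_Td,S_Af,S_Tf factors in [0, 1].
#' @return A list of class `scaling_factors`.
#' @export
scaling_factors <- function(S_Ad = 1, S_Td = 1, S_Af = 1, S_Tf = 1) {
  v <- c(S_Ad, S_Td, S_Af, S_Tf)
  if (any(v < 0 | v > 1)) stop("scaling factors must lie in [0, 1]")
  structure(list(S_Ad = S_Ad, S_Td = S_Td, S_Af = S_Af, S_Tf = S_Tf),
            class = "scaling_factors")
}

#' Stimulation spike patterns
#'
#' Named 20-pulse stimulation patterns used to probe temporal summation:
#' `theta_train` (20 spikes at 5 Hz), `gamma_train` (20 at 40 Hz),
#' `theta_burst` (4 bursts of 5 spikes at 100 Hz within bursts, burst onsets
#' at theta, 5 Hz) and `gamma_burst` (4 bursts of 5 spikes at 40 Hz within
#' bursts, onsets at 5 Hz). Exact timings are model conventions, exposed as
#' parameters.
#'
#' @param name pattern name.
#' @param n_spikes total stimulus pulses (20).
#' @param train_rate_hz spike rate of train patterns.
#' @param burst_rate_hz intra-burst spike rate of burst patterns.
#' @param burst_onset_hz burst onset rate of burst patterns.
#' @param n_bursts,spikes_per_burst burst layout (must give `n_spikes`).
#' @return A list of class `spike_pattern` with `name` and ascending
#'   `times` (ms).
#' @export
make_pattern <- function(name = c("theta_burst", "theta_train",
                                  "gamma_burst", "gamma_train"),
                         n_spikes = 20L,
                         train_rate_hz = NULL, burst_rate_hz = NULL,
                         burst_onset_hz = 5, n_bursts = 4L,
                         spikes_per_burst = 5L) {
  name <- match.arg(name)
  if (grepl("train$", name)) {
    rate <- if (!is.null(train_rate_hz)) train_rate_hz else
      if (name == "theta_train") 5 else 40
    times <- (seq_len(n_spikes) - 1) * 1000 / rate
  } else {
    rate <- if (!is.null(burst_rate_hz)) burst_rate_hz else
      if (name == "theta_burst") 100 else 40
    if (n_bursts * spikes_per_burst != n_spikes) {
      stop("burst layout must yield exactly ", n_spikes, " spikes")
    }
    onset_gap <- 1000 / burst_onset_hz
    burst_len <- (spikes_per_burst - 1) * 1000 / rate
    if (burst_len >= onset_gap) stop("overlapping bursts are not realizable")
    onsets <- (seq_len(n_bursts) - 1) * onset_gap
    times <- as.vector(outer((seq_len(spikes_per_burst) - 1) * 1000 / rate,
                             onsets, "+"))
  }
  times <- sort(times)
  if (any(diff(times) <= 0)) stop("spike times must be strictly increasing")
  structure(list(name = name, times = times), class = "spike_pattern")
}

# Per-spike plasticity factors A_td (total depression, in [0,1]) and A_tf
# (total facilitation, in [1, cap]) for a spike-time vector.
plasticity_factors <- function(params, scaling, times) {
  if (any(diff(times) <= 0)) stop("spike times must be strictly increasing")
  A_d <- params$A_d0 * scaling$S_Ad
  tau_d <- params$tau_d0 * scaling$S_Td
  A_f <- params$A_f0 * scaling$S_Af
  tau_f <- params$tau_f0 * scaling$S_Tf
  decay <- function(amp, tau, dts) {
    if (amp == 0 || length(dts) == 0) return(0)
    if (tau == 0) return(0)  # instantaneous recovery
    sum(amp * exp(-dts / tau))
  }
  n <- length(times)
  A_td <- numeric(n); A_tf <- numeric(n)
  for (i in seq_len(n)) {
    dts <- times[i] - times[seq_len(i - 1)]
    dep <- decay(A_d, tau_d, dts)
    fac <- decay(A_f, tau_f, dts) + decay(params$A_s0, params$tau_s0, dts)
    A_td[i] <- max(1 - dep, 0)
    A_tf[i] <- min(1 + fac, params$cap)
  }
  list(A_td = A_td, A_tf = A_tf, weight = A_td * A_tf)
}

#' Simulate the synaptic response of one synapse to a spike pattern
#'
#' Each presynaptic spike evokes a bi-exponential EPSP
#' `V = A_e (exp(-t/tau1) - exp(-t/tau2))` whose amplitude prefactor `A_e` is
#' the product of the total facilitation factor
#' `A_tf = min(1 + sum_j (A_fj + A_sj), cap)` and the total depression factor
#' `A_td = max(1 - sum_j A_dj, 0)` over all preceding spikes j, with
#' exponentially decaying per-spike contributions
#' `A_dj = A_d exp(-dt_j / tau_d)` (and analogously for the fast and slow
#' facilitation). EPSP traces superpose linearly; the response to spike i is
#' the maximum of the summed trace in the window from spike i to the next
#' spike (or to the end of the trace), normalized to the first response.
#' The summed response is the sum of the 20 normalized per-spike maxima.
#'
#' @param params a [synapse_params()].
#' @param scaling a [scaling_factors()].
#' @param pattern a [make_pattern()] spike pattern.
#' @param window_ms trace length after the last spike (ms).
#' @return A list of class `synapse_response`: `amplitudes` (normalized
#'   per-spike maxima, first = 1), `raw_amplitudes`, `summed` (sum of the
#'   normalized maxima), `A_td`, `A_tf`, `times`, and the voltage trace
#'   (`t`, `v`).
#' @export
simulate_synapse <- function(params, scaling = scaling_factors(),
                             pattern = make_pattern("theta_burst"),
                             window_ms = 50) {
  times <- pattern$times
  pf <- plasticity_factors(params, scaling, times)
  t_grid <- seq(0, max(times) + window_ms, by = params$dt)
  v <- numeric(length(t_grid))
  for (i in seq_along(times)) {
    tt <- t_grid - times[i]
    on <- tt >= 0
    v[on] <- v[on] + pf$weight[i] *
      (exp(-tt[on] / params$tau1) - exp(-tt[on] / params$tau2))
  }
  ends <- c(times[-1], max(t_grid))
  raw <- vapply(seq_along(times), function(i) {
    sel <- t_grid >= times[i] & t_grid <= ends[i]
    max(v[sel])
  }, numeric(1))
  if (raw[1] <= 0) stop("degenerate first response")
  structure(list(amplitudes = raw / raw[1], raw_amplitudes = raw,
                 summed = sum(raw / raw[1]),
                 A_td = pf$A_td, A_tf = pf$A_tf,
                 times = times, t = t_grid, v = v),
            class = "synapse_response")
}

#' Simulate a single unit EPSP waveform
#'
#' One spike at t = 0 with unit prefactor; used for kinetic checks (the tail
#' beyond ~10 ms decays with the slow constant `tau1`).
#'
#' @param params a [synapse_params()].
#' @param dt time step (ms); defaults to the params' step.
#' @param t_max trace length (ms).
#' @return Data frame with columns `t`, `v`.
#' @export
simulate_epsp <- function(params = synapse_params(), dt = params$dt,
                          t_max = 30) {
  t <- seq(0, t_max, by = dt)
  data.frame(t = t, v = exp(-t / params$tau1) - exp(-t / params$tau2))
}

#' Normalize intensity grids into spatial scaling profiles
#'
#' Reduces per-individual 4 radial x 10 tangential intensity grids to
#' normalized direction profiles: per (protein, genotype, age, bin) the
#' geometric mean over individuals is taken, the grid is averaged over the
#' other direction to give a 4-bin radial and a 10-bin tangential profile,
#' and each (protein, direction) family is normalized jointly over all ages,
#' genotypes and bins by subtracting the minimum and dividing by the span —
#' so relative intensity is comparable over all time points regardless of
#' genotype, and the extreme bins map exactly to 0 and 1.
#'
#' @param grids long data frame from [generate_intensity_grids()] (columns
#'   `protein`, `genotype`, `age`, `individual`, `radial`, `tangential`,
#'   `intensity`; intensities must be > 0).
#' @return Data frame with columns `protein`, `direction` (`"radial"` /
#'   `"tangential"`), `genotype`, `age`, `bin`, `value` (in [0, 1]).
#' @export
normalize_grids <- function(grids) {
  need <- c("protein", "genotype", "age", "individual", "radial",
            "tangential", "intensity")
  stopifnot(all(need %in% names(grids)))
  if (any(grids$intensity <= 0)) stop("non-positive intensity")
  gm <- stats::aggregate(intensity ~ protein + genotype + age + radial + tangential,
                         data = grids, FUN = geometric_mean)
  prof_rad <- stats::aggregate(intensity ~ protein + genotype + age + radial,
                               data = gm, FUN = mean)
  names(prof_rad)[names(prof_rad) == "radial"] <- "bin"
  prof_rad$direction <- "radial"
  prof_tan <- stats::aggregate(intensity ~ protein + genotype + age + tangential,
                               data = gm, FUN = mean)
  names(prof_tan)[names(prof_tan) == "tangential"] <- "bin"
  prof_tan$direction <- "tangential"
  prof <- rbind(prof_rad, prof_tan)
  out <- list()
  for (p in unique(prof$protein)) {
    for (dir in c("radial", "tangential")) {
      sel <- prof$protein == p & prof$direction == dir
      v <- prof$intensity[sel]
      span <- max(v) - min(v)
      if (span == 0) stop("zero span: degenerate normalization")
      block <- prof[sel, ]
      block$value <- (v - min(v)) / span
      out[[paste(p, dir)]] <- block
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("protein", "direction", "genotype", "age", "bin", "value")]
}

#' Build the 121-position synapse grid of scaling factors
#'
#' Interpolates the normalized 4-bin radial and 10-bin tangential profiles of
#' both proteins onto an 11 x 11 lattice (121 synapse positions) by separable
#' linear interpolation, clipping to [0, 1]. `S_Ad`/`S_Td` come from the
#' PSD95 tangential/radial profiles and `S_Af`/`S_Tf` from the SAP102
#' tangential/radial profiles.
#'
#' @param profiles output of [normalize_grids()] restricted to one genotype
#'   and age (or carrying exactly one of each).
#' @param n_lattice lattice side (11 gives the 121 default positions).
#' @return Data frame with 121 rows: `position`, `radial_pos`,
#'   `tangential_pos` (lattice coordinates in [0, 1]), `S_Ad`, `S_Td`,
#'   `S_Af`, `S_Tf`.
#' @export
build_synapse_grid <- function(profiles, n_lattice = 11L) {
  stopifnot(length(unique(profiles$genotype)) == 1L,
            length(unique(profiles$age)) == 1L)
  get_prof <- function(protein, direction) {
    sel <- profiles$protein == protein & profiles$direction == direction
    if (!any(sel)) stop("missing profile: ", protein, " ", direction)
    block <- profiles[sel, ]
    block$value[order(block$bin)]
  }
  interp <- function(vals) {
    x <- seq(0, 1, length.out = length(vals))
    pmin(1, pmax(0, stats::approx(x, vals, xout = seq(0, 1, length.out = n_lattice))$y))
  }
  psd_t <- interp(get_prof("PSD95", "tangential"))
  psd_r <- interp(get_prof("PSD95", "radial"))
  sap_t <- interp(get_prof("SAP102", "tangential"))
  sap_r <- interp(get_prof("SAP102", "radial"))
  grid <- expand.grid(radial_i = seq_len(n_lattice),
                      tangential_i = seq_len(n_lattice))
  data.frame(position = seq_len(nrow(grid)),
             radial_pos = (grid$radial_i - 1) / (n_lattice - 1),
             tangential_pos = (grid$tangential_i - 1) / (n_lattice - 1),
             S_Ad = psd_t[grid$tangential_i], S_Td = psd_r[grid$radial_i],
             S_Af = sap_t[grid$tangential_i], S_Tf = sap_r[grid$radial_i])
}

#' Simulate all grid positions for one pattern
#'
#' @param params a [synapse_params()].
#' @param grid a [build_synapse_grid()] data frame.
#' @param pattern a [make_pattern()].
#' @return Data frame with one row per position: `position`, `summed`
#'   (summed normalized response), plus a matrix attribute `"amplitudes"`
#'   (positions x spikes, normalized).
#' @export
simulate_grid <- function(params, grid, pattern) {
  n <- nrow(grid)
  summed <- numeric(n)
  amps <- matrix(NA_real_, n, length(pattern$times))
  for (i in seq_len(n)) {
    sc <- scaling_factors(grid$S_Ad[i], grid$S_Td[i],
                          grid$S_Af[i], grid$S_Tf[i])
    res <- simulate_synapse(params, sc, pattern)
    summed[i] <- res$summed
    amps[i, ] <- res$amplitudes
  }
  out <- data.frame(position = grid$position, summed = summed)
  attr(out, "amplitudes") <- amps
  out
}

#' Paired genotype comparison of grid responses
#'
#' Pairs the 121 per-position summed responses of control and mutant grids
#' and applies a paired t-test; families of comparisons (e.g. age x pattern)
#' are corrected together with Benjamini-Hochberg via
#' [adjust_comparisons()]. A zero-variance, nonzero difference vector is
#' degenerate and flagged (p = 0).
#'
#' @param control,mutant outputs of [simulate_grid()] on the same grid.
#' @return A one-row data frame: `mean_diff`, `t`, `p`, `degenerate`.
#' @export
compare_genotypes <- function(control, mutant) {
  stopifnot(nrow(control) == nrow(mutant),
            all(control$position == mutant$position))
  diffs <- mutant$summed - control$summed
  if (stats::sd(diffs) < 1e-12) {
    if (all(diffs == 0)) {
      return(data.frame(mean_diff = 0, t = 0, p = 1, degenerate = TRUE))
    }
    return(data.frame(mean_diff = mean(diffs), t = Inf * sign(mean(diffs)),
                      p = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(mutant$summed, control$summed, paired = TRUE)
  data.frame(mean_diff = mean(diffs), t = unname(tt$statistic),
             p = tt$p.value, degenerate = FALSE)
}

#' Benjamini-Hochberg adjustment over a family of grid comparisons
#'
#' @param comparisons data frame of stacked [compare_genotypes()] rows (plus
#'   any labelling columns).
#' @param alpha significance level.
#' @return The input with `p_adj` and `significant` columns appended.
#' @export
adjust_comparisons <- function(comparisons, alpha = 0.05) {
  comparisons$p_adj <- bh_adjust(comparisons$p)
  comparisons$significant <- comparisons$p_adj < alpha
  comparisons
}

#' Mean burst amplitudes of a theta-burst protocol
#'
#' Simulates a theta-burst protocol (default 10 bursts of 5 spikes, 100 Hz
#' within bursts, 5 Hz onsets) and returns the mean normalized per-spike
#' amplitude of the requested bursts — the quantity fitted against
#' experimental theta-burst data.
#'
#' @param params a [synapse_params()].
#' @param scaling a [scaling_factors()].
#' @param bursts burst indices to report (default 1, 2, 8, 10).
#' @param n_bursts,spikes_per_burst,intra_hz,onset_hz protocol layout.
#' @return Named numeric vector of mean normalized amplitudes per burst.
#' @export
burst_amplitudes <- function(params, scaling = scaling_factors(),
                             bursts = c(1L, 2L, 8L, 10L), n_bursts = 10L,
                             spikes_per_burst = 5L, intra_hz = 100,
                             onset_hz = 5) {
  onset_gap <- 1000 / onset_hz
  burst_len <- (spikes_per_burst - 1) * 1000 / intra_hz
  if (burst_len >= onset_gap) stop("overlapping bursts are not realizable")
  onsets <- (seq_len(n_bursts) - 1) * onset_gap
  times <- as.vector(outer((seq_len(spikes_per_burst) - 1) * 1000 / intra_hz,
                           onsets, "+"))
  pattern <- structure(list(name = "theta_burst_protocol", times = sort(times)),
                       class = "spike_pattern")
  res <- simulate_synapse(params, scaling, pattern)
  burst_of <- rep(seq_len(n_bursts), each = spikes_per_burst)
  stats::setNames(
    vapply(bursts, function(b) mean(res$amplitudes[burst_of == b]),
           numeric(1)),
    paste0("burst", bursts))
}

#' Fit free model parameters to theta-burst amplitude targets
#'
#' Bounded least squares of [burst_amplitudes()] against experimental burst
#' amplitude targets. In `"wildtype"` mode all six plasticity parameters
#' (`A_d0`, `tau_d0`, `A_f0`, `tau_f0`, `A_s0`, `tau_s0`) are free; in
#' `"knockout"` mode only `A_d0`, `tau_d0` and `A_f0` may change, the other
#' three stay frozen at their `start` values.
#'
#' @param targets named or plain numeric vector of burst amplitude targets
#'   (>= 2 bursts, all > 0).
#' @param bursts burst indices the targets correspond to.
#' @param mode `"wildtype"` or `"knockout"`.
#' @param start a [synapse_params()] providing starting values and the frozen
#'   parameters.
#' @param scaling a [scaling_factors()].
#' @return A list: `params` (fitted [synapse_params()]), `fit_error`
#'   (residual sum of squares), `fitted` (model burst amplitudes).
#' @export
fit_free_params <- function(targets, bursts = c(1L, 2L, 8L, 10L),
                            mode = c("wildtype", "knockout"),
                            start = synapse_params(),
                            scaling = scaling_factors()) {
  mode <- match.arg(mode)
  if (length(targets) < 2) stop("need at least 2 burst targets")
  if (any(targets <= 0)) stop("zero or negative amplitude targets")
  stopifnot(length(targets) == length(bursts))
  free <- if (mode == "wildtype") {
    c("A_d0", "tau_d0", "A_f0", "tau_f0", "A_s0", "tau_s0")
  } else c("A_d0", "tau_d0", "A_f0")
  lower <- c(A_d0 = 0, tau_d0 = 1, A_f0 = 0, tau_f0 = 1, A_s0 = 0, tau_s0 = 1)
  upper <- c(A_d0 = 1.5, tau_d0 = 5000, A_f0 = 3, tau_f0 = 5000,
             A_s0 = 3, tau_s0 = 10000)
  objective <- function(theta) {
    p <- start
    p[free] <- as.list(theta)
    model <- burst_amplitudes(p, scaling, bursts = bursts)
    sum((model - targets)^2)
  }
  theta0 <- unlist(start[free])
  fit <- stats::optim(theta0, objective, method = "L-BFGS-B",
                      lower = lower[free], upper = upper[free],
                      control = list(maxit = 500,
                                     parscale = pmax(abs(theta0), 0.05)))
  params <- start
  params[free] <- as.list(fit$par)
  list(params = params, fit_error = fit$value,
       fitted = burst_amplitudes(params, scaling, bursts = bursts))
}
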