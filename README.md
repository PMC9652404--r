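# synwaves

Statistics and simulation for developmental synaptome mapping: how does a
mutation reshape the brain-wide composition of excitatory synapses across
postnatal development, and what does that do to regional organization and
synaptic physiology?

The package is written for quantitative neurobiologists working with
synaptome maps — per-subregion densities of synapse types (defined by
PSD95/SAP102 expression) and subtypes (morphology) in two genotypes across
ages. It provides:

* **`synthdata`** — a seeded synthetic-cohort generator with known ground
  truth: 131 subregions in 12 main regions, 37 subtypes, nine ages, and
  configurable "phenotype waves" that perturb the mutant composition in
  age-windows while preserving total synapse density.
* **`puncta`** — classification of puncta into 3 types (channel
  thresholds) and 37 subtypes (nearest morphological centroid), and
  summaries into subregion density profiles.
* **`effectsize`** — Cohen's d with the pooled SD
  `d = (x̄₁ − x̄₂)/s`, `s² = ((n₁−1)s₁² + (n₂−1)s₂²)/(n₁+n₂−2)`; a
  Bayesian Monte-Carlo version (posterior of mean and SD per group under a
  t-distribution model, reported as the mode of the Cohen's d posterior
  with two-sided tail significance); Benjamini–Hochberg correction over
  subregions; the SPL-vs-LPL subtype contrast
  `d_SPL−LPL = (E[f_SPL] − E[f_LPL]) / sqrt((s²[f_SPL] + s²[f_LPL])/2)`;
  subtype ranking; wave detection.
* **`diversity`** — Shannon synapse diversity `H = −Σ pᵢ ln pᵢ` per
  animal × subregion with genotype contrasts.
* **`simnet`** — subregion similarity matrices (Pearson correlation of
  standardized subtype densities), the between/within main-region
  similarity ratio, top-k similarity graphs, and small-worldness
  `σ = (C/C_rand)/(L/L_rand)` against degree-preserving rewired
  references.
* **`stpmodel`** — a short-term-plasticity simulator of CA1 stratum
  radiatum: bi-exponential EPSPs (τ₁ = 3.0 ms, τ₂ = 0.4 ms) scaled by
  accumulated depression (floored at 0) and fast + slow facilitation
  (capped at 3.3 × the unit response), spatially scaled by normalized
  PSD95/SAP102 intensity gradients on a 121-position grid, driven by
  theta/gamma burst and train patterns, with paired-t genotype contrasts
  and free-parameter fitting.

The `analysis/` directory holds the numbered workflow drivers
(`01_simulate_cohort.R` … `06_stp_simulation.R`); each writes small summary
tables under `results/` (bulky intermediates go to `scratch/`).
`run_pipeline()` orchestrates the same stages programmatically with a
reproducibility manifest.

## Worked example

A two-wave cohort, its effect-size map and wave detection:

```r
library(synwaves)

cfg <- cohort_config(seed = 101L, wave_windows = list(
  wave_window(7, 21, subregions = 1:131, d = 2, mode = "homogenize"),
  wave_window(35, 42, subregions = 1:131, d = 2, mode = "homogenize")))
cohort <- generate_cohort(cfg)

map <- effectsize_map(cohort, level = "type", n_draws = 4000L, seed = 301L)
frac <- fraction_affected(map)
detect_waves(frac$fraction, frac$age, threshold = 0.25)
```

prints

```
 age_start age_end
         7      21
        35      42
```

with per-age affected fractions (from `fraction_affected`)

```
 age fraction
   1    0.000
   7    0.748
  14    0.702
  21    0.687
  28    0.000
  35    0.649
  42    0.695
  49    0.000
  56    0.000
```

i.e. roughly 70% of subregions carry a significant (BH-corrected, α = 0.05)
type-density phenotype inside the injected windows and none outside —
the two transient phenotype waves are recovered exactly. Running
`analysis/05_similarity_networks.R` on the same cohort shows the network
consequences: the mutant similarity ratio is significantly *above* control
only at in-wave ages (posterior-mode Cohen's d ≈ 17–31) and small-worldness
significantly *below* control only at in-wave ages (d ≈ −14 … −28), the
signature of transiently delayed regional differentiation.

The simulator's core facts, computed from scratch:

```r
p <- synapse_params(A_f0 = 1, A_d0 = 0, A_s0 = 0)
train <- structure(list(name = "hf", times = seq(0, 190, by = 10)),
                   class = "spike_pattern")
max(simulate_synapse(p, scaling_factors(), train)$A_tf)  # 3.3 (the cap)

e <- simulate_epsp(synapse_params(), dt = 0.1, t_max = 30)
-1 / coef(lm(log(v) ~ t, e[e$t >= 10, ]))[2]             # 3.0 ms tail decay
```

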