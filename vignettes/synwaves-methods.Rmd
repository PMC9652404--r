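---
title: "Models and methods behind synwaves"
author: "synwaves authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind synwaves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

synwaves implements the statistical and modeling machinery of developmental
synaptome mapping: synapse puncta carrying two postsynaptic marker channels
(PSD95, SAP102) are classified into 3 molecular types and 37 morphological
subtypes, their densities are summarized per brain subregion, and
mutant-vs-control cohorts are compared with Bayesian Monte-Carlo effect-size
maps, synapse-diversity maps, subregion similarity networks, and a
short-term-plasticity simulation of CA1 stratum radiatum responses. A
synthetic-cohort generator with known ground truth makes every stage
testable without imaging data. This vignette records the models, the
tunable parameters, and the design choices that were genuinely open.

# The synthetic cohort generator

The generator defines the study conditions. Defaults: 131 atlas subregions
partitioned into 12 near-equal main regions, nine postnatal ages (P1 and
weekly P7-P56), 8 animals per genotype per age, 37 subtypes, total puncta
density 1.0 per unit area per subregion, and a between-animal coefficient
of variation (CV) of 0.15. Group sizes of 8 and a CV of 0.15 are typical of
imaging cohorts in this field; the total density is an arbitrary unit since
every downstream statistic is scale-free or standardized.

**Baseline composition.** The per-subregion subtype proportions are not
published as a table anywhere, so the default baseline is a synthetic
log-linear model chosen to have the qualitative structure of a
differentiated brain: for subregion $r$,
$p_{r\cdot} \propto \exp(b + u_r v + m_{M(r)} + \varepsilon_r)$, with a
shared base $b$, a common "maturation" direction $v$ whose loading
$u_r \sim U(0.5, 1.5)$ is positive in every subregion, a main-region
deviation $m_{M(r)}$ (regional identity), and subregion jitter
$\varepsilon_r$. The softmax keeps proportions positive and summing to one.
The shared component (base + gradient) is retained so that perturbations
can selectively suppress regional identity. These vectors are arbitrary in
detail and flagged as such; all tests depend only on their statistical
structure, not particular values.

**Noise model.** Per-animal subtype densities are log-normal around the
group mean: densities are positive and biological noise is multiplicative.
The mutant group is drawn with the *control group's absolute SD*
($\sigma = \mathrm{CV} \cdot \mu_{\text{control}}$), so an injected mean
shift of $d\sigma$ has true pooled-SD Cohen's d of exactly $d$; letting the
mutant SD scale with its own mean would shrink the realized effect size by
up to 15% at $d = 2$ and make ground truth ambiguous.

**Phenotype waves.** A wave is an age-window perturbation of the mutant
composition that leaves the total density unchanged, mirroring the designed
null on synapse number. Two modes:

* `shift` — each affected subtype's mean gains $d\sigma$; the same total
  mass is removed from donor subtypes proportionally to their baseline
  (default donors: the type-2 subtypes, echoing a loss of SAP102-only
  synapses compensated by PSD95-expressing ones).
* `homogenize` — the composition is pulled toward its shared
  (region-identity-free) component with a weight calibrated so the mean
  absolute standardized subtype shift equals $d$. This is a
  delayed-differentiation phenotype: it raises between-region similarity
  while preserving the global gradient. A pull toward the grand-mean
  composition instead would be removed by the similarity standardization
  and leave the similarity ratio unchanged, which is why the shared
  component is the target.

Ground truth records $(\mu_m - \mu_c)/\sigma$ for every perturbed cell and
is empty outside the waves.

**What the generator does not emulate.** Real puncta images, spatial
autocorrelation between neighbouring subregions, age trends in the control
baseline, litter effects, and sex. Passing recovery tests therefore shows
the statistics are correct and calibrated under the stated noise model, not
that they are robust to every artifact of real imaging data.

# Puncta classification

Types follow the channel-expression rule (type 1 PSD95 only, type 2 SAP102
only, type 3 both) with detection thresholds as configuration values
(default 10 a.u. per channel) — detection itself belongs to the upstream
imaging pipeline. Subtypes are assigned by nearest centroid in
morphological feature space (size, circularity, aspect), features
standardized by robust z-score (median/MAD over the centroid table) because
size and shape live on different scales; Euclidean metric; ties break to
the lowest label. The published subtype boundaries are not available, so
the packaged centroid table (`inst/extdata/subtype_scheme_v1.json`) is a
synthetic, versioned stand-in with the correct type ranges and the SPL
(short protein lifetime: 6, 8, 11, 28, 29, 31) and LPL (2, 3, 5, 30, 34)
subtype sets.

# Bayesian effect-size estimation

The analytic effect size is Cohen's d with the pooled SD,
$d = (\bar x_1 - \bar x_2)/s$,
$s^2 = \frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2}$, mutant first.

The Bayesian estimate upscales each group by Monte Carlo under a normal
observation model with the noninformative reference prior: per group,
$\sigma^2 \mid x \sim (n-1)s^2/\chi^2_{n-1}$ and
$\mu \mid \sigma, x \sim N(\bar x, \sigma^2/n)$ — the marginal of $\mu$ is
the location-scale $t_{n-1}$, i.e. a t-distribution model for the inferred
mean and SD. Each joint draw gives a Cohen's d draw through the pooled SD.
The reported effect size is the mode of a Gaussian kernel density over the
draws (Silverman's rule bandwidth — "mode of a PDF" is undefined for raw
samples), and significance is the two-sided posterior tail mass
$P = 2\min(\Pr(d<0), \Pr(d>0))$. A full MCMC treatment with a Student-t
likelihood and weakly informative priors was considered and set aside: the
conjugate sampler is exact for the stated model, vectorizes to thousands of
map cells per second, and at the cohort's group sizes the two give
indistinguishable modes; robustness to gross outliers is not needed for
log-normal synthetic data. Draw counts: 20000 for single contrasts, 2000-
4000 inside maps (the mode's Monte-Carlo jitter averages out across cells
and replicates). Equal constant groups return $d = 0$, $P = 1$ rather than
an error; constant unequal groups are a genuine undefined-effect error.

BH correction is applied over all subregions within one age x parameter
family, and maps flag cells with adjusted $P < 0.05$.

The SPL-LPL contrast pools the posterior draws of the member subtypes into
$f_{\mathrm{SPL}}$ and $f_{\mathrm{LPL}}$ per subregion and reports
$d_{\mathrm{SPL-LPL}} = \frac{E[f_{\mathrm{SPL}}] - E[f_{\mathrm{LPL}}]}
{\sqrt{(s^2[f_{\mathrm{SPL}}] + s^2[f_{\mathrm{LPL}}])/2}}$ with
significance from the two-sided tail of the difference of (shuffled,
paired) draws. Because the PDF spreads include between-subtype
heterogeneity, this test is conservative: phenotypes spread evenly over
all subtypes do not register as SPL-dominant, only genuinely skewed ones
do.

Phenotype waves are detected as maximal contiguous age-windows in which
the fraction of significantly affected subregions exceeds a threshold
(default 0.25, far above the corrected false-positive rate and far below
the in-wave fractions of any detectable phenotype).

# Diversity

Synapse diversity is the Shannon entropy (nats) of a subtype composition,
$H = -\sum p_i \ln p_i$ with $0 \ln 0 = 0$, computed per animal x
subregion and contrasted between genotypes with the same Bayesian test and
BH family. $H$ is reported unnormalized (0 to $\ln 37 \approx 3.611$);
normalizing by $\ln 37$ would only rescale effect sizes. Note the
direction of a diversity phenotype depends on the perturbation: a
concentration wave (mass moved onto few subtypes) lowers $H$, whereas
homogenization toward the shared composition can raise it.

# Similarity networks

Per animal and age, the subregion x subtype density matrix is standardized
and each pair of subregions is scored by the Pearson correlation of their
feature vectors (bounded, symmetric, unit diagonal). Standardization is
*pooled*: each subtype density is z-scored over all animals, ages,
genotypes and subregions of the cohort. A per-matrix z-score across the
131 subregions would force the mean off-diagonal similarity toward
$-1/(n-1)$ regardless of how homogeneous the brain is, making the mean
similarity ratio insensitive to exactly the homogenization it is meant to
measure. (The generic per-matrix `standardize_parameters()` is still
exported for one-off matrices.)

The similarity ratio is the mean similarity of between-main-region pairs
divided by the mean of within-main-region pairs (off-diagonal only; means
rather than medians as the simplest aggregate; singleton main regions
contribute no within pairs). Graphs keep each subregion's top-k
similarities (k = 12 by default, one more than the largest default
main-region block so every node gains at least one between-region edge and
the graph stays connected; k is a parameter). Small-worldness is
$\sigma = (C/C_{\text{rand}})/(L/L_{\text{rand}})$ with C the average local
clustering coefficient, L the characteristic path length (largest
component, with a warning, if disconnected), and reference values averaged
over 20 degree-preserving rewirings ($10|E|$ double-edge swaps, seeded).
Group matrices are means of per-animal matrices; all genotype contrasts
run on per-animal statistics.

# The short-term-plasticity simulator

Each presynaptic spike evokes a bi-exponential EPSP
$V = A_e(e^{-t/\tau_1} - e^{-t/\tau_2})$ with $\tau_1 = 3.0$ ms,
$\tau_2 = 0.4$ ms (fast AMPA-type kinetics). The prefactor at spike $i$ is
the product of a total depression factor and a total facilitation factor
accumulated over all preceding spikes $j$ with gaps $\Delta t_j$:

$$A_{td,i} = \max\Big(1 - \sum_j A_d e^{-\Delta t_j/\tau_d},\, 0\Big),
\qquad
A_{tf,i} = \min\Big(1 + \sum_j \big(A_f e^{-\Delta t_j/\tau_f}
 + A_s e^{-\Delta t_j/\tau_s}\big),\, 3.3\Big)$$

with one depressing, one fast facilitating and one slow facilitating
component, the facilitation saturating at 3.3 times the unit response and
the depression floored at zero. (A literal reading of the depression
accumulation as $\sum_i (1 - A_{di})$ is internally inconsistent for more
than one preceding spike — it would exceed 1 — so the subtractive form
above, which matches the single-spike case and the stated positivity
limit, is implemented.) Traces superpose linearly; the response to spike
$i$ is the maximum of the summed trace between spike $i$ and the next
spike, normalized to the first response; the summed response of a pattern
is the sum of its 20 normalized maxima. Time is discretized at 1 ms
(0.1 ms for kinetic checks); halving the step moves per-spike maxima by
under 1%.

**Spatial scaling.** Intensity grids (4 radial x 10 tangential bins of
CA1sr, per individual) are reduced by geometric means over individuals
(control N = 5, mutant N = 4), averaged along the other direction into
radial and tangential profiles, and normalized per protein and direction
by the minimum and span over *all* ages and genotypes jointly, so relative
intensity is comparable across the whole design. The profiles are
interpolated onto an 11 x 11 lattice — 121 synapse positions — and scale
the parameters as $A_d = A_{d0} S_{Ad}$ (tangential PSD95),
$\tau_d = \tau_{d0} S_{Td}$ (radial PSD95), $A_f = A_{f0} S_{Af}$
(tangential SAP102), $\tau_f = \tau_{f0} S_{Tf}$ (radial SAP102); the slow
facilitation is spatially uniform. The lattice size realizes the
121-response grid; the separable linear interpolation is the simplest
scheme consistent with it.

**Stimulation patterns.** Four named 20-pulse patterns: theta train (5 Hz),
gamma train (40 Hz), theta burst (4 x 5 spikes at 100 Hz, onsets at 5 Hz)
and gamma burst (4 x 5 spikes at 40 Hz, onsets at 5 Hz — gamma-frequency
bursts nested in a theta rhythm; a 100 Hz burst at 40 Hz onsets would
overlap itself and is rejected as non-realizable). Exact timings are model
conventions exposed as parameters.

**Free parameters and fitting.** $A_{d0}, \tau_{d0}, A_{f0}, \tau_{f0},
A_{s0}, \tau_{s0}$ default to moderate values ($0.12, 150, 0.25, 100,
0.06, 800$; ms for time constants) that neither floor nor saturate a
theta-burst response — they are placeholders meant to be re-fit against
experimental burst amplitudes with `fit_free_params()` (bounded L-BFGS-B
on mean burst amplitudes of a 10-cycle theta-burst protocol, bursts 1, 2,
8 and 10; in knockout mode only $A_{d0}, \tau_{d0}, A_{f0}$ move). With
four targets and up to six parameters the fit is underdetermined in
parameters but self-consistent in amplitudes, which is what the round-trip
test asserts.

**Genotype comparison.** Summed responses of the two genotypes' grids are
compared position-by-position with a paired t-test, BH-corrected over the
age x pattern family of a run (the family choice is a run-level
convention). Zero-variance difference vectors are flagged degenerate: all
zeros gives $t = 0, P = 1$; a constant nonzero shift is reported
significant-degenerate rather than through a t-test.

# Numerical conventions and degenerate inputs

Empty sums (first spike) give $A_{td} = A_{tf} = 1$. $\tau_d = 0$ or
$\tau_f = 0$ (zero radial scaling) means instantaneous recovery, i.e. no
accumulated depression/facilitation. Proportions are renormalized within
1e-6 before entropy; the all-zero composition is an error. Constant
feature columns are dropped from standardization with a message. Every
random stage takes a named child stream derived from one master seed, so
stages are independently reproducible and adding draws to one stage never
perturbs another.

# Problem sizes

The packaged analyses and tests run at the study's own scale where that is
cheap (131 subregions, 9 ages, 8 + 8 animals; 121 synapse positions; all
four patterns) and at reduced scale where a property needs replication:
effect-size recovery and false-positive calibration use 200 replicate
cohorts at n = 8 per group with 2000 posterior draws per contrast, and the
simulator invariant suite uses a 100-point random parameter lattice.
These sizes give the recovery averages a Monte-Carlo error well below the
tolerances they are tested against.

# Known limitations

* The subtype centroids, baseline compositions and intensity surfaces are
  synthetic stand-ins; analyses of real cohorts must supply their own
  scheme, hierarchy and grids.
* The nearest-centroid subtype rule is a transparent approximation to the
  published ensemble classifier.
* The similarity ratio's absolute level depends on the standardization
  reference; only contrasts between genotypes under the same reference are
  interpretable.
* The plasticity model is phenomenological: no dendritic morphology, no
  NMDA or voltage-gated conductances, no vesicle-pool bookkeeping beyond
  the three exponential components.
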