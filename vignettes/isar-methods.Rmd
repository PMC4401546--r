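---
title: "Individual species-area relationships: models, null models, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual species-area relationships: models, null models, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isarr)
```

## The statistic

For a mapped community (every stem with species code, planar coordinates
in metres, DBH in cm) the individual species-area relationship of a target
species $t$ is

$$\mathrm{ISAR}_t(r) \;=\; \sum_{j \neq t} D_{tj}(r),$$

where $D_{tj}(r)$ is the proportion of individuals of $t$ whose nearest
individual of species $j$ lies within distance $r$. Equivalently it is the
mean, over the individuals of $t$, of the number of distinct heterospecific
species found in the closed disc of radius $r$ around each individual —
`isar_curve()` exploits this identity, summing integer disc counts and
dividing once, so the result is exact and the unit tests can demand
bitwise agreement with a brute-force per-disc census.

Conventions, all deliberate:

* distances are planar Euclidean; "within $r$" means $\le r$ (closed disc);
* duplicate coordinates are legal and count at every radius;
* **no edge correction**. The bivariate patterns involved need not be
  homogeneous, which breaks the assumptions of standard corrections; and
  since observed and simulated curves are computed with the same rule, the
  small border bias cancels in the comparison;
* conspecifics never contribute, by the $j \neq t$ in the definition;
* the default radius grid is $1, 2, \dots, 50$ m in 1 m steps.

The curve is non-decreasing in $r$ and bounded by $S - 1$; both properties
are tested, along with permutation invariance over stem order and
insensitivity to species entirely farther than $\max(r)$ from every
target.

## Null models

**Homogeneous Poisson.** `simulate_homogeneous()` redraws the target
individuals i.i.d. uniformly over the window; every other stem is kept
bit-identical. Comparing the observed ISAR against this ensemble asks
whether the species occupies neighbourhoods richer or poorer than the
plot-average species-area relationship — habitat effects included.

**Heterogeneous Poisson.** `estimate_intensity()` builds a kernel estimate
$\lambda_t(x)$ of the target's spatially varying intensity; the null
relocates the $n_t$ individuals by independent draws from the normalised
surface (cells with probability proportional to their mass, uniform within
a cell), conditioned on $n_t$. The kernel is Epanechnikov,
$k_R(d) \propto \max(0, 1 - (d/R)^2)$ — the standard distance-weighted
moving window of this literature — with $R = 50$ m by default, on a 5 m
cell grid. Two readings of "local redistribution within a maximum radius"
circulate: per-individual displacement within $R$, or sampling from a
kernel intensity with bandwidth $R$. We implement the latter; it is the
one defined by a kernel-estimated intensity function, and the bandwidth
plays exactly the role of the maximum redistribution radius. Both kernel
and bandwidth are configurable, and `bandwidth_sweep()` quantifies label
stability across radii (e.g. 30/50/70 m).

Edge handling: the raw kernel sum loses mass near borders, so the surface
is renormalised to total mass $n_t$ inside the window (verified to
relative tolerance $10^{-9}$). Cell size defaults to 5 m; halving it must
not change conclusions, which the bandwidth/cell sensitivity tests cover.
The surface can also be supplied explicitly (`run_null_ensemble(surface =
...)`); `flat_intensity()` gives the constant surface under which the
heterogeneous null provably reduces to the homogeneous one — a tested
reduction property.

The interpretation of the heterogeneous null rests on **separation of
scales**: habitat association is assumed to act above the bandwidth
($> 50$ m), individual interactions below it. Structure between those
scales is attributed to interactions by construction; this is an
assumption, not a finding, and the bandwidth sweep is the diagnostic we
offer for it.

## Inference

For each species an ensemble of 199 simulated curves plus the observed one
(index 0) is built by `run_null_ensemble()`.

*Pointwise envelopes* (`pointwise_envelope()`) take, at each radius, the
5th-smallest and 5th-largest simulated value — the two-sided 95% quantile
band conventional for 199 simulations; the order-statistic rank $k$ is
configurable. Envelopes are display and per-radius diagnostics, not the
formal test.

*Goodness-of-fit rank test* (`gof_rank_test()`): the accumulated squared
deviation $u_i = \sum_{r \in [r_\min, r_\max]} (\hat H_i(r) - \bar
H_i(r))^2$, with $\bar H_i$ the mean of all *other* curves (leave-one-out),
is computed for all $i$; the observed $u_0$ is ranked ascending among the
200 values and the departure is significant at $\alpha$ when the rank
exceeds $(1-\alpha)(n_{\mathrm{sim}}+1)$ — exactly 190 for $\alpha = 0.05$
and 199 simulations. Pooling over the five intervals 1–10, 11–20, 21–30,
31–40, 41–50 m is the device that controls Type I inflation from testing
50 radii; no further multiple-testing correction is applied across species
or intervals. Ties in $u$ give the observed statistic the smallest rank of
its tie group (conservative). Since $u$ is sign-blind, the direction of a
significant departure is the sign of the raw deviation summed over the
interval; a significant result with exactly zero summed deviation is
reported as an error rather than silently labelled.

Labels per (species, interval): under the homogeneous model
positive/negative/none ("deviation from SAR"); under the heterogeneous
model accumulator/repeller/no-effect. `summarize_classifications()`
produces the count/proportion table per (model, interval, label) and the
abundance-rank-by-interval table.

Because the observed pattern is exchangeable with its own relocations when
the data really follow the null, the rank test is exact by construction.
`null_calibration()` verifies this empirically: over 200 independent CSR
communities the rejection rate at $\alpha = 0.05$ and the envelope
containment at a fixed radius must fall inside the exact binomial 99%
bands around 0.05 and 0.95. This is what `scripts/acceptance.R`
recomputes.

## Size and abundance analyses

`stratify_by_size()` splits stems at 10 cm DBH; a stem of exactly 10 cm is
a sapling — the sapling interval 1–10 cm is read as closed, matching the
adult definition "above 10 cm". Target species are those with strictly
more than 50 **adults**; the abundance filter is counted on adults because
targets are adult individuals of major species (configurable via
`count_on = "all"`). Abundance ranks break ties by lexicographic species
code so reports are deterministic. The `large_large` mode uses adult
targets and adult neighbours; `large_small` pairs adult targets with
heterospecific sapling neighbours.

## The synthetic generator

The generator exists so every inference stage can be checked against known
ground truth; its defaults emulate a large mapped census: a 500 × 500 m
(25 ha) window, on the order of 100 species with abundances from tens to
thousands, and an expected adult share (DBH > 10 cm) of 0.16, echoing the
adult fraction of a typical stem-mapped forest plot. DBH marks are a
mixture: with probability `adult_fraction` a stem is an adult at $10 + X$,
$X \sim$ lognormal(2, 0.8) (median excess ≈ 7 cm); otherwise uniform on
[1, 10] cm — so the expected adult share equals `adult_fraction` exactly
and every mark respects the 1 cm census threshold.

* `gen_csr_community()`: every species i.i.d. uniform, exact counts — the
  null case.
* `gen_habitat_community()`: intensity $\propto \exp(\beta_s \,
  z(x, y))$ with $z$ a standardised sum of three Gaussian bumps of 100 m
  length scale (configurable) — structure deliberately placed well above
  the 50 m separation scale, so the heterogeneous null should absorb it
  while the homogeneous null flags it. $\beta_s = 0$ reduces exactly to
  CSR. Sampling is by rejection from the log-linear intensity.
* `gen_interaction_overlay()`: constructed ground truth at a known
  distance. Accumulators add `round(strength * n_t)` heterospecific
  recruits uniformly within `d_int` of randomly chosen target individuals
  — recruit seeding around targets (the mechanism invoked by
  distance-dependent natural-enemy hypotheses) rather than moving targets
  into rich areas, because it creates signal at a controlled distance and
  so yields a crisp recovery test. Recruit species are drawn uniformly
  from the non-target species to avoid confounding with abundance rank.
  Repellers delete each heterospecific stem within `d_int` of any target
  with probability `strength`; at `strength = 1` the neighbourhood is
  emptied completely.

What the generator does **not** emulate: demographic (birth–death)
dynamics, dispersal limitation, within-species clustering from
reproduction, typhoon-disturbance mechanisms, or realistic species
abundance distributions. Passing tests therefore demonstrate that the
machinery detects the structures it claims to detect at the stated scales
— not that any particular field community behaves this way.

## Randomness and determinism

One master seed governs a run. Every (species, simulation index) pair —
and every generator stage — derives its own substream seed by
deterministic integer mixing (kept below $2^{31}$), so per-species
computations can execute in any order and still reproduce bit-identically;
the pipeline manifest (seed, parameters, version) makes every table
regenerable. Two runs of `run_pipeline()` with the same config and seed
produce byte-identical CSVs, which is tested.

## Problem sizes used in validation

The calibration experiment uses 200 replicate CSR communities of 10
species × 60 stems on 200 × 200 m with 199 simulations each; recovery
experiments use 50 seeded replicates per interaction type (accumulator:
`d_int` 10 m, 3 recruits per target; repeller: `strength` 1) and 20
replicates for the habitat-contrast and flat-surface-reduction checks.
These sizes give exact-binomial power to detect miscalibration while
keeping the full suite inside a coffee break on a single CPU.

## Known limitations

* The heterogeneous null's attribution of small-scale departures to
  interactions inherits the separation-of-scales assumption wholesale;
  small-scale habitat variation (microsites) is indistinguishable from
  interaction signal.
* Kernel form and sampling mechanism are one defensible reading of
  "local redistribution"; per-individual displacement kernels would
  couple relocation to each source point rather than to the pooled
  intensity.
* No torus-translation or Gibbs-process alternatives, no pair-correlation
  or K-function machinery, no 3-D coordinates, no multi-census change
  analysis.
* The GoF direction rule resolves mixed-sign intervals by the summed
  deviation; a species that accumulates at 3 m and repels at 8 m within
  one interval is labelled by the net effect.
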