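---
title: "Methods: gamma-band network topology, wiring cost, and ictogenicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gamma-band network topology, wiring cost, and ictogenicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammanet)
```

`gammanet` analyzes gamma-band (25–80 Hz) functional networks recorded with
skull-surface multielectrode EEG arrays, of the kind used in preclinical
blast-injury studies with a 2 × 2 between-subjects design (injury group ×
post-injury timepoint). This vignette explains the models implemented, the
parameters that matter, the synthetic-data generator the test-suite runs
on, and the numerical decisions taken where the published methodology left
the choice open.

## Connectivity: the debiased weighted phase-lag index

Functional coupling between electrode pairs is estimated with the debiased
weighted phase-lag index (dwPLI). Recordings are cut into 3-s epochs;
within each epoch, Hamming-tapered Welch segments of 1.5 s with 50%
overlap provide complex cross-spectral densities per pair and frequency
bin (resolution 1/1.5 Hz). With imaginary parts $I_k$ over segments $k$,

$$\widehat{\mathrm{dwPLI}} =
  \frac{(\sum_k I_k)^2 - \sum_k I_k^2}
       {(\sum_k |I_k|)^2 - \sum_k I_k^2}.$$

Because only the imaginary cross-spectrum enters, zero-phase coupling —
the signature of volume conduction at the sensor level — is discarded.
Band values are per-pair means over bins whose center lies in the band
(inclusive).

Numerical decisions:

* Segments are pooled across epochs into one set per pair. Per-epoch
  averaging is available conceptually but pooling gives a more stable
  estimator at equal data; the estimator is consistent either way.
* The estimator targets a *squared* index and can go negative around zero
  coupling; negatives are clipped to 0 so graph algorithms downstream see
  non-negative weights.
* A zero denominator (no lagged signal at all, e.g. identical channels)
  yields 0, not a missing value: the metric's own reading is "no
  detectable lagged coupling".

## Topology against equivalent null models

Weighted clustering uses the Onnela coefficient with weights normalized by
the network maximum; nodes of degree < 2 contribute 0. Path lengths are
Dijkstra geodesics on inverse weights (a strong edge is a short
communication distance); the characteristic length $L$ is the mean over
ordered pairs, infinite (and flagged) when the network is disconnected.

Small-world propensity locates the network between two nulls that preserve
the empirical weight multiset — important when groups differ in overall
connectivity strength:

* the *equivalent regular* network lays the sorted weights along
  ring-lattice subdiagonal offsets $1, 2, \dots$ (deterministic, stable
  ties), and
* the *equivalent random* ensemble (default 100 draws) permutes the weight
  multiset uniformly over node pairs.

$$\Delta_C = \frac{C_{reg} - C_{obs}}{C_{reg} - C_{rand}}, \quad
  \Delta_L = \frac{L_{obs} - L_{rand}}{L_{reg} - L_{rand}}, \quad
  \mathrm{SWP} = 1 - \sqrt{\tfrac{\Delta_C^2 + \Delta_L^2}{2}}.$$

Both deviations are clamped to $[0, 1]$ *before* combining, so SWP stays
in $[0, 1]$ even when the observed value falls outside its null bracket;
degenerate brackets (regular = random, e.g. constant weights) set the
deviation to 0 with a warning rather than dividing by zero. Betweenness
(Brandes, fractional credit across tied geodesics, inverse-weight lengths)
is reported raw and normalized by the mean over random nulls; eigenvector
centrality is the non-negative principal eigenvector at unit Euclidean
norm, computed on the largest component when disconnected.

The weighted rich-club coefficient at richness level $k$ removes nodes of
degree ≤ $k$ and divides the surviving weight by the sum of the equally
many strongest weights anywhere in the network; normalization divides by
the mean over degree- and connectedness-preserving weighted rewirings
(edge swaps carrying their weights, redrawn if a draw disconnects).
Richness levels with fewer than two survivors, or without a valid null
mean, are reported missing rather than imputed. Because near-complete
dwPLI networks have no degree variation, `rich_club()` exposes an optional
proportional threshold (pipeline default: strongest 50% of edges) as a
sensitivity device — it is a choice of lens, not a claim about how degree
variation arises in real recordings.

## Normalized wiring cost (TEWC) and cost-efficiency

The raw spatial cost of a network over an electrode layout is
$C = \sum_{i<j} d_{ij} w_{ij}$ (distances in mm). Raw cost confounds
spatial arrangement with overall connectivity strength, so the package's
central metric normalizes it by the attainable extremes under weight
rearrangement: by the rearrangement inequality, the minimum cost pairs the
largest weights with the shortest distances and the maximum pairs them
sorted concordantly, each a single sort,

$$\mathrm{TEWC} = \frac{C_{obs} - C_{min}}{C_{max} - C_{min}} \in [0, 1].$$

Decisions: all $N(N-1)/2$ pairs, including zero-weight pairs, occupy
arrangement slots, so the weight multiset matches the connectome exactly
(zeros never change $C_{obs}$ but widen the attainable range — the
"resource allocation over fixed distances" reading). A degenerate range
($C_{max} = C_{min}$, e.g. constant weights) returns a missing value with
a warning: any imputed number would silently bias group comparisons. Ties
in weights or distances cannot change the bounds (any tie permutation has
the same dot product), so a stable sort suffices. When electrodes were
dropped for a subject, distances are recomputed on the retained subset.

Segregative and integrative cost-efficiency combine TEWC with the SWP
deviations in the same functional form:
$\mathrm{SCE} = 1 - \sqrt{(\Delta_C^2 + \mathrm{TEWC}^2)/2}$,
$\mathrm{ICE} = 1 - \sqrt{(\Delta_L^2 + \mathrm{TEWC}^2)/2}$.

## Theta-model ictogenicity

Each electrode becomes a theta neuron coupled through the (statically
max-scaled) connectome $A$:

$$\dot\theta_j = 1 - \cos\theta_j + (1 + \cos\theta_j)\, I_j, \qquad
  I_j = I_0 + \sigma \xi_j + \frac{K}{N} \sum_{i \neq j} a_{ij}
        \left[1 - \cos(\theta_i - \theta_s)\right],$$

with resting phase $\theta_s = -\mathrm{Re}\,\arccos\!\big(\tfrac{1 +
I_0}{1 - I_0}\big)$, where all phases start. Defaults follow the published
simulation study: $I_0$ swept over $[-1.7, -0.5]$ in 40 steps, $K = 10$,
$\sigma = 6$, $\delta t = 10^{-2}$, $4 \times 10^6$ steps, 5 repetitions.
Integration is Euler–Maruyama with Gaussian increments of standard
deviation $\sigma\sqrt{\delta t}$ entering through the same
$(1 + \cos\theta)$ gain as the deterministic input.

* **Ictal classification.** No published criterion is stated, so a node is
  ictal at a sample when $1 - \cos(\theta - \theta_s) > h$ with default
  $h = 1$ (more than 90° from rest, i.e. out of the fixed-point
  neighbourhood); the threshold is exposed. A consequence worth knowing:
  a freely rotating node is ictal only for the part of each cycle spent
  away from rest (≈ 0.4 at $I_0 = 0.5$), so $P_{sz}$ saturates below 1.
* **No burn-in** is discarded by default (trajectories start at rest);
  configurable.
* **BNI** is the trapezoidal integral of $P_{sz}(I_0)$ divided by the
  sweep range, bounding it in $[0, 1]$ and making it comparable across
  sweep configurations. Repetitions are averaged before integration
  (linear operations commute; only the variance bookkeeping differs).
* **NI** reruns the full sweep with each node removed ($N$ decremented,
  the scaling divisor kept from the intact network) and reports
  $(\mathrm{BNI}_{pre} - \mathrm{BNI}_{post,i})/\mathrm{BNI}_{pre}$.
  Repetition seed streams are shared across removals to reduce comparison
  variance (switchable by seeding). For $I_0 \geq 1$ the arccos argument
  leaves $[-1, 1]$ and the real-part convention applies ($\theta_s = 0$
  above $+1$, $-\pi$ below $-1$); such sweeps are flagged.
* The simulation-step default follows the published parameter table
  ($4 \times 10^6$); the accompanying text mentions $6 \times 10^6$, and
  both are reachable via `theta_params(n_steps=)`.

The two stochastic integrators (theta network, recording generator) are
implemented in C++ (Rcpp) with R's RNG, so `set.seed()` governs them and
identical seeds give bit-identical trajectories.

## Evoked potentials

`preprocess_epochs()` band-pass filters 3–300 Hz (zero-phase 4th-order
Butterworth), epochs −50 to 400 ms around stimulus onsets, drops epochs
whose raw trace exceeds 400 µV anywhere, averages, and subtracts the
prestimulus mean (baseline correction is not part of the published
description; it is on by default here for robustness to synthetic drift
and switchable). `detect_n1()` takes the largest-magnitude negative local
extremum in 15–100 ms post-stimulus, ties broken by earlier latency, with
an explicit `found` flag instead of a fabricated peak. Results are exported
per channel; aggregation across channels is left to the statistics layer.

## Permutation statistics

`perm_anova2()` computes two-way F statistics (Type II sums of squares via
QR projections, so unbalanced cells are handled) and permutes raw
observations (Manly) by default — exact under the global null and robust
to the heteroscedasticity a between-subjects injury design is expected to
show; a Freedman–Lane residual scheme is available. P-values include the
observed statistic, $(1 + \#\{F^\ast \ge F\})/(1 + B)$, so the smallest
attainable value is $1/(B+1)$. `perm_ttest2()` pairs the Welch statistic
with label-shuffling p-values and a Welch-t confidence interval.
`cohort_stats()` runs the three contrasts of interest (blast vs sham at
each timepoint, blast 1 vs 3 months) only when the interaction is
significant, Bonferroni-corrected over the family of three; curves over a
parameterized axis (richness, excitability) call for Benjamini–Hochberg
instead. `spearman_ci()` adds a percentile bootstrap interval (default
10,000 resamples).

## The synthetic-data generator

No recordings are deposited with the study this package operationalizes,
so every downstream stage is validated on synthetic data with planted
ground truth.

* **Layout**: a 4 × 8 grid spanning 11.7 × 9.6 mm (minimum spacing
  1.37 mm ≥ the hardware's 1.2 mm). The true array arrangement is not
  published; the grid is a geometric reconstruction from span and spacing.
* **Recordings** are stochastic phase oscillators about a carrier (default
  40 Hz, mid-gamma): coupled pairs are pulled toward fixed target lags
  drawn from 30–150° — away from the 0°/180° blind spots of phase-lag
  estimators — with Wiener phase noise and additive measurement noise.
  The defaults (`phase_noise_sd = 12` rad/√s, `pull = 25` rad/s) place the
  network in a weak-coupling regime: this is deliberate, because strong
  pulling globally synchronizes the network and indirect (two-step)
  coupling then swamps the planted pairwise ordering that recovery tests
  rely on.
* **Connectome families**: `lattice` (its own equivalent-regular null),
  `random` (its own random null in expectation), `small_world` (lattice
  with 10% of weight slots relocated), `rich_club` (a hub quarter of the
  nodes carrying the strongest mutual weights over a sparse background, so
  degree and weight concentration covary as a rich club requires).
* **Cohorts**: per-subject edge weights are allocated to electrode pairs
  by a biased greedy rule — with probability $b$ the next-largest weight
  goes to the farthest remaining pair, else to a uniform one — so expected
  TEWC increases monotonically in $b$ ($b = 1$ attains the maximum-cost
  arrangement, $b = 0$ sits near 0.5). Defaults plant the study's
  qualitative pattern: $b = 0.15$ for blast at 1 month, $0.5$ elsewhere,
  with cell sizes 13/20/8/9 and a modest (×1.15) blast connectivity
  scaling. The weight-gain covariate rank-matches Gaussian noise to the
  realized TEWC through a Gaussian copula (normal scores standardized to
  counteract small-sample under-dispersion), targeting Spearman −0.52 in
  blast and +0.71 in sham.

What the generator does **not** emulate: volume conduction beyond zero-lag
mixing tests, 1/f background spectra, non-stationarity, electrode
impedance drift, or any biophysical forward model. Passing tests therefore
demonstrate correctness of the estimators and the planted-effect recovery
machinery, not performance on real tissue.

## Problem sizes and reproducibility

The test-suite and the acceptance script run "desk-scale" versions of
every analysis, chosen so a full run completes in minutes on one CPU:
16-node cohorts of 6–10 subjects per cell, 20–100 null networks,
$5\times10^4$–$2\times10^5$ integration steps with 2–3 repetitions and
8–20 sweep values, and 299–1999 permutations. The full published scales
(32 nodes, 100 nulls, $4\times10^6$ steps × 5 repetitions × 40 sweep
values, 10,000 permutations) are the package defaults for real analyses.
Every random stage takes a seed derived from one master seed, and
`run_pipeline()` writes a provenance log (configuration hash, per-stage
seeds); reruns with the same configuration are byte-identical.

## Known limitations

* The rich-club richness sweep on dense dwPLI networks requires a
  thresholding choice; conclusions should be checked across thresholds.
* NI is undefined when the intact-network BNI is 0 (flagged, not imputed).
* Permutation ANOVA p-values are granular at $1/(B+1)$; post-hoc families
  at very small cell sizes have a bounded smallest attainable p-value
  because only a few label splits exist.
* The AEP module models a single N1-like component; later components are
  out of scope.
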