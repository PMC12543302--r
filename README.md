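# gammanet

Analysis of gamma-band (25–80 Hz) EEG functional networks from
multielectrode skull-surface recordings, built for preclinical injury
studies with a 2 × 2 between-subjects design (injury group × post-injury
timepoint). The package estimates phase-based connectomes, characterizes
their topology against strength-preserving null models, quantifies
spatially embedded wiring cost with a normalized metric, simulates
network seizure propensity, extracts auditory evoked potential components,
and runs the permutation statistics that tie it together — plus a
synthetic-data generator with plantable ground truth so the whole pipeline
is testable without any recordings.

## What it computes

* **Connectivity** — debiased weighted phase-lag index (dwPLI) from Welch
  cross-spectra (3-s epochs, 1.5-s Hamming windows, 50% overlap), averaged
  over gamma-band bins into a symmetric connectome. Zero-phase
  (volume-conducted) coupling is discarded by construction.
* **Topology** — Onnela weighted clustering, Dijkstra path lengths on
  inverse weights, and small-world propensity
  `SWP = 1 − sqrt((Δ_C² + Δ_L²)/2)`, where Δ_C and Δ_L are deviations from
  an equivalent regular (ring-lattice) network and an equivalent random
  ensemble that both preserve the weight multiset. Betweenness and
  eigenvector centralities; weighted rich-club curves normalized against
  degree- and connectedness-preserving rewirings.
* **Wiring cost** — raw cost `C = Σ d_ij w_ij` over electrode distances,
  and the total effective wiring cost
  `TEWC = (C_obs − C_min)/(C_max − C_min)`, where the bounds come from the
  rearrangement inequality (one sort each) and make the metric invariant
  to overall connectivity strength. Segregative and integrative
  cost-efficiency combine TEWC with Δ_C and Δ_L.
* **Ictogenicity** — a theta-neuron network driven by the connectome,
  swept over node excitability I₀: seizure probability P_sz(I₀), brain
  network ictogenicity (BNI, the normalized integral of the curve), and
  node ictogenicity (NI, the fractional BNI drop when a node is removed).
* **Evoked potentials** — band-pass filtering, epoching with 400 µV
  artifact rejection, trial averaging, and automatic N1 detection in
  15–100 ms post-stimulus.
* **Statistics** — permutation two-way ANOVA (Manly or Freedman–Lane),
  permutation Welch t tests, Spearman correlations with bootstrap CIs,
  Bonferroni and Benjamini–Hochberg corrections.

## Worked example

```r
library(gammanet)

lay  <- make_layout(4, 8)                        # 32-electrode grid, mm
net  <- plant_connectome(32, "small_world", seed = 7)
topo <- network_topology(net, n_nulls = 50, seed = 1)
as.data.frame(topo)
#>   clustering_mean path_length delta_c delta_l   swp betweenness_global
#> 1           0.437           2   0.613   0.442 0.466               6.09
#>   betweenness_norm eigenvector_global
#> 1              0.9              0.177

cost <- network_cost(net, lay, delta_c = topo$delta_c, delta_l = topo$delta_l)
as.data.frame(cost)
#>   c_obs c_min c_max  tewc   sce   ice
#> 1  1590  1322  2203 0.304 0.516 0.621

sw <- psz_curve(net, theta_params(n_i0 = 8, n_steps = 5e4, n_reps = 2,
                                  scale = "desk", seed = 4))
bni(sw)
#> [1] 0.119
```

Reading the output: this small-world fixture keeps moderate clustering
(Δ_C = 0.61 away from its lattice benchmark) while its path lengths sit
close to random (Δ_L = 0.44), giving SWP = 0.47. Its observed wiring cost
lies 30% of the way up the attainable range (TEWC = 0.304): re-arranging
the same weights over the same electrode distances could cost as little as
1322 or as much as 2203 mm·weight. The theta-model sweep integrates to a
network ictogenicity of 0.119 on the desk-scale settings.

The full pipeline — synthetic cohort, topology, cost, ictogenicity,
statistics, with every table written as tab-delimited text plus a
provenance log — runs from one configuration object:

```r
res <- run_pipeline(pipeline_config(out_dir = "out", scale = "desk", seed = 42))
res$stats      # tidy table: metric, effect, statistic, p_raw, p_adj, ...
```

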