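# microdyn

Quantification of microglial morphodynamics from 4D (time-lapse z-stack)
fluorescence imaging, for labs measuring how surveillant microglia respond to
drugs, genotypes or injury in two-photon recordings of brain tissue.

Microglia constantly extend and retract fine processes to survey the brain
parenchyma. `microdyn` turns a single-channel T×Z×Y×X recording of one
labelled cell into the standard per-cell readouts of that behaviour:

* **Surveillance index** — per transition t→t+1, the voxel counts of process
  extensions (PE, voxels gained) and retractions (PR, voxels lost);
  the index |PE| + |PR| is normalized to its mean over the baseline window
  (minutes 1–10), so the baseline mean is exactly 1 and |PE| − |PR| = Δvolume
  holds exactly.
* **Motility index** — surveillance index divided by mean projected cell
  area (cell-size independent).
* **Chemotaxis** — after a focal ablation, the "clear area"
  C = Σ_s (π/n) d_s² over n radial sectors with per-sector process-front
  distances d_s, and its monoexponential decay
  C(t) = A∞ + (A₀ − A∞)·exp(−t/τ) fitted for the time constant τ.
* **Morphometrics** — 3D skeletonization (topology-preserving thinning),
  Sholl intersection profiles N(r), process counts, total process length,
  convex-hull territory, cell volume, and process-to-soma signal ratios for
  a second channel (e.g. mRNA puncta).
* **Statistics** — the normality-driven test-selection tree
  (Shapiro-Wilk + Anderson-Darling → F test → Student/Welch t, otherwise
  Mann-Whitney/Wilcoxon; ANOVA/Welch-ANOVA/Kruskal-Wallis with matching post
  hocs for ≥3 groups) and a noncentral-t power analysis
  (power at df = 2n−2, noncentrality d·√(n/2)).
* **Simulator** — a ground-truthed synthetic 4D microglia generator
  (ramified cell models, tip extension/retraction dynamics, chemotactic
  front convergence, Poisson-Gaussian noise, rigid drift) used to validate
  every stage against exact truth.

## Worked example

Simulate a control arm and a treated arm whose process-tip speed drops by
60% at minute 20, run the full per-cell analysis, and test the groups:

```r
library(microdyn)

cfg <- run_config(
  scenario = "surveillance",
  groups = list(control = list(n_cells = 6, speed_factor = 1),
                treated = list(n_cells = 6, speed_factor = 0.4)),
  seed = 1)
run_pipeline(cfg)
#> <run_report> scenario 'surveillance', seed 1
#>     group n   mean     sem
#> 1 control 6 0.9654 0.02548
#> 2 treated 6 0.4484 0.02028
#>
#> <test_decision> Student's t test: statistic = 15.87, p = 2.025e-08
#>   normality: group1 normal, group2 normal; variances equal (p = 0.629)
```

The group means are the effect indices (mean normalized surveillance index
in minutes 35–40): control cells stay at their baseline rate (≈1), treated
cells fall to ≈0.45 — the planted 60% slowdown plus a small voxel-quantization
bias. The decision tree screened both groups as normal with equal variances
and applied Student's t test.

Chemotaxis: fit the clear-area decay of a simulated ablation response with
a true time constant of 3 min:

```r
sim <- simulate_chemotaxis(tau_true = 3, seed = 2)
tr  <- clear_area_trace(sim$truth_masks, sim$truth$center[1:2],
                        n_sectors = 36, radius = 0.9 * sim$truth$r_max)
fit_tau(tr)
#> <tau_fit> tau = 3.000 min (A0 = 32953.7, A_inf = 59.7 um^2; RSS = 270)
```

Power analysis — the planning standard for per-cell imaging metrics
(control 100%, SD 25%, effect 50%, power 0.80, α = 0.05):

```r
sample_size_two_sample_t(control_mean = 100, sd = 25, effect_pct = 50,
                         power = 0.8, alpha = 0.05)
#> [1] 6
```

A thin command-line front end over the same functions is installed at
`inst/cli/microdyn.R` (subcommands `simulate`, `chemotax`, `run`, `power`,
`stats`).

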