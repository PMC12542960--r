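---
title: "Quantifying microglial morphodynamics: models, metrics and design choices"
author: "microdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglial morphodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microdyn)
```

## The measurement problem

Microglia survey the brain parenchyma by continuously extending and
retracting fine processes while their somata stay in place. Two-photon
time-lapse imaging of labelled microglia produces 4D stacks (typically
50-µm z-stacks at 2-µm steps, one frame per minute for surveillance;
25-µm stacks every 30 s for chemotaxis after a focal laser ablation).
`microdyn` turns such stacks into a small set of per-cell numbers:

* **Surveillance index** — per frame-to-frame transition, the number of
  voxels newly occupied (process extensions, PE) plus newly vacated
  (process retractions, PR), normalized to the mean over a baseline
  window (minutes 1–10 by convention). By construction
  `|PE| − |PR| = Δvolume` holds exactly at every transition, and the mean
  normalized index over the baseline is exactly 1.
* **Motility index** — the raw index divided by the mean projected cell
  area over the same window, removing the trivial dependence on cell
  size.
* **Stationary-process area** — pixels occupied in *every* frame of a
  15-min window, soma excluded. For binary masks the temporal minimum
  projection equals this intersection, which is the implementation used.
* **Territory** — the area of the convex hull of the max-z projection,
  the smallest convex polygon around all distal process tips. The hull
  is computed on the outer corners of occupied pixels so that a filled
  10-µm square yields exactly 100 µm² and the hull can never be smaller
  than the projected area. A 3D hull volume is not offered; reported
  territories in this literature are 2D areas.
* **Clear area and τ** — around an ablation site the projection is split
  into radial sectors (36 by default, i.e. 10° resolution — a compromise
  between front localization and robustness to empty wedges); per sector
  the front is the nearest occupied pixel, and the clear area is
  `Σ (π/n) d_s²`. Its decay is fitted with
  `C(t) = A_inf + (A0 − A_inf)·exp(−t/τ)`; `fit_tau()` returns a classed
  model object with `coef`, `predict` and `residuals` methods.
* **Skeleton morphometrics** — Sholl intersection profiles, primary
  process counts, total process length (sum of Euclidean inter-node
  distances), cell volume, and process-vs-soma compartment ratios for a
  second (e.g. mRNA) channel.
* **Statistics** — the test-selection decision tree and a noncentral-t
  power analysis (below).

## The synthetic-data generator

Real acute-slice recordings have no voxel-level ground truth, so every
stage is validated against a simulator whose geometry is known exactly.

`build_cell_model()` draws a spherical soma (4 µm radius) with
`n_primary` tube-like processes (0.8 µm radius, nominal length
`length_scale`), which branch at interior nodes with probability
`branch_prob`; children are 60% the length of their parent. Growth
directions are damped in z (`z_flatten = 0.3`) because cells imaged in
thin stacks are quasi-planar. The RNG draw order is fixed and documented
so the branching process can be replayed independently; the model stores
`P_true` (primary process count) and `L_true` (exact total nominal
length, since polyline segments have equal arc length).

`simulate_surveillance()` moves every process tip along its
pre-computed track by `speed × Δt` per transition with a random sign,
reflecting at the track limits; tracks are clipped to the imaging volume
so dynamics can never push a tip outside it, and a cell whose resting
geometry does not fit is rejected. The defaults — 2.5 µm/min tip speed,
one frame per minute, 41 frames — put baseline per-transition
displacements at 2–3 voxels, matching the few-µm/min process motility of
cortical microglia. The soma is static, isolating process dynamics in
the ground truth. Rendering is centre-of-voxel capsule rasterization
with the centreline always marked, so thin processes never break into
pieces at coarse z-steps and the noiseless masks binarize exactly.

`simulate_chemotaxis()` renders fronts that converge on the ablation
site such that the true clear area follows the monoexponential law
exactly (the occupied region at time *t* is the annulus outside
`r(t) = sqrt(A(t)/π)`), giving a closed-form reference trace for the
fitting chain. `tau_true = Inf` freezes the fronts.

`inject_artifacts()` applies per-frame integer drift (recorded for
round-trip tests) followed by Poisson shot noise (`photon_scale` photons
per intensity unit, default 0.2, i.e. ~20 photons at the cell level)
plus Gaussian read noise (SD 5 on a background 10 / cell 110 two-level
intensity model), the standard approximation to two-photon counting
statistics without modelling the instrument.

What the simulator does **not** emulate: the optical PSF, photobleaching,
multi-cell crowding, soma displacement, and intensity heterogeneity
within a cell. Passing the simulator-based tests therefore demonstrates
the correctness of the measurement code, not robustness to every optical
artefact of real tissue.

## Preprocessing

Per frame a constant background (10th-percentile intensity) is
subtracted and a 2D median filter (radius 1) applied per z-plane — the
kernel and background rule are configurable since published pipelines
rarely state them. Drift is modelled as a rigid integer-voxel
translation per frame: lateral shifts from FFT cross-correlation of
max-z projections against a reference frame, z-shifts from max-y
projections; frames whose aligned projection correlates poorly with the
reference (r < 0.5, e.g. pure noise) are flagged low-confidence, and
estimated shifts beyond 10% of the field of view raise a warning.
Correction is idempotent to within one voxel.

Manual cell selection is replaced by a reproducible rule: threshold
(Otsu by default, computed inside a dilated bounding box of the seed
component), keep the 26-connected component containing a seed point
(26-connectivity keeps thin diagonal processes attached), and estimate
the soma as the largest inscribed sphere at the intensity-weighted
centroid. Relative thresholds make the masks invariant under global
intensity scaling.

## Skeletonization

Automated 3D tracing is implemented as topology-preserving thinning:
the mask is first resampled to an isotropic grid (linear interpolation
to the finest voxel pitch; thinning a 2-µm-z grid directly would bias
skeletons toward the lateral plane), then eroded by deleting simple
points in order of increasing distance-to-background, preserving curve
endpoints. The surviving voxels become a spatial graph; cycles are
pruned to a minimum spanning tree, spurs shorter than `prune_um`
(default 3 µm) are removed, and degree-2 chains are Laplacian-smoothed
(3 iterations) because the raw 26-connected voxel path systematically
overestimates length through diagonal zigzag. On unbranched cells the
recovered total length is within ~1% of truth; on heavily branched
cells it is biased low by 10–20% because sibling tubes overlap near
junctions and sub-resolution twigs are pruned — a known property of all
thinning-based tracing, which is why the exactness tests for Sholl
profiles run on analytically constructed graphs rather than on images.

Sholl crossings count edges straddling concentric shells around the
root; node-to-root distances are rounded at 1 nm before the comparison
so that tips lying exactly on a shell register as crossings regardless
of floating-point representation. "Number of processes" is reported as
the crossing count at the first shell outside the soma radius (primary
processes); the total branch count is also available from the model, as
figure axes in this literature do not disambiguate the two readings.

## Statistics

Two-group comparisons follow the decision tree: normality screening by
Shapiro-Wilk *and* Anderson-Darling (both must reach p ≥ 0.05 — a
conservative conjunction, since no combination rule is standard; the
Anderson-Darling implementation requires n ≥ 8, so smaller groups are
screened by Shapiro-Wilk alone); normal data get an F test on variances
and then Student's or Welch's t; any normality failure routes to
Mann-Whitney (independent) or Wilcoxon signed-rank (paired) tests. All
tests are two-sided. Multi-group data go to one-way ANOVA + Tukey,
Welch's ANOVA + Games-Howell, or Kruskal-Wallis + Dunn (Bonferroni);
the k-group variance screen is Bartlett's test, the normal-theory
analogue of the two-group F test.

A limitation worth knowing: under a heteroscedastic normal null, the
*composite* tree rejects slightly above α (~0.06 at n = 30), because
replicates that fail the normality screen by chance are routed to the
rank test, which is anti-conservative when variances differ (the
Behrens-Fisher problem). Each branch's test holds its size where it is
applied; the inflation is a property of screen-then-test procedures,
not of this implementation.

Power analysis uses the noncentral-t formulation of the two-sided
two-sample t-test (df = 2n − 2, noncentrality d·√(n/2)) and returns the
smallest integer n reaching the target power. The standard planning
spec for per-cell imaging metrics — control mean 100, SD 25, effect 50%
of control, power 0.80, α = 0.05 — gives n = 6 per group (n = 5 reaches
only 0.79).

```{r power}
sample_size_two_sample_t(control_mean = 100, sd = 25, effect_pct = 50,
                         power = 0.8, alpha = 0.05)
achieved_power(n = 6, d = 2, alpha = 0.05)
```

## Numerical choices and degenerate inputs

* τ fits are initialized at `A0 = C(0)`, `A_inf = C(end)`, τ = time to
  half-decay, with τ bounded in (0, 10 × recording length]; a fit at the
  bound or with < 1% decay is flagged non-converged rather than raised.
  Recovery is unbiased (< 10% across τ = 1–10 min at 5% trace noise)
  when the recording covers at least ~3 time constants; slower decays
  need proportionally longer recordings to identify τ.
* A static cell has a zero baseline and no definable surveillance
  index; `surveillance_trace()` fails explicitly rather than returning
  0/0.
* Segmentation of a featureless stack fails naming the frame;
  a component lost mid-recording falls back to maximal overlap with the
  previous frame before failing.
* Pipeline seeds derive deterministically from the master seed, group
  and cell indices (kept below 2³¹), so entire runs are bit-for-bit
  reproducible.

## Problem sizes used in the test-suite simulations

Validation runs use 96-µm, 96-pixel fields of view (1 µm lateral pitch,
2-µm z-steps, 30-µm depth for surveillance and 25 µm for chemotaxis),
cells with 4–6 primary processes of 16–25 µm, and 41-frame surveillance
recordings — a quarter-scale field of view at native voxel anisotropy,
which preserves every geometric regime of full-size recordings (the
metrics are per-cell, not per-field). The planted-effect experiment (a
60% tip-speed reduction from minute 20, read out as the mean normalized
index in minutes 35–40 across 20 cells) recovers 0.40 with a small
positive quantization bias (~+0.03) because voxel-level changes cannot
scale perfectly linearly with sub-voxel displacements.

## Known limitations

* Thinning-based skeleton lengths are biased low on densely branched
  cells (see above); Sholl profiles and process counts are unaffected.
* The clear-area metric quantizes at the pixel grid near the ablation
  centre: even a fully covered disc retains a residual clear area below
  1% of the analysis disc.
* Drift correction is rigid and integer-voxel; rotational or non-rigid
  tissue motion is out of scope.
* The simulator's two-level intensity model ignores depth-dependent
  attenuation; segmentation thresholds on real data may need the
  percentile method instead of Otsu.
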