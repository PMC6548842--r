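---
title: "Aligning plot grids with vegetation: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning plot grids with vegetation: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plotalign)
```

## The problem

Agronomic research trials sow hundreds of rectangular micro-plots in a
regular design, and aerial phenotyping reduces each plot to traits — canopy
coverage, vigor, counts — extracted from an orthomosaic. Those traits are
only as good as the plot boundaries they are integrated over. In practice
plots drift from their nominal design positions (seeder track variation,
partial emergence, residual georeferencing error), so a uniformly spaced
grid laid over the mosaic is systematically misaligned with the actual
canopy, and analyses based on it inherit that error.

`plotalign` refines a coarse uniform grid by estimating one bounded 2D
displacement per cell, so that each fixed-size cell lands on its underlying
plot. It treats the task as a single bound-constrained optimisation over
all cells jointly rather than as per-plot detection, which is what lets it
work through touching plots, weak plots and empty neighbourhoods.

## The model

All energies are computed on a scalar vegetation-index field $S$, by
default the green–red difference index $S = (G - R)/(G + R)$, which is high
over canopy and near zero over soil. For a grid of $P \times Q$ cells of
size $W \times H$ centred at $(u_{pq}, v_{pq})$, a candidate solution is a
displacement field $\theta = \{(\delta^u_{pq}, \delta^v_{pq})\}$ with
$|\delta^u| \le \Delta^u$, $|\delta^v| \le \Delta^v$.

* **Intra-cell energy** $d_{pq}$: the sum of $S$ over the displaced cell
  rectangle — the vegetation captured by the cell.
* **Inter-cell energy** $g_{pq}$: for each of the cell's von Neumann
  neighbours whose displaced rectangle overlaps it, the sum of $S$ over
  the overlap, attributed with the coefficient
  $d_{p'q'}/(d_{pq}+d_{p'q'})$, so the two members of a pair always split
  the pair's overlap mass exactly. Overlap over vegetation is therefore
  penalised in proportion to how much both cells want it.
* **Net energy** $f_{pq} = (d_{pq} - g_{pq})/(W H)$ and the grid cost
  $f = \exp(-\tfrac{1}{PQ}\sum f_{pq})$, minimised by the optimizer. The
  exponential keeps the objective positive and bounded over the search
  box.

The soft proportional overlap penalty, rather than an outright ban on
overlapping configurations, is what keeps the search space connected: a
hard infinite penalty rejects every intermediate configuration in which
cells brush past each other, and is provided in this package only as a
test oracle.

### Key assumption: the background is index-neutral

The energies assume $S \approx 0$ on soil and clearly positive on canopy.
Because every cell always integrates exactly $W \times H$ pixels, a
*uniformly* negative soil background contributes a constant offset to each
$d_{pq}$ and does not distort the intra-cell incentives — but it does
distort the overlap term, because overlap over negative-$S$ soil would be
*rewarded* ($g_{pq} < 0$). If your index is strongly negative over the
background (red soils under some indices), rescale or clamp it toward zero
before fitting; the synthetic-trial generator uses a near-neutral soil for
the same reason.

## Optimisation

The $N = 2PQ$ displacement coordinates are searched with a bound-constrained
adaptive particle swarm (`pso_control()`):

* $K = \mathrm{round}(8N)$ particles by default; densities of 6–12
  particles per coordinate work well, and the swarm always contains one
  **null particle** at zero displacement, so the returned fit can never be
  worse than the uniform grid it started from.
* Velocity update $v \leftarrow wv + 1.49\,r_1(p_{best}-x) +
  1.49\,r_2(n_{best}-x)$ with inertia $w$ adapted in $[0.1, 1.1]$: it
  doubles while the swarm keeps improving and halves under persistent
  stagnation, which switches the search from exploration to refinement
  automatically.
* $n_{best}$ is the best personal best in a *dynamic random neighbourhood*:
  each particle draws a fresh random subset (at least a quarter of the
  swarm, sampled with replacement) every iteration; the subset grows while
  the best cost stalls. Random per-iteration neighbourhoods spread
  information without the premature convergence of a fully global
  topology.
* Velocities are clamped to the bound span, positions are clamped to the
  box (with the velocity component zeroed on contact), so every reported
  displacement is feasible.
* Termination: the run stops when the best cost improves by no more than
  `tolerance` (default $10^{-4}$) over 20 consecutive iterations.
  Tolerances below $10^{-4}$ refine the well-aligned cells slightly but do
  not rescue cells caught in a wrong basin, which matches the tolerance
  sweep behaviour on synthetic trials.

The default displacement bounds are half the grid pitch per direction.
Larger bounds would allow a cell to jump onto a neighbouring plot outright;
smaller bounds may exclude the true position. Half-pitch is the largest
bound under which every cell's own plot is always the nearest reachable
one.

The hot path — evaluating the grid cost for the whole swarm — is compiled
(Rcpp) and uses a summed-area table, so one cost evaluation is $O(PQ)$
lookups per particle regardless of cell size in pixels.

### Discretisation

The displaced cell rectangle is rounded to the integer pixel lattice: the
left/top edge is `floor(center - size/2 + 0.5)` and the rectangle spans
exactly `round(W) x round(H)` pixels. Every cell therefore contributes the
same number of samples at every displacement, which makes costs comparable
across positions and exactly summable in $O(1)$; the swarm still searches
*continuous* displacements, so sub-pixel moves simply snap to the nearest
lattice cell during evaluation. Cells partly outside the mosaic are
clipped; outside pixels contribute zero energy, so border plots near the
mosaic edge are handled without special cases. Half-away-from-zero rounding
is used in both the R and compiled paths, avoiding the R `round()`
half-to-even rule whose behaviour differs between languages.

Two degenerate cases are defined explicitly: a neighbour pair whose
intra-cell energies sum to exactly zero (both cells over index-free
ground) contributes no overlap term, and the grid cost of an all-zero
field is exactly 1.

## The synthetic world

No orthomosaic is shipped with the package; validation runs on rendered
trials with known ground truth (`trial_spec()`, `simulate_trial()`). The
generator states one concrete world and keeps it fixed:

* **Validation layout**: 5 × 12 plots of 1.2 × 4 m, six plant rows at
  0.2 m spacing, at 0.8 cm/px. **Test layout**: 48 × 12 single-row plots
  of 0.3 × 5 m. Pitches (1.6/5.0 m and 0.4/6.0 m) are typical wheel-track
  and alley spacings for these plot sizes.
* **Soil** is rendered near green–red-neutral (RGB ≈ (105, 100, 78),
  $S \approx -0.02$) with brightness texture that cancels in the index
  ratio — the index-neutral background the energy model assumes.
* **Canopy** rows are Gaussian-profile strips (half-width 5.5 cm) of
  green-dominant pixels with colour jitter, thinned by an emergence rate
  of 0.92 and tapered toward the plot ends over the outer 12 % of plot
  length (seeder rows start and finish thin). The end taper is what makes
  a 50 %-trimmed cell *overestimate* coverage: its denominator excludes
  the thin ends it cropped away.
* **Vigor**: per-plot greenness multipliers, by default 1.0 vs 0.75
  (fertilized vs unfertilized), assigned at random. The contrast is kept
  above the point where stealing a share of a greener neighbour's plot
  beats staying on one's own weak plot (that degeneracy sets in when the
  weak plot's per-pixel capture gain falls below half the strong plot's).
  The deliberately hard scenario — `row_pairing = TRUE` — goes past that
  point on purpose: alternate pairs of plot rows touch with no gap and
  pair a 1.0 row with a 0.55 row, which is the regime where a cost
  without the overlap penalty visibly fails (`run_ablation()`).
* **True displacements** are i.i.d. uniform within half the pitch for the
  validation world. The test world uses anisotropic bounds (±0.12 m
  lateral, ±1 m longitudinal) reflecting how single-row sowing actually
  errs: along the track, not across it.

What a green test on this world establishes: that the estimator recovers
known misalignment through realistic index statistics (weak plots, thin
ends, touching rows, soil noise). What it does not establish: performance
under weeds, shadows, lodging, stitching artefacts or photorealistic
texture — none of which the renderer attempts. Misalignment of an
*existing* mosaic is also supported (`displace_plots_reflect()`), which
translates an enlarged region around each plot and fills the exposed band
by mirror reflection, so the modified mosaic has no voids and seams fall
in the soil margin; the exact geometric rule is this package's own
declared approximation of that construction.

## Evaluation machinery

* `alignment_error()`: per-cell Euclidean distance between true and fitted
  displacement vectors, in cm; summarised with median/quartiles/1.5-IQR
  whiskers (`boxplot_summary()`), the convention used throughout.
* A run is a **successful alignment** when its median error is at most a
  quarter of the smaller pitch (`success_threshold()`); the criterion is a
  package-level definition, stated once so robustness counts are
  reproducible.
* `canopy_coverage()` divides plant pixels by the cell's own pixel count —
  including for trimmed cells, which is exactly what produces the
  documented trimmed-grid overestimation.
* `coverage_comparison()` runs a one-way ANOVA across grid variants with a
  Tukey HSD multiple comparison at α = 0.05 (the specific multiple
  comparison is this package's choice).
* Plant segmentation defaults to Otsu's threshold on the index histogram —
  a reproducible stand-in for a visually tuned threshold — and accepts an
  explicit value.

## Known limitations

* A cost-optimal configuration is not always the truth: under extreme
  half-pitch misalignment a small fraction of cells can swap onto a
  neighbouring plot at nearly identical cost; the median error is robust
  to this, the upper quartile is not. Re-running with a different swarm
  seed is the practical remedy, as the initialization study shows.
* Rotation is handled by resampling the field into the grid frame once
  (bilinear), not by rotated-rectangle geometry; strong rotations plus
  strong shear in the geotransform are outside scope.
* Cell dimensions are fixed by design: traits are quoted per sown plot
  area, so the estimator aligns fixed-size cells rather than tracing
  canopy outlines.
* The shapefile and TIFF codecs are minimal by intent (uncompressed
  baseline TIFF, single-ring polygons, dBase III attributes) — enough for
  GIS interchange of grids and index fields, not general-purpose I/O.
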