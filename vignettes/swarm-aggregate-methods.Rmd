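---
title: "Quantifying the swarm-to-biofilm transition: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the swarm-to-biofilm transition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Toward the end of surface swarming, colonies of *Bacillus subtilis* enter a
coexistence regime: most cells still swarm rapidly in whirls and jets, while
connected regions of essentially immobile cells — *stationary aggregates* —
appear, persist, grow, merge, and eventually mature into biofilm. A small
subpopulation of immotile, EPS-secreting cells (roughly a quarter of all
cells) acts as nucleation seeds; swarming cells that run into such a seed
cluster can be trapped, and trapped cells occasionally escape, so trapping
is partially reversible. `swarmaggr` implements the quantitative toolchain
for this regime: optical-flow velocimetry, speed-threshold segmentation of
stationary aggregates, aggregate-size-distribution (ASD) statistics,
single-cell mean-square-displacement (MSD) classification, speed-versus-
coverage diagnostics, and EPS-subpopulation quantification — together with
an agent-based generator that produces calibrated two-channel image stacks
with full ground truth, so every stage can be validated end to end.

## The measurement chain

**Dense optical flow.** Displacements between consecutive frames are
estimated with a polynomial-expansion (Farnebäck) estimator implemented in
compiled code: each frame is approximated locally by a quadratic polynomial
over a Gaussian-weighted window (half-width `flow_poly_n` = 7 px, sigma
1.5), the expansions of the two frames are equated to a linear system for
the displacement, the normal equations are averaged over `flow_winsize` =
15 px, and the solution is refined over 3 pyramid levels with 3 iterations
each. These defaults are meant for the native imaging regime (1/6 um/px);
analyses of coarser renderings should scale the pixel windows to the same
physical size (about 1-3 um). On noise-free static scenes the estimator
returns identically zero flow; exact integer translations of textured
images are recovered to machine accuracy.

**Coarse graining and coverage.** Flow is converted to um/s and block-
averaged over non-overlapping square analysis windows (`flow_window` = 4 um
by default), evaluated only over cell-mask pixels; windows without cells
are missing, not zero. The local surface coverage is the cell-mask fraction
of the same windows, so speed, coverage, and aggregate membership share one
grid. The cell mask is an Otsu threshold after background flattening. A
4 um window (below the spec-sheet starting point of 8 um) was adopted after
measuring segmentation accuracy against ground truth: at 8 um the boundary
quantization of aggregates dominates the error budget.

**Stationary aggregates.** The window speed field is first smoothed with a
temporal median over the previous `speed_smooth_pairs` = 5 frame pairs —
transient traffic at aggregate boundaries otherwise flickers windows above
threshold. The stationary threshold is adaptive: the log window speeds are
split into two groups (k-means with quantile-anchored starts), reflecting
the two dynamical populations, and the threshold is placed at the geometric
midpoint of the group centers. A fraction-of-median rule (`"median"`
method) is available as a fallback and is used automatically for degenerate
speed distributions. The below-threshold mask is morphologically closed
(one node), holes are filled, components are labeled with 8-connectivity,
and components below `min_aggregate_area` = 10 um^2 are dropped. A
component is *stationary* only if at least half of its footprint lies on
the below-threshold mask in each of the previous `persistence_frames` = 25
frame pairs (0.5 s at 50 fps); this footprint-overlap persistence replaces
a per-component IoU chain, which proved brittle when components merge or
split between frames. Transient jams in mutant-like data are removed by
persistence, not by the threshold.

**Region membership for statistics.** For the speed-versus-coverage
relations, a window is *inside* when it is below the stationary threshold
on the shared grid — the inside/outside distinction *is* the threshold
speed — whereas the ASD, the aggregate ratio, and ground-truth comparisons
use only the persistent components. With one partition per analysis, the
per-bin mean speed of all windows equals the count-weighted combination of
the inside and outside means exactly (the package asserts this to floating
tolerance).

**ASD statistics.** The pooled areas of persistent components (sampled
every `stride` frame pairs for decorrelation) are summarized by the
empirical complementary CDF and fitted by maximum likelihood within three
families on `[xmin, Inf)`: a pure power law (closed-form Pareto MLE), a
shifted exponential (closed form), and a power law with exponential cutoff
`p(r) ~ r^(-alpha) e^(-lambda r)`, whose normalizer is evaluated through
the upper incomplete gamma function with an asymptotic branch and an
adaptive-quadrature fallback (absolute accuracy ~1e-10 relative to the
normalizer). Because the information about `lambda` is carried by the few
largest observations, the cutoff MLE is computed by profiling `lambda` on a
log grid anchored to the data range, maximizing `alpha` per grid point, and
refining locally with bounded L-BFGS-B; a solution at the `lambda = 0`
boundary is flagged (the family then degenerates to the pure power law).
Families are compared by AIC (`2k - 2 loglik`); a gap below 2 between the
two best models is flagged inconclusive. `xmin` is fixed to the
segmentation resolution floor (`min_aggregate_area`) rather than scanned,
since the sample has a hard detection cutoff there. The finite field of
view truncates the size range; the package reports the field size with
fits rather than modeling censoring.

**Trajectories.** Detections are linked frame-to-frame by greedy
nearest-neighbor assignment with a per-frame displacement cap and optional
gap closing. Per track, the time-averaged MSD is computed over lags up to
`msd_fit_fraction` = 0.25 of the duration and fitted by least squares on
log-log axes. Classes: subdiffusive below `beta_sub_max` = 0.9,
superdiffusive above `beta_super_min` = 1.1, diffusive between — the
narrow diffusive band is required to reproduce the empirically observed
three classes — and *transitive* when the exponents of the two track
halves differ by more than `delta_beta` = 0.5 while straddling 1 (a cell
entering or leaving an aggregate). A fit qualifies when R^2 >= 0.8 *or*
the slope standard error is at most 0.1: R^2 alone cannot qualify a flat
MSD (explained variance vanishes as the slope approaches zero), which is
precisely the strongly subdiffusive case of a trapped cell under
localization noise. The histogram of exponents of non-transitive tracks is
summarized by the sample bimodality coefficient
`(g1^2 + 1) / (g2 + 3 (n-1)^2 / ((n-2)(n-3)))`, with values above 5/9 read
as bimodal.

**EPS subpopulation.** The fluorescence channel is segmented with the same
conventions as the cell mask plus a minimum-area filter. The EPS fraction
is an *area* fraction, `|eps & cells| / |cells|` — individual cells are
unresolved at high coverage, so a count fraction would not be well defined;
this choice is recorded in the output metadata. Displacement between two
time points matches components by nearest centroid within a cap and
reports the global Jaccard overlap.

## The synthetic-data generator

`simulate_colony()` is a first-class, tested module, not a fixture. Agents
live in a periodic box (the imaged field is a small interior region; walls
would add artifacts the analysis never sees in practice). Motile cells
perform run-and-tumble motion with run durations drawn from a truncated
Pareto law (tail exponent 1.6 on 0.04-2 s), giving superdiffusive free
motion on sub-run time scales; headings also align with motile neighbors
within 4 um (relaxation 0.7 per step), feel a mild cohesive steering
toward the local center of mass (0.05), rotational noise
(0.15 rad/sqrt(s)), and a soft elliptical excluded-volume push that keeps
the swarm at monolayer packing. The swimming speed rises with local
crowding, `v = v0 (0.15 + 0.85 min(1, n/12))` with `v0` = 25 um/s — the
cooperative speed-up of dense swarms, and the microscopic origin of the
rising speed-versus-coverage relation the pipeline must detect.

A fraction `eps_fraction` = 0.25 of agents is EPS-immotile from the start,
placed as compact nuclei of ~240 cells whose radius follows from a nucleus
packing of 2 (nuclei are effectively multilayered, consistent with local
coverage rising toward and beyond 1 near maturing aggregates); the packing
also calibrates the rendered EPS area fraction to the generating number
fraction under the channel segmentation conventions. Aggregates are obstacles: a motile cell whose tentative move
lands within `trap_radius` = 2 um of at least 3 non-motile cells is either
trapped there (probability `p_trap` = 0.03 per step), deflected into a
tangential slide along the boundary, or — after 15 consecutive blocked
moves — jammed into the trapped state; trapped cells escape at `p_escape`
= 0.01 per step. Trapping and escape rates are free parameters of the
generator (no measured values exist for them); the defaults were chosen so
that the trapped population reaches a fluctuating steady state with an
aggregate ratio around 0.3-0.5 and a visible exchange of cells between
swarm and aggregates. An optional slow drift of EPS cells pushed by the
surrounding swarm exists and is off by default.

Rendering draws each cell as an anisotropic flat-top (super-Gaussian)
kernel oriented along its heading (FWHM equal to the 5 x 1 um cell body),
composited per-pixel by maximum with a fixed per-cell brightness in
0.6-1.0, plus additive Gaussian noise of 5% of the kernel peak. The
flat-top edge makes thresholded footprints insensitive to the exact
threshold, and the brightness texture is what the flow estimator tracks;
saturating sums would erase the texture inside dense aggregates and with
it the very signal the velocimetry needs. The default agent density
(0.30 um^-2) was calibrated once so that thresholded coverage falls in the
0.5-0.8 regime of dense swarming monolayers.

What the generator does *not* emulate: phase-contrast optics (halos,
shading), cell growth and division, rafting hydrodynamics, multilayer
escape in the third dimension, and colony-scale gradients. Passing the
suite therefore demonstrates that the estimators recover known structure
from realistic-looking dense-monolayer image stacks — not that every
biological detail of real swarms is reproduced.

## Numerical choices and degenerate inputs

* Quadrature: normalizer accuracy ~1e-10 (relative); model CCDFs are
  evaluated through the same normalizer, so they are non-increasing and
  equal 1 at `xmin` by construction.
* The segmentation threshold falls back from the cluster rule to
  `speed_threshold_frac x median` when the speed distribution has fewer
  than 10 distinct values or k-means cannot separate two groups.
* Constant frames yield empty masks with a warning; empty cell masks give
  an `NA` aggregate ratio (missing, not zero).
* Ties in window region membership cannot occur (membership is defined on
  the same grid), and ambiguous linking ties are broken by distance, then
  by track id.
* Tracks shorter than `min_track_length` are skipped with a log entry;
  zero MSDs refuse a fit rather than returning `-Inf` slopes.
* All stochastic stages consume the R RNG, so a single `seed` per
  configuration makes simulation, rendering, and sampling bit-reproducible.

## Problem sizes used by the tests and drivers

The bundled analyses run at desk scale chosen for thorough statistics on a
single CPU: 75 um fields of view at the native 1/6 um/px and 50 fps
(450 x 450 px), 40-60 recorded frames after a 10 s equilibration, ten
seeded wild-type-like fields plus three mutant-like controls; parameter
recovery for the ASD estimators uses 1e5 draws. The full 150 um / 900 px
regime is the package default for `sim_config()` and runs unchanged, just
longer.

## Known limitations

* The measured speed-versus-coverage relation is only interpretable over
  the coverage range actually realized in dense fields (bins >= 0.3);
  near-empty windows carry raft-edge artifacts where a window's few cell
  pixels belong to a dense, fast raft just outside it.
* The boundary band of an aggregate mixes static and moving material at
  the window scale; recall of the ground-truth aggregate area saturates
  around 0.8-0.9 there, which bounds the achievable mask IoU (~0.75-0.85).
* `lambda` of the cutoff law is informed by the few largest aggregate
  sizes; its sampling spread is roughly a factor of two at n = 1e5 for
  cutoffs near the field-of-view scale, and fits on small pooled samples
  frequently (and correctly) return the boundary solution.
* The persistence filter needs `persistence_frames` prior pairs, so the
  first half second of each recording contributes no stationary
  components.
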