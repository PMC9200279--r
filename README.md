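# swarmaggr

Quantitative analysis of the swarm-to-biofilm transition in dense
bacterial colonies, from time-lapse microscopy.

At the end of surface swarming, colonies of *Bacillus subtilis* enter a
coexistence regime: most cells swarm rapidly while connected regions of
immobile cells — **stationary aggregates** — nucleate around a small
subpopulation (~25%) of immotile, EPS-secreting cells, trap passing
swarmers, and mature into biofilm. `swarmaggr` provides the measurement
chain for this regime, for microscopists and biophysicists working with
calibrated phase-contrast / fluorescence stacks (or with the bundled
synthetic generator):

* **Dense optical flow** between consecutive frames (Farnebäck polynomial
  expansion, compiled), coarse-grained to window velocity and speed fields
  in µm/s.
* **Stationary-aggregate segmentation**: windows with speed below an
  adaptive threshold, morphologically cleaned, 8-connected, filtered by a
  persistence criterion; aggregate areas and the *aggregate ratio*
  (fraction of cell area inside aggregates).
* **Aggregate size distribution (ASD)**: empirical complementary CDF
  `P(x)` and maximum-likelihood fits of a pure power law
  `p(r) ∝ r^(−α)`, a shifted exponential, and a **power law with
  exponential cutoff** `p(r) ∝ r^(−α) e^(−λr)` on `[xmin, ∞)`, compared by
  AIC. The cutoff-law likelihood is
  `ℓ(α, λ) = −n log Z(α, λ, xmin) − α Σ log x_i − λ Σ x_i` with
  `Z = ∫_xmin^∞ r^(−α) e^(−λr) dr`.
* **Single-cell trajectories**: nearest-neighbor linking with gap closing,
  time-averaged MSD `⟨r²(τ)⟩ ∼ τ^β`, and classification into
  subdiffusive (β < 0.9), diffusive, superdiffusive (β > 1.1), and
  transitive tracks, with a bimodality diagnostic of the β histogram.
* **Coverage diagnostics**: local surface coverage on the same grid as the
  speed field, mean speed per coverage bin for all / inside / outside
  aggregate windows (with an exact fraction-weighted decomposition),
  aggregate fraction per bin, and radial colony profiles.
* **EPS subpopulation**: segmentation of the reporter channel, EPS area
  fraction and its time course, and component displacement between time
  points.
* **Agent-based generator** (`simulate_colony()` / `render_frames()`):
  run-and-tumble swarmers with Lévy-like run durations, alignment,
  excluded volume, EPS seed nuclei, reversible trapping with jamming, and
  two-channel rendering with ground-truth tracks and aggregate masks —
  the validation substrate for every stage.

## Worked example

```r
library(swarmaggr)

# a 75 µm field of view at 1/6 µm/px and 50 frames/s, defaults otherwise
cfg   <- sim_config(box_side = 75, n_steps = 40, burn_in = 500,
                    pixel_size = 1/6, seed = 1)
truth <- simulate_colony(cfg)
stack <- render_frames(truth)
an    <- analyze_stack(stack, pipeline_config(persistence_frames = 20))
an
#> swarm_analysis: 18 x 18 windows (4 um), 39 frame pairs
#>   mean speed 9.45 um/s, mean coverage 0.456
#>   speed threshold 2.41 um/s, aggregate ratio 0.194
```

The analysis reports 18×18 analysis windows of 4 µm; the adaptive
stationary threshold lands at ≈2.4 µm/s between the static and swarming
speed modes, and about a fifth of the cell-covered area belongs to
persistent stationary aggregates — the coexistence regime. Downstream:

```r
sizes <- pool_sizes(an$labeling, stride = 10)     # aggregate areas, µm²
fit   <- fit_powerlaw_cutoff(
           sample_powerlaw_cutoff(1e5, 1.9, 2e-5, 1, seed = 1), xmin = 1)
round(c(alpha = fit$alpha, lambda = fit$lam), 6)
#>    alpha   lambda
#> 1.896675 0.000026
```

drawn at the shape/rate scales typical of swarm-colony aggregate data, the
estimator recovers the exponent to ±0.01 and the cutoff rate within its
sampling spread. The numbered scripts under `analysis/` run the full
study — simulation, segmentation accuracy, ASD fits, MSD classification,
coverage relations, and EPS quantification — writing tables under
`results/`:

```sh
Rscript analysis/01_simulate_colony.R
Rscript analysis/02_flow_aggregates.R   # ... through 06
```

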