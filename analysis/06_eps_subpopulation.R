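#!/usr/bin/env Rscript
# The EPS-secreting subpopulation seen through the fluorescence channel:
# per-field area fraction, a densifying time series (coverage rises, EPS
# fraction stays ~25%), and the displacement of EPS cells over time.

library(swarmaggr)

runs <- readRDS("results/runs.rds")
dir.create("results/eps", showWarnings = FALSE, recursive = TRUE)

fr <- vapply(runs$wt, function(run) {
  st <- run$stack_small
  nf <- dim(st)[3]
  mean(vapply(seq_len(nf), function(f) {
    eps_fraction(segment_eps(st$channels$eps[, , f], st$pixel_size),
                 cell_mask(st$channels$all[, , f]))
  }, numeric(1)))
}, numeric(1))
write.csv(data.frame(seed = vapply(runs$wt, function(r) r$config$seed, 1),
                     eps_area_fraction = fr),
          "results/eps/eps_fraction_per_field.csv", row.names = FALSE)
message(sprintf("EPS area fraction: %.3f +- %.3f (generator truth 0.25)",
                mean(fr), sd(fr)))

# densifying series at two-hour spacing
mk <- function(dens, seed) {
  render_frames(simulate_colony(
    sim_config(box_side = 50, n_agents = round(dens * 2500), n_steps = 4,
               burn_in = 300, pixel_size = 1 / 6, seed = seed)))
}
ts <- eps_timeseries(list(mk(0.22, 11), mk(0.30, 12), mk(0.38, 13)),
                     times_s = c(0, 7200, 14400))
write.csv(ts, "results/eps/eps_timeseries.csv", row.names = FALSE)
print(ts)

# displacement between the first and last kept frame of one field
st <- runs$wt[[1]]$stack_small
px <- st$pixel_size
m1 <- segment_eps(st$channels$eps[, , 1], px)
m2 <- segment_eps(st$channels$eps[, , dim(st)[3]], px)
rep_ <- eps_displacement(m1, m2, pixel_size = px, max_match_dist = 3)
jsonlite::write_json(list(
  overlap = rep_$overlap,
  n_matches = nrow(rep_$matches),
  median_displacement_um = median(rep_$matches$displacement_um)
), "results/eps/displacement.json", auto_unbox = TRUE, digits = NA,
   pretty = TRUE)
message(sprintf("EPS mask overlap %.2f, median displacement %.2f um",
                rep_$overlap, median(rep_$matches$displacement_um)))
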