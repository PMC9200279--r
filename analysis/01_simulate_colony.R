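#!/usr/bin/env Rscript
# Generate the synthetic study data: ten seeded fields of view of a
# swarming colony with an EPS-secreting subpopulation (the "wild-type"
# series) and three fields of a nonbiofilm-mutant-like colony (no EPS, no
# trapping). Each field is simulated, rendered to a two-channel stack,
# and pushed through the full per-field analysis. Everything downstream
# (02-06) reads the cache written here.
#
# Study conditions: 75 um field of view at 1/6 um/px and 50 frames/s,
# 40 recorded frames after a 10 s equilibration; all other parameters at
# the package defaults.

library(swarmaggr)

out_dir <- "results"
dir.create(file.path(out_dir, "sim"), recursive = TRUE, showWarnings = FALSE)

cfg_pipe <- pipeline_config(persistence_frames = 20L)

run_field <- function(seed, keep_stack = FALSE, ...) {
  scfg <- sim_config(box_side = 75, n_steps = 40L, burn_in = 500L,
                     pixel_size = 1 / 6, seed = seed, ...)
  truth <- simulate_colony(scfg)
  stack <- render_frames(truth)
  analysis <- analyze_stack(stack, cfg_pipe)
  # keep the cache light: drop the pixel masks and store only the frames
  # that the downstream drivers read (every 8th, plus first and last)
  analysis$masks <- analysis$masks[1]
  keep <- sort(unique(c(1L, seq(1L, scfg$n_steps, by = 8L), scfg$n_steps)))
  small <- stack
  small$channels <- lapply(stack$channels, function(a) a[, , keep, drop = FALSE])
  small$kept_frames <- keep
  list(config = scfg, truth = truth, analysis = analysis,
       stack_small = small, stack = if (keep_stack) stack else NULL)
}

message("simulating 10 wild-type-like fields of view ...")
wt <- lapply(1:10, function(s) {
  message("  seed ", s)
  run_field(s, keep_stack = (s == 1))
})

message("simulating 3 nonbiofilm-mutant-like fields ...")
mut <- lapply(101:103, function(s) {
  message("  seed ", s)
  run_field(s, eps_fraction = 0, p_trap = 0)
})

# artifacts a reader can open: one two-channel stack, its ground-truth
# tracks, and the provenance sidecars
write_stack(wt[[1]]$stack,
            file.path(out_dir, "sim", c("wt_seed1_all.tif",
                                        "wt_seed1_eps.tif")))
write_tracks(truth_tracks(wt[[1]]$truth),
             file.path(out_dir, "sim", "wt_seed1_tracks.csv"))
log_config(wt[[1]]$config, file.path(out_dir, "sim", "sim_config.json"))
log_config(cfg_pipe, file.path(out_dir, "sim", "pipeline_config.json"))
wt[[1]]$stack <- NULL

saveRDS(list(wt = wt, mut = mut), file.path(out_dir, "runs.rds"))
message("cached ", length(wt), " + ", length(mut), " analyzed fields in ",
        file.path(out_dir, "runs.rds"))
message(sprintf("wild-type field 1: coverage %.2f, aggregate ratio %.2f",
                mean(wt[[1]]$analysis$coverages),
                aggregate_ratio(wt[[1]]$analysis)$overall))
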