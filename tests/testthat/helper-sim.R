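# Shared fixtures for the suite, generated in code.
#
# Desk-scale study conditions: a 75 um field of view at the native pixel
# size (1/6 um/px) and frame rate (50 fps), 40-50 recorded frames after a
# 10 s equilibration. Heavy objects are built lazily and cached for the
# whole run.

.fixture_env <- new.env(parent = emptyenv())

desk_sim_config <- function(seed = 1L, n_steps = 40L, box_side = 75, ...) {
  sim_config(box_side = box_side, n_steps = n_steps, burn_in = 500L,
             pixel_size = 1 / 6, seed = seed, ...)
}

desk_pipeline_config <- function(...) {
  pipeline_config(persistence_frames = 20L, ...)
}

# one full paper-like desk run (truth + rendered stack + analysis); the
# per-frame pixel cell masks are dropped from the cache (the window-level
# fields retain everything the tests use) to keep ten cached runs light
desk_run <- function(seed, ...) {
  scfg <- desk_sim_config(seed = seed, ...)
  truth <- simulate_colony(scfg)
  stack <- render_frames(truth)
  analysis <- analyze_stack(stack, desk_pipeline_config())
  analysis$masks <- analysis$masks[1]
  list(config = scfg, truth = truth, stack = stack, analysis = analysis)
}

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# the ten seeded paper-like runs used by the segmentation / coverage / EPS
# acceptance checks
paper_runs <- function(n = 10L) {
  cached("paper_runs", lapply(seq_len(n), desk_run))
}

# three nonbiofilm-mutant-like runs (no EPS subpopulation, no trapping)
mutant_runs <- function() {
  cached("mutant_runs", lapply(101:103, function(s) {
    desk_run(s, eps_fraction = 0, p_trap = 0)
  }))
}

# window-grid ground-truth aggregate mask of a run at frame-pair t
truth_window_mask <- function(run, t) {
  w <- round(run$analysis$window / run$stack$pixel_size)
  gt <- truth_aggregate_mask(run$truth, t)
  swarmaggr:::block_stat(gt * 1, w) >= 0.5
}

# small textured frame pair with a known integer shift, for flow tests
shifted_pair <- function(n = 200, shift = 2L, seed = 7) {
  set.seed(seed)
  base <- matrix(stats::runif(n * n), n, n)
  sm <- as.matrix(EBImage::gblur(base, sigma = 2))
  f2 <- cbind(sm[, (n - shift + 1):n], sm[, 1:(n - shift)])
  image_stack(list(ch = array(c(sm, f2), c(n, n, 2))),
              pixel_size = 1 / 6, frame_interval = 0.02)
}
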