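small_cfg <- function(...) {
  sim_config(box_side = 40, n_agents = 300, n_steps = 20, burn_in = 50,
             pixel_size = 1 / 3, seed = 42, ...)
}

test_that("configuration invariants are enforced", {
  expect_error(sim_config(eps_fraction = 1.2), "eps_fraction")
  expect_error(sim_config(p_trap = -0.1), "p_trap")
  expect_error(sim_config(run_time_min = 2, run_time_max = 1), "run_time_min")
  expect_error(sim_config(box_side = 10, trap_radius = 6), "trap_radius")
  cfg <- small_cfg()
  expect_s3_class(cfg, "sim_config")
  # YAML round trip
  p <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, p)
  expect_equal(unclass(read_sim_config(p)), unclass(cfg), tolerance = 1e-9)
})

test_that("without seeds or trapping no agent is ever trapped", {
  tr <- simulate_colony(small_cfg(eps_fraction = 0, p_trap = 0))
  expect_true(all(tr$state == 0L))
  expect_false(any(truth_aggregate_mask(tr, 1)))
  expect_false(any(truth_aggregate_mask(tr, ncol(tr$x))))
})

test_that("the EPS-immotile count is the configured fraction, and EPS never move", {
  cfg <- small_cfg(eps_fraction = 0.25)
  tr <- simulate_colony(cfg)
  n_eps <- sum(tr$state[, 1] == 2L)
  expect_equal(n_eps, round(0.25 * cfg$n_agents))
  eps <- which(tr$state[, 1] == 2L)
  expect_true(all(tr$state[eps, ] == 2L))
  expect_equal(tr$x[eps, ], tr$x[eps, c(1, 1:(ncol(tr$x) - 1))])
  expect_equal(max(abs(tr$x[eps, ] - tr$x[eps, 1])), 0)
  expect_equal(max(abs(tr$y[eps, ] - tr$y[eps, 1])), 0)
})

test_that("irreversible trapping gives a nondecreasing trapped count", {
  cfg <- sim_config(box_side = 30, n_agents = 50, n_steps = 500, burn_in = 0,
                    pixel_size = 1 / 3, seed = 5, eps_fraction = 0.3,
                    p_trap = 1, p_escape = 0)
  tr <- simulate_colony(cfg)
  trapped <- colSums(tr$state == 1L) # direct-count oracle per frame
  expect_true(all(diff(trapped) >= 0))
  expect_gt(trapped[500], 0)
})

test_that("simulation and rendering are bit-reproducible given the seed", {
  cfg <- small_cfg()
  t1 <- simulate_colony(cfg)
  t2 <- simulate_colony(cfg)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$state, t2$state)
  s1 <- render_frames(t1)
  s2 <- render_frames(t2)
  expect_identical(s1$channels$all, s2$channels$all)
})

test_that("with escape the trapped population reaches a fluctuating steady state", {
  cfg <- sim_config(box_side = 50, n_agents = 750, n_steps = 600,
                    burn_in = 600, pixel_size = 1 / 3, seed = 8)
  tr <- simulate_colony(cfg)
  frac <- colMeans(tr$state == 1L)
  q3 <- frac[301:450]
  q4 <- frac[451:600]
  # Monte-Carlo standard error from block means (the per-frame series is
  # strongly autocorrelated)
  blocks <- vapply(split(frac[301:600], rep(1:10, each = 30)), mean,
                   numeric(1))
  se <- stats::sd(blocks) / sqrt(10) * sqrt(2)
  expect_lt(abs(mean(q4) - mean(q3)), 3 * max(se, 1e-6))
})

test_that("free motile agents are superdiffusive over sub-run-time lags", {
  cfg <- sim_config(box_side = 60, n_agents = 500, n_steps = 100,
                    burn_in = 100, pixel_size = 1 / 3, seed = 12,
                    eps_fraction = 0, p_trap = 0)
  tr <- simulate_colony(cfg)
  tracks <- truth_phase_tracks(tr, "MOTILE", min_length = 100, sigma = 0)
  # ensemble MSD across agents, lags up to 0.5 s (< run_time_max)
  lags <- c(2, 4, 8, 16, 25)
  msd <- vapply(lags, function(k) {
    mean(vapply(tracks, function(d) {
      n <- nrow(d)
      mean((d$x_um[(1 + k):n] - d$x_um[1:(n - k)])^2 +
             (d$y_um[(1 + k):n] - d$y_um[1:(n - k)])^2)
    }, numeric(1)))
  }, numeric(1))
  beta <- stats::coef(stats::lm(log(msd) ~ log(lags)))[2]
  expect_gt(beta, 1.2)
})

test_that("rendering produces calibrated two-channel frames", {
  cfg <- small_cfg(eps_fraction = 0.25)
  tr <- simulate_colony(cfg)
  st <- render_frames(tr)
  expect_s3_class(st, "image_stack")
  d <- dim(st)
  expect_equal(d[1:2], c(120, 120))
  expect_equal(d[3], cfg$n_steps)
  expect_true(all(st$channels$all >= 0 & st$channels$all <= 1))
  # EPS channel is strictly a subset scene of the all-cells channel
  expect_lt(mean(st$channels$eps[, , 1] > 0.5),
            mean(st$channels$all[, , 1] > 0.5))

  # empty scene: both channels are pure noise around the background level
  cfg0 <- sim_config(box_side = 20, n_agents = 0, n_steps = 2, burn_in = 0,
                     pixel_size = 1 / 2, seed = 1)
  st0 <- render_frames(simulate_colony(cfg0))
  expect_lt(mean(st0$channels$all), 0.05)

  # one stationary agent at the center: intensity peaks near the center
  cfg1 <- sim_config(box_side = 20, n_agents = 1, n_steps = 3, burn_in = 0,
                     pixel_size = 1 / 4, seed = 1, eps_fraction = 1,
                     noise_sd = 0)
  tr1 <- simulate_colony(cfg1)
  tr1$x[] <- 10; tr1$y[] <- 10
  st1 <- render_frames(tr1)
  for (f in 1:3) {
    pk <- which(st1$channels$all[, , f] == max(st1$channels$all[, , f]),
                arr.ind = TRUE)[1, ]
    expect_lt(max(abs(pk - 40.5)) * cfg1$pixel_size, cfg1$cell_width + 0.5)
  }

  # a box that does not map onto whole pixels is rejected
  cfg_bad <- small_cfg()
  cfg_bad$pixel_size <- 0.33
  expect_error(render_frames(simulate_colony(small_cfg()), cfg_bad),
               "integer pixel grid")
})

test_that("ground-truth masks cover every non-motile agent position", {
  cfg <- small_cfg(eps_fraction = 0.3, p_trap = 0.2)
  tr <- simulate_colony(cfg)
  np <- 120
  for (f in c(1, 10, 20)) {
    msk <- truth_aggregate_mask(tr, f)
    nm <- which(tr$state[, f] != 0L)
    rows <- pmin(pmax(floor(tr$y[nm, f] / cfg$pixel_size) + 1, 1), np)
    cols <- pmin(pmax(floor(tr$x[nm, f] / cfg$pixel_size) + 1, 1), np)
    expect_true(all(msk[cbind(rows, cols)]))
  }
})
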