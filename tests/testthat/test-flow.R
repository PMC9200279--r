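test_that("identical frames yield zero flow", {
  set.seed(4)
  f <- as.matrix(EBImage::gblur(matrix(runif(150 * 150), 150), 2))
  st <- image_stack(list(ch = array(c(f, f), c(150, 150, 2))), 1 / 6, 0.02)
  fl <- compute_dense_flow(st, 1)
  expect_lt(max(abs(fl$dx)), 1e-3)
  expect_lt(max(abs(fl$dy)), 1e-3)
})

test_that("a 2 px translation is recovered within 0.2 px in the interior", {
  st <- shifted_pair(n = 200, shift = 2L)
  # independent oracle: integer-shift cross-correlation
  f1 <- st$channels$ch[, , 1]
  f2 <- st$channels$ch[, , 2]
  cc <- vapply(0:4, function(s) {
    cor(as.vector(f1[, 1:(200 - 4)]), as.vector(f2[, (1 + s):(200 - 4 + s)]))
  }, numeric(1))
  expect_equal(which.max(cc) - 1L, 2L)

  fl <- compute_dense_flow(st, 1)
  interior <- 30:170
  expect_lt(abs(median(fl$dx[interior, interior]) - 2), 0.2)
  expect_lt(abs(median(fl$dy[interior, interior])), 0.2)
})

test_that("mirroring both frames negates the x-component", {
  st <- shifted_pair(n = 160, shift = 1L)
  n <- 160
  flipped <- image_stack(
    list(ch = array(c(st$channels$ch[, n:1, 1], st$channels$ch[, n:1, 2]),
                    c(n, n, 2))), st$pixel_size, st$frame_interval)
  fl <- compute_dense_flow(st, 1)
  flf <- compute_dense_flow(flipped, 1)
  interior <- 25:135
  expect_equal(median(flf$dx[interior, interior]),
               -median(fl$dx[interior, interior]), tolerance = 0.05)
})

test_that("coarse graining block-averages exactly and conserves the mean", {
  fl <- structure(list(dx = matrix(3, 48, 48), dy = matrix(-4, 48, 48),
                       pixel_size = 0.5, frame_interval = 0.1),
                  class = "dense_flow")
  ff <- coarse_grain(fl, window = 4) # 8 px windows, tile exactly
  expect_true(all(ff$vx == 3 * 0.5 / 0.1))
  expect_true(all(ff$vy == -4 * 0.5 / 0.1))

  # checkerboard of +v/-v averages to ~0
  chk <- matrix(rep(c(1, -1), length.out = 48 * 48), 48, 48)
  fl$dx <- chk; fl$dy <- -chk
  ff <- coarse_grain(fl, window = 4)
  expect_lt(max(abs(ff$vx)), 1e-12)

  # random field equals the brute-force window mean, and conserves the
  # domain mean when windows tile the image
  set.seed(2)
  fl$dx <- matrix(rnorm(48 * 48), 48, 48)
  fl$dy <- matrix(rnorm(48 * 48), 48, 48)
  ff <- coarse_grain(fl, window = 4)
  expect_equal(ff$vx[2, 3], mean(fl$dx[9:16, 17:24]) * 5)
  expect_equal(mean(ff$vx), mean(fl$dx) * 5)

  expect_error(coarse_grain(fl, window = 100), "window larger than image")
  expect_error(coarse_grain(fl, window = 0.5), "at least 2 pixels")
})

test_that("masked coarse graining marks cell-free windows missing", {
  fl <- structure(list(dx = matrix(1, 24, 24), dy = matrix(0, 24, 24),
                       pixel_size = 1, frame_interval = 1),
                  class = "dense_flow")
  mask <- matrix(FALSE, 24, 24)
  mask[1:8, 1:8] <- TRUE
  ff <- coarse_grain(fl, window = 8, cell_mask = mask)
  expect_equal(ff$vx[1, 1], 1)
  expect_true(is.na(ff$vx[2, 2]))
  expect_true(is.na(ff$vx[3, 1]))
})

test_that("speed is the per-node Euclidean norm", {
  ff <- structure(list(vx = matrix(3, 2, 2), vy = matrix(4, 2, 2),
                       x = 1:2, y = 1:2, window = 1), class = "flow_field")
  expect_true(all(speed(ff)$speed == 5))
  ff$vx[] <- 0; ff$vy[] <- 0
  expect_true(all(speed(ff)$speed == 0))
  set.seed(1)
  ff$vx <- matrix(rnorm(4), 2); ff$vy <- matrix(rnorm(4), 2)
  expect_equal(speed(ff)$speed, sqrt(ff$vx^2 + ff$vy^2))
})

test_that("flow separates a static region from the moving swarm", {
  # noise-free scene: a static seeded cluster surrounded by swarming cells
  cfg <- sim_config(box_side = 40, n_agents = 450, n_steps = 4, burn_in = 150,
                    pixel_size = 1 / 3, seed = 6, eps_fraction = 0.3,
                    noise_sd = 0)
  tr <- simulate_colony(cfg)
  st <- render_frames(tr)
  fl <- compute_dense_flow(st, 2)
  mag <- sqrt(fl$dx^2 + fl$dy^2)
  gt <- truth_aggregate_mask(tr, 2)
  core <- EBImage::erode(gt * 1, EBImage::makeBrush(15, "disc")) > 0
  moving <- !gt & cell_mask(st$channels$all[, , 2])
  expect_gt(sum(core), 50)
  expect_gt(sum(moving), 50)
  expect_lt(mean(mag[core]), 0.1 * mean(mag[moving]))

  # and the full pipeline sees the same contrast on a paper-like run
  run <- paper_runs()[[1]]
  an <- run$analysis
  t <- dim(an$speeds)[3]
  gtw <- truth_window_mask(run, t)
  sp <- an$speeds_smoothed[, , t]
  expect_lt(median(sp[gtw], na.rm = TRUE),
            0.5 * median(sp[!gtw], na.rm = TRUE))
})
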