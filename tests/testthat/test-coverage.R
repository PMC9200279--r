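test_that("local coverage is the window mean of the cell mask", {
  mask <- matrix(TRUE, 24, 24)
  cov <- local_coverage(mask, window = 4, pixel_size = 0.5)
  expect_true(all(cov$coverage == 1))

  mask[, 13:24] <- FALSE
  cov <- local_coverage(mask, window = 12, pixel_size = 0.5)
  expect_equal(dim(cov$coverage), c(1, 1))
  expect_equal(cov$coverage[1, 1], 0.5)

  half <- matrix(FALSE, 8, 8); half[1:4, ] <- TRUE
  cov <- local_coverage(half, window = 8, pixel_size = 1)
  expect_equal(cov$coverage[1, 1], 0.5)
})

test_that("a constant frame yields an empty mask with a warning", {
  expect_warning(m <- cell_mask(matrix(0.5, 32, 32)), "constant")
  expect_false(any(m))
})

test_that("cell masks recover rendered cell footprints", {
  cfg <- sim_config(box_side = 30, n_agents = 120, n_steps = 2, burn_in = 20,
                    pixel_size = 1 / 3, seed = 3, eps_fraction = 0)
  tr <- simulate_colony(cfg)
  st <- render_frames(tr)
  m <- cell_mask(st$channels$all[, , 1])
  gt <- swarmaggr:::.render_mask_cpp(tr$x[, 1], tr$y[, 1], tr$heading[, 1],
                                     rep(TRUE, nrow(tr$x)), 90, 1 / 3, 30,
                                     cfg$cell_length / 2, cfg$cell_width / 2)
  expect_gt(mask_iou(m, gt), 0.6)
})

test_that("speed binning is exact on constructed fields", {
  # uniform speed: every populated bin reports that speed, all regions
  speeds <- array(7, c(6, 6, 4))
  covs <- array(rep(seq(0.05, 0.95, length.out = 36), 4), c(6, 6, 4))
  inside <- array(FALSE, c(6, 6, 4))
  inside[1:3, , ] <- TRUE
  cfg <- pipeline_config(min_windows_per_bin = 1L)
  for (r in c("ALL", "INSIDE", "OUTSIDE")) {
    rel <- bin_speed_by_coverage(speeds, covs, inside, r, cfg)
    expect_true(all(rel$mean_speed == 7))
  }

  # suppression of sparse bins
  cfg10 <- pipeline_config(min_windows_per_bin = 1000L)
  rel <- bin_speed_by_coverage(speeds, covs, inside, "ALL", cfg10)
  expect_equal(nrow(rel), 0)

  # weighted decomposition is exact by construction
  set.seed(5)
  speeds <- array(runif(6 * 6 * 4, 0, 20), c(6, 6, 4))
  relA <- bin_speed_by_coverage(speeds, covs, inside, "ALL", cfg)
  relI <- bin_speed_by_coverage(speeds, covs, inside, "INSIDE", cfg)
  relO <- bin_speed_by_coverage(speeds, covs, inside, "OUTSIDE", cfg)
  m <- merge(merge(relA, relI, by = "coverage", suffixes = c("_a", "_i")),
             relO, by = "coverage")
  recon <- (m$n_i * m$mean_speed_i + m$n * m$mean_speed) / (m$n_i + m$n)
  expect_equal(m$mean_speed_a, recon, tolerance = 1e-12)
})

test_that("aggregate fraction per coverage bin matches direct counting", {
  covs <- array(c(0.2, 0.2, 0.8, 0.8, 0.8, 0.2, 0.8, 0.2), c(2, 2, 2))
  inside <- array(c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE),
                  c(2, 2, 2))
  cfg <- pipeline_config(coverage_bin_width = 0.5, min_windows_per_bin = 1L)
  af <- aggregate_fraction_by_coverage(covs, inside, cfg)
  # low bin: coverages 0.2 x4, inside 1 of them -> 0.2/(0.8)
  low <- af$aggregate_fraction[af$bin_lo == 0]
  expect_equal(low, 0.25)
  hi <- af$aggregate_fraction[af$bin_lo == 0.5]
  expect_equal(hi, 0.5)

  # no aggregates -> 0; all stationary -> 1
  af0 <- aggregate_fraction_by_coverage(covs, inside & FALSE, cfg)
  expect_true(all(af0$aggregate_fraction == 0))
  af1 <- aggregate_fraction_by_coverage(covs, inside | TRUE, cfg)
  expect_true(all(af1$aggregate_fraction == 1))
})

test_that("radial profiles summarize tagged fields of view", {
  mk <- function(speed, ratio_on) {
    speeds <- array(speed, c(4, 4, 3))
    covs <- array(0.6, c(4, 4, 3))
    cellw <- covs >= 0.5
    cfg <- pipeline_config(speed_threshold = 1, persistence_frames = 1L,
                           speed_smooth_pairs = 1L)
    if (ratio_on) speeds[1:2, , ] <- 0.1
    lb <- segment_stationary(speeds, cellw[, , 1:3], cfg, window = 4)
    structure(list(speeds = speeds, coverages = covs, cellw = cellw,
                   labeling = lb, inside = persistent_mask(lb)),
              class = "swarm_analysis")
  }
  rp <- radial_profile(list(mk(10, TRUE), mk(12, FALSE)), c(0, 4))
  expect_equal(nrow(rp), 2)
  expect_equal(rp$aggregate_ratio[rp$distance_mm == 4], 0)
  expect_gt(rp$aggregate_ratio[rp$distance_mm == 0], 0.3)

  # single distance is a single-row profile
  rp1 <- radial_profile(list(mk(10, FALSE)), 2)
  expect_equal(nrow(rp1), 1)

  # duplicate distances are averaged with a warning
  expect_warning(rpd <- radial_profile(list(mk(10, FALSE), mk(20, FALSE)),
                                       c(2, 2)), "duplicate")
  expect_equal(nrow(rpd), 1)
  expect_equal(rpd$mean_speed, 15)
})
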