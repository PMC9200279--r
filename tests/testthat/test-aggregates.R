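test_that("8-connected labeling joins diagonals and separates islands", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- m[2, 2] <- TRUE # diagonal touch: one component
  m[5, 5] <- TRUE
  lab <- swarmaggr:::.label8_cpp(m)
  expect_equal(max(lab), 2L)
  expect_equal(lab[1, 1], lab[2, 2])
  expect_true(lab[5, 5] != lab[1, 1])
})

test_that("a uniformly fast field has no stationary aggregates", {
  speeds <- array(10, c(8, 8, 5))
  cellw <- array(TRUE, c(8, 8, 5))
  lb <- segment_stationary(speeds, cellw, pipeline_config(
    speed_threshold = 1, persistence_frames = 2L, speed_smooth_pairs = 1L),
    window = 4)
  expect_equal(nrow(lb$components), 0)
  expect_false(any(persistent_mask(lb)))
})

test_that("a persistent slow block is segmented with the right area", {
  speeds <- array(10, c(10, 10, 6))
  speeds[3:6, 3:7, ] <- 0.1 # 20 windows, static throughout
  cellw <- array(TRUE, c(10, 10, 6))
  cfg <- pipeline_config(speed_threshold = 1, persistence_frames = 2L,
                         speed_smooth_pairs = 1L)
  lb <- segment_stationary(speeds, cellw, cfg, window = 4)
  cc <- lb$components
  # first K frames cannot be assessed; later ones are persistent
  expect_true(all(!cc$persistent[cc$frame <= 2]))
  late <- cc[cc$frame > 2, ]
  expect_true(all(late$persistent))
  expect_true(all(late$area_um2 == 20 * 16))
})

test_that("raising the threshold never shrinks the raw stationary area", {
  set.seed(9)
  speeds <- array(runif(10 * 10 * 4, 0, 10), c(10, 10, 4))
  cellw <- array(TRUE, c(10, 10, 4))
  areas <- vapply(c(1, 3, 5, 8), function(thr) {
    lb <- segment_stationary(speeds, cellw, pipeline_config(
      speed_threshold = thr, persistence_frames = 1L,
      speed_smooth_pairs = 1L), window = 4)
    sum(lb$threshold_mask)
  }, numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("the aggregate ratio is the cell-area fraction inside aggregates", {
  # constructed: half the (fully covered) field stationary
  speeds <- array(10, c(10, 10, 4))
  speeds[1:5, , ] <- 0.1
  cellw <- array(TRUE, c(10, 10, 4))
  cfg <- pipeline_config(speed_threshold = 1, persistence_frames = 1L,
                         speed_smooth_pairs = 1L)
  lb <- segment_stationary(speeds, cellw, cfg, window = 4)
  an <- list(labeling = lb, coverages = array(1, c(10, 10, 4)))
  r <- aggregate_ratio(an)
  expect_equal(r$per_frame[3], 0.5, tolerance = 0.01)

  # all stationary -> 1; none -> 0
  speeds[] <- 0.1
  lb <- segment_stationary(speeds, cellw, cfg, window = 4)
  expect_equal(aggregate_ratio(list(labeling = lb,
                                    coverages = an$coverages))$per_frame[3], 1)
  speeds[] <- 10
  lb <- segment_stationary(speeds, cellw, cfg, window = 4)
  expect_equal(aggregate_ratio(list(labeling = lb,
                                    coverages = an$coverages))$per_frame[3], 0)

  # zero cell area is reported missing
  expect_warning(
    lb0 <- segment_stationary(array(NA_real_, c(4, 4, 2)),
                              array(FALSE, c(4, 4, 2)), cfg, window = 4),
    "empty cell mask")
  r0 <- aggregate_ratio(list(labeling = lb0,
                             coverages = array(0, c(4, 4, 2))))
  expect_true(all(is.na(r0$per_frame)))
})

test_that("pooling collects persistent areas with the requested stride", {
  speeds <- array(10, c(12, 12, 6))
  # blocks at least two windows from the border: morphological closing with
  # replicate boundary handling leaves them intact
  speeds[3:5, 3:5, ] <- 0.1
  speeds[8:10, 6:9, ] <- 0.1
  cellw <- array(TRUE, c(12, 12, 6))
  cfg <- pipeline_config(speed_threshold = 1, persistence_frames = 1L,
                         speed_smooth_pairs = 1L)
  lb <- segment_stationary(speeds, cellw, cfg, window = 4)
  s1 <- pool_sizes(lb, stride = 1)
  # two components in each of frames 2..6
  expect_length(s1, 10)
  expect_setequal(unique(s1), c(9, 12) * 16)
  s5 <- pool_sizes(lb, stride = 5)
  expect_length(s5, 2)
  expect_gte(min(s1), cfg$min_aggregate_area)
})

test_that("small components are removed by the minimum-area filter", {
  speeds <- array(10, c(12, 12, 3))
  speeds[1, 1, ] <- 0.1            # single 4x4 um window = 16 um^2
  speeds[5:8, 5:8, ] <- 0.1        # 16 windows
  cellw <- array(TRUE, c(12, 12, 3))
  cfg <- pipeline_config(speed_threshold = 1, min_aggregate_area = 100,
                         persistence_frames = 1L, speed_smooth_pairs = 1L)
  lb <- segment_stationary(speeds, cellw, cfg, window = 4)
  cc <- lb$components[lb$components$frame == 2, ]
  expect_equal(nrow(cc), 1)
  expect_gte(cc$area_um2, 100)
})

test_that("mask IoU behaves as a similarity measure", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  expect_equal(mask_iou(a, a), 1)
  b <- matrix(FALSE, 4, 4); b[3:4, 3:4] <- TRUE
  expect_equal(mask_iou(a, b), 0)
  c2 <- matrix(FALSE, 4, 4); c2[1:2, 1:4] <- TRUE
  expect_equal(mask_iou(a, c2), 0.5)
})
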