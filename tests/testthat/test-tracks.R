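cfg <- pipeline_config()

test_that("linking follows single and well-separated movers without swaps", {
  # one detection per frame
  d <- data.frame(frame = 0:99, x_um = cumsum(runif(100, 0, 0.2)),
                  y_um = cumsum(runif(100, 0, 0.2)))
  lk <- link_tracks(d, max_disp = 0.5)
  expect_equal(length(unique(lk$track_id)), 1)
  expect_equal(nrow(lk), 100)

  # two movers far apart: two tracks, zero identity swaps
  d2 <- rbind(
    data.frame(frame = 0:99, x_um = 1 + 0.1 * (0:99), y_um = 1, who = 1),
    data.frame(frame = 0:99, x_um = 50 - 0.1 * (0:99), y_um = 50, who = 2))
  lk2 <- link_tracks(d2[order(d2$frame), ], max_disp = 0.5)
  expect_equal(length(unique(lk2$track_id)), 2)
  purity <- tapply(lk2$who, lk2$track_id,
                   function(w) max(table(w)) / length(w))
  expect_true(all(purity == 1))

  # gap closing bridges a missing detection
  d3 <- d[-50, ]
  lk3 <- link_tracks(d3, max_disp = 0.5, memory = 2)
  expect_equal(length(unique(lk3$track_id)), 1)
})

test_that("sparse simulator detections are linked to the right agents", {
  run <- paper_runs()[[1]]
  det <- detections_from_truth(run$truth, fraction = 0.01, sigma = 0.05)
  lk <- link_tracks(det[c("frame", "x_um", "y_um", "agent_id")],
                    max_disp = 0.8, memory = 2)
  correct <- sum(vapply(split(lk$agent_id, lk$track_id),
                        function(a) max(table(a)), numeric(1))) / nrow(lk)
  expect_gte(correct, 0.95)
})

test_that("MSD matches closed forms", {
  # stationary track: identically zero
  trk <- data.frame(frame = 0:99, x_um = 5, y_um = 7)
  m <- compute_msd(trk, 0.02, cfg)
  expect_true(all(m$msd == 0))
  expect_error(fit_beta(m), "zero MSD")

  # ballistic: MSD = v^2 tau^2 exactly, beta = 2
  v <- c(3, 4)
  tt <- 0:199
  bal <- data.frame(frame = tt, x_um = v[1] * tt * 0.02,
                    y_um = v[2] * tt * 0.02)
  m <- compute_msd(bal, 0.02, cfg)
  expect_equal(m$msd, 25 * m$tau^2, tolerance = 1e-12)
  fb <- suppressWarnings(fit_beta(m))
  expect_equal(fb$beta, 2, tolerance = 0.01)

  # random walk: beta near 1 and MSD near the ensemble closed form,
  # averaged over tracks to tame single-track fluctuations
  set.seed(6)
  sig <- 0.3
  betas <- numeric(10)
  msd1 <- numeric(10)
  for (i in 1:10) {
    rw <- data.frame(frame = 0:400,
                     x_um = cumsum(c(0, rnorm(400, 0, sig))),
                     y_um = cumsum(c(0, rnorm(400, 0, sig))))
    m <- compute_msd(rw, 0.02, cfg)
    betas[i] <- fit_beta(m)$beta
    msd1[i] <- m$msd[10]
  }
  expect_equal(mean(betas), 1, tolerance = 0.1)
  expect_equal(mean(msd1), 2 * sig^2 * 10, tolerance = 0.15)

  # short tracks are refused
  expect_error(compute_msd(bal[1:10, ], 0.02, cfg), "min_track_length")
})

test_that("beta fitting recovers exact and noisy exponents", {
  tau <- (1:50) * 0.02
  mk <- function(b, noise = 0) {
    data.frame(lag = 1:50, tau = tau,
               msd = tau^b * exp(rnorm(50, 0, noise)))
  }
  expect_equal(suppressWarnings(fit_beta(structure(mk(2), class = c("msd_curve", "data.frame"))))$beta,
               2, tolerance = 1e-9)
  expect_equal(suppressWarnings(fit_beta(structure(mk(0.5), class = c("msd_curve", "data.frame"))))$beta,
               0.5, tolerance = 1e-9)
  set.seed(8)
  b15 <- fit_beta(structure(mk(1.5, 0.01), class = c("msd_curve", "data.frame")))
  expect_equal(b15$beta, 1.5, tolerance = 0.05 / 1.5)
  expect_error(fit_beta(structure(mk(2)[1:3, ], class = c("msd_curve", "data.frame"))),
               "at least 5")
})

test_that("trajectories are classified by their scaling regime", {
  tt <- 0:199
  mk_b <- function(v) data.frame(frame = tt, x_um = v * tt * 0.02,
                                 y_um = 0.3 * v * tt * 0.02)
  sup <- suppressWarnings(classify_trajectory(mk_b(10), 0.02, cfg))
  expect_equal(sup$class, "SUPER")
  expect_gt(sup$beta, 1.6)

  # confined jitter: subdiffusive
  set.seed(9)
  conf <- data.frame(frame = tt, x_um = 3 + rnorm(200, 0, 0.05),
                     y_um = 3 + rnorm(200, 0, 0.05))
  sub <- classify_trajectory(conf, 0.02, cfg)
  expect_equal(sub$class, "SUB")
  expect_lt(sub$beta, 0.5)

  # ballistic first half, confined second half: transitive
  sw <- rbind(
    data.frame(frame = 0:99, x_um = 0.2 * (0:99), y_um = 0.1 * (0:99)),
    data.frame(frame = 100:199, x_um = 0.2 * 99 + rnorm(100, 0, 0.05),
               y_um = 0.1 * 99 + rnorm(100, 0, 0.05)))
  tra <- suppressWarnings(classify_trajectory(sw, 0.02, cfg))
  expect_equal(tra$class, "TRANSITIVE")
})

test_that("time reversal leaves the time-averaged MSD unchanged", {
  set.seed(10)
  trk <- data.frame(frame = 0:150,
                    x_um = cumsum(c(0, rnorm(150, 0.05, 0.2))),
                    y_um = cumsum(c(0, rnorm(150, 0, 0.2))))
  rev <- data.frame(frame = 0:150, x_um = rev(trk$x_um), y_um = rev(trk$y_um))
  expect_equal(compute_msd(trk, 0.02, cfg)$msd,
               compute_msd(rev, 0.02, cfg)$msd)
})

test_that("the exponent histogram flags unimodal and empty inputs sanely", {
  tt <- 0:199
  tab <- suppressWarnings(analyze_tracks(do.call(rbind, lapply(1:6, function(i) {
    data.frame(track_id = i, frame = tt, x_um = i + 5 * tt * 0.02,
               y_um = 2 * i * tt * 0.02)
  })), 0.02, cfg))
  h <- beta_histogram(tab)
  expect_equal(h$n, 6)
  expect_true(all(abs(h$betas - 2) < 0.05))

  h0 <- beta_histogram(numeric(0))
  expect_equal(h0$n, 0)
  expect_true(is.na(h0$bimodality))
})
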