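#' Simulation configuration for the synthetic swarm generator
#'
#' Builds and validates the parameter set of the agent-based generator:
#' motile swarmer cells performing run-and-tumble motion with heavy-tailed
#' (truncated Pareto) run durations, an immotile EPS-secreting subpopulation
#' placed as clustered nuclei, and neighborhood-triggered, partially
#' reversible trapping of motile cells near non-motile ones. The defaults
#' emulate the imaging regime of a dense swarming monolayer: a 150 um
#' periodic box at 1/6 um/px (a 900 px field of view), 50 frames/s, ~5 um
#' long cells, a 25% EPS-secreting subpopulation, and an agent density that
#' yields a thresholded surface coverage around 0.6.
#'
#' @param box_side side of the periodic box (um).
#' @param n_agents number of agents; `NULL` picks a density calibrated to a
#'   thresholded surface coverage in the 0.5-0.8 regime at the
#'   defaults (0.30 agents/um^2).
#' @param eps_fraction fraction of agents that are immotile EPS secretors
#'   (in `[0, 1]`).
#' @param speed_motile free swimming speed scale (um/s).
#' @param run_time_exponent tail exponent of the truncated-Pareto run
#'   durations (dimensionless; values in (1, 2) give Levy-like
#'   superdiffusive runs).
#' @param run_time_min,run_time_max run-duration truncation bounds (s).
#' @param trap_radius neighborhood radius for trapping (um).
#' @param trap_min_neighbors minimum number of non-motile neighbors within
#'   `trap_radius` required before a motile agent can be trapped.
#' @param p_trap,p_escape per-step trapping / escape probabilities.
#' @param dt time step = frame interval (s).
#' @param n_steps number of recorded frames.
#' @param burn_in unrecorded equilibration steps before the first frame.
#' @param pixel_size um per pixel for rendering.
#' @param cell_length,cell_width cell body dimensions (um).
#' @param align_radius,align_strength radius (um) and per-step relaxation
#'   rate of local heading alignment among motile cells (raft coherence).
#' @param cohesion_strength per-step steering toward the local motile
#'   center of mass; organises the swarm into dense rafts.
#' @param repulsion_push per-step push amplitude of the soft elliptical
#'   excluded-volume interaction keeping motile cells at monolayer
#'   packing (the exclusion zone follows the cell body dimensions).
#' @param rot_noise rotational diffusion amplitude (rad/sqrt(s)).
#' @param speed_base_frac fraction of `speed_motile` retained at zero local
#'   crowding; speed rises linearly with the local neighbor count up to
#'   `n_sat` neighbors (cooperative speed-up of dense swarms).
#' @param n_sat neighbor count within `align_radius` at which the speed
#'   saturates.
#' @param eps_nucleus_size mean number of EPS cells per nucleus; together
#'   with `eps_fraction` this sets how many aggregate seeds the field of
#'   view holds.
#' @param eps_nucleus_packing surface coverage of a nucleus disc; the
#'   nucleus radius is derived from it and the cell footprint.
#' @param eps_drift if `TRUE`, EPS cells adjacent to three or more motile
#'   cells drift slowly along the local swarm direction (off by default).
#' @param eps_drift_speed drift speed for the option above (um/s).
#' @param noise_sd additive Gaussian image noise (fraction of kernel peak).
#' @param seed integer RNG seed; every stochastic stage of the generator is
#'   reproducible given the seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(box_side = 150, n_agents = NULL, eps_fraction = 0.25,
                       speed_motile = 25, run_time_exponent = 1.6,
                       run_time_min = 0.04, run_time_max = 2,
                       trap_radius = 2, trap_min_neighbors = 3,
                       p_trap = 0.03, p_escape = 0.01,
                       dt = 0.02, n_steps = 150, burn_in = 400,
                       pixel_size = 1 / 6, cell_length = 5, cell_width = 1,
                       align_radius = 4, align_strength = 0.7, cohesion_strength = 0.05,
                       repulsion_push = 0.15,
                       rot_noise = 0.15, speed_base_frac = 0.15, n_sat = 12,
                       eps_nucleus_size = 240, eps_nucleus_packing = 2,
                       eps_drift = FALSE, eps_drift_speed = 0.2,
                       noise_sd = 0.05, seed = 1L) {
  if (is.null(n_agents)) n_agents <- round(0.30 * box_side^2)
  cfg <- list(box_side = box_side, n_agents = as.integer(n_agents),
              eps_fraction = eps_fraction, speed_motile = speed_motile,
              run_time_exponent = run_time_exponent,
              run_time_min = run_time_min, run_time_max = run_time_max,
              trap_radius = trap_radius,
              trap_min_neighbors = as.integer(trap_min_neighbors),
              p_trap = p_trap, p_escape = p_escape, dt = dt,
              n_steps = as.integer(n_steps), burn_in = as.integer(burn_in),
              pixel_size = pixel_size, cell_length = cell_length,
              cell_width = cell_width, align_radius = align_radius,
              align_strength = align_strength,
              cohesion_strength = cohesion_strength,
              repulsion_push = repulsion_push, rot_noise = rot_noise,
              speed_base_frac = speed_base_frac, n_sat = n_sat,
              eps_nucleus_size = eps_nucleus_size,
              eps_nucleus_packing = eps_nucleus_packing,
              eps_drift = isTRUE(eps_drift),
              eps_drift_speed = eps_drift_speed,
              noise_sd = noise_sd, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(
      box_side > 0, n_agents >= 0, dt > 0, n_steps > 0, burn_in >= 0,
      pixel_size > 0, cell_length > 0, cell_width > 0,
      speed_motile > 0, run_time_min > 0, run_time_max > 0,
      trap_radius > 0, trap_min_neighbors > 0, noise_sd >= 0
    )
    if (eps_fraction < 0 || eps_fraction > 1) stop("eps_fraction must be in [0,1]")
    if (p_trap < 0 || p_trap > 1) stop("p_trap must be in [0,1]")
    if (p_escape < 0 || p_escape > 1) stop("p_escape must be in [0,1]")
    if (run_time_min >= run_time_max) stop("run_time_min must be < run_time_max")
    if (trap_radius > box_side / 2) {
      stop("trap_radius exceeds box_side/2: neighborhoods are ill-posed")
    }
  })
  invisible(cfg)
}

#' Read / write a simulation configuration as YAML
#'
#' @param path YAML file path.
#' @param cfg a [sim_config()] object.
#' @return `read_sim_config` returns a `sim_config`; `write_sim_config`
#'   returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 12L)
  invisible(path)
}

#' Run the agent-based swarm simulation
#'
#' Simulates `n_agents` cells in a periodic box. A fraction `eps_fraction`
#' of agents is immotile (EPS-secreting) from the start, placed as clustered
#' nuclei; the rest perform run-and-tumble motion with truncated-Pareto run
#' durations (superdiffusive free motion), weak local alignment, and a
#' cooperative density-dependent speed. A motile agent within `trap_radius`
#' of at least `trap_min_neighbors` non-motile agents becomes trapped with
#' probability `p_trap` per step; trapped agents escape with probability
#' `p_escape` per step. Trapped and EPS agents do not move.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `swarm_truth`: arrays `x`, `y`, `heading`
#'   (`n_agents x n_frames`, um and radians), integer `state`
#'   (`0` motile, `1` trapped, `2` EPS-immotile), and the `config`.
#' @seealso [truth_tracks()], [truth_aggregate_mask()], [render_frames()]
#' @export
simulate_colony <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_agents
  n_eps <- round(config$eps_fraction * n)
  # EPS nuclei: cluster centers uniform in the box, members scattered
  # isotropically around them (truncated at the nucleus radius * 2)
  state0 <- integer(n)
  x0 <- stats::runif(n, 0, config$box_side)
  y0 <- stats::runif(n, 0, config$box_side)
  if (n_eps > 0) {
    state0[seq_len(n_eps)] <- 2L
    n_nuc <- max(1L, round(n_eps / config$eps_nucleus_size))
    # nucleus radius such that the disc is covered at eps_nucleus_packing
    cell_area <- pi * (config$cell_length / 2) * (config$cell_width / 2)
    nuc_r <- sqrt(config$eps_nucleus_size * cell_area /
                    (pi * config$eps_nucleus_packing))
    cx <- stats::runif(n_nuc, 0, config$box_side)
    cy <- stats::runif(n_nuc, 0, config$box_side)
    assign_nuc <- sample.int(n_nuc, n_eps, replace = TRUE)
    r <- nuc_r * sqrt(stats::runif(n_eps)) # uniform in the disc
    th <- stats::runif(n_eps, 0, 2 * pi)
    x0[seq_len(n_eps)] <- (cx[assign_nuc] + r * cos(th)) %% config$box_side
    y0[seq_len(n_eps)] <- (cy[assign_nuc] + r * sin(th)) %% config$box_side
    # motile agents start outside the nuclei (aggregates exclude swimmers)
    mot <- if (n_eps < n) (n_eps + 1):n else integer(0)
    for (it in seq_len(if (length(mot)) 50 else 0)) {
      dx <- outer(x0[mot], cx, function(a, b) {
        d <- abs(a - b); pmin(d, config$box_side - d)
      })
      dy <- outer(y0[mot], cy, function(a, b) {
        d <- abs(a - b); pmin(d, config$box_side - d)
      })
      bad <- rowSums(dx^2 + dy^2 < (nuc_r + 1)^2) > 0
      if (!any(bad)) break
      x0[mot[bad]] <- stats::runif(sum(bad), 0, config$box_side)
      y0[mot[bad]] <- stats::runif(sum(bad), 0, config$box_side)
    }
  }
  h0 <- stats::runif(n, 0, 2 * pi)
  res <- .sim_colony_cpp(x0, y0, h0, state0, config$box_side, config$dt,
                         config$n_steps, config$burn_in,
                         config$speed_motile, config$run_time_exponent,
                         config$run_time_min, config$run_time_max,
                         config$trap_radius, config$trap_min_neighbors,
                         config$p_trap, config$p_escape,
                         config$align_radius, config$align_strength,
                         config$cohesion_strength,
                         config$cell_length / 2 + 0.3,
                         config$cell_width + 0.2, config$repulsion_push,
                         config$rot_noise, config$speed_base_frac,
                         config$n_sat, config$eps_drift,
                         config$eps_drift_speed)
  nf <- config$n_steps
  truth <- list(
    x = matrix(res$x, n, nf),
    y = matrix(res$y, n, nf),
    heading = matrix(res$heading, n, nf),
    state = matrix(res$state, n, nf),
    config = config
  )
  class(truth) <- "swarm_truth"
  truth
}

#' @export
print.swarm_truth <- function(x, ...) {
  nf <- ncol(x$x)
  frac <- table(factor(x$state[, nf], levels = 0:2)) / nrow(x$x)
  cat(sprintf("swarm_truth: %d agents, %d frames, box %g um\n",
              nrow(x$x), nf, x$config$box_side))
  cat(sprintf("final state fractions: motile %.3f, trapped %.3f, EPS %.3f\n",
              frac[1], frac[2], frac[3]))
  invisible(x)
}

#' Ground-truth tracks as a data frame
#'
#' @param truth a `swarm_truth` object from [simulate_colony()].
#' @return data frame with columns `agent_id`, `frame` (0-based), `x_um`,
#'   `y_um`, `state` (`"MOTILE"`, `"TRAPPED"`, `"EPS_IMMOTILE"`).
#' @export
truth_tracks <- function(truth) {
  stopifnot(inherits(truth, "swarm_truth"))
  n <- nrow(truth$x); nf <- ncol(truth$x)
  data.frame(
    agent_id = rep(seq_len(n), nf),
    frame = rep(seq_len(nf) - 1L, each = n),
    x_um = as.vector(truth$x),
    y_um = as.vector(truth$y),
    state = c("MOTILE", "TRAPPED", "EPS_IMMOTILE")[as.vector(truth$state) + 1L]
  )
}

n_pixels <- function(config) {
  np <- config$box_side / config$pixel_size
  # the periodic box must tile the pixel grid exactly (up to numerical
  # tolerance), otherwise wrapping and stamping disagree at the seam
  if (abs(np - round(np)) > 0.01) {
    stop("box_side does not map onto an integer pixel grid")
  }
  as.integer(round(np))
}

#' Ground-truth stationary-aggregate mask
#'
#' Boolean pixel mask that is true where a trapped or EPS-immotile agent's
#' cell footprint lies, dilated by one cell width.
#'
#' @param truth a `swarm_truth`.
#' @param frame frame index (1-based).
#' @return logical matrix (rows = y, cols = x) on the rendering pixel grid.
#' @export
truth_aggregate_mask <- function(truth, frame) {
  cfg <- truth$config
  np <- n_pixels(cfg)
  keep <- truth$state[, frame] != 0L
  .render_mask_cpp(truth$x[, frame], truth$y[, frame], truth$heading[, frame],
                   keep, np, cfg$pixel_size, cfg$box_side,
                   cfg$cell_length / 2 + cfg$cell_width,
                   cfg$cell_width / 2 + cfg$cell_width)
}

#' Render a simulation to a two-channel image stack
#'
#' Channel `"all"` draws every agent as an anisotropic Gaussian intensity
#' kernel oriented along its heading (FWHM = cell dimensions); channel
#' `"eps"` draws only the EPS-immotile agents. Additive Gaussian noise of
#' standard deviation `noise_sd` (relative to the unit kernel peak) is added
#' and intensities are clipped to `[0, 1]`.
#'
#' @param truth a `swarm_truth` from [simulate_colony()].
#' @param config optionally, an overriding [sim_config()]; defaults to the
#'   one stored in `truth`.
#' @return An [image_stack()] with channels `all` and `eps`, pixel size and
#'   frame interval taken from the configuration.
#' @export
render_frames <- function(truth, config = truth$config) {
  validate_sim_config(config)
  np <- n_pixels(config)
  set.seed(config$seed + 1L)
  nf <- ncol(truth$x)
  sig_l <- config$cell_length / 2.11 # FWHM of the flat-top kernel = cell length
  sig_w <- config$cell_width / 2.11
  all_ch <- array(0, dim = c(np, np, nf))
  eps_ch <- array(0, dim = c(np, np, nf))
  n <- nrow(truth$x)
  # fixed per-cell brightness: the cell-to-cell contrast that the flow
  # estimator tracks (phase-contrast-like texture)
  amp <- stats::runif(n, 0.6, 1)
  for (f in seq_len(nf)) {
    a <- .render_frame_cpp(truth$x[, f], truth$y[, f], truth$heading[, f],
                           rep(TRUE, n), amp, np, config$pixel_size,
                           config$box_side, sig_l, sig_w)
    e <- .render_frame_cpp(truth$x[, f], truth$y[, f], truth$heading[, f],
                           truth$state[, f] == 2L, amp, np, config$pixel_size,
                           config$box_side, sig_l, sig_w)
    if (config$noise_sd > 0) {
      a <- a + matrix(stats::rnorm(np * np, 0, config$noise_sd), np, np)
      e <- e + matrix(stats::rnorm(np * np, 0, config$noise_sd), np, np)
    }
    all_ch[, , f] <- pmin(pmax(a, 0), 1)
    eps_ch[, , f] <- pmin(pmax(e, 0), 1)
  }
  image_stack(list(all = all_ch, eps = eps_ch),
              pixel_size = config$pixel_size, frame_interval = config$dt)
}

#' Detections emulating sparse fluorescent labeling
#'
#' Emulates the dual-color tracking scheme in which a small fraction of
#' cells carries a distinguishing label: a random subset of agents is
#' "marked" and their positions reported per frame with Gaussian
#' localization noise.
#'
#' @param truth a `swarm_truth`.
#' @param fraction fraction of agents marked (default 0.01).
#' @param sigma localization noise s.d. (um).
#' @param seed RNG seed.
#' @return data frame `frame` (0-based), `x_um`, `y_um`, plus the hidden
#'   ground-truth `agent_id` for validation.
#' @export
detections_from_truth <- function(truth, fraction = 0.01, sigma = 0.05,
                                  seed = truth$config$seed + 2L) {
  set.seed(seed)
  n <- nrow(truth$x)
  nf <- ncol(truth$x)
  marked <- sort(sample.int(n, max(1L, round(fraction * n))))
  d <- data.frame(
    agent_id = rep(marked, nf),
    frame = rep(seq_len(nf) - 1L, each = length(marked)),
    x_um = as.vector(truth$x[marked, ]) +
      stats::rnorm(length(marked) * nf, 0, sigma),
    y_um = as.vector(truth$y[marked, ]) +
      stats::rnorm(length(marked) * nf, 0, sigma)
  )
  d[order(d$frame, d$agent_id), ]
}

#' Sample from a power law with exponential cutoff
#'
#' Draws i.i.d. sizes from the density proportional to
#' `r^(-alpha) exp(-lambda r)` on `[xmin, Inf)` by rejection sampling
#' against the pure power-law (Pareto) envelope, for which the acceptance
#' probability is `exp(-lambda (x - xmin))`.
#'
#' @param n number of draws (`>= 1`).
#' @param alpha power-law exponent (`> 1`).
#' @param lam exponential cutoff rate (`>= 0`, units 1/area).
#' @param xmin lower support bound (`> 0`).
#' @param seed integer RNG seed.
#' @return numeric vector of length `n`, all values `>= xmin`.
#' @export
sample_powerlaw_cutoff <- function(n, alpha, lam, xmin, seed = 1L) {
  stopifnot(n >= 1, alpha > 1, lam >= 0, xmin > 0)
  set.seed(as.integer(seed))
  out <- numeric(0)
  tried <- 0
  accepted <- 0
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 1000L)
    u <- stats::runif(m)
    x <- xmin * u^(-1 / (alpha - 1)) # Pareto envelope
    acc <- stats::runif(m) < exp(-lam * (x - xmin))
    out <- c(out, x[acc])
    tried <- tried + m
    accepted <- accepted + sum(acc)
    if (tried >= 1e4 && accepted / tried < 1e-4) {
      stop("sample_powerlaw_cutoff: acceptance rate below 1e-4; ",
           "the cutoff is too strong for the power-law envelope")
    }
  }
  out[seq_len(n)]
}

#' Extract constant-state track segments from the ground truth
#'
#' Returns, per agent, the longest stretch of frames spent in one motility
#' state (optionally requiring motile segments to keep a clearance from all
#' non-motile cells, i.e. freely swarming rather than hugging aggregate
#' boundaries), with Gaussian localization noise emulating centroid
#' detection.
#'
#' @param truth a `swarm_truth`.
#' @param state `"MOTILE"`, `"TRAPPED"`, or `"EPS_IMMOTILE"`.
#' @param min_length minimum segment length (frames).
#' @param clearance minimum distance (um) to any non-motile agent required
#'   throughout the segment (0 disables; only meaningful for motile
#'   segments).
#' @param sigma localization noise s.d. (um).
#' @param seed RNG seed for the noise.
#' @return list of data frames (`frame`, `x_um`, `y_um`), one per segment.
#' @export
truth_phase_tracks <- function(truth, state = c("MOTILE", "TRAPPED",
                                                "EPS_IMMOTILE"),
                               min_length = 60L, clearance = 0,
                               sigma = 0.05, seed = truth$config$seed + 3L) {
  state <- match.arg(state)
  code <- match(state, c("MOTILE", "TRAPPED", "EPS_IMMOTILE")) - 1L
  set.seed(seed)
  n <- nrow(truth$x); nf <- ncol(truth$x)
  ok <- truth$state == code
  if (clearance > 0) {
    clr <- .clearance_cpp(as.vector(truth$x), as.vector(truth$y),
                          as.vector(truth$state), n, nf,
                          truth$config$box_side, clearance)
    ok <- ok & clr
  }
  out <- list()
  for (i in seq_len(n)) {
    r <- rle(ok[i, ])
    if (!any(r$values & r$lengths >= min_length)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    k <- which(r$values & r$lengths >= min_length)
    k <- k[which.max(r$lengths[k])]
    idx <- starts[k]:ends[k]
    # periodic unwrap so displacements are physical
    L <- truth$config$box_side
    unwrap <- function(v) {
      d <- diff(v)
      d <- d - L * round(d / L)
      cumsum(c(v[1], d))
    }
    out[[length(out) + 1L]] <- data.frame(
      frame = idx,
      x_um = unwrap(truth$x[i, idx]) + stats::rnorm(length(idx), 0, sigma),
      y_um = unwrap(truth$y[i, idx]) + stats::rnorm(length(idx), 0, sigma)
    )
  }
  out
}
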