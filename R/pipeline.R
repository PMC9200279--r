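#' Run the field-of-view analysis pipeline on an image stack
#'
#' The core per-field-of-view computation: for every consecutive frame
#' pair, dense optical flow is estimated on the cell channel,
#' coarse-grained on the shared analysis grid (flow evaluated only where
#' the cell mask is nonzero, missing elsewhere), and reduced to a window
#' speed field; per frame, the cell mask and local surface coverage are
#' computed on the same grid; stationary aggregates are then segmented
#' from the speed fields with the persistence filter.
#'
#' @param stack an [image_stack()]; the analysis runs on channel
#'   `channel`.
#' @param cfg a [pipeline_config()].
#' @param channel channel name or index (default 1).
#' @return Object of class `swarm_analysis`:
#'   \describe{
#'     \item{speeds}{array `gr x gc x (T-1)`, window speed (um/s), `NA`
#'       where the window holds no cells}
#'     \item{coverages}{array `gr x gc x T`, local coverage}
#'     \item{cellw}{logical array `gr x gc x T`, window majority-covered
#'       by the cell mask}
#'     \item{inside}{logical array `gr x gc x (T-1)`, window belongs to a
#'       persistent stationary aggregate}
#'     \item{stationary}{logical array, window is below the stationary
#'       speed threshold (before morphology and the persistence filter);
#'       used as the region membership for the speed-coverage statistics,
#'       where the inside/outside distinction is the threshold speed
#'       itself}
#'     \item{labeling}{the [segment_stationary()] result}
#'     \item{masks}{list of per-frame pixel cell masks}
#'     \item{window, pixel_size, frame_interval, cfg}{geometry and
#'       provenance}
#'   }
#' @export
analyze_stack <- function(stack, cfg = pipeline_config(), channel = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  T <- n_frames(stack)
  if (T < 2) stop("analyze_stack: need at least 2 frames")
  w_px <- round(cfg$flow_window / stack$pixel_size)
  masks <- vector("list", T)
  covs <- NULL
  for (f in seq_len(T)) {
    masks[[f]] <- cell_mask(get_frame(stack, f, channel))
    cf <- local_coverage(masks[[f]], cfg$coverage_window, stack$pixel_size)
    if (is.null(covs)) {
      covs <- array(NA_real_, c(dim(cf$coverage), T))
      grid <- cf
    }
    covs[, , f] <- cf$coverage
  }
  cellw <- covs >= 0.5
  speeds <- array(NA_real_, c(dim(covs)[1:2], T - 1))
  for (t in seq_len(T - 1)) {
    fl <- compute_dense_flow(stack, t, channel, cfg)
    ff <- coarse_grain(fl, cfg$flow_window, cell_mask = masks[[t]])
    speeds[, , t] <- speed(ff)$speed
  }
  labeling <- segment_stationary(speeds, cellw[, , seq_len(T - 1), drop = FALSE],
                                 cfg, window = grid$window)
  stationary <- labeling$threshold_mask
  structure(list(speeds = speeds,
                 speeds_smoothed = labeling$speeds_smoothed,
                 coverages = covs, cellw = cellw,
                 inside = persistent_mask(labeling), stationary = stationary,
                 labeling = labeling,
                 masks = masks, window = grid$window,
                 pixel_size = stack$pixel_size,
                 frame_interval = stack$frame_interval, cfg = cfg),
            class = "swarm_analysis")
}

#' @export
print.swarm_analysis <- function(x, ...) {
  d <- dim(x$speeds)
  cat(sprintf("swarm_analysis: %d x %d windows (%.3g um), %d frame pairs\n",
              d[1], d[2], x$window, d[3]))
  cat(sprintf("  mean speed %.3g um/s, mean coverage %.3f\n",
              mean(x$speeds, na.rm = TRUE), mean(x$coverages)))
  cat(sprintf("  speed threshold %.3g um/s, aggregate ratio %.3f\n",
              x$labeling$speed_threshold, aggregate_ratio(x)$overall))
  invisible(x)
}

#' Pixel-grid mask of the persistent stationary aggregates
#'
#' Upsamples the window-level persistent aggregate mask of a frame pair
#' back to the pixel grid (for comparison against ground truth or
#' overlays).
#'
#' @param analysis a `swarm_analysis`.
#' @param t frame-pair index.
#' @return logical matrix on the stack's pixel grid.
#' @export
aggregate_pixel_mask <- function(analysis, t) {
  w_px <- round(analysis$window / analysis$pixel_size)
  window_mask_to_pixels(analysis$inside[, , t],
                        w_px, dim(analysis$masks[[1]]))
}

#' Speed-coverage relations of an analysis, all regions
#'
#' Convenience wrapper computing [bin_speed_by_coverage()] for the three
#' regions on the shared grid. Each frame pair's (temporally smoothed)
#' speed field is paired with the same frame's coverage field; region
#' membership defaults to the raw below-threshold mask, i.e. the
#' inside/outside distinction is the stationary speed threshold itself,
#' regardless of whether a component survives the persistence filter.
#'
#' @param analysis a `swarm_analysis`.
#' @param membership `"stationary"` (default, raw threshold mask) or
#'   `"persistent"` (only persistent aggregates count as INSIDE).
#' @return data frame with the three stacked `binned_relation` tables.
#' @export
speed_coverage_relations <- function(analysis, membership = c("stationary",
                                                              "persistent")) {
  membership <- match.arg(membership)
  P <- dim(analysis$speeds)[3]
  cov <- analysis$coverages[, , seq_len(P), drop = FALSE]
  ins <- if (membership == "stationary") analysis$stationary
  else analysis$inside
  do.call(rbind, lapply(c("ALL", "INSIDE", "OUTSIDE"), function(r) {
    bin_speed_by_coverage(analysis$speeds_smoothed, cov, ins, r,
                          analysis$cfg)
  }))
}
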