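#' Calibrated time-lapse image stack
#'
#' Container for one or more channels of a time-lapse recording, with the
#' physical calibration needed downstream. Frames are stored per channel as
#' `H x W x T` arrays with intensities in `[0, 1]`; pixel indices are
#' 0-based with the origin at the top-left, x rightward (columns), y
#' downward (rows), and physical coordinates are pixel centers times
#' `pixel_size`.
#'
#' @param channels named list of `H x W x T` numeric arrays (a single
#'   `H x W` matrix is promoted to one frame).
#' @param pixel_size um per pixel (`> 0`).
#' @param frame_interval seconds between frames (`> 0`).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, pixel_size, frame_interval) {
  stopifnot(is.list(channels), length(channels) >= 1,
            pixel_size > 0, frame_interval > 0)
  if (is.null(names(channels)) || any(names(channels) == "")) {
    names(channels) <- paste0("ch", seq_along(channels))
  }
  channels <- lapply(channels, function(a) {
    if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1L))
    stopifnot(length(dim(a)) == 3)
    a
  })
  d1 <- dim(channels[[1]])
  for (a in channels) {
    if (!all(dim(a) == d1)) stop("all channels must share dimensions")
  }
  structure(list(channels = channels, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "image_stack: %d x %d px, %d frame(s), %d channel(s) [%s]\n",
    d[1], d[2], d[3], length(x$channels),
    paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  pixel_size %.4g um/px, frame_interval %.4g s (%.3g fps)\n",
              x$pixel_size, x$frame_interval, 1 / x$frame_interval))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$channels[[1]])

n_frames <- function(stack) dim(stack$channels[[1]])[3]

get_frame <- function(stack, frame, channel = 1L) {
  stack$channels[[channel]][, , frame]
}

#' Read a multi-page TIFF as a calibrated image stack
#'
#' Intensities are rescaled to `[0, 1]` by the file's sample depth (the
#' `tiff` package already returns values on that scale).
#'
#' @param path one TIFF file per channel; a character vector of paths reads
#'   multiple channels (named by file basename unless `channel_names`
#'   given).
#' @param pixel_size um per pixel.
#' @param frame_interval seconds between frames.
#' @param channel_names optional channel names.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_size, frame_interval,
                       channel_names = NULL) {
  stopifnot(length(path) >= 1)
  channels <- lapply(path, function(p) {
    if (!file.exists(p)) stop("read_stack: file not found: ", p)
    pages <- tiff::readTIFF(p, all = TRUE, as.is = FALSE)
    if (is.array(pages) && !is.list(pages)) pages <- list(pages)
    if (length(pages) == 0) stop("read_stack: zero frames in ", p)
    pages <- lapply(pages, function(m) {
      if (length(dim(m)) == 3) m <- m[, , 1] # collapse grayscale-as-RGB
      m
    })
    d <- dim(pages[[1]])
    for (m in pages) {
      if (!all(dim(m) == d)) stop("read_stack: non-uniform frame shapes in ", p)
    }
    arr <- array(0, dim = c(d[1], d[2], length(pages)))
    for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
    arr
  })
  names(channels) <- channel_names %||%
    vapply(path, function(p) sub("\\.[^.]*$", "", basename(p)), character(1))
  image_stack(channels, pixel_size, frame_interval)
}

#' Write an image stack to multi-page TIFF files (one per channel)
#'
#' @param stack an [image_stack()].
#' @param paths output paths, one per channel.
#' @param bits.per.sample TIFF bit depth (default 16).
#' @return `paths`, invisibly.
#' @export
write_stack <- function(stack, paths, bits.per.sample = 16L) {
  stopifnot(inherits(stack, "image_stack"),
            length(paths) == length(stack$channels))
  for (i in seq_along(paths)) {
    arr <- stack$channels[[i]]
    frames <- lapply(seq_len(dim(arr)[3]),
                     function(f) pmin(pmax(arr[, , f], 0), 1))
    tiff::writeTIFF(frames, paths[i], bits.per.sample = bits.per.sample)
  }
  invisible(paths)
}

#' Write / read single-cell tracks as CSV
#'
#' Lossless round trip of the track table `(agent_id, frame, x_um, y_um[,
#' state])`. Reading validates the file and reports malformed rows (missing
#' or non-finite coordinates) with their row numbers.
#'
#' @param tracks data frame with columns `agent_id`, `frame`, `x_um`,
#'   `y_um` and optionally `state`.
#' @param path CSV path.
#' @return `write_tracks` returns `path` invisibly; `read_tracks` returns
#'   the validated data frame.
#' @export
write_tracks <- function(tracks, path) {
  need <- c("agent_id", "frame", "x_um", "y_um")
  if (!all(need %in% names(tracks))) {
    stop("write_tracks: tracks must have columns ",
         paste(need, collapse = ", "))
  }
  keep <- intersect(c(need, "state"), names(tracks))
  utils::write.csv(tracks[keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("read_tracks: file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("agent_id", "frame", "x_um", "y_um")
  if (!all(need %in% names(d))) {
    stop("read_tracks: missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  }
  bad <- which(!is.finite(d$x_um) | !is.finite(d$y_um) |
                 !is.finite(d$frame) | is.na(d$agent_id))
  if (length(bad)) {
    stop("read_tracks: malformed rows (non-finite values) at row(s) ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analysis pipeline configuration
#'
#' Tunable parameters of the downstream analysis, with units. All grids are
#' shared: the flow coarse-graining window equals the local-coverage window
#' so that speed, coverage, and aggregate membership live on congruent
#' grids (which makes the speed decomposition across regions exact).
#'
#' @param speed_threshold stationary-aggregate speed threshold (um/s), or
#'   `NULL` for an adaptive threshold (see `speed_threshold_method`).
#' @param speed_threshold_method adaptive threshold rule. `"cluster"`
#'   (default) splits the log window speeds into two groups (k-means, the
#'   stationary and the swarming dynamical populations) and thresholds at
#'   the geometric midpoint of the group centers; `"median"` uses
#'   `speed_threshold_frac` times the median cell-window speed of the
#'   first (up to) 50 frame pairs. The cluster rule falls back to the
#'   median rule when the speed distribution is degenerate.
#' @param speed_threshold_frac fraction of the median speed used by the
#'   `"median"` rule (and its fallback).
#' @param speed_smooth_pairs temporal median window (frame pairs) applied
#'   to the speed field before thresholding; robust to transient traffic
#'   at aggregate boundaries. 1 disables smoothing.
#' @param min_aggregate_area smallest reported aggregate (um^2).
#' @param coverage_window,flow_window coarse-graining window (um); kept
#'   equal by default.
#' @param persistence_frames number of consecutive previous frame pairs a
#'   component must overlap (IoU >= 0.5) to count as stationary.
#' @param min_track_length minimum track length (frames) for MSD analysis.
#' @param msd_fit_fraction fraction of the track duration used as maximum
#'   MSD lag.
#' @param beta_sub_max,beta_super_min class boundaries for the MSD exponent
#'   (subdiffusive below, superdiffusive above; a narrow diffusive band
#'   between).
#' @param delta_beta half-track exponent difference that (straddling 1)
#'   marks a transitive trajectory.
#' @param r2_min minimum log-log fit R^2 for a usable exponent.
#' @param xmin lower bound of ASD fits (um^2); defaults to
#'   `min_aggregate_area`.
#' @param coverage_bin_width width of surface-coverage bins.
#' @param min_windows_per_bin coverage bins with fewer windows are
#'   suppressed.
#' @param flow_levels,flow_winsize,flow_iters,flow_poly_n,flow_poly_sigma
#'   dense-flow estimator parameters (pyramid levels, averaging window in
#'   px, iterations per level, polynomial window half-width in px, and its
#'   Gaussian applicability sigma).
#' @param seed integer seed for any stochastic analysis step.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(speed_threshold = NULL,
                            speed_threshold_method = c("cluster", "median"),
                            speed_threshold_frac = 1.0,
                            speed_smooth_pairs = 5L,
                            min_aggregate_area = 10,
                            coverage_window = 4, flow_window = 4,
                            persistence_frames = 25L,
                            min_track_length = 50L,
                            msd_fit_fraction = 0.25,
                            beta_sub_max = 0.9, beta_super_min = 1.1,
                            delta_beta = 0.5, r2_min = 0.8,
                            xmin = min_aggregate_area,
                            coverage_bin_width = 0.05,
                            min_windows_per_bin = 10L,
                            flow_levels = 3L, flow_winsize = 15L,
                            flow_iters = 3L, flow_poly_n = 7L,
                            flow_poly_sigma = 1.5,
                            seed = 1L) {
  cfg <- list(speed_threshold = speed_threshold,
              speed_threshold_method = match.arg(speed_threshold_method),
              speed_threshold_frac = speed_threshold_frac,
              speed_smooth_pairs = as.integer(speed_smooth_pairs),
              min_aggregate_area = min_aggregate_area,
              coverage_window = coverage_window, flow_window = flow_window,
              persistence_frames = as.integer(persistence_frames),
              min_track_length = as.integer(min_track_length),
              msd_fit_fraction = msd_fit_fraction,
              beta_sub_max = beta_sub_max, beta_super_min = beta_super_min,
              delta_beta = delta_beta, r2_min = r2_min, xmin = xmin,
              coverage_bin_width = coverage_bin_width,
              min_windows_per_bin = as.integer(min_windows_per_bin),
              flow_levels = as.integer(flow_levels),
              flow_winsize = as.integer(flow_winsize),
              flow_iters = as.integer(flow_iters),
              flow_poly_n = as.integer(flow_poly_n),
              flow_poly_sigma = flow_poly_sigma,
              seed = as.integer(seed))
  stopifnot(cfg$min_aggregate_area > 0, cfg$coverage_window > 0,
            cfg$flow_window > 0, cfg$min_track_length > 0,
            cfg$msd_fit_fraction > 0, cfg$xmin > 0,
            cfg$beta_sub_max < cfg$beta_super_min)
  if (!is.null(cfg$speed_threshold) && cfg$speed_threshold <= 0) {
    stop("speed_threshold must be positive")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Log a configuration and seed to a JSON sidecar
#'
#' Provenance helper used by the analysis drivers: writes the configuration
#' (simulation or pipeline), the seed, and a timestamp next to a result.
#'
#' @param cfg a `sim_config` or `pipeline_config`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
log_config <- function(cfg, path) {
  jsonlite::write_json(
    list(class = class(cfg)[1], config = unclass(cfg),
         written = format(Sys.time(), tz = "UTC")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
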