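#' Cell mask of a frame
#'
#' Foreground (cell) segmentation of one grayscale frame: the illumination
#' background is flattened by subtracting a heavily blurred copy, then the
#' frame is thresholded with Otsu's method. A constant (degenerate) frame
#' yields an empty mask with a warning.
#'
#' @param frame numeric matrix in `[0, 1]`.
#' @param flatten_sigma Gaussian sigma (px) of the background estimate;
#'   `0` disables flattening. Default 50 px.
#' @return logical matrix, `TRUE` on cells.
#' @export
cell_mask <- function(frame, flatten_sigma = 50) {
  rng <- range(frame)
  if (diff(rng) < 1e-6) {
    warning("cell_mask: constant frame, returning empty mask")
    return(matrix(FALSE, nrow(frame), ncol(frame)))
  }
  if (flatten_sigma > 0) {
    # keep the blur brush inside the image
    flatten_sigma <- min(flatten_sigma, floor((min(dim(frame)) - 1) / 7))
    bg <- as.matrix(EBImage::gblur(frame, sigma = flatten_sigma))
    frame <- frame - bg + mean(bg)
    frame <- (frame - min(frame)) / diff(range(frame))
  }
  th <- EBImage::otsu(frame, range = c(0, 1))
  frame > th
}

#' Local surface coverage
#'
#' Fraction of cell-mask pixels in non-overlapping square windows; the
#' coverage grid is congruent with the coarse-grained flow grid when the
#' same window is used.
#'
#' @param mask logical cell mask (per pixel).
#' @param window window side (um).
#' @param pixel_size um per pixel.
#' @return A list of class `coverage_field`: matrix `coverage` in `[0, 1]`,
#'   node centers `x`, `y` (um), and `window` (um).
#' @export
local_coverage <- function(mask, window, pixel_size) {
  w <- round(window / pixel_size)
  if (w < 2) stop("local_coverage: window must be at least 2 px")
  cov <- block_stat(mask * 1, w)
  win_um <- w * pixel_size
  structure(list(coverage = cov,
                 x = (seq_len(ncol(cov)) - 0.5) * win_um,
                 y = (seq_len(nrow(cov)) - 0.5) * win_um,
                 window = win_um),
            class = "coverage_field")
}

coverage_bins <- function(width) {
  edges <- seq(0, 1, by = width)
  if (edges[length(edges)] < 1) edges <- c(edges, 1)
  edges
}

#' Mean speed binned by local surface coverage
#'
#' Reproduces the speed-density diagnostic: analysis windows are assigned
#' to coverage bins and the mean speed (with SEM) is reported per bin, for
#' all windows, only windows inside stationary aggregates, or only windows
#' outside. A window belongs to INSIDE when it is part of a persistent
#' stationary aggregate on its own grid (the shared window grid makes the
#' region decomposition exact).
#'
#' @param speeds numeric matrix/array of window speeds (um/s; nodes x
#'   frames; `NA` = no cells).
#' @param coverages matching array of local coverages in `[0, 1]`.
#' @param inside matching logical array: window belongs to a persistent
#'   stationary aggregate.
#' @param region `"ALL"`, `"INSIDE"`, or `"OUTSIDE"`.
#' @param cfg a [pipeline_config()] (bin width and the per-bin minimum
#'   count below which a bin is suppressed).
#' @return data frame of class `binned_relation`: `bin_lo`, `bin_hi`,
#'   `coverage` (midpoint), `n`, `mean_speed`, `sem`, `region`.
#' @export
bin_speed_by_coverage <- function(speeds, coverages, inside,
                                  region = c("ALL", "INSIDE", "OUTSIDE"),
                                  cfg = pipeline_config()) {
  region <- match.arg(region)
  v <- as.vector(speeds)
  cv <- as.vector(coverages)
  ins <- as.vector(inside)
  keep <- is.finite(v) & is.finite(cv)
  if (region == "INSIDE") keep <- keep & ins
  if (region == "OUTSIDE") keep <- keep & !ins
  v <- v[keep]; cv <- cv[keep]
  edges <- coverage_bins(cfg$coverage_bin_width)
  if (length(v) == 0) {
    out <- data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      coverage = numeric(0), n = numeric(0),
                      mean_speed = numeric(0), sem = numeric(0),
                      region = character(0))
    class(out) <- c("binned_relation", "data.frame")
    return(out)
  }
  idx <- cut(cv, edges, include.lowest = TRUE, labels = FALSE)
  agg <- tapply(v, idx, function(z) c(n = length(z), m = mean(z),
                                      s = stats::sd(z) / sqrt(length(z))))
  bins <- as.integer(names(agg))
  out <- data.frame(
    bin_lo = edges[bins], bin_hi = edges[bins + 1],
    coverage = (edges[bins] + edges[bins + 1]) / 2,
    n = vapply(agg, `[`, numeric(1), 1),
    mean_speed = vapply(agg, `[`, numeric(1), 2),
    sem = vapply(agg, `[`, numeric(1), 3),
    region = region
  )
  out <- out[out$n >= cfg$min_windows_per_bin, ]
  rownames(out) <- NULL
  class(out) <- c("binned_relation", "data.frame")
  out
}

#' Fraction of cell area inside stationary aggregates, by coverage bin
#'
#' Per coverage bin, the cell-mask area belonging to persistent stationary
#' aggregates divided by the total cell-mask area of the member windows.
#'
#' @inheritParams bin_speed_by_coverage
#' @return data frame `bin_lo`, `bin_hi`, `coverage`, `n`,
#'   `aggregate_fraction`.
#' @export
aggregate_fraction_by_coverage <- function(coverages, inside,
                                           cfg = pipeline_config()) {
  cv <- as.vector(coverages)
  ins <- as.vector(inside)
  keep <- is.finite(cv)
  cv <- cv[keep]; ins <- ins[keep]
  edges <- coverage_bins(cfg$coverage_bin_width)
  idx <- cut(cv, edges, include.lowest = TRUE, labels = FALSE)
  num <- tapply(cv * ins, idx, sum)
  den <- tapply(cv, idx, sum)
  n <- tapply(cv, idx, length)
  bins <- as.integer(names(den))
  out <- data.frame(
    bin_lo = edges[bins], bin_hi = edges[bins + 1],
    coverage = (edges[bins] + edges[bins + 1]) / 2,
    n = as.vector(n),
    aggregate_fraction = as.vector(num / den)
  )
  out <- out[out$n >= cfg$min_windows_per_bin, ]
  rownames(out) <- NULL
  out
}

#' Radial colony profiles
#'
#' Summarizes a series of fields of view recorded at known distances from
#' the edge of the inoculum: per distance, the time-averaged mean speed
#' over cell-covered windows, mean local coverage, and aggregate ratio.
#' Imaging different distances from the colony center stands in for
#' different stages of the swarm-to-biofilm transition.
#'
#' @param analyses list of `swarm_analysis` objects (see
#'   [analyze_stack()]), one per field of view.
#' @param distances_mm numeric vector of distances from the inoculum edge
#'   (mm), parallel to `analyses`. Duplicate distances are averaged with a
#'   warning.
#' @param series optional series label(s) (e.g. wild-type vs mutant).
#' @return data frame of class `radial_profile`: `distance_mm`, `series`,
#'   `mean_speed`, `mean_coverage`, `aggregate_ratio`.
#' @export
radial_profile <- function(analyses, distances_mm, series = "WT") {
  stopifnot(length(analyses) == length(distances_mm))
  if (any(distances_mm < 0)) stop("distances must be >= 0")
  series <- rep_len(series, length(analyses))
  rows <- lapply(seq_along(analyses), function(i) {
    a <- analyses[[i]]
    data.frame(distance_mm = distances_mm[i], series = series[i],
               mean_speed = mean(a$speeds, na.rm = TRUE),
               mean_coverage = mean(a$coverages),
               aggregate_ratio = aggregate_ratio(a)$overall)
  })
  out <- do.call(rbind, rows)
  dup <- duplicated(out[c("distance_mm", "series")])
  if (any(dup)) {
    warning("radial_profile: duplicate distances averaged")
    out <- stats::aggregate(
      out[c("mean_speed", "mean_coverage", "aggregate_ratio")],
      by = out[c("distance_mm", "series")], FUN = mean)
  }
  out <- out[order(out$series, out$distance_mm), ]
  rownames(out) <- NULL
  class(out) <- c("radial_profile", "data.frame")
  out
}
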