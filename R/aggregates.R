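#' Segment stationary aggregates from window speed fields
#'
#' Stationary aggregates are connected regions of cell-covered analysis
#' windows whose coarse-grained speed falls below the threshold. Per frame
#' pair the raw mask `(speed < speed_threshold) & cell windows` is
#' morphologically closed (one-node radius), labeled with 8-connectivity,
#' (holes are filled), and components smaller than `min_aggregate_area`
#' are removed. A component counts as *stationary* (persistent) only if at
#' least half of its footprint lies on the below-threshold mask in each of
#' the previous `persistence_frames` frame pairs, which excludes transient
#' jams.
#'
#' @param speeds numeric array `gr x gc x P` of window speeds (um/s, `NA`
#'   where no cells).
#' @param cellw logical array `gr x gc x P`: window contains cells
#'   (coverage majority).
#' @param cfg a [pipeline_config()]; `cfg$speed_threshold = NULL` uses the
#'   adaptive threshold `speed_threshold_frac *` median cell-window speed
#'   of the first (up to) 50 frame pairs.
#' @param window window side (um), for converting counts to areas.
#' @return An object of class `swarm_labeling`: per-pair label matrices
#'   (`labels`), component tables (`components`: frame, label, area_um2,
#'   persistent), the raw masks, the speed threshold used, `window`, and
#'   `persistence_frames`.
#' @export
segment_stationary <- function(speeds, cellw, cfg = pipeline_config(),
                               window) {
  stopifnot(length(dim(speeds)) == 3, all(dim(speeds) == dim(cellw)))
  P <- dim(speeds)[3]
  if (all(!cellw)) warning("segment_stationary: empty cell mask")
  # temporal median over the previous speed_smooth_pairs frame pairs:
  # robust to transient traffic at aggregate boundaries
  ks <- max(1L, cfg$speed_smooth_pairs)
  if (ks > 1L && P > 1L) {
    sm <- speeds
    for (t in seq_len(P)) {
      idx <- max(1L, t - ks + 1L):t
      sm[, , t] <- apply(speeds[, , idx, drop = FALSE], c(1, 2),
                         stats::median, na.rm = TRUE)
    }
    sm[is.nan(sm)] <- NA_real_
    speeds <- sm
  }
  thr <- cfg$speed_threshold
  if (is.null(thr)) {
    thr <- adaptive_speed_threshold(speeds, cellw, cfg)
  }
  win_area <- window^2
  min_windows <- ceiling(cfg$min_aggregate_area / win_area)
  kern <- matrix(1, 3, 3) # one-node structuring element
  labels <- vector("list", P)
  masks <- vector("list", P)
  comp <- vector("list", P)
  thr_mask <- array(FALSE, dim(speeds))
  for (t in seq_len(P)) {
    m <- speeds[, , t] < thr & cellw[, , t]
    m[is.na(m)] <- FALSE
    thr_mask[, , t] <- m
    m <- EBImage::closing(m * 1, kern) > 0
    m <- EBImage::fillHull(m * 1) > 0 # interior holes are not moving regions
    lab <- .label8_cpp(m)
    if (max(lab) > 0) {
      sizes <- tabulate(lab[lab > 0], nbins = max(lab))
      drop <- which(sizes < min_windows)
      if (length(drop)) {
        lab[lab %in% drop] <- 0L
        m <- lab > 0
      }
      # compact the label ids
      keep <- sort(unique(lab[lab > 0]))
      if (length(keep)) {
        relab <- integer(max(keep))
        relab[keep] <- seq_along(keep)
        lab[lab > 0] <- relab[lab[lab > 0]]
        sizes <- tabulate(lab[lab > 0], nbins = length(keep))
      } else sizes <- numeric(0)
    } else {
      sizes <- numeric(0)
      m <- lab > 0
    }
    labels[[t]] <- lab
    masks[[t]] <- m
    comp[[t]] <- if (length(sizes)) {
      data.frame(frame = t, label = seq_along(sizes),
                 area_um2 = sizes * win_area, persistent = NA)
    } else {
      data.frame(frame = integer(0), label = integer(0),
                 area_um2 = numeric(0), persistent = logical(0))
    }
  }
  # persistence: a component is stationary only if at least half of its
  # footprint lies on below-threshold mask in each of the K previous frame
  # pairs (robust to splits/merges of the per-pair components)
  K <- cfg$persistence_frames
  for (t in seq_len(P)) {
    nc <- nrow(comp[[t]])
    if (nc == 0) next
    if (t <= K) {
      comp[[t]]$persistent <- FALSE
      next
    }
    for (ci in seq_len(nc)) {
      foot <- labels[[t]] == ci
      area <- sum(foot)
      ok <- TRUE
      for (k in seq_len(K)) {
        if (sum(foot & masks[[t - k]]) < 0.5 * area) { ok <- FALSE; break }
      }
      comp[[t]]$persistent[ci] <- ok
    }
  }
  structure(list(labels = labels, masks = masks,
                 components = do.call(rbind, comp),
                 threshold_mask = thr_mask,
                 speeds_smoothed = speeds,
                 speed_threshold = thr, window = window,
                 persistence_frames = K),
            class = "swarm_labeling")
}

# Adaptive stationary-speed threshold. "cluster": two-group k-means split of
# the log window speeds (the stationary and swarming dynamical populations),
# thresholded at the geometric midpoint of the group centers. Falls back to
# speed_threshold_frac * median for degenerate distributions.
adaptive_speed_threshold <- function(speeds, cellw, cfg) {
  first <- seq_len(min(50L, dim(speeds)[3]))
  v <- speeds[, , first, drop = FALSE][cellw[, , first, drop = FALSE]]
  v <- v[is.finite(v) & v > 0]
  med <- stats::median(v)
  fallback <- cfg$speed_threshold_frac * med
  if (!is.finite(fallback)) return(0)
  if (cfg$speed_threshold_method != "cluster" || length(unique(v)) < 10) {
    return(fallback)
  }
  lv <- log(v)
  centers <- stats::quantile(lv, c(0.1, 0.9))
  if (diff(centers) <= 0) return(fallback)
  km <- tryCatch(stats::kmeans(lv, centers = matrix(centers, 2, 1)),
                 error = function(e) NULL)
  if (is.null(km)) return(fallback)
  exp(mean(sort(km$centers)))
}

#' @export
print.swarm_labeling <- function(x, ...) {
  cc <- x$components
  cat(sprintf(
    "swarm_labeling: %d frame pairs, threshold %.3g um/s, window %.3g um\n",
    length(x$labels), x$speed_threshold, x$window))
  cat(sprintf("  %d components, %d persistent (K = %d)\n",
              nrow(cc), sum(cc$persistent, na.rm = TRUE),
              x$persistence_frames))
  invisible(x)
}

# logical window mask of persistent aggregates, one slice per frame pair
persistent_mask <- function(labeling) {
  P <- length(labeling$labels)
  d <- dim(labeling$labels[[1]])
  out <- array(FALSE, c(d, P))
  cc <- labeling$components
  for (t in seq_len(P)) {
    keep <- cc$label[cc$frame == t & cc$persistent %in% TRUE]
    if (length(keep)) out[, , t] <- labeling$labels[[t]] %in% keep
  }
  out
}

#' Aggregate ratio: fraction of cell area inside stationary aggregates
#'
#' The ratio of cells that belong to a stationary aggregate to all cells
#' in the field of view, computed as cell-covered area (window coverage
#' times window area) inside persistent aggregates over total cell-covered
#' area.
#'
#' @param analysis a `swarm_analysis` from [analyze_stack()], or a list
#'   with elements `coverages` (array `gr x gc x >=P`) and `labeling`.
#' @return list with `per_frame` (numeric vector, `NA` where the frame has
#'   zero cell area) and `overall` (time average).
#' @export
aggregate_ratio <- function(analysis) {
  labeling <- analysis$labeling
  P <- length(labeling$labels)
  ins <- persistent_mask(labeling)
  pf <- numeric(P)
  for (t in seq_len(P)) {
    cov <- analysis$coverages[, , t]
    tot <- sum(cov)
    pf[t] <- if (tot > 0) sum(cov[ins[, , t]]) / tot else NA_real_
  }
  list(per_frame = pf, overall = mean(pf, na.rm = TRUE))
}

#' Pool persistent aggregate sizes across frames
#'
#' Collects the areas of persistent components every `stride` frame pairs
#' (decorrelation between samples) into one pooled size sample for ASD
#' fitting.
#'
#' @param labelings a `swarm_labeling` or list of them (e.g. several
#'   fields of view).
#' @param stride sampling stride in frame pairs.
#' @return numeric vector of areas (um^2), each `>=` the configured
#'   minimum aggregate area.
#' @export
pool_sizes <- function(labelings, stride = 10L) {
  if (inherits(labelings, "swarm_labeling")) labelings <- list(labelings)
  stopifnot(length(labelings) >= 1, stride >= 1)
  unlist(lapply(labelings, function(lb) {
    cc <- lb$components
    cc <- cc[cc$persistent %in% TRUE, ]
    frames <- sort(unique(cc$frame))
    frames <- frames[seq(1, length(frames), by = stride)]
    cc$area_um2[cc$frame %in% frames]
  }), use.names = FALSE)
}

#' Intersection-over-union of two masks
#'
#' @param a,b logical matrices of equal size.
#' @return IoU in `[0, 1]`; `NaN` when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sum(a & b) / sum(a | b)
}

# upsample a window-grid mask to the pixel grid it was computed from
window_mask_to_pixels <- function(wmask, window_px, dim_px) {
  out <- matrix(FALSE, dim_px[1], dim_px[2])
  gr <- nrow(wmask); gc <- ncol(wmask)
  up <- wmask[rep(seq_len(gr), each = window_px),
              rep(seq_len(gc), each = window_px), drop = FALSE]
  out[seq_len(nrow(up)), seq_len(ncol(up))] <- up
  out
}
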