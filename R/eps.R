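#' Segment EPS-secreting cells from the fluorescence channel
#'
#' Otsu threshold on the EPS reporter channel (same conventions as
#' [cell_mask()]) followed by a minimum-area filter on 8-connected
#' components. A channel with no appreciable signal yields an empty mask
#' with a warning.
#'
#' @param frame numeric matrix in `[0, 1]` (EPS channel).
#' @param pixel_size um per pixel.
#' @param min_area_um2 components smaller than this are removed (default
#'   one cell body, 2.5 um^2).
#' @param flatten_sigma background flattening sigma (px), see
#'   [cell_mask()]; disabled by default because fluorescence backgrounds
#'   are flat and flattening can split bright isolated cells.
#' @return logical matrix, `TRUE` on EPS-secreting cells.
#' @export
segment_eps <- function(frame, pixel_size, min_area_um2 = 2.5,
                        flatten_sigma = 0) {
  if (diff(range(frame)) < 1e-6 || stats::quantile(frame, 0.999) < 0.2) {
    warning("segment_eps: dark channel, returning empty mask")
    return(matrix(FALSE, nrow(frame), ncol(frame)))
  }
  m <- cell_mask(frame, flatten_sigma = flatten_sigma)
  lab <- .label8_cpp(m)
  if (max(lab) > 0) {
    min_px <- ceiling(min_area_um2 / pixel_size^2)
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    m[lab %in% which(sizes < min_px)] <- FALSE
  }
  m
}

#' EPS area fraction
#'
#' Fraction of the cell-mask area occupied by EPS-secreting cells:
#' `|eps & cell| / |cell|`. An area fraction (not a cell-count fraction)
#' is used because individual cells are unresolved in dense regions.
#'
#' @param eps_mask,cells logical masks on the same pixel grid.
#' @return fraction in `[0, 1]`, or `NA` (with a warning) for an empty
#'   cell mask.
#' @export
eps_fraction <- function(eps_mask, cells) {
  stopifnot(all(dim(eps_mask) == dim(cells)))
  tot <- sum(cells)
  if (tot == 0) {
    warning("eps_fraction: empty cell mask")
    return(NA_real_)
  }
  sum(eps_mask & cells) / tot
}

#' EPS fraction and total coverage over a time series of stacks
#'
#' For each two-channel stack (tagged with its acquisition time), the
#' frame-averaged total surface coverage and EPS area fraction.
#'
#' @param stacks list of two-channel [image_stack()]s (channels `all` and
#'   `eps`).
#' @param times_s acquisition times (s), parallel to `stacks`.
#' @return data frame of class `eps_timeseries`: `t_s`, `coverage`,
#'   `eps_fraction`.
#' @export
eps_timeseries <- function(stacks, times_s) {
  stopifnot(length(stacks) == length(times_s))
  rows <- lapply(seq_along(stacks), function(i) {
    st <- stacks[[i]]
    nf <- n_frames(st)
    covs <- numeric(nf); fr <- numeric(nf)
    for (f in seq_len(nf)) {
      cm <- cell_mask(get_frame(st, f, "all"))
      em <- segment_eps(get_frame(st, f, "eps"), st$pixel_size)
      covs[f] <- mean(cm)
      fr[f] <- eps_fraction(em, cm)
    }
    data.frame(t_s = times_s[i], coverage = mean(covs),
               eps_fraction = mean(fr, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("eps_timeseries", "data.frame")
  out
}

#' Displacement of EPS-secreting cells between two time points
#'
#' Labels the EPS masks at the two times, matches components by nearest
#' centroid within `max_match_dist`, and reports per-match centroid
#' displacements together with the global overlap (Jaccard index) of the
#' two masks.
#'
#' @param mask_t1,mask_t2 logical EPS masks on the same calibrated grid.
#' @param pixel_size um per pixel.
#' @param max_match_dist maximum centroid distance for a match (um).
#' @return list of class `displacement_report`: `overlap` (Jaccard),
#'   `matches` (data frame `label_t1`, `label_t2`, `displacement_um`),
#'   `unmatched_t1`, `unmatched_t2` (label vectors).
#' @export
eps_displacement <- function(mask_t1, mask_t2, pixel_size,
                             max_match_dist = 5) {
  stopifnot(all(dim(mask_t1) == dim(mask_t2)))
  uni <- sum(mask_t1 | mask_t2)
  overlap <- if (uni > 0) sum(mask_t1 & mask_t2) / uni else 0
  cent <- function(mask) {
    lab <- .label8_cpp(mask)
    if (max(lab) == 0) {
      return(data.frame(label = integer(0), x = numeric(0), y = numeric(0)))
    }
    idx <- which(lab > 0, arr.ind = TRUE)
    l <- lab[lab > 0]
    data.frame(
      label = sort(unique(l)),
      x = tapply((idx[, 2] - 0.5) * pixel_size, l, mean),
      y = tapply((idx[, 1] - 0.5) * pixel_size, l, mean)
    )
  }
  c1 <- cent(mask_t1)
  c2 <- cent(mask_t2)
  matches <- data.frame(label_t1 = integer(0), label_t2 = integer(0),
                        displacement_um = numeric(0))
  if (nrow(c1) && nrow(c2)) {
    dist <- sqrt(outer(c1$x, c2$x, `-`)^2 + outer(c1$y, c2$y, `-`)^2)
    cand <- which(dist <= max_match_dist, arr.ind = TRUE)
    if (nrow(cand)) {
      used1 <- logical(nrow(c1)); used2 <- logical(nrow(c2))
      for (k in order(dist[cand])) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (used1[i] || used2[j]) next
        used1[i] <- TRUE; used2[j] <- TRUE
        matches <- rbind(matches, data.frame(
          label_t1 = c1$label[i], label_t2 = c2$label[j],
          displacement_um = dist[i, j]))
      }
    }
  }
  structure(list(overlap = overlap, matches = matches,
                 unmatched_t1 = setdiff(c1$label, matches$label_t1),
                 unmatched_t2 = setdiff(c2$label, matches$label_t2)),
            class = "displacement_report")
}
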