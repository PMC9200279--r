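#' Link per-frame detections into single-cell tracks
#'
#' Greedy nearest-neighbor frame-to-frame assignment: candidate pairs
#' (active track head, detection) are sorted by distance and matched in
#' order, subject to the per-frame displacement cap `max_disp`; ties are
#' broken by smallest distance, then smallest track id. Tracks missing a
#' detection may be bridged across up to `memory` skipped frames
#' (gap closing, with the cap scaled by the gap length). Unmatched
#' detections start new tracks.
#'
#' @param detections data frame with columns `frame` (0-based or 1-based,
#'   any increasing integer), `x_um`, `y_um`, sorted by frame (sorted
#'   internally otherwise).
#' @param max_disp maximum displacement per frame (um).
#' @param memory number of frames a track may go undetected and still be
#'   continued.
#' @return data frame `track_id`, `frame`, `x_um`, `y_um` (plus any other
#'   input columns), ordered by track then frame.
#' @export
link_tracks <- function(detections, max_disp, memory = 0L) {
  d <- detections[order(detections$frame), , drop = FALSE]
  frames <- sort(unique(d$frame))
  n_tracks <- 0L
  head_x <- numeric(0); head_y <- numeric(0); head_f <- numeric(0)
  out_id <- integer(nrow(d))
  row_of_frame <- split(seq_len(nrow(d)), d$frame)
  for (f in frames) {
    rows <- row_of_frame[[as.character(f)]]
    px <- d$x_um[rows]; py <- d$y_um[rows]
    active <- which(head_f >= f - 1 - memory & head_f < f)
    assigned_det <- rep(FALSE, length(rows))
    assigned_trk <- rep(FALSE, length(active))
    if (length(active) && length(rows)) {
      dx <- outer(head_x[active], px, `-`)
      dy <- outer(head_y[active], py, `-`)
      dist <- sqrt(dx^2 + dy^2)
      gap <- f - head_f[active]
      cap <- max_disp * gap
      cand <- which(dist <= cap, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(dist[cand], active[cand[, 1]])
        for (k in ord) {
          ti <- cand[k, 1]; di <- cand[k, 2]
          if (assigned_trk[ti] || assigned_det[di]) next
          assigned_trk[ti] <- TRUE
          assigned_det[di] <- TRUE
          id <- active[ti]
          out_id[rows[di]] <- id
          head_x[id] <- px[di]; head_y[id] <- py[di]; head_f[id] <- f
        }
      }
    }
    for (di in which(!assigned_det)) {
      n_tracks <- n_tracks + 1L
      out_id[rows[di]] <- n_tracks
      head_x[n_tracks] <- px[di]
      head_y[n_tracks] <- py[di]
      head_f[n_tracks] <- f
    }
  }
  d$track_id <- out_id
  d <- d[order(d$track_id, d$frame), ]
  rownames(d) <- NULL
  d[c("track_id", setdiff(names(d), "track_id"))]
}

#' Time-averaged mean square displacement of a track
#'
#' `MSD(tau) = < |r(t + tau) - r(t)|^2 >_t` over all ordered pairs at each
#' lag, up to `msd_fit_fraction` of the track duration.
#'
#' @param track data frame with `frame`, `x_um`, `y_um` for one track
#'   (consecutive frames).
#' @param frame_interval seconds per frame.
#' @param cfg a [pipeline_config()] (`min_track_length`,
#'   `msd_fit_fraction`).
#' @return data frame of class `msd_curve`: `lag` (frames), `tau` (s),
#'   `msd` (um^2).
#' @export
compute_msd <- function(track, frame_interval, cfg = pipeline_config()) {
  n <- nrow(track)
  if (n < cfg$min_track_length) {
    stop("compute_msd: track shorter than min_track_length (skip it)")
  }
  if (is.unsorted(track$frame, strictly = TRUE)) {
    stop("compute_msd: frames must be strictly increasing")
  }
  max_lag <- max(1L, floor(cfg$msd_fit_fraction * (n - 1)))
  x <- track$x_um; y <- track$y_um
  msd <- vapply(seq_len(max_lag), function(k) {
    dx <- x[(1 + k):n] - x[1:(n - k)]
    dy <- y[(1 + k):n] - y[1:(n - k)]
    mean(dx^2 + dy^2)
  }, numeric(1))
  out <- data.frame(lag = seq_len(max_lag),
                    tau = seq_len(max_lag) * frame_interval, msd = msd)
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Power-law fit of an MSD curve
#'
#' Least-squares line on `(ln tau, ln MSD)`; the slope is the anomalous
#' diffusion exponent beta (`beta = 1` normal diffusion, `< 1`
#' subdiffusion, `> 1` superdiffusion, `2` ballistic).
#'
#' @param msd an `msd_curve` from [compute_msd()].
#' @param fit_range optional `c(tau_min, tau_max)` (s); default all lags.
#' @return list `beta`, `prefactor` (um^2 at tau = 1 s), `r2`, `n_points`.
#' @export
fit_beta <- function(msd, fit_range = NULL) {
  d <- msd
  if (!is.null(fit_range)) d <- d[d$tau >= fit_range[1] & d$tau <= fit_range[2], ]
  if (nrow(d) < 5) stop("fit_beta: need at least 5 lag points in range")
  if (any(d$msd <= 0)) stop("fit_beta: zero MSD values in range, fit refused")
  fit <- stats::lm(log(msd) ~ log(tau), data = d)
  ss <- summary(fit)
  list(beta = unname(stats::coef(fit)[2]),
       prefactor = exp(unname(stats::coef(fit)[1])),
       r2 = ss$r.squared,
       beta_se = unname(ss$coefficients[2, 2]),
       n_points = nrow(d))
}

#' Classify a trajectory by its MSD scaling
#'
#' Whole-track exponent below `beta_sub_max` is subdiffusive (`"SUB"`),
#' above `beta_super_min` superdiffusive (`"SUPER"`), else `"DIFFUSIVE"`.
#' If the exponents fitted separately on the two halves of the track
#' differ by more than `delta_beta` *and* straddle 1, the track changed
#' regime (entered or left an aggregate) and is `"TRANSITIVE"`. Tracks
#' whose MSD cannot be fitted (e.g. strictly zero) or whose exponent is
#' poorly determined (R^2 below `r2_min` *and* slope standard error above
#' 0.1) are `"UNCLASSIFIED"`.
#'
#' @param track one track's data frame (`frame`, `x_um`, `y_um`).
#' @param frame_interval seconds per frame.
#' @param cfg a [pipeline_config()].
#' @return list `class`, `beta`, `r2`, `beta_first`, `beta_second`.
#' @export
classify_trajectory <- function(track, frame_interval,
                                cfg = pipeline_config()) {
  res <- list(class = "UNCLASSIFIED", beta = NA_real_, r2 = NA_real_,
              beta_first = NA_real_, beta_second = NA_real_)
  fit <- tryCatch({
    m <- compute_msd(track, frame_interval, cfg)
    fit_beta(m)
  }, error = function(e) NULL)
  if (is.null(fit)) return(res)
  res$beta <- fit$beta
  res$r2 <- fit$r2
  n <- nrow(track)
  half <- floor(n / 2)
  halves <- tryCatch({
    cfg_half <- cfg
    cfg_half$min_track_length <- max(10L, floor(cfg$min_track_length / 2))
    b1 <- fit_beta(compute_msd(track[1:half, ], frame_interval, cfg_half))
    b2 <- fit_beta(compute_msd(track[(half + 1):n, ], frame_interval,
                               cfg_half))
    c(b1$beta, b2$beta)
  }, error = function(e) c(NA_real_, NA_real_))
  res$beta_first <- halves[1]
  res$beta_second <- halves[2]
  if (all(is.finite(halves)) &&
      abs(halves[1] - halves[2]) > cfg$delta_beta &&
      min(halves) < 1 && max(halves) > 1) {
    res$class <- "TRANSITIVE"
    return(res)
  }
  # R^2 cannot assess a flat MSD (explained variance vanishes as the slope
  # approaches 0); a well-determined slope (small standard error) is accepted
  # regardless of R^2
  if (fit$r2 < cfg$r2_min && fit$beta_se > 0.1) return(res)
  res$class <- if (fit$beta < cfg$beta_sub_max) "SUB"
  else if (fit$beta > cfg$beta_super_min) "SUPER"
  else "DIFFUSIVE"
  res
}

#' Classify all tracks in a linked track table
#'
#' @param tracks data frame with `track_id`, `frame`, `x_um`, `y_um`.
#' @param frame_interval seconds per frame.
#' @param cfg a [pipeline_config()]; tracks shorter than
#'   `min_track_length` are skipped.
#' @return data frame `track_id`, `n_frames`, `beta`, `r2`, `class`,
#'   `beta_first`, `beta_second`.
#' @export
analyze_tracks <- function(tracks, frame_interval, cfg = pipeline_config()) {
  ids <- unique(tracks$track_id)
  rows <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, ]
    if (nrow(tr) < cfg$min_track_length) return(NULL)
    cl <- classify_trajectory(tr, frame_interval, cfg)
    data.frame(track_id = id, n_frames = nrow(tr), beta = cl$beta,
               r2 = cl$r2, class = cl$class, beta_first = cl$beta_first,
               beta_second = cl$beta_second)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(track_id = integer(0), n_frames = integer(0),
                      beta = numeric(0), r2 = numeric(0),
                      class = character(0), beta_first = numeric(0),
                      beta_second = numeric(0))
  }
  out
}

#' Histogram of MSD exponents with a bimodality diagnostic
#'
#' Bins the exponents of non-transitive, classified tracks and reports the
#' sample bimodality coefficient `(g1^2 + 1) / (g2 + 3 (n-1)^2 / ((n-2)(n-3)))`
#' (sample skewness `g1`, sample excess kurtosis `g2`); values above 5/9
#' indicate bimodality. A mixture of trapped (subdiffusive) and swarming
#' (superdiffusive) cells shows one mode below 1 and one above.
#'
#' @param track_table output of [analyze_tracks()] (or a numeric vector of
#'   exponents).
#' @param breaks histogram breaks passed to [graphics::hist()].
#' @return list of class `beta_histogram`: `counts`, `mids`, `breaks`,
#'   `betas`, `bimodality`, `n`.
#' @export
beta_histogram <- function(track_table, breaks = seq(-0.25, 3.25, by = 0.25)) {
  betas <- if (is.numeric(track_table)) track_table
  else track_table$beta[track_table$class %in% c("SUB", "DIFFUSIVE", "SUPER")]
  betas <- betas[is.finite(betas)]
  if (length(betas) == 0) {
    return(structure(list(counts = integer(0), mids = numeric(0),
                          breaks = breaks, betas = numeric(0),
                          bimodality = NA_real_, n = 0L),
                     class = "beta_histogram"))
  }
  rng <- range(betas)
  if (rng[1] < min(breaks) || rng[2] > max(breaks)) {
    breaks <- seq(floor(rng[1] * 4) / 4, ceiling(rng[2] * 4) / 4, by = 0.25)
  }
  h <- graphics::hist(betas, breaks = breaks, plot = FALSE)
  n <- length(betas)
  bim <- if (n >= 4) {
    g1 <- e1071::skewness(betas, type = 2)
    g2 <- e1071::kurtosis(betas, type = 2)
    (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
  } else NA_real_
  structure(list(counts = h$counts, mids = h$mids, breaks = h$breaks,
                 betas = betas, bimodality = bim, n = n),
            class = "beta_histogram")
}

#' @export
print.beta_histogram <- function(x, ...) {
  cat(sprintf("beta_histogram: %d tracks, bimodality coefficient %.3f %s\n",
              x$n, x$bimodality,
              if (is.finite(x$bimodality) && x$bimodality > 5 / 9)
                "(bimodal)" else ""))
  invisible(x)
}
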