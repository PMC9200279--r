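#' Dense optical flow between consecutive frames
#'
#' Estimates per-pixel displacements (px/frame) between frames
#' `frame_index` and `frame_index + 1` with a polynomial-expansion dense
#' flow estimator (Farneback): each frame is approximated locally by a
#' quadratic polynomial over a Gaussian-weighted window and the
#' displacement field is solved iteratively over an image pyramid.
#'
#' @param stack an [image_stack()] with at least two frames.
#' @param frame_index 1-based index of the first frame of the pair.
#' @param channel channel name or index (default first).
#' @param cfg a [pipeline_config()] supplying estimator parameters.
#' @return A list of class `dense_flow` with matrices `dx`, `dy`
#'   (displacement in px/frame along x = columns and y = rows), and the
#'   stack calibration as attributes.
#' @export
compute_dense_flow <- function(stack, frame_index, channel = 1L,
                               cfg = pipeline_config()) {
  stopifnot(inherits(stack, "image_stack"))
  nf <- n_frames(stack)
  if (nf < 2) stop("compute_dense_flow: stack has fewer than two frames")
  if (frame_index < 1 || frame_index + 1 > nf) {
    stop("compute_dense_flow: frame pair out of range")
  }
  f1 <- get_frame(stack, frame_index, channel)
  f2 <- get_frame(stack, frame_index + 1L, channel)
  res <- .farneback_cpp(f1, f2, cfg$flow_levels, cfg$flow_winsize,
                        cfg$flow_iters, cfg$flow_poly_n, cfg$flow_poly_sigma)
  structure(list(dx = res$dx, dy = res$dy,
                 pixel_size = stack$pixel_size,
                 frame_interval = stack$frame_interval),
            class = "dense_flow")
}

block_stat <- function(m, w, fun = mean, na.rm = FALSE) {
  nr <- nrow(m) %/% w
  nc <- ncol(m) %/% w
  if (nr < 1 || nc < 1) stop("window larger than image")
  sub <- m[seq_len(nr * w), seq_len(nc * w), drop = FALSE]
  a <- array(sub, dim = c(w, nr, w, nc))
  if (na.rm) apply(a, c(2, 4), fun, na.rm = TRUE) else apply(a, c(2, 4), fun)
}

#' Coarse-grained velocity field
#'
#' Block-averages a per-pixel displacement field over non-overlapping
#' square windows and converts to physical velocity (um/s). Grid nodes sit
#' at window centers. If a per-pixel cell mask is supplied, the flow is
#' averaged only over masked (cell) pixels, and windows containing no cell
#' pixels are reported as missing (`NA`).
#'
#' @param flow a `dense_flow` from [compute_dense_flow()].
#' @param window window side (um); must be at least two pixels.
#' @param cell_mask optional logical per-pixel matrix (TRUE = cells).
#' @return A list of class `flow_field` with matrices `vx`, `vy` (um/s),
#'   node center coordinates `x`, `y` (um), and `window` (um).
#' @export
coarse_grain <- function(flow, window, cell_mask = NULL) {
  stopifnot(inherits(flow, "dense_flow"))
  w <- round(window / flow$pixel_size)
  if (w < 2) stop("coarse_grain: window must be at least 2 pixels")
  scale <- flow$pixel_size / flow$frame_interval # px/frame -> um/s
  dx <- flow$dx
  dy <- flow$dy
  if (!is.null(cell_mask)) {
    stopifnot(all(dim(cell_mask) == dim(dx)))
    dx[!cell_mask] <- NA_real_
    dy[!cell_mask] <- NA_real_
    vx <- block_stat(dx, w, mean, na.rm = TRUE) * scale
    vy <- block_stat(dy, w, mean, na.rm = TRUE) * scale
    vx[is.nan(vx)] <- NA_real_
    vy[is.nan(vy)] <- NA_real_
  } else {
    vx <- block_stat(dx, w, mean) * scale
    vy <- block_stat(dy, w, mean) * scale
  }
  win_um <- w * flow$pixel_size
  structure(list(
    vx = vx, vy = vy,
    x = (seq_len(ncol(vx)) - 0.5) * win_um,
    y = (seq_len(nrow(vx)) - 0.5) * win_um,
    window = win_um
  ), class = "flow_field")
}

#' Scalar speed field
#'
#' Elementwise Euclidean norm of a coarse-grained velocity field.
#'
#' @param flow a `flow_field` from [coarse_grain()].
#' @return A list of class `speed_field` with matrix `speed` (um/s, `NA`
#'   where the flow is missing) and the grid geometry of the input.
#' @export
speed <- function(flow) {
  stopifnot(inherits(flow, "flow_field"))
  structure(list(speed = sqrt(flow$vx^2 + flow$vy^2),
                 x = flow$x, y = flow$y, window = flow$window),
            class = "speed_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("flow_field: %d x %d nodes, window %.3g um\n",
              nrow(x$vx), ncol(x$vx), x$window))
  cat(sprintf("  mean |v| = %.3g um/s (%d missing nodes)\n",
              mean(sqrt(x$vx^2 + x$vy^2), na.rm = TRUE),
              sum(is.na(x$vx))))
  invisible(x)
}
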