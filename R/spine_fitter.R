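## Spinal-cord refinement: the quasi-circular cord boundary is re-fitted on
## every slice by a Hough circle transform on Sobel edge points inside a small
## tracking ROI centred on the previous slice's circle.

#' Sobel gradient magnitude
#'
#' @param img numeric matrix.
#' @return matrix of the same size; border pixels are zero.
#' @export
sobel_magnitude <- function(img) {
  img <- matrix(as.numeric(img), nrow(img), ncol(img))
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 3L || nc < 3L) return(matrix(0, nr, nc))
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- img
  # replicate borders so image edges do not fire
  p[1L, ] <- p[2L, ]; p[nr + 2L, ] <- p[nr + 1L, ]
  p[, 1L] <- p[, 2L]; p[, nc + 2L] <- p[, nc + 1L]
  sh <- function(dr, dc) p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  sqrt(gx^2 + gy^2)
}

clamp_int <- function(x, lo, hi) pmin(pmax(as.integer(round(x)), lo), hi)

## square tracking window clipped to the image
spine_window <- function(center, halfwidth, img_dim) {
  r0 <- clamp_int(center[1] - halfwidth, 1L, img_dim[1L])
  r1 <- clamp_int(center[1] + halfwidth, 1L, img_dim[1L])
  c0 <- clamp_int(center[2] - halfwidth, 1L, img_dim[2L])
  c1 <- clamp_int(center[2] + halfwidth, 1L, img_dim[2L])
  rw_roi(r0, r1, c0, c1)
}

#' Binary edge points inside the spine tracking ROI
#'
#' Sobel gradient magnitude inside the window, thresholded at a percentile;
#' a constant window yields no edge points.
#'
#' @param slice_gray windowed grey-level matrix (full slice).
#' @param center (row, col) of the tracking window.
#' @param halfwidth half-width of the square window in pixels.
#' @param percentile threshold percentile of the in-window Sobel magnitude
#'   (default 0.9).
#' @return matrix of edge-point coordinates (`row`, `col`, absolute).
#' @export
spine_edges <- function(slice_gray, center, halfwidth = 25L,
                        percentile = 0.9) {
  w <- spine_window(center, halfwidth, dim(slice_gray))
  sub <- slice_gray[w$row_min:w$row_max, w$col_min:w$col_max, drop = FALSE]
  mag <- sobel_magnitude(sub)
  thr <- quantile(mag, percentile, names = FALSE)
  pts <- which(mag > thr, arr.ind = TRUE)
  if (nrow(pts)) {
    pts[, 1L] <- pts[, 1L] + w$row_min - 1L
    pts[, 2L] <- pts[, 2L] + w$col_min - 1L
  }
  colnames(pts) <- c("row", "col")
  pts
}

#' Fit a circle to edge points by Hough voting
#'
#' Accumulates votes over integer (center, radius) cells: every edge point
#' votes for all centres at distance `r` for each candidate radius. The peak
#' cell wins; ties break by smallest radius, then lexicographic centre. The
#' returned radius is refined as the median distance from the winning centre
#' to its supporting edge points, which is robust to the two-pixel-wide edge
#' band a Sobel step response produces.
#'
#' @param points edge points, matrix with columns (row, col).
#' @param r_min,r_max radius search range in pixels (defaults 4 and 12).
#' @param min_points minimum number of edge points required (default 10).
#' @return list with `center` (row, col), `radius`, `votes`; or `NULL` when
#'   there are fewer than `min_points` edge points.
#' @export
fit_circle_hough <- function(points, r_min = 4L, r_max = 12L,
                             min_points = 10L) {
  if (is.null(points) || nrow(points) < min_points) return(NULL)
  radii <- seq.int(as.integer(r_min), as.integer(r_max))
  rmin_c <- min(points[, 1L]) - r_max; rmax_c <- max(points[, 1L]) + r_max
  cmin_c <- min(points[, 2L]) - r_max; cmax_c <- max(points[, 2L]) + r_max
  nrc <- rmax_c - rmin_c + 1L; ncc <- cmax_c - cmin_c + 1L
  best <- NULL
  for (r in radii) {
    d <- seq(-r, r)
    ring <- which(abs(sqrt(outer(d^2, d^2, "+")) - r) < 0.5, arr.ind = TRUE)
    offs <- cbind(ring[, 1L] - r - 1L, ring[, 2L] - r - 1L)
    cr <- rep(points[, 1L], each = nrow(offs)) - offs[, 1L]
    cc <- rep(points[, 2L], each = nrow(offs)) - offs[, 2L]
    idx <- (cc - cmin_c) * nrc + (cr - rmin_c) + 1L
    acc <- tabulate(idx, nbins = nrc * ncc)
    v <- max(acc)
    if (is.null(best) || v > best$votes) {
      cell <- which.max(acc)             # lowest index on ties: lexicographic
      ctr <- c(rmin_c + (cell - 1L) %% nrc, cmin_c + (cell - 1L) %/% nrc)
      best <- list(center = ctr, radius = as.numeric(r), votes = v, r_cell = r)
    }
  }
  dists <- sqrt((points[, 1L] - best$center[1L])^2 +
                (points[, 2L] - best$center[2L])^2)
  near <- dists[abs(dists - best$r_cell) <= 1.5]
  if (length(near) >= min_points / 2) best$radius <- median(near)
  best$r_cell <- NULL
  best
}

rasterize_disk <- function(center, radius, img_dim) {
  r0 <- max(1L, floor(center[1] - radius)); r1 <- min(img_dim[1L], ceiling(center[1] + radius))
  c0 <- max(1L, floor(center[2] - radius)); c1 <- min(img_dim[2L], ceiling(center[2] + radius))
  m <- matrix(0L, img_dim[1L], img_dim[2L])
  if (r1 < r0 || c1 < c0) return(m)
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - center[1])^2, (cc - center[2])^2, "+")
  m[rr, cc] <- as.integer(d2 <= radius^2)
  m
}

#' Replace the spinal-cord label by a fitted disk
#'
#' Fits a circle to the Sobel edges around the cord and replaces the
#' random-walker cord region with the rasterised disk; former cord pixels
#' outside the disk revert to `body`. The tracking window for the next slice
#' re-centres on the new circle. Fit failures (too few edge points) or
#' centre jumps beyond `max_drift` fall back to the previous circle; if no
#' previous circle exists the label map is left unchanged and flagged.
#'
#' @param labelmap integer matrix of category codes.
#' @param slice_gray windowed grey levels of the same slice.
#' @param prev previous slice's circle (list `center`, `radius`) or `NULL`.
#' @param r_min,r_max,halfwidth,percentile,max_drift,min_points tuning
#'   parameters (see [fit_circle_hough()] and [spine_edges()]).
#' @return list `labelmap`, `circle`, `flagged`.
#' @export
refine_spine <- function(labelmap, slice_gray, prev = NULL,
                         r_min = 4L, r_max = 12L, halfwidth = 25L,
                         percentile = 0.9, max_drift = 10, min_points = 10L) {
  cord <- category_code("spinal_cord")
  center <- if (!is.null(prev)) prev$center else {
    pix <- which(labelmap == cord, arr.ind = TRUE)
    if (!nrow(pix)) return(list(labelmap = labelmap, circle = NULL,
                                flagged = TRUE))
    c(round(mean(pix[, 1L])), round(mean(pix[, 2L])))
  }
  pts <- spine_edges(slice_gray, center, halfwidth, percentile)
  fit <- fit_circle_hough(pts, r_min, r_max, min_points)
  flagged <- FALSE
  if (is.null(fit)) {
    if (is.null(prev)) {
      return(list(labelmap = labelmap, circle = NULL, flagged = TRUE))
    }
    fit <- prev; flagged <- TRUE
  } else if (!is.null(prev) &&
             sqrt(sum((fit$center - prev$center)^2)) > max_drift) {
    fit <- prev; flagged <- TRUE
  }
  disk <- rasterize_disk(fit$center, fit$radius, dim(labelmap))
  out <- labelmap
  out[out == cord & disk == 0L] <- category_code("body")
  out[disk == 1L] <- cord
  list(labelmap = out, circle = list(center = fit$center, radius = fit$radius),
       flagged = flagged)
}
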