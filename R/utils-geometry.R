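#' @importFrom stats median mad kmeans rnorm runif quantile setNames fft sd
#' @importFrom grDevices chull contourLines
#' @importFrom utils read.csv write.csv head tail
NULL

# Angle conventions used throughout the package:
#   * degrees, measured counterclockwise from the image x-axis (columns),
#     with the y-axis pointing "up" (towards decreasing row index);
#   * axial (nematic) data: theta and theta + 180 are the same fiber axis,
#     so every angle is wrapped into [-90, 90).
# Coordinates are 0-based (row, col) pixel indices; subpixel positions are
# real-valued (row, col).

#' Wrap angles into the axial range [-90, 90)
#'
#' Fiber orientations are axial quantities: an axis at \code{theta} and at
#' \code{theta + 180} degrees is the same physical direction. This helper
#' wraps arbitrary angles (degrees) into the canonical interval.
#'
#' @param theta_deg numeric vector of angles in degrees.
#' @return numeric vector of the same length, in [-90, 90).
#' @export
wrap_axial <- function(theta_deg) {
  ((theta_deg + 90) %% 180) - 90
}

# perimeter of a closed polyline given as n x 2 matrix (row, col) or (x, y)
polygon_perimeter <- function(pts) {
  if (nrow(pts) < 2) return(0)
  d <- diff(rbind(pts, pts[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

# perimeter of the convex hull of a point set (n x 2 matrix)
hull_perimeter <- function(pts) {
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  polygon_perimeter(pts[h, , drop = FALSE])
}

# minimum distance from points (m x 2) to a closed polyline (n x 2),
# measured to the segments, not just the vertices
dist_to_polyline <- function(pts, poly) {
  a <- poly
  b <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  ab <- b - a
  len2 <- rowSums(ab^2)
  len2[len2 == 0] <- 1e-12
  apply(pts, 1, function(p) {
    ap1 <- p[1] - a[, 1]
    ap2 <- p[2] - a[, 2]
    t <- pmin(pmax((ap1 * ab[, 1] + ap2 * ab[, 2]) / len2, 0), 1)
    dx <- ap1 - t * ab[, 1]
    dy <- ap2 - t * ab[, 2]
    sqrt(min(dx * dx + dy * dy))
  })
}

# TRUE for points inside a closed polygon (even-odd rule); pts m x 2, poly n x 2
points_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  vapply(seq_len(nrow(pts)), function(k) {
    x <- pts[k, 1]; y <- pts[k, 2]
    crossing <- (poly[, 2] > y) != (poly[j, 2] > y)
    xin <- poly[j, 1] + (y - poly[j, 2]) /
      (poly[, 2] - poly[j, 2] + 1e-300) * (poly[, 1] - poly[j, 1])
    sum(crossing & (x < xin)) %% 2 == 1
  }, logical(1))
}

# Gaussian smoothing that tolerates sigma = 0 and keeps plain-matrix in/out
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  as.matrix(EBImage::gblur(m, sigma = sigma))
}

# subpixel outline of a binary mask: light Gaussian smoothing followed by a
# marching-squares contour at the half level. Returns the longest closed
# contour as an n x 2 matrix of 0-based (row, col) positions.
subpixel_contour <- function(mask, smooth_sigma = 1) {
  # pad with a zero frame so masks touching the image edge still close
  pad <- max(2, ceiling(2 * smooth_sigma))
  m0 <- matrix(0, nrow(mask) + 2 * pad, ncol(mask) + 2 * pad)
  m0[pad + seq_len(nrow(mask)), pad + seq_len(ncol(mask))] <- mask * 1
  m <- gauss_smooth(m0, smooth_sigma)
  cl <- grDevices::contourLines(seq_len(nrow(m)), seq_len(ncol(m)), m,
                                levels = 0.5)
  if (length(cl) == 0) stop("mask has no 0.5-level contour")
  lens <- vapply(cl, function(ct) length(ct$x), numeric(1))
  ct <- cl[[which.max(lens)]]
  # contourLines x follows the first matrix index (rows); convert to 0-based
  cbind(row = ct$x - 1 - pad, col = ct$y - 1 - pad)
}

# deterministic RNG scope: runs expr with the given seed, restoring the
# caller's RNG state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# largest connected component of a binary mask (8-connectivity)
largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  if (max(lab) == 0) return(mask & FALSE)
  tab <- tabulate(as.integer(lab[lab > 0]))
  matrix(as.integer(lab) == which.max(tab), nrow(mask), ncol(mask))
}
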