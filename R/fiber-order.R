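#' Nematic scalar order parameter of axial orientation data
#'
#' Summarizes a sample of fiber orientation measurements by the 2D nematic
#' order parameter. The orientations (axial data, period 180 degrees) are
#' assembled into the second-order tensor
#' \deqn{S_2 = \begin{pmatrix} \langle\cos 2\theta\rangle &
#'   \langle\sin 2\theta\rangle \\ \langle\sin 2\theta\rangle &
#'   -\langle\cos 2\theta\rangle \end{pmatrix}}
#' whose eigenvalues are \eqn{\pm S} with
#' \deqn{S = \sqrt{\langle\cos 2\theta\rangle^2 +
#'   \langle\sin 2\theta\rangle^2}.}
#' \eqn{S = 0} for a uniform angle distribution and \eqn{S = 1} when all
#' measurements share one axis. Averages may be weighted, e.g. by the
#' structure-tensor coherency of each measurement.
#'
#' @param angles_deg numeric vector of orientation angles in degrees
#'   (any range; treated modulo 180).
#' @param weights optional non-negative weights, same length; must not all
#'   be zero. \code{NULL} (default) means equal weights.
#' @return an object of class \code{order_parameter}: a list with
#'   \item{S}{scalar order parameter in [0, 1];}
#'   \item{n_angles}{number of measurements;}
#'   \item{mean_cos2, mean_sin2}{the (weighted) averages of cos 2\eqn{\theta}
#'     and sin 2\eqn{\theta};}
#'   \item{S2}{the 2 x 2 order tensor;}
#'   \item{lambda}{its eigenvalues, \code{c(S, -S)};}
#'   \item{mean_angle_deg}{the director axis, in [-90, 90).}
#' @examples
#' order_parameter(rep(37, 100))$S        # 1: perfectly aligned
#' order_parameter(seq(-90, 89, by = 1))$S # 0: uniform axial distribution
#' @export
order_parameter <- function(angles_deg, weights = NULL) {
  if (length(angles_deg) < 1) stop("need at least one angle")
  if (any(!is.finite(angles_deg))) stop("angles must be finite (no NaN/NA)")
  if (is.null(weights)) {
    weights <- rep(1, length(angles_deg))
  } else {
    stopifnot(length(weights) == length(angles_deg))
    if (any(!is.finite(weights)) || any(weights < 0))
      stop("weights must be finite and non-negative")
    if (sum(weights) <= 0) stop("weights must not all be zero")
  }
  th2 <- 2 * angles_deg * pi / 180
  w <- weights / sum(weights)
  c2 <- sum(w * cos(th2))
  s2 <- sum(w * sin(th2))
  S <- sqrt(c2^2 + s2^2)
  structure(list(
    S = S,
    n_angles = length(angles_deg),
    mean_cos2 = c2,
    mean_sin2 = s2,
    S2 = matrix(c(c2, s2, s2, -c2), 2, 2),
    lambda = c(S, -S),
    mean_angle_deg = wrap_axial(atan2(s2, c2) / 2 * 180 / pi)
  ), class = "order_parameter")
}

#' @export
print.order_parameter <- function(x, ...) {
  cat(sprintf("nematic order parameter S = %.4f (n = %d, director %.1f deg)\n",
              x$S, x$n_angles, x$mean_angle_deg))
  invisible(x)
}

#' Concentration of the axial von Mises model implied by an order parameter
#'
#' For fiber angles whose doubled angles follow a von Mises distribution
#' with concentration \eqn{\kappa}, the expected order parameter is the
#' Bessel ratio \eqn{S = I_1(\kappa)/I_0(\kappa)}. This inverts that
#' relation numerically, giving a model-based concentration estimate from
#' a measured \code{S}.
#'
#' @param S order parameter in [0, 1).
#' @return estimated concentration \eqn{\kappa \ge 0}.
#' @seealso [vm_order_parameter()] for the forward relation.
#' @export
kappa_from_order_parameter <- function(S) {
  stopifnot(length(S) == 1, is.finite(S), S >= 0)
  if (S >= 1) stop("S must be < 1 for a finite concentration")
  if (S == 0) return(0)
  stats::uniroot(function(k) vm_order_parameter(k) - S,
                 lower = 1e-8, upper = 1e4, tol = 1e-10)$root
}

#' Expected order parameter of the axial von Mises model
#'
#' @param kappa concentration (>= 0) of the von Mises distribution on the
#'   doubled angle.
#' @return \eqn{I_1(\kappa)/I_0(\kappa)}, computed with exponentially
#'   scaled Bessel functions for numerical stability at large \code{kappa}.
#' @export
vm_order_parameter <- function(kappa) {
  stopifnot(all(kappa >= 0))
  besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
}

#' Per-pixel fiber orientation and coherency by the structure tensor
#'
#' Estimates the local fiber axis at every pixel from the eigenstructure of
#' the smoothed gradient outer product (the structure tensor). The gradient
#' is taken on a Gaussian-regularized image (\code{sigma_grad}); the tensor
#' components are then averaged over a Gaussian window
#' (\code{sigma_window}). The orientation reported is the axis of least
#' intensity variation — the fiber direction — and the coherency
#' \eqn{(\lambda_{max}-\lambda_{min})/(\lambda_{max}+\lambda_{min})}
#' grades how anisotropic the neighborhood is (0 isotropic, 1 perfectly
#' oriented). Pixels whose gradient energy falls below
#' \code{energy_floor_rel} times the image intensity maximum carry no
#' meaningful orientation and are marked invalid.
#'
#' Angles are degrees counterclockwise from the image x-axis (columns, with
#' y up), wrapped to [-90, 90).
#'
#' @param img numeric matrix (single channel).
#' @param sigma_grad Gaussian scale (px) for gradient regularization.
#' @param sigma_window Gaussian scale (px) for tensor averaging.
#' @param energy_floor_rel relative gradient-energy validity floor.
#' @return an object of class \code{orientation_field}: list with matrices
#'   \code{theta_deg} (NA where invalid), \code{coherency}, \code{energy},
#'   and logical \code{valid}.
#' @export
structure_tensor_orientation <- function(img, sigma_grad = 1,
                                         sigma_window = 4,
                                         energy_floor_rel = 1e-6) {
  stopifnot(is.matrix(img), sigma_grad > 0, sigma_window >= 0)
  # separable derivative-of-Gaussian gradient: rotationally well balanced,
  # unlike plain central differences which bias orientations toward 45 deg
  k <- dog_kernels(sigma_grad)
  gx <- as.matrix(EBImage::filter2(img, outer(k$g, k$gd),
                                   boundary = "replicate"))
  gy <- -as.matrix(EBImage::filter2(img, outer(k$gd, k$g),
                                    boundary = "replicate"))
  jxx <- gauss_smooth(gx * gx, sigma_window)
  jyy <- gauss_smooth(gy * gy, sigma_window)
  jxy <- gauss_smooth(gx * gy, sigma_window)
  energy <- jxx + jyy
  disc <- sqrt((jxx - jyy)^2 + 4 * jxy^2)
  coherency <- ifelse(energy > 0, disc / pmax(energy, 1e-300), 0)
  # dominant eigenvector of J is the gradient axis; fiber axis is orthogonal
  theta_grad <- 0.5 * atan2(2 * jxy, jxx - jyy) * 180 / pi
  theta <- wrap_axial(theta_grad + 90)
  valid <- energy > energy_floor_rel * max(abs(img))
  theta[!valid] <- NA_real_
  structure(list(theta_deg = theta, coherency = coherency,
                 energy = energy, valid = valid),
            class = "orientation_field")
}

#' Foreground mask of a fiber channel
#'
#' Otsu threshold on the Gaussian-smoothed channel: TRUE where fiber
#' signal is present. Orientation statistics pooled over an image are
#' meaningful only where there are fibers; combining this mask with the
#' validity mask of [structure_tensor_orientation()] restricts pooling to
#' pixels that carry signal.
#'
#' @param img numeric matrix (fiber channel).
#' @param smooth_sigma_px smoothing before thresholding.
#' @return logical matrix.
#' @export
fiber_foreground <- function(img, smooth_sigma_px = 1) {
  sm <- gauss_smooth(img, smooth_sigma_px)
  rng <- range(sm)
  if (diff(rng) <= 0) return(matrix(FALSE, nrow(img), ncol(img)))
  norm <- (sm - rng[1]) / diff(rng)
  norm > EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
}

# 1D Gaussian and derivative-of-Gaussian kernels; the derivative kernel is
# zero-mean and normalized to unit response on a unit ramp
dog_kernels <- function(sigma) {
  r <- max(3, ceiling(4 * sigma))
  x <- -r:r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  gd <- -x / sigma^2 * exp(-x^2 / (2 * sigma^2))
  gd <- gd - mean(gd)
  gd <- gd / sum(gd * (-x))
  list(g = g, gd = gd)
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf("orientation_field: %d x %d px, %.1f%% valid, median coherency %.3f\n",
              nrow(x$theta_deg), ncol(x$theta_deg),
              100 * mean(x$valid), median(x$coherency[x$valid])))
  invisible(x)
}

#' Rim-anchored rectangular regions of interest
#'
#' Places rectangular ROIs along the organoid boundary: each ROI is
#' anchored at a contour point, spans \code{width_um} tangentially and
#' extends \code{depth_um} outward along the local boundary normal, with
#' the zero of its distance axis at the cell-matrix interface. The default
#' 30 x 50 um footprint probes collagen alignment in the first 50 um of
#' matrix beyond the rim.
#'
#' @param organoid an \code{organoid_mask} (see [segment_organoid()]).
#' @param spacing_um arc-length spacing between ROI anchors.
#' @param width_um tangential extent of each ROI.
#' @param depth_um outward (normal) extent of each ROI.
#' @return list of \code{rim_roi} objects: \code{anchor} (row, col, px),
#'   \code{normal}, \code{tangent} (unit vectors in (row, col) px coords),
#'   \code{width_um}, \code{depth_um}, \code{pixel_size_um}.
#' @export
extract_rim_rois <- function(organoid, spacing_um = 30, width_um = 30,
                             depth_um = 50) {
  stopifnot(inherits(organoid, "organoid_mask"))
  px <- organoid$pixel_size_um
  contour <- organoid$contour
  seg <- sqrt(rowSums(diff(rbind(contour, contour[1, , drop = FALSE]))^2))
  arc <- c(0, cumsum(seg))
  total_um <- arc[length(arc)] * px
  n_roi <- max(1L, floor(total_um / spacing_um))
  targets <- (seq_len(n_roi) - 1) * spacing_um / px
  idx <- vapply(targets, function(t) which.min(abs(arc[-length(arc)] - t)),
                integer(1))
  centroid <- organoid$centroid
  lapply(seq_along(idx), function(k) {
    i <- idx[k]
    n <- nrow(contour)
    # tangent from a symmetric window of contour points; the window grows
    # with contour resolution so staircase noise averages out
    hw <- max(2, round(n / 80))
    i_prev <- ((i - 1 - hw) %% n) + 1
    i_next <- ((i - 1 + hw) %% n) + 1
    tg <- contour[i_next, ] - contour[i_prev, ]
    tg <- tg / max(sqrt(sum(tg^2)), 1e-12)
    nm <- c(-tg[2], tg[1])             # rotate 90 deg in (row, col)
    out_dir <- contour[i, ] - centroid
    if (sum(nm * out_dir) < 0) nm <- -nm
    structure(list(anchor = contour[i, ], normal = nm, tangent = tg,
                   width_um = width_um, depth_um = depth_um,
                   pixel_size_um = px),
              class = "rim_roi")
  })
}

# pixels of the field grid falling inside one rim ROI, with their
# distance-from-interface (um); returns a data.frame
roi_pixels <- function(roi, dims, max_distance_um = Inf) {
  px <- roi$pixel_size_um
  half_w <- roi$width_um / 2 / px
  depth <- min(roi$depth_um, max_distance_um) / px
  # bounding box in pixel coords
  corners <- rbind(
    roi$anchor + roi$tangent * half_w,
    roi$anchor - roi$tangent * half_w,
    roi$anchor + roi$tangent * half_w + roi$normal * depth,
    roi$anchor - roi$tangent * half_w + roi$normal * depth)
  r0 <- max(1, floor(min(corners[, 1])) + 1)
  r1 <- min(dims[1], ceiling(max(corners[, 1])) + 1)
  c0 <- max(1, floor(min(corners[, 2])) + 1)
  c1 <- min(dims[2], ceiling(max(corners[, 2])) + 1)
  if (r0 > r1 || c0 > c1)
    return(data.frame(row = integer(), col = integer(), dist_um = numeric()))
  g <- expand.grid(row = r0:r1, col = c0:c1)
  dr <- (g$row - 1) - roi$anchor[1]
  dc <- (g$col - 1) - roi$anchor[2]
  u <- dr * roi$tangent[1] + dc * roi$tangent[2]
  v <- dr * roi$normal[1] + dc * roi$normal[2]
  keep <- abs(u) <= half_w & v >= 0 & v <= depth
  data.frame(row = g$row[keep], col = g$col[keep], dist_um = v[keep] * px)
}

#' Order parameter of fiber orientations near the organoid rim
#'
#' Evaluates the nematic order parameter within each rim-anchored ROI,
#' using the valid pixels of an orientation field up to
#' \code{max_distance_um} from the cell-matrix interface. By default each
#' orientation measurement is weighted by its coherency, which suppresses
#' pixels without clear fiber signal; set \code{weight_by_coherency =
#' FALSE} for plain averages. Alongside S, the angle between each ROI's
#' director and the local rim normal is reported, so radial versus
#' tangential alignment can be read off without altering the
#' rotation-invariant S itself.
#'
#' @param field an \code{orientation_field}.
#' @param rois list of \code{rim_roi} from [extract_rim_rois()].
#' @param max_distance_um include pixels up to this distance from the rim.
#' @param weight_by_coherency logical.
#' @param foreground optional logical matrix (e.g. [fiber_foreground()]):
#'   restrict pooling to pixels with fiber signal, so empty matrix regions
#'   do not dilute the ROI statistics.
#' @return a data.frame with one row per ROI (\code{roi}, \code{n_valid},
#'   \code{S}, \code{mean_angle_deg}, \code{angle_vs_normal_deg}; S is NA
#'   for ROIs without valid pixels) plus attribute \code{pooled}, the
#'   \code{order_parameter} over all ROIs' pixels.
#' @export
rim_order_profile <- function(field, rois, max_distance_um = 50,
                              weight_by_coherency = TRUE,
                              foreground = NULL) {
  stopifnot(inherits(field, "orientation_field"))
  dims <- dim(field$theta_deg)
  usable <- field$valid
  if (!is.null(foreground)) usable <- usable & foreground
  all_angles <- numeric(0)
  all_w <- numeric(0)
  rows <- lapply(seq_along(rois), function(k) {
    pxs <- roi_pixels(rois[[k]], dims, max_distance_um)
    if (nrow(pxs) == 0)
      return(data.frame(roi = k, n_valid = 0L, S = NA_real_,
                        mean_angle_deg = NA_real_,
                        angle_vs_normal_deg = NA_real_))
    ind <- cbind(pxs$row, pxs$col)
    ok <- usable[ind]
    if (!any(ok))
      return(data.frame(roi = k, n_valid = 0L, S = NA_real_,
                        mean_angle_deg = NA_real_,
                        angle_vs_normal_deg = NA_real_))
    th <- field$theta_deg[ind][ok]
    w <- if (weight_by_coherency) field$coherency[ind][ok]
         else rep(1, sum(ok))
    if (sum(w) <= 0) w <- rep(1, length(th))
    op <- order_parameter(th, w)
    nm <- rois[[k]]$normal
    # normal in (row, col); angle of that axis in the x/y-up convention
    normal_deg <- wrap_axial(atan2(-nm[1], nm[2]) * 180 / pi)
    dang <- abs(wrap_axial(op$mean_angle_deg - normal_deg))
    all_angles <<- c(all_angles, th)
    all_w <<- c(all_w, w)
    data.frame(roi = k, n_valid = length(th), S = op$S,
               mean_angle_deg = op$mean_angle_deg,
               angle_vs_normal_deg = dang)
  })
  out <- do.call(rbind, rows)
  attr(out, "pooled") <- if (length(all_angles))
    order_parameter(all_angles, all_w) else NULL
  out
}
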