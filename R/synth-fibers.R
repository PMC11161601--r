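#' Specification of a synthetic fiber field
#'
#' Parameters of the stamped-fiber renderer emulating a collagen
#' reflection / CNA35 channel: straight fibers of fixed length whose axes
#' follow the doubled-angle von Mises distribution around \code{mu_deg}
#' with concentration \code{kappa} (kappa = 0 gives an isotropic field).
#'
#' @param mu_deg mean fiber axis, degrees in [-90, 90).
#' @param kappa von Mises concentration on the doubled angle (>= 0).
#' @param n_fibers number of fibers stamped.
#' @param fiber_length_um fiber length (um).
#' @param fiber_width_px fiber width (px).
#' @param pixel_size_um pixel size (um/px).
#' @param frame_um image side length (um).
#' @param background_level additive background intensity.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed RNG seed.
#' @return a \code{synthetic_fiber_spec} list.
#' @export
synthetic_fiber_spec <- function(mu_deg = 0, kappa = 2, n_fibers = 1000,
                                 fiber_length_um = 20, fiber_width_px = 1,
                                 pixel_size_um = 0.5, frame_um = 200,
                                 background_level = 5, noise_sd = 0,
                                 seed = 1) {
  stopifnot(kappa >= 0, n_fibers >= 1, fiber_length_um > 0,
            fiber_width_px >= 1, pixel_size_um > 0, frame_um > 0,
            noise_sd >= 0)
  mu_deg <- wrap_axial(mu_deg)
  structure(as.list(environment()), class = "synthetic_fiber_spec")
}

#' Render a synthetic fiber field with known per-fiber angles
#'
#' Stamps \code{n_fibers} straight fibers at uniformly random positions;
#' each fiber's axis is drawn from the doubled-angle von Mises model, so
#' the analytic expectation of the sample order parameter is
#' \eqn{I_1(\kappa)/I_0(\kappa)}. The ground truth records the exact angle
#' sample and a per-pixel map of the stamped angle (NA off-fiber; the last
#' stamped fiber wins where fibers cross).
#'
#' @param spec a [synthetic_fiber_spec()].
#' @return list with \code{image} (a \code{multichannel_image} with one
#'   channel \code{fibers}) and \code{truth}: \code{angles_deg} (the
#'   sample), \code{angle_map} (per-pixel), \code{fiber_mask}, the spec.
#' @export
gen_fiber_field <- function(spec) {
  stopifnot(inherits(spec, "synthetic_fiber_spec"))
  with_seed(spec$seed, {
    px <- spec$pixel_size_um
    n_px <- ceiling(spec$frame_um / px)
    canvas <- matrix(0, n_px, n_px)
    angle_map <- matrix(NA_real_, n_px, n_px)
    angles <- rfiber_angles(spec$n_fibers, spec$mu_deg, spec$kappa)
    len_px <- spec$fiber_length_um / px
    half_w <- (spec$fiber_width_px - 1) / 2
    cr <- runif(spec$n_fibers, 1, n_px)
    cc <- runif(spec$n_fibers, 1, n_px)
    ts <- seq(-len_px / 2, len_px / 2, by = 0.4)
    offs <- if (half_w > 0) seq(-half_w, half_w, by = 0.4) else 0
    for (i in seq_len(spec$n_fibers)) {
      a <- angles[i] * pi / 180
      dr <- -sin(a); dc <- cos(a)        # y up: row decreases with +angle
      rows <- cr[i] + outer(ts * dr, offs * dc, "+")   # offsets along the normal
      cols <- cc[i] + outer(ts * dc, offs * (-dr), "+")
      rr <- round(as.vector(rows)); cchere <- round(as.vector(cols))
      ok <- rr >= 1 & rr <= n_px & cchere >= 1 & cchere <= n_px
      idx <- cbind(rr[ok], cchere[ok])
      canvas[idx] <- canvas[idx] + 1
      angle_map[idx] <- angles[i]
    }
    img <- pmin(canvas, 2) / 2 * 200 + spec$background_level
    img <- add_noise(img, spec$noise_sd)
    list(image = multichannel_image(list(fibers = img), px),
         truth = list(angles_deg = angles, angle_map = angle_map,
                      fiber_mask = canvas > 0, spec = spec))
  })
}

#' Render a field of radial fibers around an organoid
#'
#' Convenience generator for alignment-recovery tests: fibers point along
#' the local radial direction from \code{center_px}, emulating collagen
#' aligned perpendicular to the organoid rim.
#'
#' @param dims image size c(rows, cols) in px.
#' @param center_px 0-based (row, col) of the organoid center.
#' @param inner_radius_px fibers start beyond this radius.
#' @param n_fibers number of fibers.
#' @param fiber_length_px fiber length (px).
#' @param pixel_size_um pixel size.
#' @param jitter_deg SD of angular jitter around the radial axis.
#' @param seed RNG seed.
#' @return list with \code{image} and \code{truth} (per-fiber angles and
#'   anchor positions).
#' @export
gen_radial_fiber_field <- function(dims = c(256, 256), center_px = NULL,
                                   inner_radius_px = 40, n_fibers = 800,
                                   fiber_length_px = 30, pixel_size_um = 0.5,
                                   jitter_deg = 0, seed = 1) {
  if (is.null(center_px)) center_px <- (dims - 1) / 2
  with_seed(seed, {
    canvas <- matrix(0, dims[1], dims[2])
    max_r <- min(dims) / 2 - 2
    rad <- sqrt(runif(n_fibers, (inner_radius_px / max_r)^2, 1)) * max_r
    ang <- runif(n_fibers, 0, 2 * pi)
    cr <- center_px[1] - rad * sin(ang)
    cc <- center_px[2] + rad * cos(ang)
    fiber_deg <- wrap_axial(ang * 180 / pi +
                            if (jitter_deg > 0) rnorm(n_fibers, 0, jitter_deg)
                            else 0)
    ts <- seq(-fiber_length_px / 2, fiber_length_px / 2, by = 0.4)
    for (i in seq_len(n_fibers)) {
      a <- fiber_deg[i] * pi / 180
      rr <- round(cr[i] + 1 - ts * sin(a))
      cchere <- round(cc[i] + 1 + ts * cos(a))
      ok <- rr >= 1 & rr <= dims[1] & cchere >= 1 & cchere <= dims[2]
      canvas[cbind(rr[ok], cchere[ok])] <- 1
    }
    img <- canvas * 200 + 5
    list(image = multichannel_image(list(fibers = img), pixel_size_um),
         truth = list(angles_deg = fiber_deg,
                      anchors = cbind(row = cr, col = cc)))
  })
}
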