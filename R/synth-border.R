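#' Star-like tumor-border mask with exact perimeter ground truth
#'
#' Builds a star-shaped polygon in polar form,
#' \deqn{r(\phi) = R - d/2 + (d/2)\cos(n\phi),}
#' i.e. a disk of base radius \eqn{R} carved by \eqn{n} protrusion lobes of
#' depth \eqn{d}; \code{n_protrusions = 0} or \code{depth_um = 0} gives a
#' plain disk. The ground-truth polygon is a dense polyline sampling of
#' this curve; its perimeter and the perimeter of its convex hull are
#' computed exactly by segment-length summation (a pure polygon oracle,
#' independent of any image-based measurement), so the true protrusive
#' index of the rasterized mask is known.
#'
#' @param n_protrusions number of lobes (>= 0).
#' @param depth_um protrusion depth (um); must be smaller than
#'   \code{base_radius_um}.
#' @param base_radius_um outer radius of the shape (um).
#' @param pixel_size_um pixel size (um/px).
#' @param margin_um blank margin around the shape.
#' @param n_vertices vertices of the ground-truth polygon.
#' @return list with \code{mask} (logical matrix) and \code{truth}:
#'   \code{polygon} (n x 2, 0-based row/col px), \code{perimeter_um},
#'   \code{hull_perimeter_um}, \code{protrusive_index_true},
#'   \code{pixel_size_um}.
#' @export
gen_border_mask <- function(n_protrusions, depth_um, base_radius_um,
                            pixel_size_um = 1, margin_um = 20,
                            n_vertices = 4096) {
  stopifnot(depth_um >= 0, base_radius_um > 0, n_protrusions >= 0,
            pixel_size_um > 0)
  if (depth_um >= base_radius_um)
    stop("protrusion depth must be smaller than the base radius ",
         "(degenerate shape)")
  radius_at <- function(phi) {
    if (n_protrusions == 0 || depth_um == 0) rep(base_radius_um, length(phi))
    else base_radius_um - depth_um / 2 + (depth_um / 2) * cos(n_protrusions * phi)
  }
  extent_um <- base_radius_um + margin_um
  n_px <- ceiling(2 * extent_um / pixel_size_um)
  ctr <- (n_px - 1) / 2

  phi <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  rv <- radius_at(phi) / pixel_size_um
  poly <- cbind(row = ctr - rv * sin(phi), col = ctr + rv * cos(phi))
  per <- polygon_perimeter(poly) * pixel_size_um
  hullper <- hull_perimeter(poly) * pixel_size_um

  g <- expand.grid(row = seq_len(n_px), col = seq_len(n_px))
  dx <- (g$col - 1) - ctr
  dy <- -((g$row - 1) - ctr)
  prad <- sqrt(dx^2 + dy^2)
  pang <- atan2(dy, dx)
  mask <- matrix(prad <= radius_at(pang) / pixel_size_um, n_px, n_px)

  list(mask = mask,
       truth = list(polygon = poly, perimeter_um = per,
                    hull_perimeter_um = hullper,
                    protrusive_index_true = per / hullper,
                    pixel_size_um = pixel_size_um))
}
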