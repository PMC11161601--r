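#' Protrusive index of a tumor border
#'
#' Reproduces the border-morphometry macro pipeline: Gaussian blur,
#' thresholding (Otsu for grayscale input; the half level for an already
#' binary mask), binary erosion, selection of the largest component, and
#' measurement of the boundary perimeter and the perimeter of its convex
#' hull on a subpixel marching-squares contour. The protrusive index is
#' boundary perimeter / hull perimeter: 1 for convex borders, larger the
#' more protrusive the border is. (A perimeter is compared with a
#' perimeter, keeping the index dimensionless and exactly 1 in the convex
#' limit.)
#'
#' @param x numeric matrix: binary mask or grayscale image.
#' @param blur_sigma_px Gaussian blur (px).
#' @param erosion_iter binary erosion iterations (3 x 3 box).
#' @param pixel_size_um pixel size (um/px).
#' @return a \code{border_shape}: list with \code{mask} (processed binary),
#'   \code{contour} (n x 2 subpixel row/col), \code{perimeter_um},
#'   \code{hull_perimeter_um}, \code{protrusive_index}.
#' @export
protrusive_index <- function(x, blur_sigma_px = 2, erosion_iter = 2,
                             pixel_size_um = 1) {
  stopifnot(is.matrix(x), any(x > 0))
  is_binary <- all(x %in% c(0, 1))
  sm <- gauss_smooth(x * 1, blur_sigma_px)
  if (is_binary) {
    bin <- sm > 0.5
  } else {
    rng <- range(sm)
    norm <- (sm - rng[1]) / max(diff(rng), 1e-300)
    bin <- norm > EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  }
  if (erosion_iter > 0) {
    brush <- EBImage::makeBrush(3, "box")
    for (i in seq_len(erosion_iter))
      bin <- as.matrix(EBImage::erode(bin * 1, brush)) > 0
  }
  if (!any(bin))
    stop("mask vanished during processing; reduce erosion_iter or blur")
  bin <- largest_component(bin)
  bin <- as.matrix(EBImage::fillHull(bin * 1)) > 0
  contour <- subpixel_contour(bin)
  per <- polygon_perimeter(contour) * pixel_size_um
  hull <- hull_perimeter(contour) * pixel_size_um
  structure(list(mask = bin, contour = contour, perimeter_um = per,
                 hull_perimeter_um = hull,
                 protrusive_index = per / hull),
            class = "border_shape")
}

#' @export
print.border_shape <- function(x, ...) {
  cat(sprintf("border_shape: perimeter %.1f um, hull %.1f um, protrusive index %.3f\n",
              x$perimeter_um, x$hull_perimeter_um, x$protrusive_index))
  invisible(x)
}

#' Organoid area growth between two time points
#'
#' @param mask_t0,mask_t1 logical/binary matrices at the two time points.
#' @param pixel_size_um pixel size (um/px).
#' @return area(t1) / area(t0) (dimensionless; areas in um^2 internally).
#' @export
organoid_area_change <- function(mask_t0, mask_t1, pixel_size_um = 1) {
  a0 <- sum(mask_t0 > 0)
  a1 <- sum(mask_t1 > 0)
  if (a0 == 0) stop("mask at t0 is empty")
  (a1 * pixel_size_um^2) / (a0 * pixel_size_um^2)
}

#' Count and length of invading strands
#'
#' Strand identification is an input (strands are annotated, typically by
#' hand): this measures given annotations. Polyline input gives exact arc
#' lengths; a label-mask input measures each labeled strand along its
#' longest internal path (see [cell_region_length()]).
#'
#' @param strands either a data.frame with columns \code{strand_id},
#'   \code{vertex_index}, \code{row}, \code{col} (subpixel polylines, px
#'   coords) or an integer label matrix (0 = background).
#' @param pixel_size_um pixel size (um/px).
#' @return list with \code{count}, \code{cumulative_length_um} and
#'   \code{lengths_um} (named per strand). An empty set gives (0, 0).
#' @export
strand_metrics <- function(strands, pixel_size_um = 1) {
  if (is.matrix(strands)) {
    ids <- sort(setdiff(unique(as.integer(strands)), 0L))
    lens <- vapply(ids, function(i)
      cell_region_length(strands == i, pixel_size_um), numeric(1))
    names(lens) <- ids
  } else if (is.data.frame(strands)) {
    stopifnot(all(c("strand_id", "vertex_index", "row", "col") %in%
                    names(strands)))
    if (nrow(strands) == 0)
      return(list(count = 0L, cumulative_length_um = 0,
                  lengths_um = numeric(0)))
    lens <- vapply(split(strands, strands$strand_id), function(s) {
      s <- s[order(s$vertex_index), ]
      if (nrow(s) < 2) return(0)
      sum(sqrt(diff(s$row)^2 + diff(s$col)^2)) * pixel_size_um
    }, numeric(1))
  } else stop("strands must be a polyline data.frame or a label matrix")
  list(count = length(lens), cumulative_length_um = sum(lens),
       lengths_um = lens)
}
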