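#' Segment organoids from a multichannel plane
#'
#' Selects organoid bodies from the background by intensity thresholding
#' on the combined K8 + K14 signal: the summed channel is Gaussian
#' smoothed, thresholded with Otsu's method (computed from the image, so
#' the result is invariant to a positive intensity gain), holes are
#' filled, and connected components above a minimum area are kept. Each
#' component becomes one organoid mask with its subpixel boundary contour,
#' centroid and equivalent radius.
#'
#' @param img a \code{multichannel_image} with K8 and K14 channels.
#' @param smooth_sigma_px Gaussian smoothing before thresholding (px).
#' @param min_area_px2 minimum component area (px^2).
#' @return list of \code{organoid_mask} objects (possibly empty): each has
#'   \code{mask} (logical), \code{contour} (n x 2, 0-based subpixel
#'   row/col), \code{centroid} (row, col), \code{equiv_radius_um},
#'   \code{area_px}, \code{pixel_size_um}.
#' @export
segment_organoid <- function(img, smooth_sigma_px = 1, min_area_px2 = 500) {
  stopifnot(inherits(img, "multichannel_image"))
  comb <- get_channel(img, "K8") + get_channel(img, "K14")
  sm <- gauss_smooth(comb, smooth_sigma_px)
  rng <- range(sm)
  if (diff(rng) <= 0) return(list())
  norm <- (sm - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  bin <- norm > thr
  if (!any(bin)) return(list())
  bin <- as.matrix(EBImage::fillHull(bin * 1)) > 0
  lab <- EBImage::bwlabel(bin * 1)
  n <- max(lab)
  out <- list()
  for (i in seq_len(n)) {
    m <- matrix(as.integer(lab) == i, nrow(bin), ncol(bin))
    area <- sum(m)
    if (area < min_area_px2) next
    m <- as.matrix(EBImage::fillHull(m * 1)) > 0
    out[[length(out) + 1]] <- new_organoid_mask(m, img$pixel_size_um)
  }
  out
}

# build an organoid_mask object from a logical matrix
new_organoid_mask <- function(mask, pixel_size_um) {
  idx <- which(mask, arr.ind = TRUE)
  centroid <- c(mean(idx[, 1]) - 1, mean(idx[, 2]) - 1)
  area <- nrow(idx)
  structure(list(
    mask = mask,
    contour = subpixel_contour(mask),
    centroid = centroid,
    area_px = area,
    equiv_radius_um = sqrt(area / pi) * pixel_size_um,
    pixel_size_um = pixel_size_um
  ), class = "organoid_mask")
}

#' @export
print.organoid_mask <- function(x, ...) {
  cat(sprintf("organoid_mask: %d px^2, equiv radius %.1f um, centroid (%.1f, %.1f)\n",
              x$area_px, x$equiv_radius_um, x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Detect nuclei on the DAPI channel within an organoid
#'
#' Separates nucleus from non-nucleus pixels inside the organoid mask by a
#' two-class (k = 2) k-means on the DAPI intensities — an adaptive
#' threshold between the two intensity populations — and then splits
#' touching nuclei by a watershed on the smoothed DAPI signal, seeded at
#' its regional maxima. Labels are restricted to the organoid mask and
#' specks below \code{min_area_px2} are discarded.
#'
#' @param dapi numeric matrix (DAPI channel).
#' @param organoid an \code{organoid_mask}.
#' @param smooth_sigma_px smoothing before the watershed split (px).
#' @param min_area_px2 minimum nucleus area.
#' @param split_tolerance watershed tolerance as a fraction of the
#'   in-mask intensity range; maxima closer in height than this merge.
#' @return integer label matrix (0 = background), one label per nucleus.
#' @export
detect_nuclei <- function(dapi, organoid, smooth_sigma_px = 2,
                          min_area_px2 = 20, split_tolerance = 0.2) {
  stopifnot(is.matrix(dapi), inherits(organoid, "organoid_mask"))
  mask <- organoid$mask
  vals <- dapi[mask]
  out <- matrix(0L, nrow(dapi), ncol(dapi))
  if (length(vals) == 0 || sd(vals) < 1e-8) return(out)
  km <- kmeans(vals, centers = range(vals), iter.max = 50)
  hi <- which.max(km$centers)
  nuc_bin <- matrix(FALSE, nrow(dapi), ncol(dapi))
  nuc_bin[mask] <- km$cluster == hi
  if (!any(nuc_bin)) return(out)
  sm <- gauss_smooth(dapi, smooth_sigma_px)
  rng <- diff(range(sm[mask]))
  surf <- matrix(0, nrow(dapi), ncol(dapi))
  surf[nuc_bin] <- sm[nuc_bin] - min(sm[nuc_bin]) + 1e-6
  ws <- EBImage::watershed(EBImage::Image(surf),
                           tolerance = split_tolerance * max(rng, 1e-12))
  lab <- matrix(as.integer(ws), nrow(dapi), ncol(dapi))
  lab[!mask] <- 0L
  relabel_min_area(lab, min_area_px2)
}

# drop labels under a minimum area and renumber 1..n
relabel_min_area <- function(lab, min_area) {
  if (max(lab) == 0) return(lab)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(sizes >= min_area)
  map <- integer(max(lab))
  map[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  pos <- lab > 0
  out[pos] <- map[lab[pos]]
  out
}

#' Segment cells by nucleus-seeded watershed
#'
#' Partitions the organoid mask into one region per nucleus. The watershed
#' elevation surface is a multi-scale Hessian membrane enhancement of the
#' combined K8 + K14 signal: at each scale the image is Gaussian smoothed
#' and the scale-normalized negative minor Hessian eigenvalue (bright
#' ridge strength) is computed; scales are aggregated by the per-pixel
#' maximum. Every organoid pixel is then assigned to the nucleus with the
#' smallest elevation-weighted geodesic distance (Dijkstra over the
#' 8-connected mask graph, edge cost = mean elevation of the endpoints
#' plus a small distance regularization): intensity ridges between cells
#' act as soft barriers, and the assignment degrades gracefully to a
#' geodesic Voronoi partition where no membrane signal exists.
#'
#' @param nuclei integer nucleus label matrix (from [detect_nuclei()]).
#' @param img the \code{multichannel_image} (K8/K14 used for membranes).
#' @param organoid the \code{organoid_mask} to partition.
#' @param scales_px Hessian scales in px; matched to the apparent membrane
#'   width.
#' @param eps_frac distance regularization, as a fraction of the mean
#'   ridge strength: larger values push the partition toward plain
#'   geodesic Voronoi.
#' @return a \code{cell_label_map}: list with \code{cells} and
#'   \code{nuclei} integer matrices and \code{map}, a data.frame pairing
#'   cell labels with their nucleus labels (a bijection).
#' @export
segment_cells <- function(nuclei, img, organoid, scales_px = c(1, 2),
                          eps_frac = 0.02) {
  stopifnot(is.matrix(nuclei), inherits(img, "multichannel_image"),
            inherits(organoid, "organoid_mask"))
  mask <- organoid$mask
  inside <- nuclei
  dropped <- setdiff(unique(inside[!mask & inside > 0]), 0L)
  if (length(dropped) > 0) {
    warning(sprintf("dropping %d nucleus label(s) outside the organoid mask: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
    inside[inside %in% dropped] <- 0L
  }
  inside[!mask] <- 0L
  if (max(inside) == 0) stop("no nucleus seeds inside the organoid mask")
  comb <- get_channel(img, "K8") + get_channel(img, "K14")
  elev <- hessian_ridge_max(comb, scales_px)

  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  id <- matrix(0L, nrow(mask), ncol(mask))
  id[mask] <- seq_len(n)
  ev <- elev[mask]
  eps <- eps_frac * mean(ev) + 1e-9
  edges <- NULL
  w <- NULL
  steps <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  for (s in 1:4) {
    nb <- cbind(idx[, 1] + steps[s, 1], idx[, 2] + steps[s, 2])
    ok <- nb[, 1] >= 1 & nb[, 1] <= nrow(mask) &
          nb[, 2] >= 1 & nb[, 2] <= ncol(mask)
    j <- rep(0L, n)
    j[ok] <- id[nb[ok, , drop = FALSE]]
    use <- j > 0
    len <- sqrt(sum(steps[s, ]^2))
    edges <- rbind(edges, cbind(which(use), j[use]))
    w <- c(w, ((ev[use] + ev[j[use]]) / 2 + eps) * len)
  }
  nl <- sort(setdiff(unique(inside[mask]), 0L))
  # one virtual source per nucleus, attached to all its pixels
  vsrc <- do.call(rbind, lapply(seq_along(nl), function(k)
    cbind(n + k, id[inside == nl[k] & mask])))
  g <- igraph::graph_from_edgelist(rbind(edges, vsrc), directed = FALSE)
  igraph::E(g)$weight <- c(w, rep(1e-12, nrow(vsrc)))
  if (igraph::vcount(g) < n + length(nl))
    g <- igraph::add_vertices(g, n + length(nl) - igraph::vcount(g))
  d <- igraph::distances(g, v = n + seq_along(nl), to = seq_len(n))
  lab <- nl[max.col(-t(d))]
  cells <- matrix(0L, nrow(mask), ncol(mask))
  cells[mask] <- lab
  ids <- sort(setdiff(unique(as.integer(cells)), 0L))
  structure(list(cells = cells, nuclei = inside,
                 map = data.frame(cell = ids, nucleus = ids)),
            class = "cell_label_map")
}

#' @export
print.cell_label_map <- function(x, ...) {
  cat(sprintf("cell_label_map: %d cells over %d px\n",
              nrow(x$map), sum(x$cells > 0)))
  invisible(x)
}

# multi-scale bright-ridge enhancement: max over scales of the
# scale-normalized negative minor eigenvalue of the Hessian
hessian_ridge_max <- function(img, scales_px) {
  out <- matrix(0, nrow(img), ncol(img))
  for (s in scales_px) {
    sm <- gauss_smooth(img, s)
    nr <- nrow(sm); nc <- ncol(sm)
    hrr <- matrix(0, nr, nc); hcc <- matrix(0, nr, nc); hrc <- matrix(0, nr, nc)
    hrr[2:(nr - 1), ] <- sm[1:(nr - 2), ] - 2 * sm[2:(nr - 1), ] + sm[3:nr, ]
    hcc[, 2:(nc - 1)] <- sm[, 1:(nc - 2)] - 2 * sm[, 2:(nc - 1)] + sm[, 3:nc]
    gr <- matrix(0, nr, nc)
    gr[2:(nr - 1), ] <- (sm[3:nr, ] - sm[1:(nr - 2), ]) / 2
    hrc[, 2:(nc - 1)] <- (gr[, 3:nc] - gr[, 1:(nc - 2)]) / 2
    lam_min <- (hrr + hcc) / 2 - sqrt(((hrr - hcc) / 2)^2 + hrc^2)
    out <- pmax(out, s^2 * pmax(-lam_min, 0))
  }
  out
}

#' Classify cells as outer (matrix-contacting) or inner
#'
#' A cell is "outer" — in contact with the surrounding collagen — when its
#' region shares at least one pixel with the 1-px boundary band of the
#' organoid mask; otherwise it is "inner". Purely geometric: intensities
#' play no role.
#'
#' @param cells a \code{cell_label_map}.
#' @param organoid the \code{organoid_mask}.
#' @return named character vector (cell label -> "outer"/"inner").
#' @export
classify_layers <- function(cells, organoid) {
  stopifnot(inherits(cells, "cell_label_map"),
            inherits(organoid, "organoid_mask"))
  mask <- organoid$mask
  er <- as.matrix(EBImage::erode(mask * 1,
                                 EBImage::makeBrush(3, "box"))) > 0
  band <- mask & !er
  ids <- cells$map$cell
  touching <- unique(cells$cells[band])
  setNames(ifelse(ids %in% touching, "outer", "inner"), ids)
}
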