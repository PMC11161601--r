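#' Estimate the image background level
#'
#' Median intensity outside a dilated union of the organoid masks; the
#' dilation keeps the halo of out-of-focus signal around each organoid out
#' of the estimate, and the median is robust to stray debris.
#'
#' @param channel numeric matrix.
#' @param organoids one \code{organoid_mask} or a list of them.
#' @param dilate_px dilation radius (px).
#' @return background intensity (scalar).
#' @export
estimate_background <- function(channel, organoids, dilate_px = 10) {
  if (inherits(organoids, "organoid_mask")) organoids <- list(organoids)
  mask <- Reduce(`|`, lapply(organoids, function(o) o$mask))
  brush <- EBImage::makeBrush(2 * dilate_px + 1, "disc")
  dil <- as.matrix(EBImage::dilate(mask * 1, brush)) > 0
  outside <- channel[!dil]
  if (length(outside) == 0)
    stop("organoid fills the frame; supply an explicit background value")
  median(outside)
}

#' Background-subtracted nuclear/cytoplasmic intensity ratio
#'
#' \deqn{ratio = \frac{\overline{I}_{nuc} - b}{\overline{I}_{cyto} - b}}
#' where \eqn{b} is the background level. Defined only when the cytoplasmic
#' mean exceeds the background; otherwise NA is returned and the caller is
#' expected to exclude the cell from summaries.
#'
#' @param nuc_mean mean channel intensity over the nucleus region.
#' @param cyto_mean mean over the cytoplasm (cell minus nucleus) region.
#' @param background background intensity.
#' @return the ratio, or NA when \code{cyto_mean <= background}.
#' @export
nuc_cyto_ratio <- function(nuc_mean, cyto_mean, background) {
  ifelse(cyto_mean > background,
         (nuc_mean - background) / (cyto_mean - background), NA_real_)
}

#' Measure per-cell intensity and shape records
#'
#' Builds the per-cell table consumed by the Yap analysis: nuclear and
#' cytoplasmic mean Yap intensity, background-subtracted
#' nuclear/cytoplasmic ratio, mean K14 intensity over the cell region,
#' outer/inner layer, K14 Hi/Lo class, rim/leader/none role and cell
#' length. Cells whose cytoplasmic mean does not exceed the background are
#' flagged (\code{ratio_valid = FALSE}, ratio NA).
#'
#' @param img a \code{multichannel_image} with DAPI, K14 and Yap channels.
#' @param cellmap a \code{cell_label_map} from [segment_cells()].
#' @param organoid the \code{organoid_mask}.
#' @param background background intensity for the Yap channel;
#'   \code{NULL} = estimated by [estimate_background()].
#' @param e_min elongation threshold for leader calls (major/minor axis).
#' @param p_min_um protrusion threshold for leader calls (um beyond the
#'   organoid body outline).
#' @param measure_length compute skeleton-path cell lengths (slower).
#' @return data.frame with one row per cell: \code{cell}, \code{layer},
#'   \code{role}, \code{k14_class}, \code{nuc_mean}, \code{cyto_mean},
#'   \code{background}, \code{ratio}, \code{ratio_valid}, \code{k14_mean},
#'   \code{elongation}, \code{protrusion_um}, \code{length_um},
#'   \code{centroid_row}, \code{centroid_col}.
#' @export
measure_cells <- function(img, cellmap, organoid, background = NULL,
                          e_min = 2, p_min_um = 5, measure_length = TRUE) {
  stopifnot(inherits(img, "multichannel_image"),
            inherits(cellmap, "cell_label_map"),
            inherits(organoid, "organoid_mask"))
  yap <- get_channel(img, "Yap")
  k14 <- get_channel(img, "K14")
  if (is.null(background)) background <- estimate_background(yap, organoid)
  px <- img$pixel_size_um
  cells <- cellmap$cells
  nuclei <- cellmap$nuclei
  ids <- cellmap$map$cell
  cyto_lab <- cells
  cyto_lab[nuclei > 0] <- 0L

  mean_by <- function(ch, lab) {
    v <- tapply(ch[lab > 0], lab[lab > 0], mean)
    out <- setNames(rep(NA_real_, length(ids)), ids)
    out[names(v)] <- v
    out
  }
  nuc_mean <- mean_by(yap, nuclei)
  cyto_mean <- mean_by(yap, cyto_lab)
  k14_mean <- mean_by(k14, cells)

  layer <- classify_layers(cellmap, organoid)[as.character(ids)]
  shape <- cell_shape_stats(cells, ids)
  prot <- cell_protrusions(cells, ids, organoid)

  ratio <- nuc_cyto_ratio(nuc_mean, cyto_mean, background)
  df <- data.frame(
    cell = ids,
    layer = unname(layer),
    nuc_mean = unname(nuc_mean),
    cyto_mean = unname(cyto_mean),
    background = background,
    ratio = unname(ratio),
    ratio_valid = unname(!is.na(ratio)),
    k14_mean = unname(k14_mean),
    elongation = shape$elongation,
    centroid_row = shape$centroid_row,
    centroid_col = shape$centroid_col,
    protrusion_um = prot * px,
    stringsAsFactors = FALSE)
  df$k14_class <- classify_k14(df)
  df$role <- classify_role(df, e_min = e_min, p_min_um = p_min_um)
  df$length_um <- if (measure_length)
    vapply(ids, function(i) cell_region_length(cells == i, px), numeric(1))
  else NA_real_
  rownames(df) <- NULL
  df
}

# elongation (sqrt eigenvalue ratio of the pixel covariance) and centroid
cell_shape_stats <- function(cells, ids) {
  el <- numeric(length(ids)); cr <- numeric(length(ids)); cc <- numeric(length(ids))
  for (k in seq_along(ids)) {
    idx <- which(cells == ids[k], arr.ind = TRUE)
    cr[k] <- mean(idx[, 1]) - 1
    cc[k] <- mean(idx[, 2]) - 1
    if (nrow(idx) < 3) { el[k] <- 1; next }
    cv <- stats::cov(idx)
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    el[k] <- sqrt(max(ev[1], 1e-12) / max(ev[2], 1e-12))
  }
  list(elongation = el, centroid_row = cr, centroid_col = cc)
}

# distance (px) by which each cell's farthest pixel lies beyond the convex
# outline of the organoid body built from all *other* cells
cell_protrusions <- function(cells, ids, organoid) {
  vapply(seq_along(ids), function(k) {
    body <- cells > 0 & cells != ids[k]
    if (!any(body)) return(0)
    bpts <- which(body, arr.ind = TRUE) - 1
    hull <- bpts[grDevices::chull(bpts), , drop = FALSE]
    cpts <- which(cells == ids[k], arr.ind = TRUE) - 1
    inside <- points_in_polygon(cpts, hull)
    if (all(inside)) return(0)
    max(dist_to_polyline(cpts[!inside, , drop = FALSE], hull))
  }, numeric(1))
}

#' Classify cells as K14-high or K14-low
#'
#' The threshold is the mean of the per-cell K14 means over the outer
#' (matrix-contacting) cells of the same image — the rim population; a
#' cell is "Hi" when its K14 mean exceeds that threshold strictly (ties
#' are "Lo"). With fewer than two outer cells the classification is
#' skipped with a warning (all NA).
#'
#' @param cells data.frame with columns \code{k14_mean} and \code{layer}.
#' @return character vector ("Hi"/"Lo"/NA) along the rows of \code{cells}.
#' @export
classify_k14 <- function(cells) {
  stopifnot(all(c("k14_mean", "layer") %in% names(cells)))
  outer_means <- cells$k14_mean[cells$layer == "outer"]
  if (length(outer_means) < 2) {
    warning("fewer than two outer cells; K14 classification skipped")
    return(rep(NA_character_, nrow(cells)))
  }
  thr <- mean(outer_means)
  ifelse(cells$k14_mean > thr, "Hi", "Lo")
}

#' Classify cells as rim, leader or none
#'
#' Inner cells get "none". Outer cells are "rim" by default and "leader"
#' when they are both elongated (major/minor axis >= \code{e_min}) and
#' protrusive (farthest point >= \code{p_min_um} beyond the convex outline
#' of the organoid body formed by the remaining cells) — a reproducible
#' operationalization of the morphological leader-cell criteria, which in
#' practice are applied by eye.
#'
#' @param cells data.frame with columns \code{layer}, \code{elongation},
#'   \code{protrusion_um}.
#' @param e_min elongation threshold.
#' @param p_min_um protrusion threshold (um).
#' @return character vector ("rim"/"leader"/"none").
#' @export
classify_role <- function(cells, e_min = 2, p_min_um = 5) {
  stopifnot(all(c("layer", "elongation", "protrusion_um") %in% names(cells)))
  ifelse(cells$layer != "outer", "none",
         ifelse(cells$elongation >= e_min & cells$protrusion_um >= p_min_um,
                "leader", "rim"))
}

#' Length of a cell region along its longest internal path
#'
#' Measures the geodesic diameter of the region: the longest shortest path
#' between any two of its pixels, walking 8-connected with diagonal steps
#' weighted by sqrt(2). For elongated cells this is the length of the
#' medial path; for a disk it equals the diameter. Computed by a
#' double-sweep shortest-path search on the pixel graph.
#'
#' @param region logical matrix (the cell's pixels).
#' @param pixel_size_um pixel size.
#' @return length in um (a single pixel returns \code{pixel_size_um}).
#' @export
cell_region_length <- function(region, pixel_size_um) {
  idx <- which(region, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) return(0)
  if (n == 1) return(pixel_size_um)
  key <- idx[, 1] + 1i * idx[, 2]
  lut <- setNames(seq_len(n), as.character(key))
  edges <- NULL; w <- NULL
  steps <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  for (s in seq_len(4)) {
    nb <- as.character((idx[, 1] + steps[s, 1]) + 1i * (idx[, 2] + steps[s, 2]))
    j <- lut[nb]
    ok <- !is.na(j)
    if (!any(ok)) next
    edges <- rbind(edges, cbind(which(ok), unname(j[ok])))
    w <- c(w, rep(sqrt(sum(steps[s, ]^2)), sum(ok)))
  }
  if (is.null(edges)) return(pixel_size_um)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- w
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  d1 <- igraph::distances(g, v = 1)[1, ]
  d1[!is.finite(d1)] <- -1
  far <- which.max(d1)
  d2 <- igraph::distances(g, v = far)[1, ]
  d2[!is.finite(d2)] <- -1
  max(d2) * pixel_size_um
}
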