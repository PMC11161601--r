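#' Specification of a synthetic organoid image
#'
#' Parameters of the schematic organoid renderer: a disk of packed cells
#' with a single outer rim layer, optional elongated leader cells
#' protruding beyond the rim, nuclei with distinct DAPI signal, per-role
#' true Yap nuclear/cytoplasmic ratios, and a bimodal K14 pattern among
#' outer cells. Defaults describe a mid-size mammary organoid plane
#' (radius 40 um, cell radius 8 um) at 0.5 um/px.
#'
#' @param organoid_radius_um organoid body radius (um).
#' @param cell_radius_um nominal cell radius (um); must be smaller than the
#'   organoid radius.
#' @param n_rim_cells number of cells forming the single outer layer.
#' @param yap_ratio_by_role named numeric vector with entries \code{rim},
#'   \code{inner} and \code{leader}: true nuclear/cytoplasmic Yap ratios.
#' @param k14_hi_fraction fraction of outer cells rendered K14-high.
#' @param background_level additive background intensity.
#' @param noise_sd standard deviation of additive Gaussian noise (clipped
#'   at zero).
#' @param pixel_size_um pixel size (um/px).
#' @param n_leader_cells number of rim positions replaced by elongated,
#'   protruding leader cells.
#' @param leader_protrusion_um how far leader tips extend beyond the body.
#' @param frame_um image side length (um); \code{NULL} sizes the frame to
#'   the organoid plus a margin. A frame too small for the organoid is an
#'   error.
#' @param seed RNG seed; identical specs render bit-identical images.
#' @return a \code{synthetic_organoid_spec} list.
#' @export
synthetic_organoid_spec <- function(organoid_radius_um = 40,
                                    cell_radius_um = 8,
                                    n_rim_cells = 12,
                                    yap_ratio_by_role = c(rim = 2, inner = 1.2,
                                                          leader = 3),
                                    k14_hi_fraction = 0.5,
                                    background_level = 10,
                                    noise_sd = 2,
                                    pixel_size_um = 0.5,
                                    n_leader_cells = 0,
                                    leader_protrusion_um = 15,
                                    frame_um = NULL,
                                    seed = 1) {
  stopifnot(organoid_radius_um > cell_radius_um, cell_radius_um > 0,
            k14_hi_fraction >= 0, k14_hi_fraction <= 1,
            noise_sd >= 0, pixel_size_um > 0, n_rim_cells >= 1,
            n_leader_cells >= 0, n_leader_cells <= n_rim_cells,
            all(c("rim", "inner", "leader") %in% names(yap_ratio_by_role)),
            all(yap_ratio_by_role > 0))
  structure(as.list(environment()), class = "synthetic_organoid_spec")
}

#' Render a synthetic multichannel organoid image with ground truth
#'
#' Builds an organoid as a Voronoi packing of cell seeds inside a disk:
#' \code{n_rim_cells} seeds on an outer ring (one-cell rim layer), a
#' hexagonal packing of inner seeds, and optionally elongated leader cells
#' protruding radially beyond the body. Four channels are rendered — DAPI
#' (nuclei), K8 (all cell bodies), K14 (bimodal among outer cells), Yap
#' (nucleus intensity = background + A * true ratio, cytoplasm =
#' background + A) — so that the background-subtracted nuclear/cytoplasmic
#' ratio of each cell equals its specified true value exactly before noise.
#'
#' @param spec a [synthetic_organoid_spec()].
#' @return list with \code{image} (a \code{multichannel_image}) and
#'   \code{truth}: \code{cells} data.frame (cell, role, layer, seed/nucleus
#'   positions in 0-based px, \code{yap_ratio_true}, \code{k14_class_true}),
#'   \code{mask} (logical organoid mask), \code{cell_labels} and
#'   \code{nucleus_labels} (integer matrices), \code{n_rim}, and the spec.
#' @export
gen_organoid_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_organoid_spec"))
  with_seed(spec$seed, {
    px <- spec$pixel_size_um
    R <- spec$organoid_radius_um
    r <- spec$cell_radius_um
    extent_um <- R + ifelse(spec$n_leader_cells > 0,
                            spec$leader_protrusion_um, 0)
    frame_um <- if (is.null(spec$frame_um)) 2 * extent_um + 24 else spec$frame_um
    if (frame_um < 2 * extent_um + 2)
      stop("organoid (plus protrusions) does not fit the requested frame")
    n_px <- ceiling(frame_um / px)
    ctr <- (n_px - 1) / 2            # 0-based center (row = col)

    # --- seeds (um coordinates relative to center, x right / y up) ---
    rim_angles <- seq(0, 2 * pi, length.out = spec$n_rim_cells + 1)[- (spec$n_rim_cells + 1)]
    rim_xy <- cbind(x = (R - r) * cos(rim_angles), y = (R - r) * sin(rim_angles))
    leader_idx <- if (spec$n_leader_cells > 0)
      seq_len(spec$n_leader_cells) else integer(0)

    hex <- hex_seeds(R - 2.2 * r, 1.9 * r)
    # drop inner seeds colliding with rim seeds
    if (nrow(hex) > 0 && nrow(rim_xy) > 0) {
      dmin <- apply(hex, 1, function(p)
        min(sqrt((rim_xy[, 1] - p[1])^2 + (rim_xy[, 2] - p[2])^2)))
      hex <- hex[dmin > 1.2 * r, , drop = FALSE]
    }

    seeds <- rbind(rim_xy, hex)
    role <- c(ifelse(seq_len(nrow(rim_xy)) %in% leader_idx, "leader", "rim"),
              rep("inner", nrow(hex)))
    layer <- ifelse(role == "inner", "inner", "outer")

    # leader geometry: ellipse along the radial axis, tip at R + protrusion
    lead_geom <- lapply(leader_idx, function(i) {
      ang <- rim_angles[i]
      a <- (spec$leader_protrusion_um + 2 * r) / 2
      b <- min(r / 1.25, a / 3)     # elongated: major/minor about 3
      c_rad <- R + spec$leader_protrusion_um - a
      list(center = c(c_rad * cos(ang), c_rad * sin(ang)),
           a = a, b = b, ang = ang)
    })
    if (length(leader_idx) > 0)
      seeds[leader_idx, ] <- t(vapply(lead_geom, function(g) g$center,
                                      numeric(2)))
    # leader nuclei sit in the protruding tip, not at the cell base
    nuc_pos <- seeds
    if (length(leader_idx) > 0)
      nuc_pos[leader_idx, ] <- t(vapply(lead_geom, function(g)
        g$center + 0.35 * g$a * c(cos(g$ang), sin(g$ang)), numeric(2)))

    # --- pixel grid in um coords ---
    g <- expand.grid(row = seq_len(n_px), col = seq_len(n_px))
    xs <- ((g$col - 1) - ctr) * px
    ys <- -((g$row - 1) - ctr) * px
    rad <- sqrt(xs^2 + ys^2)
    in_disk <- rad <= R

    in_leader <- rep(FALSE, length(xs))
    leader_of <- rep(0L, length(xs))
    for (k in seq_along(lead_geom)) {
      gm <- lead_geom[[k]]
      ca <- cos(gm$ang); sa <- sin(gm$ang)
      u <- (xs - gm$center[1]) * ca + (ys - gm$center[2]) * sa
      v <- -(xs - gm$center[1]) * sa + (ys - gm$center[2]) * ca
      inside <- (u / gm$a)^2 + (v / gm$b)^2 <= 1
      in_leader <- in_leader | inside
      leader_of[inside] <- leader_idx[k]
    }
    in_org <- in_disk | in_leader

    # --- cell assignment: Voronoi over non-leader seeds within the disk;
    # leader cells own exactly their ellipse ---
    lab <- rep(0L, length(xs))
    pix <- which(in_org)
    vor_ids <- setdiff(seq_len(nrow(seeds)), leader_idx)
    d2 <- matrix(Inf, length(pix), length(vor_ids))
    for (s in seq_along(vor_ids))
      d2[, s] <- (xs[pix] - seeds[vor_ids[s], 1])^2 +
                 (ys[pix] - seeds[vor_ids[s], 2])^2
    lab[pix] <- vor_ids[max.col(-d2)]
    lab[leader_of > 0] <- leader_of[leader_of > 0]
    lab[!in_org] <- 0L

    cell_labels <- matrix(lab, n_px, n_px)
    mask <- matrix(in_org, n_px, n_px)

    # --- nuclei: disk of radius 0.45 r at each seed ---
    nuc <- rep(0L, length(xs))
    nr2 <- (0.45 * r)^2
    for (s in seq_len(nrow(seeds))) {
      inside <- (xs - nuc_pos[s, 1])^2 + (ys - nuc_pos[s, 2])^2 <= nr2
      nuc[inside & lab == s] <- s
    }
    nucleus_labels <- matrix(nuc, n_px, n_px)

    # --- K14 classes: exact count of Hi among outer cells ---
    outer_ids <- which(layer == "outer")
    n_hi <- round(spec$k14_hi_fraction * length(outer_ids))
    hi_ids <- if (n_hi > 0) sample(outer_ids, n_hi) else integer(0)
    k14_class <- ifelse(seq_len(nrow(seeds)) %in% hi_ids, "Hi", "Lo")

    # --- channels ---
    bg <- spec$background_level
    A <- 60
    ratios <- unname(spec$yap_ratio_by_role[role])
    is_cell <- lab > 0
    is_nuc <- nuc > 0
    dapi <- bg + 150 * is_nuc
    # cell-to-cell variation in K8 expression gives each cell boundary an
    # intensity step, as in real keratin stainings
    k8_level <- 120 * runif(nrow(seeds), 0.8, 1.2)
    k8 <- bg + ifelse(is_cell, k8_level[pmax(lab, 1)], 0)
    k14_level <- c(Hi = 160, Lo = 25)[k14_class]
    k14 <- bg + ifelse(is_cell, k14_level[pmax(lab, 1)], 0)
    yap <- bg + ifelse(is_cell,
                       ifelse(is_nuc, A * ratios[pmax(lab, 1)], A), 0)

    chans <- lapply(list(DAPI = dapi, K8 = k8, K14 = k14, Yap = yap),
                    function(v) add_noise(matrix(v, n_px, n_px), spec$noise_sd))
    img <- multichannel_image(chans, px)

    um2px <- function(xy) cbind(row = ctr - xy[, 2] / px,
                                col = ctr + xy[, 1] / px)
    sp <- um2px(seeds)
    np <- um2px(nuc_pos)
    cells <- data.frame(cell = seq_len(nrow(seeds)), role = role,
                        layer = layer, seed_row = sp[, 1], seed_col = sp[, 2],
                        nucleus_row = np[, 1], nucleus_col = np[, 2],
                        yap_ratio_true = ratios, k14_class_true = k14_class,
                        stringsAsFactors = FALSE)
    list(image = img,
         truth = list(cells = cells, mask = mask, cell_labels = cell_labels,
                      nucleus_labels = nucleus_labels,
                      n_rim = sum(layer == "outer"), spec = spec))
  })
}

# hexagonal packing of points within a disk of given radius (um)
hex_seeds <- function(max_radius, spacing) {
  if (max_radius <= 0) return(matrix(numeric(0), 0, 2))
  dy <- spacing * sqrt(3) / 2
  rows <- seq(-max_radius, max_radius, by = dy)
  pts <- do.call(rbind, lapply(seq_along(rows), function(i) {
    xoff <- ifelse(i %% 2 == 0, spacing / 2, 0)
    xs <- seq(-max_radius - xoff, max_radius, by = spacing) + xoff
    cbind(xs, rows[i])
  }))
  pts <- pts[sqrt(rowSums(pts^2)) <= max_radius, , drop = FALSE]
  if (nrow(pts) == 0) pts <- matrix(c(0, 0), 1, 2)
  colnames(pts) <- c("x", "y")
  pts
}
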