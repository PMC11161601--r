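#' Specification of a synthetic bead time-lapse
#'
#' Beads embedded in the matrix around an organoid are advected radially
#' toward its center at constant speed while the whole field of view
#' drifts by a fixed (row, col) offset per frame — emulating matrix
#' pulling observed by time-lapse confocal imaging of fluorescent
#' microspheres with stage drift. Defaults reflect a 10-frame excerpt at a
#' scale where bead motion is a few pixels per frame.
#'
#' @param n_beads number of beads.
#' @param radial_speed_um_per_frame inward radial advection per frame (um).
#' @param drift_per_frame numeric length-2, global (row, col) drift per
#'   frame in px.
#' @param n_frames number of frames (>= 2).
#' @param organoid_center 0-based (row, col) px of the organoid center;
#'   \code{NULL} = frame center.
#' @param organoid_radius_um organoid body radius (um).
#' @param frame_px image size c(rows, cols).
#' @param pixel_size_um pixel size (um/px).
#' @param bead_sigma_px Gaussian radius of a rendered bead spot.
#' @param min_separation_px minimum initial distance between beads
#'   (positions are resampled until satisfied), so spots are resolvable.
#' @param background_level,noise_sd rendering background and noise.
#' @param render_organoid draw the organoid disk (dim, drifting with the
#'   field) so frames carry a large registration feature.
#' @param seed RNG seed.
#' @return a \code{synthetic_bead_spec} list.
#' @export
synthetic_bead_spec <- function(n_beads = 20,
                                radial_speed_um_per_frame = 2,
                                drift_per_frame = c(0, 0),
                                n_frames = 10,
                                organoid_center = NULL,
                                organoid_radius_um = 30,
                                frame_px = c(256, 256),
                                pixel_size_um = 0.5,
                                bead_sigma_px = 1.3,
                                min_separation_px = 8,
                                background_level = 8,
                                noise_sd = 1,
                                render_organoid = TRUE,
                                seed = 1) {
  stopifnot(n_frames >= 2, n_beads >= 1, length(drift_per_frame) == 2,
            pixel_size_um > 0, organoid_radius_um > 0, noise_sd >= 0)
  structure(as.list(environment()), class = "synthetic_bead_spec")
}

#' Render a synthetic bead time-lapse with known trajectories and drift
#'
#' Beads start outside the organoid at uniformly random angles and radii
#' and move radially inward at \code{radial_speed_um_per_frame}; the
#' rendered (drifted) position of bead \eqn{i} in frame \eqn{t} is its
#' drift-free position plus the cumulative drift \eqn{t \cdot d}. Truth
#' stores both trajectories, the per-frame cumulative drift, and flags for
#' beads that leave the frame (they are rendered truncated, never
#' silently dropped).
#'
#' @param spec a [synthetic_bead_spec()].
#' @return list with \code{frames} (list of matrices), \code{truth}
#'   (arrays \code{pos_drifted}, \code{pos_free} of dim n_beads x n_frames
#'   x 2 in 0-based (row, col) px; \code{cum_drift}; \code{left_frame}
#'   flags; organoid geometry; the spec) and \code{pixel_size_um}.
#' @export
gen_bead_timelapse <- function(spec) {
  stopifnot(inherits(spec, "synthetic_bead_spec"))
  with_seed(spec$seed, {
    px <- spec$pixel_size_um
    dims <- spec$frame_px
    ctr <- if (is.null(spec$organoid_center)) (dims - 1) / 2
           else spec$organoid_center
    R_px <- spec$organoid_radius_um / px
    speed_px <- spec$radial_speed_um_per_frame / px
    nT <- spec$n_frames
    max_r <- min(dims) / 2 - 6
    # beads are advected toward the body but must stay in the matrix:
    # start far enough out that the final radius is still outside
    r_min <- R_px + speed_px * (nT - 1) + 6
    r0 <- runif(spec$n_beads, r_min, max(r_min + 2, max_r))
    ang <- runif(spec$n_beads, 0, 2 * pi)
    # resample crowded beads so initial spots are resolvable
    for (it in seq_len(200)) {
      p0 <- cbind(ctr[1] - r0 * sin(ang), ctr[2] + r0 * cos(ang))
      pd <- as.matrix(stats::dist(p0))
      diag(pd) <- Inf
      bad <- which(apply(pd, 1, min) < spec$min_separation_px)
      if (length(bad) == 0) break
      r0[bad] <- runif(length(bad), r_min, max(r_min + 2, max_r))
      ang[bad] <- runif(length(bad), 0, 2 * pi)
    }
    pos_free <- array(NA_real_, c(spec$n_beads, nT, 2))
    for (t in seq_len(nT)) {
      rt <- pmax(r0 - speed_px * (t - 1), 1)
      pos_free[, t, 1] <- ctr[1] - rt * sin(ang)
      pos_free[, t, 2] <- ctr[2] + rt * cos(ang)
    }
    cum_drift <- outer(0:(nT - 1), spec$drift_per_frame)
    pos_drifted <- pos_free
    for (t in seq_len(nT)) {
      pos_drifted[, t, 1] <- pos_free[, t, 1] + cum_drift[t, 1]
      pos_drifted[, t, 2] <- pos_free[, t, 2] + cum_drift[t, 2]
    }
    left_frame <- apply(pos_drifted, 1, function(p)
      any(p[, 1] < 2 | p[, 1] > dims[1] - 3 | p[, 2] < 2 | p[, 2] > dims[2] - 3))

    g <- expand.grid(row = seq_len(dims[1]), col = seq_len(dims[2]))
    frames <- lapply(seq_len(nT), function(t) {
      f <- matrix(spec$background_level, dims[1], dims[2])
      if (spec$render_organoid) {
        oc <- ctr + cum_drift[t, ]
        d <- sqrt((g$row - 1 - oc[1])^2 + (g$col - 1 - oc[2])^2)
        f <- f + matrix(30 * (d <= R_px), dims[1], dims[2])
      }
      for (i in seq_len(spec$n_beads)) {
        p <- pos_drifted[i, t, ]
        r0i <- max(1, floor(p[1] - 4 * spec$bead_sigma_px) + 1)
        r1i <- min(dims[1], ceiling(p[1] + 4 * spec$bead_sigma_px) + 1)
        c0i <- max(1, floor(p[2] - 4 * spec$bead_sigma_px) + 1)
        c1i <- min(dims[2], ceiling(p[2] + 4 * spec$bead_sigma_px) + 1)
        if (r0i > r1i || c0i > c1i) next
        rr <- r0i:r1i; cc <- c0i:c1i
        d2 <- outer((rr - 1 - p[1])^2, (cc - 1 - p[2])^2, "+")
        f[rr, cc] <- f[rr, cc] + 180 * exp(-d2 / (2 * spec$bead_sigma_px^2))
      }
      add_noise(f, spec$noise_sd)
    })
    list(frames = frames,
         truth = list(pos_drifted = pos_drifted, pos_free = pos_free,
                      cum_drift = cum_drift, left_frame = left_frame,
                      organoid_center = ctr, organoid_radius_px = R_px,
                      spec = spec),
         pixel_size_um = px)
  })
}
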