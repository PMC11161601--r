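#' Estimate global xy drift of a time-lapse by phase correlation
#'
#' Registers consecutive frames by translation: the cross-power spectrum
#' of Hann-windowed frame pairs is inverted and the correlation peak
#' located with subpixel parabolic refinement; per-pair shifts are
#' accumulated against the reference frame (frame 1, offset (0, 0)).
#' Nearly featureless stacks yield zero offsets with a warning.
#'
#' @param frames list of numeric matrices (one per time point).
#' @return a \code{drift_model}: list with \code{offsets} (n_frames x 2,
#'   cumulative (row, col) displacement of each frame relative to frame 1)
#'   and \code{reference = 1}. Subtracting \code{offsets[t, ]} from a
#'   position observed in frame t moves it into reference coordinates.
#' @export
estimate_drift <- function(frames) {
  stopifnot(is.list(frames), length(frames) >= 2)
  nT <- length(frames)
  offsets <- matrix(0, nT, 2)
  if (all(vapply(frames, sd, numeric(1)) < 1e-12)) {
    warning("featureless stack; assuming zero drift")
    return(structure(list(offsets = offsets, reference = 1L),
                     class = "drift_model"))
  }
  for (t in 2:nT) {
    offsets[t, ] <- offsets[t - 1, ] +
      phase_correlate(frames[[t - 1]], frames[[t]])
  }
  structure(list(offsets = offsets, reference = 1L), class = "drift_model")
}

# translation of b relative to a (b ~ a shifted by +shift), subpixel
phase_correlate <- function(a, b) {
  nr <- nrow(a); nc <- ncol(a)
  han <- outer(0.5 - 0.5 * cos(2 * pi * (0:(nr - 1)) / (nr - 1)),
               0.5 - 0.5 * cos(2 * pi * (0:(nc - 1)) / (nc - 1)))
  fa <- fft((a - mean(a)) * han)
  fb <- fft((b - mean(b)) * han)
  cp <- fa * Conj(fb)
  denom <- Mod(cp)
  cp <- cp / pmax(denom, max(denom) * 1e-12)
  corr <- Re(fft(cp, inverse = TRUE)) / length(cp)
  pk <- which(corr == max(corr), arr.ind = TRUE)[1, ]
  # subpixel: parabola through the peak and wrap-around neighbors
  sub <- function(i, n, along) {
    im <- ((i - 2) %% n) + 1
    ip <- (i %% n) + 1
    if (along == 1) { ym <- corr[im, pk[2]]; y0 <- corr[i, pk[2]]; yp <- corr[ip, pk[2]] }
    else { ym <- corr[pk[1], im]; y0 <- corr[pk[1], i]; yp <- corr[pk[1], ip] }
    den <- ym - 2 * y0 + yp
    if (abs(den) < 1e-300) 0 else 0.5 * (ym - yp) / den
  }
  shift <- c(pk[1] - 1 + sub(pk[1], nr, 1), pk[2] - 1 + sub(pk[2], nc, 2))
  shift[1] <- ifelse(shift[1] > nr / 2, shift[1] - nr, shift[1])
  shift[2] <- ifelse(shift[2] > nc / 2, shift[2] - nc, shift[2])
  # corr peak at +s means a(x) ~ b(x + s): b is a shifted by -s
  -shift
}

#' Detect bead spots in one frame
#'
#' Gaussian-smoothed local maxima above an adaptive (Otsu) threshold,
#' refined to subpixel by an intensity-weighted centroid over a 5 x 5
#' neighborhood. Connected foreground larger than \code{max_spot_area}
#' (e.g. the organoid body) is excluded before peak picking.
#'
#' @param frame numeric matrix.
#' @param smooth_sigma_px pre-smoothing (px).
#' @param max_spot_area foreground components above this area (px^2) are
#'   not beads.
#' @return m x 2 matrix of 0-based subpixel (row, col) positions.
#' @export
detect_spots <- function(frame, smooth_sigma_px = 1, max_spot_area = 400) {
  sm <- gauss_smooth(frame, smooth_sigma_px)
  rng <- range(sm)
  if (diff(rng) <= 0) return(matrix(numeric(0), 0, 2))
  norm <- (sm - rng[1]) / diff(rng)
  fg <- norm > EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  lab <- EBImage::bwlabel(fg * 1)
  if (max(lab) > 0) {
    sizes <- tabulate(as.integer(lab[lab > 0]))
    big <- which(sizes > max_spot_area)
    if (length(big)) fg[matrix(as.integer(lab) %in% big, nrow(fg))] <- FALSE
  }
  if (!any(fg)) return(matrix(numeric(0), 0, 2))
  nr <- nrow(sm); nc <- ncol(sm)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- sm
  ismax <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ismax <- ismax & sm >= pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  peaks <- which(ismax & fg, arr.ind = TRUE)
  if (nrow(peaks) == 0) return(matrix(numeric(0), 0, 2))
  t(apply(peaks, 1, function(p) {
    rr <- max(1, p[1] - 2):min(nr, p[1] + 2)
    cc <- max(1, p[2] - 2):min(nc, p[2] + 2)
    wts <- pmax(sm[rr, cc] - rng[1], 0)
    s <- sum(wts)
    c(sum(outer(rr, rep(1, length(cc))) * wts) / s - 1,
      sum(outer(rep(1, length(rr)), cc) * wts) / s - 1)
  }))
}

#' Detect beads in every frame and link them into tracks
#'
#' Spots are detected per frame, moved into drift-corrected coordinates,
#' and linked between consecutive frames by a minimum-cost assignment
#' (Hungarian algorithm) on predicted positions: each open track predicts
#' its next position by constant-velocity extrapolation, candidate links
#' farther than \code{max_step_px} are forbidden, and the global
#' assignment resolves close encounters that defeat independent
#' nearest-neighbor linking (e.g. chains of beads advected along one ray).
#' Tracks not present in every frame are kept but flagged
#' \code{complete = FALSE} (and are never eligible for displacement
#' measurement).
#'
#' @param frames list of matrices (the time-lapse).
#' @param drift a \code{drift_model} from [estimate_drift()]; \code{NULL}
#'   means no correction.
#' @param max_step_px maximum per-frame step in corrected coordinates.
#' @param ... passed to [detect_spots()].
#' @return data.frame of class \code{bead_tracks}: columns \code{bead},
#'   \code{frame}, \code{row}, \code{col} (as imaged),
#'   \code{corrected_row}, \code{corrected_col}; attribute \code{complete}
#'   is a named logical per bead.
#' @export
detect_and_link <- function(frames, drift = NULL, max_step_px = 10, ...) {
  nT <- length(frames)
  if (is.null(drift))
    drift <- structure(list(offsets = matrix(0, nT, 2), reference = 1L),
                       class = "drift_model")
  dets <- lapply(seq_len(nT), function(t) {
    d <- detect_spots(frames[[t]], ...)
    if (nrow(d) == 0) return(cbind(d, d))
    cbind(d, d[, 1] - drift$offsets[t, 1], d[, 2] - drift$offsets[t, 2])
  })
  next_id <- 0L
  rows <- list()
  # open tracks: position, velocity and last frame, in corrected coords
  open <- data.frame(bead = integer(), r = numeric(), c = numeric(),
                     vr = numeric(), vc = numeric(), last_frame = integer())
  for (t in seq_len(nT)) {
    d <- dets[[t]]
    m <- nrow(d)
    assigned <- rep(NA_integer_, m)
    active <- which(open$last_frame == t - 1)
    if (m > 0 && length(active) > 0) {
      pr <- open$r[active] + open$vr[active]
      pc <- open$c[active] + open$vc[active]
      dm <- sqrt(outer(pr, d[, 3], "-")^2 + outer(pc, d[, 4], "-")^2)
      dm[dm > max_step_px] <- Inf
      sol <- solve_assignment(dm)
      for (k in seq_along(active))
        if (!is.na(sol[k])) assigned[sol[k]] <- active[k]
    }
    for (j in seq_len(m)) {
      if (!is.na(assigned[j])) {
        i <- assigned[j]
        bead <- open$bead[i]
        open$vr[i] <- d[j, 3] - open$r[i]
        open$vc[i] <- d[j, 4] - open$c[i]
        open$r[i] <- d[j, 3]; open$c[i] <- d[j, 4]; open$last_frame[i] <- t
      } else {
        next_id <- next_id + 1L
        bead <- next_id
        open <- rbind(open, data.frame(bead = bead, r = d[j, 3], c = d[j, 4],
                                       vr = 0, vc = 0, last_frame = t))
      }
      rows[[length(rows) + 1]] <- data.frame(
        bead = bead, frame = t, row = d[j, 1], col = d[j, 2],
        corrected_row = d[j, 3], corrected_col = d[j, 4])
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(bead = integer(), frame = integer(), row = numeric(),
                         col = numeric(), corrected_row = numeric(),
                         corrected_col = numeric())
  complete <- vapply(split(out$frame, out$bead),
                     function(f) length(unique(f)) == nT, logical(1))
  attr(out, "complete") <- complete
  attr(out, "n_frames") <- nT
  class(out) <- c("bead_tracks", "data.frame")
  out
}

#' Apply the bead selection and exclusion rules
#'
#' A bead is included when (i) it is trackable through the whole
#' time-lapse, (ii) its initial distance to the organoid border does not
#' exceed the selection distance — the organoid's diameter or radius,
#' depending on \code{mode} — and (iii) it is not within the selection
#' distance of two organoids at once (beads caught between neighboring
#' organoids are excluded).
#'
#' @param tracks a \code{bead_tracks} data.frame.
#' @param organoids one \code{organoid_mask} or a list (geometry at t = 0).
#' @param mode \code{"diameter"} or \code{"radius"}.
#' @param pixel_size_um pixel size (um/px).
#' @param manual optional data.frame (\code{bead}, \code{included})
#'   overriding the geometric rule per bead.
#' @return data.frame with one row per bead: \code{bead}, \code{complete},
#'   \code{initial_distance_um} (to the nearest border), \code{n_near},
#'   \code{included}.
#' @export
select_beads <- function(tracks, organoids, mode = c("diameter", "radius"),
                         pixel_size_um, manual = NULL) {
  mode <- match.arg(mode)
  if (inherits(organoids, "organoid_mask")) organoids <- list(organoids)
  complete <- attr(tracks, "complete")
  beads <- as.integer(names(complete))
  first <- do.call(rbind, lapply(split(tracks, tracks$bead), function(s) {
    s <- s[order(s$frame), ]
    data.frame(bead = s$bead[1], r = s$corrected_row[1], c = s$corrected_col[1])
  }))
  first <- first[match(beads, first$bead), ]
  dists <- sapply(organoids, function(o) {
    lim_um <- switch(mode, diameter = 2 * o$equiv_radius_um,
                     radius = o$equiv_radius_um)
    d_um <- dist_to_polyline(cbind(first$r, first$c), o$contour) * pixel_size_um
    cbind(d_um, d_um <= lim_um)
  }, simplify = FALSE)
  d_mat <- vapply(dists, function(x) x[, 1], numeric(nrow(first)))
  near <- vapply(dists, function(x) x[, 2], numeric(nrow(first)))
  d_mat <- matrix(d_mat, nrow = nrow(first))
  near <- matrix(near, nrow = nrow(first))
  n_near <- rowSums(near)
  out <- data.frame(bead = beads, complete = unname(complete),
                    initial_distance_um = apply(d_mat, 1, min),
                    n_near = n_near,
                    included = unname(complete) & n_near == 1)
  if (!is.null(manual)) {
    i <- match(out$bead, manual$bead)
    override <- !is.na(i)
    out$included[override] <- manual$included[i[override]]
  }
  out
}

#' Net bead displacement toward the organoid body
#'
#' The change in distance to the organoid border between the first and
#' last frame, in drift-corrected coordinates:
#' \code{d(first) - d(last)} in um, positive when the bead moved toward
#' the organoid. With \code{path = TRUE} the per-interval distance changes
#' are summed instead (path-integrated inward motion).
#'
#' @param tracks a \code{bead_tracks} data.frame.
#' @param organoid the \code{organoid_mask} the displacement refers to.
#' @param pixel_size_um pixel size (um/px).
#' @param beads bead ids to measure (default: all).
#' @param path logical; path-integrated variant.
#' @return named numeric vector of displacements (um) per bead.
#' @export
displacement_toward_organoid <- function(tracks, organoid, pixel_size_um,
                                         beads = NULL, path = FALSE) {
  stopifnot(inherits(organoid, "organoid_mask"))
  if (is.null(beads)) beads <- unique(tracks$bead)
  vapply(setNames(beads, beads), function(b) {
    s <- tracks[tracks$bead == b, ]
    s <- s[order(s$frame), ]
    d <- dist_to_polyline(cbind(s$corrected_row, s$corrected_col),
                          organoid$contour) * pixel_size_um
    if (path) -sum(diff(d)) else d[1] - d[length(d)]
  }, numeric(1))
}

#' Run the full bead-displacement analysis on a time-lapse
#'
#' Drift estimation, detection and linking, selection, and displacement
#' toward the nearest organoid, returning per-bead results and a summary.
#'
#' @param frames list of matrices.
#' @param organoids one \code{organoid_mask} or a list.
#' @param pixel_size_um pixel size (um/px).
#' @param mode selection mode, \code{"diameter"} or \code{"radius"}.
#' @param drift_correct logical; estimate and remove global drift.
#' @param ... passed to [detect_and_link()].
#' @return list with \code{tracks}, \code{drift}, \code{selection} (with a
#'   \code{displacement_um} column, NA for excluded beads) and
#'   \code{summary} (mean and SD over included beads).
#' @export
analyze_bead_displacement <- function(frames, organoids, pixel_size_um,
                                      mode = "diameter",
                                      drift_correct = TRUE, ...) {
  drift <- if (drift_correct) estimate_drift(frames) else NULL
  tracks <- detect_and_link(frames, drift, ...)
  if (inherits(organoids, "organoid_mask")) organoids <- list(organoids)
  sel <- select_beads(tracks, organoids, mode, pixel_size_um)
  sel$displacement_um <- NA_real_
  inc <- sel$bead[sel$included]
  if (length(inc) > 0) {
    # displacement is measured against the nearest organoid's border
    first <- tracks[tracks$frame == 1, ]
    disp <- vapply(inc, function(b) {
      p <- first[first$bead == b, c("corrected_row", "corrected_col")]
      dists <- vapply(organoids, function(o)
        dist_to_polyline(as.matrix(p), o$contour), numeric(1))
      displacement_toward_organoid(tracks, organoids[[which.min(dists)]],
                                   pixel_size_um, beads = b)
    }, numeric(1))
    sel$displacement_um[match(inc, sel$bead)] <- disp
  }
  list(tracks = tracks, drift = drift, selection = sel,
       summary = data.frame(
         n_included = length(inc),
         mean_displacement_um = mean(sel$displacement_um, na.rm = TRUE),
         sd_displacement_um = sd(sel$displacement_um, na.rm = TRUE)))
}
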