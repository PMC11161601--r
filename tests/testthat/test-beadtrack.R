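# Drift estimation, detection/linking, selection rules and displacement.

test_that("phase correlation recovers synthetic per-frame drift", {
  sp <- synthetic_bead_spec(n_beads = 20, radial_speed_um_per_frame = 2,
                            drift_per_frame = c(3, -2), n_frames = 10,
                            seed = 5)
  g <- gen_bead_timelapse(sp)
  dm <- estimate_drift(g$frames)
  err <- abs(dm$offsets - g$truth$cum_drift)
  expect_lt(max(err), 0.5)
  expect_identical(dm$offsets[1, ], c(0, 0))
})

test_that("a static stack gives zero offsets; correction is idempotent", {
  sp <- synthetic_bead_spec(n_beads = 15, radial_speed_um_per_frame = 0,
                            drift_per_frame = c(0, 0), n_frames = 6,
                            noise_sd = 0, seed = 7)
  g <- gen_bead_timelapse(sp)
  dm <- estimate_drift(g$frames)
  expect_lt(max(abs(dm$offsets)), 0.1)
  # apply an estimated integer correction, re-estimate: offsets near zero
  spd <- synthetic_bead_spec(n_beads = 15, radial_speed_um_per_frame = 0,
                             drift_per_frame = c(2, 1), n_frames = 6,
                             noise_sd = 0, seed = 7)
  gd <- gen_bead_timelapse(spd)
  dmd <- estimate_drift(gd$frames)
  shifted <- lapply(seq_along(gd$frames), function(t) {
    off <- round(dmd$offsets[t, ])
    f <- gd$frames[[t]]
    out <- matrix(median(f), nrow(f), ncol(f))
    src_r <- seq_len(nrow(f)) + off[1]
    src_c <- seq_len(ncol(f)) + off[2]
    okr <- src_r >= 1 & src_r <= nrow(f)
    okc <- src_c >= 1 & src_c <= ncol(f)
    out[which(okr), which(okc)] <- f[src_r[okr], src_c[okc]]
    out
  })
  dm2 <- estimate_drift(shifted)
  expect_lt(max(abs(dm2$offsets)), 0.5)
})

test_that("a featureless stack warns and returns zero drift", {
  frames <- replicate(4, matrix(3, 64, 64), simplify = FALSE)
  expect_warning(dm <- estimate_drift(frames), "featureless")
  expect_true(all(dm$offsets == 0))
})

test_that("all beads are tracked completely with subpixel accuracy", {
  sp <- synthetic_bead_spec(n_beads = 20, radial_speed_um_per_frame = 2,
                            drift_per_frame = c(3, -2), n_frames = 10,
                            seed = 5)
  g <- gen_bead_timelapse(sp)
  tr <- detect_and_link(g$frames, estimate_drift(g$frames))
  comp <- attr(tr, "complete")
  expect_identical(sum(comp), 20L)
  # RMSE of raw (uncorrected) positions against the drifted truth
  f1 <- tr[tr$frame == 1, ]
  errs <- unlist(lapply(seq_len(nrow(f1)), function(i) {
    tb <- which.min((g$truth$pos_drifted[, 1, 1] - f1$row[i])^2 +
                    (g$truth$pos_drifted[, 1, 2] - f1$col[i])^2)
    s <- tr[tr$bead == f1$bead[i], ]
    s <- s[order(s$frame), ]
    if (nrow(s) < 10) return(NULL)
    (s$row - g$truth$pos_drifted[tb, , 1])^2 +
      (s$col - g$truth$pos_drifted[tb, , 2])^2
  }))
  expect_lt(sqrt(mean(errs)), 0.5)
})

test_that("a bead blinking off for one frame yields an incomplete track", {
  sp <- synthetic_bead_spec(n_beads = 6, radial_speed_um_per_frame = 1,
                            n_frames = 6, seed = 9)
  g <- gen_bead_timelapse(sp)
  # erase one bead from frame 3 by painting background over it
  p <- g$truth$pos_drifted[1, 3, ]
  f3 <- g$frames[[3]]
  rr <- max(1, round(p[1]) - 5):min(nrow(f3), round(p[1]) + 7)
  cc <- max(1, round(p[2]) - 5):min(ncol(f3), round(p[2]) + 7)
  f3[rr, cc] <- 8
  g$frames[[3]] <- f3
  tr <- detect_and_link(g$frames, NULL)
  comp <- attr(tr, "complete")
  expect_identical(sum(!comp), 2L)  # the pre- and post-blink fragments
  expect_identical(sum(comp), 5L)
})

test_that("selection applies the distance and two-organoid exclusion rules", {
  org1 <- disk_mask(20, pixel_size_um = 1, dims = c(300, 300))  # r = 20 um
  # fake minimal tracks: three beads at controlled distances from border
  mk_tracks <- function(pos) {
    df <- do.call(rbind, lapply(seq_along(pos), function(i)
      data.frame(bead = i, frame = 1:2, row = pos[[i]][1],
                 col = pos[[i]][2], corrected_row = pos[[i]][1],
                 corrected_col = pos[[i]][2])))
    attr(df, "complete") <- setNames(rep(TRUE, length(pos)),
                                     seq_along(pos))
    attr(df, "n_frames") <- 2L
    class(df) <- c("bead_tracks", "data.frame")
    df
  }
  ctr <- org1$centroid
  tracks <- mk_tracks(list(
    ctr + c(0, 20 + 60),    # 1.5x diameter from border -> excluded
    ctr + c(0, 20 + 16),    # 0.4x diameter -> included either way
    ctr + c(0, 20 + 38)))   # just inside diameter -> included
  sel <- select_beads(tracks, org1, mode = "diameter", pixel_size_um = 1)
  expect_identical(sel$included, c(FALSE, TRUE, TRUE))
  # radius mode is stricter: only the closest bead stays
  sel_r <- select_beads(tracks, org1, mode = "radius", pixel_size_um = 1)
  expect_identical(sel_r$included, c(FALSE, TRUE, FALSE))

  # a bead between two close organoids is excluded even when near both
  m2 <- matrix(FALSE, 300, 300)
  g <- expand.grid(r = 1:300, c = 1:300)
  m2[matrix(sqrt((g$r - 150)^2 + (g$c - 220)^2) <= 20, 300, 300)] <- TRUE
  org2 <- mechanoquant:::new_organoid_mask(m2, 1)
  tracks2 <- mk_tracks(list(ctr + c(0, 35)))  # between the two organoids
  sel2 <- select_beads(tracks2, list(org1, org2), mode = "diameter",
                       pixel_size_um = 1)
  expect_identical(sel2$n_near, 2)
  expect_false(sel2$included)
  # incomplete tracks are never included
  attr(tracks2, "complete")[] <- FALSE
  sel3 <- select_beads(tracks2, org1, mode = "diameter", pixel_size_um = 1)
  expect_false(sel3$included)
  # manual override wins
  sel4 <- select_beads(tracks2, org1, mode = "diameter", pixel_size_um = 1,
                       manual = data.frame(bead = 1, included = TRUE))
  expect_true(sel4$included)
})

test_that("displacement is the change in border distance, toward positive", {
  org <- disk_mask(20, pixel_size_um = 1, dims = c(300, 300))
  ctr <- org$centroid
  mk <- function(rows, cols) {
    df <- data.frame(bead = 1, frame = seq_along(rows), row = rows,
                     col = cols, corrected_row = rows, corrected_col = cols)
    attr(df, "complete") <- c("1" = TRUE)
    class(df) <- c("bead_tracks", "data.frame")
    df
  }
  # radial approach from 50 um to 30 um from the center: 30 -> 10 from border
  tr <- mk(rep(ctr[1], 5), ctr[2] + seq(50, 30, length.out = 5))
  d <- displacement_toward_organoid(tr, org, pixel_size_um = 1)
  expect_equal(unname(d), 20, tolerance = 0.3)
  # purely tangential motion: zero net displacement
  ang <- seq(0, 2 * pi / 3, length.out = 8)
  tr_t <- mk(ctr[1] + 45 * sin(ang), ctr[2] + 45 * cos(ang))
  d_t <- displacement_toward_organoid(tr_t, org, pixel_size_um = 1)
  expect_lt(abs(unname(d_t)), 0.5)
  # path-integrated variant agrees for monotone approach
  d_p <- displacement_toward_organoid(tr, org, pixel_size_um = 1,
                                      path = TRUE)
  expect_equal(unname(d_p), unname(d), tolerance = 1e-9)
})

test_that("the 20 um radial case is recovered with and without drift", {
  om <- disk_mask(30, pixel_size_um = 0.5)
  means <- vapply(list(c(0, 0), c(3, -2)), function(dr) {
    sp <- synthetic_bead_spec(n_beads = 20, radial_speed_um_per_frame = 2,
                              drift_per_frame = dr, n_frames = 11, seed = 5)
    g <- gen_bead_timelapse(sp)
    res <- analyze_bead_displacement(g$frames, om, 0.5, mode = "diameter")
    expect_identical(res$summary$n_included, 20L)
    res$summary$mean_displacement_um
  }, numeric(1))
  expect_equal(means[1], 20, tolerance = 1)
  expect_equal(means[2], 20, tolerance = 1)
  # drift invariance of per-bead displacement
  expect_lt(abs(means[1] - means[2]), 1)
})

test_that("selection is deterministic and order-independent", {
  om <- disk_mask(30, pixel_size_um = 0.5)
  sp <- synthetic_bead_spec(n_beads = 12, radial_speed_um_per_frame = 1,
                            n_frames = 6, seed = 31)
  g <- gen_bead_timelapse(sp)
  tr <- detect_and_link(g$frames, NULL)
  s1 <- select_beads(tr, om, mode = "diameter", pixel_size_um = 0.5)
  s2 <- select_beads(tr, om, mode = "diameter", pixel_size_um = 0.5)
  expect_identical(s1, s2)
  # shuffling track rows does not change the outcome
  trs <- tr[sample(nrow(tr)), ]
  attributes(trs)$complete <- attr(tr, "complete")
  class(trs) <- class(tr)
  s3 <- select_beads(trs, om, mode = "diameter", pixel_size_um = 0.5)
  expect_identical(s3[order(s3$bead), ], s1[order(s1$bead), ])
})
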