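# Generators: determinism, exact ground truth, and analytic limits.

test_that("organoid generator is deterministic and renders exact ratios", {
  spec <- synthetic_organoid_spec(noise_sd = 0, seed = 5,
                                  yap_ratio_by_role = c(rim = 2, inner = 2,
                                                        leader = 2))
  g1 <- gen_organoid_image(spec)
  g2 <- gen_organoid_image(spec)
  expect_identical(g1$image$channels, g2$image$channels)
  expect_identical(g1$truth$cells, g2$truth$cells)

  # noise-free rendering: per-cell background-subtracted nuc/cyto ratio
  # equals the specified value exactly
  yap <- get_channel(g1$image, "Yap")
  bg <- spec$background_level
  for (i in g1$truth$cells$cell) {
    nucpx <- g1$truth$nucleus_labels == i
    cytpx <- g1$truth$cell_labels == i & !nucpx
    ratio <- (mean(yap[nucpx]) - bg) / (mean(yap[cytpx]) - bg)
    expect_equal(ratio, 2.0, tolerance = 1e-12)
  }
})

test_that("ground truth lists exactly the requested number of rim cells", {
  g <- gen_organoid_image(synthetic_organoid_spec(n_rim_cells = 12, seed = 2))
  expect_identical(sum(g$truth$cells$layer == "outer"), 12L)
  expect_identical(g$truth$n_rim, 12L)
  # each truth cell has exactly one nucleus blob
  for (i in g$truth$cells$cell)
    expect_gt(sum(g$truth$nucleus_labels == i), 0)
})

test_that("an organoid larger than the frame is rejected", {
  expect_error(gen_organoid_image(
    synthetic_organoid_spec(organoid_radius_um = 40, frame_um = 60)),
    "fit")
})

test_that("generated images carry pixel-size metadata", {
  g <- gen_organoid_image(synthetic_organoid_spec(seed = 3))
  expect_identical(g$image$pixel_size_um, 0.5)
  f <- gen_fiber_field(synthetic_fiber_spec(seed = 3, n_fibers = 50))
  expect_identical(f$image$pixel_size_um, 0.5)
})

test_that("fiber-angle samples follow the von Mises order-parameter law", {
  # kappa = 0: uniform limit
  g0 <- gen_fiber_field(synthetic_fiber_spec(kappa = 0, n_fibers = 4000,
                                             frame_um = 100, seed = 9))
  expect_lt(order_parameter(g0$truth$angles_deg)$S, 3 / sqrt(4000))
  # very large kappa: delta limit at mu
  gd <- gen_fiber_field(synthetic_fiber_spec(mu_deg = 25, kappa = 1e6,
                                             n_fibers = 500, frame_um = 100,
                                             seed = 9))
  expect_lt(max(abs(gd$truth$angles_deg - 25)), 0.2)
  expect_gt(order_parameter(gd$truth$angles_deg)$S, 0.9999)
  # intermediate: sample S near the Bessel ratio I1(2)/I0(2)
  g2 <- gen_fiber_field(synthetic_fiber_spec(kappa = 2, n_fibers = 5000,
                                             frame_um = 150, seed = 9))
  expect_equal(order_parameter(g2$truth$angles_deg)$S, vm_order_parameter(2),
               tolerance = 0.03)
  expect_error(synthetic_fiber_spec(kappa = -1), "kappa")
})

test_that("stamped pixels record the stamping fiber's angle", {
  g <- gen_fiber_field(synthetic_fiber_spec(kappa = 3, n_fibers = 40,
                                            frame_um = 80, seed = 4))
  on_fiber <- !is.na(g$truth$angle_map)
  expect_identical(unname(on_fiber), unname(g$truth$fiber_mask))
  expect_true(all(g$truth$angle_map[on_fiber] %in% g$truth$angles_deg))
})

test_that("bead truth obeys the advection + drift construction exactly", {
  sp <- synthetic_bead_spec(n_beads = 8, radial_speed_um_per_frame = 2,
                            drift_per_frame = c(3, -2), n_frames = 10,
                            seed = 6)
  g <- gen_bead_timelapse(sp)
  # drifted = free + cumulative drift, identically
  for (t in 1:10) {
    expect_equal(g$truth$pos_drifted[, t, 1],
                 g$truth$pos_free[, t, 1] + g$truth$cum_drift[t, 1])
    expect_equal(g$truth$pos_drifted[, t, 2],
                 g$truth$pos_free[, t, 2] + g$truth$cum_drift[t, 2])
  }
  # radial speed 2 um/frame over 10 frames: 9 intervals of 4 px at 0.5 um/px
  ctr <- g$truth$organoid_center
  r1 <- sqrt((g$truth$pos_free[, 1, 1] - ctr[1])^2 +
             (g$truth$pos_free[, 1, 2] - ctr[2])^2)
  r10 <- sqrt((g$truth$pos_free[, 10, 1] - ctr[1])^2 +
              (g$truth$pos_free[, 10, 2] - ctr[2])^2)
  expect_equal((r1 - r10) * sp$pixel_size_um, rep(18, 8), tolerance = 1e-9)

  # zero speed: drift-free positions constant
  sp0 <- synthetic_bead_spec(n_beads = 5, radial_speed_um_per_frame = 0,
                             drift_per_frame = c(3, -2), n_frames = 6,
                             seed = 6)
  g0 <- gen_bead_timelapse(sp0)
  for (t in 2:6)
    expect_equal(g0$truth$pos_free[, t, ], g0$truth$pos_free[, 1, ])
  expect_error(synthetic_bead_spec(n_frames = 1), "n_frames")
})

test_that("beads leaving the frame are flagged, not dropped", {
  sp <- synthetic_bead_spec(n_beads = 10, radial_speed_um_per_frame = 0,
                            drift_per_frame = c(30, 0), n_frames = 8,
                            seed = 8)
  g <- gen_bead_timelapse(sp)
  expect_identical(length(g$truth$left_frame), 10L)
  expect_true(any(g$truth$left_frame))
  expect_identical(dim(g$truth$pos_drifted), c(10L, 8L, 2L))
})

test_that("border-mask truth matches an independent polygon oracle", {
  # shoelace-style oracle: arc length of the polar curve by very fine
  # independent sampling
  oracle_ratio <- function(n, depth, R) {
    phi <- seq(0, 2 * pi, length.out = 20001)
    r <- R - depth / 2 + (depth / 2) * cos(n * phi)
    x <- r * cos(phi); y <- r * sin(phi)
    per <- sum(sqrt(diff(x)^2 + diff(y)^2))
    h <- grDevices::chull(x, y)
    hx <- x[h]; hy <- y[h]
    hull <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
    per / hull
  }
  b0 <- gen_border_mask(0, 0, 100)
  expect_equal(b0$truth$protrusive_index_true, 1, tolerance = 1e-6)
  b8 <- gen_border_mask(8, 20, 100)
  expect_gt(b8$truth$protrusive_index_true, 1)
  expect_equal(b8$truth$protrusive_index_true, oracle_ratio(8, 20, 100),
               tolerance = 1e-3)
  # truth ratio strictly increases with depth at fixed lobe count
  ratios <- vapply(c(5, 10, 20, 30), function(d)
    gen_border_mask(8, d, 100)$truth$protrusive_index_true, numeric(1))
  expect_true(all(diff(ratios) > 0))
  expect_error(gen_border_mask(8, 120, 100), "degenerate")
})
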