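# Structure tensor, rim ROIs and the order-parameter profile.

test_that("structure tensor recovers grating orientations within a degree", {
  for (ang in c(0, 30, -75, 45)) {
    f <- structure_tensor_orientation(gen_grating(c(128, 128), ang, 8))
    int <- f$theta_deg[20:108, 20:108]
    modal <- order_parameter(as.vector(int))$mean_angle_deg
    delta <- abs(((modal - ang + 90) %% 180) - 90)
    expect_lt(delta, 1)
  }
})

test_that("a constant image has zero coherency and no valid pixels", {
  f <- structure_tensor_orientation(matrix(5, 64, 64))
  expect_false(any(f$valid))
  expect_identical(max(f$coherency), 0)
  expect_true(all(is.na(f$theta_deg)))
})

test_that("rotating a grating by 90 degrees shifts theta by 90 with wrapping", {
  f1 <- structure_tensor_orientation(gen_grating(c(128, 128), 30, 8))
  f2 <- structure_tensor_orientation(gen_grating(c(128, 128), 120, 8))
  m1 <- order_parameter(as.vector(f1$theta_deg[20:108, 20:108]))$mean_angle_deg
  m2 <- order_parameter(as.vector(f2$theta_deg[20:108, 20:108]))$mean_angle_deg
  expect_equal(m2, wrap_axial(m1 + 90), tolerance = 0.5)
  expect_true(m2 >= -90 && m2 < 90)
})

test_that("coherency lies in [0, 1] and theta in [-90, 90) on fiber images", {
  g <- gen_fiber_field(synthetic_fiber_spec(kappa = 1, n_fibers = 300,
                                            frame_um = 100, seed = 13))
  f <- structure_tensor_orientation(get_channel(g$image, "fibers"))
  expect_true(all(f$coherency >= 0 & f$coherency <= 1 + 1e-12))
  th <- f$theta_deg[f$valid]
  expect_true(all(th >= -90 & th < 90))
})

test_that("rim ROIs are normal to the boundary with the right footprint", {
  org <- disk_mask(40, pixel_size_um = 0.5)
  rois <- extract_rim_rois(org, spacing_um = 30)
  expect_gte(length(rois), 6)
  ctr <- org$centroid
  for (roi in rois) {
    radial <- roi$anchor - ctr
    radial <- radial / sqrt(sum(radial^2))
    expect_gte(sum(radial * roi$normal), 0.99)
    # footprint in px at 0.5 um/px: 60 wide, 100 deep
    expect_equal(roi$width_um / roi$pixel_size_um, 60)
    expect_equal(roi$depth_um / roi$pixel_size_um, 100)
  }
  pxs <- mechanoquant:::roi_pixels(rois[[1]], c(256, 256))
  expect_true(all(pxs$dist_um >= 0 & pxs$dist_um <= 50))
})

test_that("ROI normals match the edge normal on a straight border", {
  mask <- matrix(FALSE, 120, 120)
  mask[, 1:60] <- TRUE             # vertical straight edge at col 60
  org <- mechanoquant:::new_organoid_mask(mask, 1)
  rois <- extract_rim_rois(org, spacing_um = 25)
  # keep ROIs anchored on the straight edge, away from the image corners
  edge <- Filter(function(r) abs(r$anchor[2] - 60) < 3 &&
                   r$anchor[1] > 20 && r$anchor[1] < 100, rois)
  expect_gte(length(edge), 1)
  for (roi in edge) {
    ang <- abs(sum(roi$normal * c(0, 1)))
    expect_gte(ang, cos(2 * pi / 180))   # within 2 degrees of the +col axis
  }
})

test_that("uniform fiber fields give low S; radial fields give high S", {
  # the organoid is large relative to the ROI width, so the rim normal is
  # nearly constant within each ROI
  org <- disk_mask(150, pixel_size_um = 1, dims = c(512, 512))
  rois <- extract_rim_rois(org, spacing_um = 40)

  gu <- gen_fiber_field(synthetic_fiber_spec(kappa = 0, n_fibers = 4000,
                                             frame_um = 512,
                                             pixel_size_um = 1,
                                             fiber_length_um = 10, seed = 17))
  chu <- get_channel(gu$image, "fibers")
  fu <- structure_tensor_orientation(chu, sigma_window = 1.5)
  prof_u <- rim_order_profile(fu, rois, foreground = fiber_foreground(chu))
  # pixel orientations within one fiber are identical, so the effective
  # sample size per ROI is the fiber count, not the pixel count: the
  # uniform limit is asserted on the pooled estimate
  expect_gte(sum(prof_u$n_valid), 2000)
  expect_lte(attr(prof_u, "pooled")$S, 0.1)
  expect_true(all(prof_u$S <= 0.5))

  gr <- gen_radial_fiber_field(dims = c(512, 512), inner_radius_px = 155,
                               n_fibers = 1800, fiber_length_px = 40,
                               pixel_size_um = 1, seed = 18)
  chr <- get_channel(gr$image, "fibers")
  fr <- structure_tensor_orientation(chr, sigma_window = 1.5)
  prof_r <- rim_order_profile(fr, rois, foreground = fiber_foreground(chr))
  expect_true(all(prof_r$S >= 0.95))
  # radial alignment: director close to the rim normal
  expect_true(all(prof_r$angle_vs_normal_deg <= 5))
})

test_that("ROIs without valid pixels report S as missing, not zero", {
  org <- disk_mask(28, pixel_size_um = 0.5)
  blank <- structure_tensor_orientation(matrix(1, 256, 256))
  prof <- rim_order_profile(blank, extract_rim_rois(org, spacing_um = 40))
  expect_true(all(is.na(prof$S)))
  expect_true(all(prof$n_valid == 0))
})

test_that("pooled S tracks the von Mises expectation on a kappa = 2 field", {
  org <- disk_mask(150, pixel_size_um = 1, dims = c(1024, 1024))
  g <- gen_fiber_field(synthetic_fiber_spec(kappa = 2, mu_deg = 10,
                                            n_fibers = 9000, frame_um = 1024,
                                            pixel_size_um = 1,
                                            fiber_length_um = 20, seed = 19))
  f <- structure_tensor_orientation(get_channel(g$image, "fibers"),
                                    sigma_window = 1.5)
  prof <- rim_order_profile(f, extract_rim_rois(org, spacing_um = 25))
  pooled <- attr(prof, "pooled")
  expect_equal(pooled$S, vm_order_parameter(2), tolerance = 0.05)
})

test_that("inverting S on synthetic fields recovers the concentration", {
  g <- gen_fiber_field(synthetic_fiber_spec(kappa = 2, n_fibers = 5000,
                                            frame_um = 1448,
                                            pixel_size_um = 1,
                                            fiber_length_um = 30, seed = 23))
  ch <- get_channel(g$image, "fibers")
  f <- structure_tensor_orientation(ch, sigma_window = 1.5)
  ok <- f$valid & fiber_foreground(ch)
  S <- order_parameter(f$theta_deg[ok], f$coherency[ok])$S
  expect_lt(abs(kappa_from_order_parameter(S) / 2 - 1), 0.15)
})
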