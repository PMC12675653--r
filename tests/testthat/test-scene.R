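cam0 <- camera_model()                                  # no distortion
camk <- camera_model(distortion = c(-0.1, 0, 0, 0, 0))  # barrel
screen <- screen_geometry()

# closed-form point-projection oracle, written independently of the
# package's projection helpers
oracle_project <- function(p_mm, z, cam) {
  xn <- p_mm[1] / z
  yn <- -p_mm[2] / z
  k1 <- cam$distortion[1]; k2 <- cam$distortion[2]
  p1 <- cam$distortion[3]; p2 <- cam$distortion[4]; k3 <- cam$distortion[5]
  r2 <- xn^2 + yn^2
  rad <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
  xd <- xn * rad + 2 * p1 * xn * yn + p2 * (r2 + 2 * xn^2)
  yd <- yn * rad + p1 * (r2 + 2 * yn^2) + 2 * p2 * xn * yn
  c(cam$fx * xd + cam$cx, cam$fy * yd + cam$cy)
}

test_that("rendered ground truth matches the closed-form projection oracle", {
  for (cam in list(cam0, camk, camera_model(distortion = c(-0.1, 0.02, 0.001, -0.001, 0)))) {
    fr <- render_scene_frame(cam, screen, "bright", gaze_angle = c(4, -3))
    for (nm in rownames(screen$marker_layout)) {
      expect_equal(as.numeric(fr$truth$marker_px[nm, ]),
                   unname(oracle_project(screen$marker_layout[nm, ], 930, cam)),
                   tolerance = 1e-6)
    }
    gaze_mm <- 930 * tan(c(4, -3) * pi / 180)
    expect_equal(fr$truth$gaze_px, unname(oracle_project(gaze_mm, 930, cam)),
                 tolerance = 1e-6)
  }
})

test_that("render symmetry: central gaze projects to the screen-center pixel", {
  fr <- render_scene_frame(cam0, screen, "bright", gaze_angle = c(0, 0))
  expect_equal(fr$truth$gaze_px, as.numeric(fr$truth$marker_px["target", ]),
               tolerance = 1e-9)
  expect_equal(fr$truth$gaze_px, c(cam0$cx, cam0$cy), tolerance = 1e-9)
})

test_that("doubling the distance halves the corner-marker pixel span", {
  f1 <- render_scene_frame(cam0, screen, "bright", distance_mm = 930)
  f2 <- render_scene_frame(cam0, screen, "bright", distance_mm = 1860)
  span1 <- dist(f1$truth$marker_px[1:4, ])
  span2 <- dist(f2$truth$marker_px[1:4, ])
  expect_equal(as.numeric(span2), as.numeric(span1) / 2, tolerance = 1e-9)
})

test_that("screen outside the field of view raises a geometry error", {
  expect_error(render_scene_frame(cam0, screen, "bright", distance_mm = 300),
               class = "psaqc_geometry_error")
})

test_that("marker detection recovers rendered centers", {
  for (cond in c("bright", "dark")) {
    fr <- render_scene_frame(camk, screen, cond)
    det <- detect_markers(fr$image)
    got <- rbind(det$corner_points, target = det$target_point)
    expect_lt(max(abs(got - fr$truth$marker_px)), 0.5)
  }
  # with Gaussian intensity noise (sigma = 2 of 255), within 1 px
  frn <- render_scene_frame(camk, screen, "bright", noise_sd = 2 / 255, seed = 4)
  detn <- detect_markers(frn$image)
  gotn <- rbind(detn$corner_points, target = detn$target_point)
  expect_lt(max(abs(gotn - frn$truth$marker_px)), 1)
})

test_that("uniform frames and degenerate inputs raise detection errors", {
  expect_error(detect_markers(matrix(1, 100, 100)),
               class = "psaqc_markers_not_found")
  expect_error(detect_markers(matrix(0.5, 100, 100),
                              threshold_config = list(lo = 0.6, hi = 0.7)),
               class = "psaqc_markers_not_found")
})

test_that("undistort_points is exact inverse of the forward model", {
  # identity with zero coefficients
  pts <- cbind(runif(20, 1, 640), runif(20, 1, 480))
  expect_identical(undistort_points(pts, cam0), pts)
  # principal point is a fixed point of radial-only distortion
  pp <- c(camk$cx, camk$cy)
  expect_equal(as.numeric(undistort_points(pp, camk)), pp, tolerance = 1e-10)
  # round trip over the central 80% of the image, |k1| <= 0.2
  for (k1 in c(-0.2, -0.05, 0.1, 0.2)) {
    cam <- camera_model(distortion = c(k1, 0, 0, 0, 0))
    gx <- seq(0.1 * 640, 0.9 * 640, length.out = 7)
    gy <- seq(0.1 * 480, 0.9 * 480, length.out = 7)
    grid <- as.matrix(expand.grid(gx, gy))
    nd <- cbind((grid[, 1] - cam$cx) / cam$fx, (grid[, 2] - cam$cy) / cam$fy)
    r2 <- nd[, 1]^2 + nd[, 2]^2
    fwd <- cbind(cam$fx * nd[, 1] * (1 + k1 * r2) + cam$cx,
                 cam$fy * nd[, 2] * (1 + k1 * r2) + cam$cy)
    back <- undistort_points(fwd, cam)
    expect_lt(max(abs(back - grid)), 1e-4)
  }
})

# fronto-parallel pixel layout: mm coordinates scaled by 1/scale, image y down
px_layout <- function(px_per_mm) {
  layout <- screen_geometry()$marker_layout[1:4, ]
  cbind(layout[, 1] * px_per_mm, -layout[, 2] * px_per_mm) + 320
}

test_that("scaling factor follows the physical/apparent ratio", {
  # fronto-parallel detection with all pairs consistent: 0.5 mm/px
  det <- marker_detection(px_layout(2), target_point = c(320, 320))
  expect_equal(compute_scaling_factor(det, screen), 0.5, tolerance = 1e-12)
  # homogeneity: scaling all coordinates by 2 halves the factor
  det2 <- marker_detection(px_layout(4), target_point = c(320, 320))
  expect_equal(compute_scaling_factor(det2, screen), 0.25, tolerance = 1e-12)
  # rendered frame at known pose: within 1% of Z/f
  fr <- render_scene_frame(cam0, screen, "bright")
  det3 <- undistort_detection(detect_markers(fr$image), cam0)
  expect_equal(compute_scaling_factor(det3, screen), 930 / 900,
               tolerance = 0.01)
  # translation invariance
  det4 <- marker_detection(sweep(px_layout(2), 2, c(220, 270)),
                           target_point = c(100, 50))
  expect_equal(compute_scaling_factor(det4, screen),
               compute_scaling_factor(det, screen), tolerance = 1e-12)
  # coincident points (mutate a valid detection after construction)
  dd <- marker_detection(px_layout(2), c(320, 320))
  dd$corner_points[2, ] <- dd$corner_points[1, ] + c(1e-12, 0)
  expect_error(compute_scaling_factor(dd, screen),
               class = "psaqc_degenerate_geometry")
})

test_that("viewing distance follows the pinhole size formula", {
  det <- marker_detection(px_layout(1), c(320, 320),
                          corner_sizes_px = rep(10, 4))
  # focal 1000 px, 10-mm marker spanning 10 px -> 1000 mm
  cam <- camera_model(fx = 1000, fy = 1000)
  scr10 <- screen_geometry(marker_diameter_mm = 10)
  expect_equal(estimate_viewing_distance(det, scr10, cam), 1000, tolerance = 1e-12)
  # inverse proportionality to apparent size
  det2 <- marker_detection(px_layout(1), c(320, 320),
                           corner_sizes_px = rep(20, 4))
  expect_equal(estimate_viewing_distance(det2, scr10, cam), 500, tolerance = 1e-12)
  # rendered frame at 930 mm: within 1%
  fr <- render_scene_frame(cam0, screen, "bright")
  det3 <- undistort_detection(detect_markers(fr$image), cam0)
  expect_equal(estimate_viewing_distance(det3, screen, cam0), 930,
               tolerance = 0.01)
  # missing sizes
  det4 <- marker_detection(px_layout(1), c(320, 320))
  expect_error(estimate_viewing_distance(det4, screen, cam0),
               class = "psaqc_degenerate_geometry")
  # >10% disagreement warns but returns
  det5 <- marker_detection(px_layout(1), c(320, 320),
                           corner_sizes_px = c(10, 10, 10, 13))
  expect_warning(estimate_viewing_distance(det5, scr10, cam),
                 "disagree")
})

test_that("map_gaze_to_degrees applies center, scale, arctan and y flip", {
  det <- marker_detection(px_layout(1), c(320, 320))
  # gaze at detected target center -> (0, 0)
  expect_equal(as.numeric(map_gaze_to_degrees(c(320, 320), det, 0.5, 930)),
               c(0, 0))
  # gaze_mm equal to distance on one axis -> 45 degrees
  out <- map_gaze_to_degrees(c(320 + 930 / 0.5, 320), det, 0.5, 930)
  expect_equal(as.numeric(out), c(45, 0), tolerance = 1e-12)
  # image y down maps to negative (downward) degrees
  out2 <- map_gaze_to_degrees(c(320, 420), det, 0.5, 930)
  expect_lt(out2[2], 0)
  # NaN propagates, no exception
  outn <- map_gaze_to_degrees(rbind(c(NaN, NaN), c(320, 320)), det, 0.5, 930)
  expect_true(all(is.nan(outn[1, ])))
  # monotone in each pixel coordinate
  us <- seq(100, 500, 50)
  xs <- map_gaze_to_degrees(cbind(us, 320), det, 0.5, 930)[, 1]
  expect_true(all(diff(xs) > 0))
})

test_that("eyelink conversion is the stated linear map", {
  expect_equal(as.numeric(eyelink_pixels_to_degrees(c(960, 540), c(960, 540), 35)),
               c(0, 0))
  expect_equal(as.numeric(eyelink_pixels_to_degrees(c(995, 540), c(960, 540), 35)),
               c(1, 0))
  # linearity of the centered map
  f <- function(p) eyelink_pixels_to_degrees(p, c(960, 540), c(30, 40))
  a <- c(100, 50); b <- c(-30, 70)
  expect_equal(f(a) + f(b + c(960, 540)), f(a + b), tolerance = 1e-12)
  expect_error(eyelink_pixels_to_degrees(c(1, 1), c(0, 0), 0),
               class = "psaqc_config_error")
  expect_true(all(is.nan(eyelink_pixels_to_degrees(c(NaN, NaN), c(960, 540), 35))))
})

test_that("full scene round trip recovers true gaze within 0.1 degree", {
  dev <- device_profile(noise_std = 0, blink_rate = 0)
  true_gaze <- c(3, -2)
  fr <- render_scene_frame(camk, screen, "bright", gaze_angle = true_gaze)
  # synthesize a pixel-space recording jittered around the true gaze pixel
  n <- 50
  px <- cbind(rep(fr$truth$gaze_px[1], n), rep(fr$truth$gaze_px[2], n))
  rec <- gaze_recording(seq_len(n) / 100, px[, 1], px[, 2], space = "px")
  det <- detect_markers(fr$image)
  res <- scene_map_recording(rec, det, screen, camk)
  expect_equal(attr(res$recording, "space"), "deg")
  expect_lt(abs(mean(res$recording$x) - true_gaze[1]), 0.1)
  expect_lt(abs(mean(res$recording$y) - true_gaze[2]), 0.1)
  expect_equal(res$distance_mm, 930, tolerance = 0.01)
})
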