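test_that("world-to-camera transform matches the homogeneous oracle", {
  expect_equal(world_to_camera(c(1, 2, 3), rigid_transform()), c(1, 2, 3))
  ext <- rigid_transform(rot_z(pi / 2), c(0, 0, 5))
  oracle <- (rbind(cbind(rot_z(pi / 2), c(0, 0, 5)), c(0, 0, 0, 1)) %*%
               c(1, 0, 0, 1))[1:3]
  expect_equal(world_to_camera(c(1, 0, 0), ext), oracle, tolerance = 1e-12)
  expect_equal(world_to_camera(c(1, 0, 0), ext), c(0, 1, 5), tolerance = 1e-12)
  Tv <- c(-3, 7, 2)
  expect_equal(world_to_camera(c(0, 0, 0), rigid_transform(rot_x(0.3), Tv)), Tv)
  expect_error(rigid_transform(matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 2), 3)),
               "orthogonal|det")
})

test_that("projection matches the K [R|T] matrix form", {
  cam <- camera_model(fx = 500, u0 = 176, v0 = 176,
                      ideal_resolution = c(352, 352))
  ext <- rigid_transform()
  expect_equal(project_point(c(0, 0, 50), ext, cam), c(176, 176))
  expect_equal(project_point(c(5, 0, 50), ext, cam),
               project_oracle(c(5, 0, 50), diag(3), c(0, 0, 0), cam$K))
  expect_equal(project_point(c(5, 0, 50), ext, cam), c(226, 176))
  # projective scale invariance
  lam <- 3.7
  ext2 <- rigid_transform(diag(3), lam * c(0.5, -0.2, 1))
  p1 <- project_point(c(1, 2, 10), rigid_transform(diag(3), c(0.5, -0.2, 1)), cam)
  p2 <- project_point(lam * c(1, 2, 10), ext2, cam)
  expect_equal(p1, p2, tolerance = 1e-10)
  expect_error(project_point(c(0, 0, -1), ext, cam), "behind")
})

test_that("projection equals the explicit matrix product on random points", {
  set.seed(11)
  cam <- camera_model(fx = 480, fy = 510, u0 = 160, v0 = 170,
                      ideal_resolution = c(352, 352))
  R <- rot_z(0.2) %*% rot_x(-0.15)
  Tv <- c(0.3, -0.4, 2)
  ext <- rigid_transform(R, Tv)
  for (k in 1:1000) {
    pw <- c(stats::runif(2, -5, 5), stats::runif(1, 10, 100))
    expect_equal(project_point(pw, ext, cam),
                 project_oracle(pw, R, Tv, cam$K), tolerance = 1e-9)
  }
})

test_that("window displacements rescale linearly to ideal resolution", {
  rm1 <- resolution_map(c(352, 352), c(704, 704))
  expect_equal(to_ideal_resolution(10, rm1), 20)
  expect_equal(to_ideal_resolution(0, rm1), 0)
  rm2 <- resolution_map(c(352, 352), c(1056, 1056))
  expect_equal(to_ideal_resolution(7, rm2), 7 * 1056 / 352)
  expect_equal(to_ideal_resolution(7, rm2), 21)
  expect_error(resolution_map(c(0, 352), c(704, 704)), "positive")
  expect_error(to_ideal_resolution(-1, rm1), "non-negative")
})

test_that("range estimation inverts the forward projection of the marker", {
  # forward-project a 33.40 cm segment at a known range, then invert
  for (case in list(list(f = 500, L = 50), list(f = 600, L = 75))) {
    cam <- test_cam(case$f)
    ext <- rigid_transform()
    u1 <- project_point(c(-33.40 / 2, 0, case$L), ext, cam)[1]
    u2 <- project_point(c(33.40 / 2, 0, case$L), ext, cam)[1]
    Ap <- u2 - u1
    expect_equal(estimate_range(Ap, cam), case$L, tolerance = 1e-9)
  }
  cam <- test_cam(500)
  expect_equal(estimate_range(334, cam, 33.40), 50)
  expect_equal(estimate_range(2 * 334, cam, 33.40), 25)   # Ap doubled
  expect_equal(estimate_range(267.2, camera_model(fx = 600,
                                                  ideal_resolution = c(704, 704)),
                              33.40), 75, tolerance = 1e-9)
  expect_error(estimate_range(0, cam), "degenerate")
})

test_that("pixel displacement maps to depth through the pinhole geometry", {
  cam <- test_cam(500)
  ext <- rigid_transform()
  # a 5 cm vertical stroke at 50 cm spans 50 px at 500 px focal length
  v1 <- project_point(c(0, 0, 50), ext, cam)[2]
  v2 <- project_point(c(0, 5, 50), ext, cam)[2]
  expect_equal(v2 - v1, 50)
  expect_equal(displacement_to_depth(v2 - v1, 50, cam), 5, tolerance = 1e-9)
  expect_equal(displacement_to_depth(0, 50, cam), 0)
  cam6 <- camera_model(fx = 600, ideal_resolution = c(704, 704))
  expect_equal(displacement_to_depth(30, 60, cam6), 3, tolerance = 1e-12)
})

test_that("noiseless geometric round trip is exact and monotone", {
  cam <- camera_model(fx = 615, ideal_resolution = c(704, 704))
  ext <- rigid_transform()
  for (L in c(50, 62.5, 75)) for (H in c(3, 5, 6.2)) {
    Ap <- project_point(c(33.40 / 2, 0, L), ext, cam)[1] -
      project_point(c(-33.40 / 2, 0, L), ext, cam)[1]
    Bp <- project_point(c(0, H, L), ext, cam)[2] -
      project_point(c(0, 0, L), ext, cam)[2]
    Lhat <- estimate_range(Ap, cam)
    expect_equal(displacement_to_depth(Bp, Lhat, cam) / H, 1,
                 tolerance = 1e-9)
  }
  # H increasing in Bp at fixed L; L decreasing in Ap
  H1 <- displacement_to_depth(10, 60, cam)
  H2 <- displacement_to_depth(20, 60, cam)
  expect_gt(H2, H1)
  expect_gt(estimate_range(200, cam), estimate_range(300, cam))
})

test_that("camera calibration files round-trip through YAML and JSON", {
  cfg <- list(focal_px = 600, principal_point = c(352, 352),
              ideal_resolution = c(704, 704),
              window_resolution = c(352, 352),
              marker_length_cm = 33.40, marker_width_cm = 3.80)
  fy <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, fy)
  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, fj, auto_unbox = TRUE)
  for (f in c(fy, fj)) {
    cc <- read_camera_config(f)
    expect_s3_class(cc$cam, "camera_model")
    expect_equal(cc$cam$fx, 600)
    expect_equal(cc$marker_length_cm, 33.40)
    expect_equal(cc$rmap$window_resolution, c(352L, 352L))
  }
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(focal_px = 600), bad, auto_unbox = TRUE)
  expect_error(read_camera_config(bad), "missing required keys")
})
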