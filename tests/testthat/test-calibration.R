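test_that("camera model construction enforces its invariants", {
  expect_error(camera_model(-1, 500, 320, 240, image_size = c(640, 480)),
               "positive")
  expect_error(camera_model(500, 500, 700, 240, image_size = c(640, 480)),
               "principal point")
  expect_error(camera_model(500, 500, 320, 240, dist = 1:3,
                            image_size = c(640, 480)), "5 coefficients")
  expect_error(camera_model(500, 500, 320, 240, rms = -1,
                            image_size = c(640, 480)), "rms")
})

test_that("checkerboard detection finds ordered subpixel corners", {
  views <- calib_views()
  det <- calib_detections()
  ok <- vapply(det, inherits, logical(1), "cm_checkerboard")
  expect_true(all(ok))
  for (i in seq_along(det)) {
    expect_equal(nrow(det[[i]]$corners), 35)
    expect_lt(corner_error(det[[i]]$corners, views$corners[[i]]), 0.5)
  }
  # uniform image: typed not-found, degenerate input: error
  expect_failure_value(detect_checkerboard(matrix(0.5, 480, 640)))
  expect_error(detect_checkerboard(matrix(0.5, 4, 4)), "degenerate")
})

test_that("in-plane rotation keeps corner ordering consistent with board axes", {
  model <- camera_model(fx = 500, fy = 500, cx = 319.5, cy = 239.5,
                       image_size = c(640, 480))
  # fronto-parallel board rotated 30 degrees about the optical axis
  R <- cystomap:::rodrigues_to_matrix(c(0, 0, 30 * pi / 180))
  ctr <- c(20, 30, 0)
  tvec <- c(0, 0, 180) - as.vector(R %*% ctr)
  img <- cystomap:::render_checkerboard(model, R, tvec, 5, 7, 10)
  grid <- as.matrix(expand.grid(x = (0:4) * 10, y = (0:6) * 10))
  grid <- grid[order(grid[, 2], grid[, 1]), ]
  truth <- cystomap:::project_points(cbind(grid, 0), R, tvec, model)
  d <- detect_checkerboard(img)
  expect_s3_class(d, "cm_checkerboard")
  expect_lt(corner_error(d$corners, truth), 0.5)
})

test_that("calibration recovers a distortion-free model from rendered views", {
  model0 <- camera_model(fx = 500, fy = 500, cx = 319.5, cy = 239.5,
                         image_size = c(640, 480))
  views <- generate_checkerboard_views(model0, n_views = 14, seed = 2)
  det <- lapply(views$images, detect_checkerboard)
  det <- Filter(function(d) inherits(d, "cm_checkerboard"), det)
  expect_gte(length(det), 10)
  m <- calibrate_camera(det, square_size = 10, image_size = c(640, 480))
  expect_lt(abs(m$fx - 500) / 500, 0.02)
  expect_lt(abs(m$fy - 500) / 500, 0.02)
  expect_true(all(abs(m$dist) < 1e-2))
})

test_that("noise-free corner sets calibrate to near-zero reprojection error", {
  views <- calib_views()
  m <- calibrate_camera(truth_detections(views), square_size = 10,
                        image_size = c(640, 480))
  expect_lt(m$rms, 0.1)
  expect_lt(abs(m$fx - 500) / 500, 0.005)
  expect_lt(abs(m$dist[1] + 0.2), 0.01)
})

test_that("degenerate calibration inputs raise typed errors", {
  views <- calib_views()
  det <- truth_detections(views)
  expect_error(calibrate_camera(det[1:2], 10, c(640, 480)), ">= 3")
  expect_error(calibrate_camera(det[c(1, 1, 1)], 10, c(640, 480)),
               "identical poses")
})

test_that("undistortion is deterministic, size-preserving and straightening", {
  truth <- truth_camera()
  views <- calib_views()
  img <- views$images[[1]]
  u1 <- undistort(img, truth)
  u2 <- undistort(img, truth)
  expect_identical(u1$pixels, u2$pixels)
  expect_equal(dim(u1$pixels), dim(img))
  # zero-distortion model is the identity mapping
  m0 <- camera_model(500, 500, 319.5, 239.5, image_size = c(640, 480))
  expect_identical(undistort(img, m0)$pixels, img)
  expect_error(undistort(matrix(0, 10, 10), truth), "does not match")

  # line-fit oracle: distorted corner rows straighten after undistortion
  rows_id <- rep(1:7, each = 5)
  d_before <- detect_checkerboard(img)
  d_after <- detect_checkerboard(u1$pixels)
  expect_s3_class(d_after, "cm_checkerboard")
  r_before <- cystomap:::collinearity_residual(d_before$corners, rows_id)
  r_after <- cystomap:::collinearity_residual(d_after$corners, rows_id)
  expect_lt(r_after, r_before)
  expect_lt(r_after, 0.5)   # round-trip straightness on synthetic renders
})

test_that("camera models survive a JSON round trip", {
  m <- camera_model(501.3, 499.8, 320.1, 239.9,
                    dist = c(-0.21, 0.03, 1e-4, -2e-4, 0.01),
                    rms = 0.087, image_size = c(640, 480))
  path <- withr::local_tempfile(fileext = ".json")
  save_camera(m, path)
  m2 <- load_camera(path)
  expect_equal(m2[c("fx", "fy", "cx", "cy", "dist", "rms")],
               m[c("fx", "fy", "cx", "cy", "dist", "rms")], tolerance = 1e-12)
  expect_equal(m2$image_size, m$image_size)
})
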