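test_that("a single-row sweep yields no spatial neighbors", {
  scene <- synthetic_scene(seed = 3, n_frames = 15, pattern = "longitudinal")
  rf <- render_frames(scene)
  map <- stitch_sequence(rf$frames)
  cand <- find_spatial_neighbors(map, min_gap = 10)
  expect_equal(nrow(cand), 0)
})

test_that("serpentine rows are linked with verified overlap and gap", {
  sc <- drift_scenario()
  cand <- find_spatial_neighbors(sc$map, min_gap = 10, min_overlap = 0.25)
  expect_gt(nrow(cand), 0)
  expect_true(all(cand$index_b - cand$index_a >= 10))
  expect_true(all(table(cand$index_b) == 1))
  # oracle: overlap recomputed from ground-truth poses
  for (k in seq_len(nrow(cand))) {
    ov <- overlap_fraction(sc$rf$truth_poses[[cand$index_a[k]]],
                           sc$rf$truth_poses[[cand$index_b[k]]], 256, 256)
    expect_gte(ov, 0.25 - 0.05)
  }
})

test_that("loop residuals vanish on drift-free poses and expose injected bias", {
  rf <- rf25()
  map <- map25()
  clean <- map
  clean$poses <- lapply(seq_along(rf$frames), function(i) {
    truth_canvas_pose(map, rf$truth_poses, i)
  })
  cand <- find_spatial_neighbors(clean, min_gap = 10)
  expect_gt(nrow(cand), 0)
  # formula oracle: with an exact direct measurement injected, the residual
  # of drift-free poses is the identity
  a <- cand$index_a[1]; b <- cand$index_b[1]
  exact <- structure(list(index_a = a, index_b = b,
                          direct = tf_compose(tf_invert(clean$poses[[a]]),
                                              clean$poses[[b]]),
                          residual = tf_identity(), inlier_count = 99L),
                     class = "cm_loop_closure")
  expect_lt(max(abs(cystomap:::closure_residual_now(clean, exact) -
                      tf_identity())), 1e-9)
  # feature-measured residual on drift-free poses is close to identity:
  # sub-pixel translation, near-identity linear part
  cl <- measure_loop_residual(cand[nrow(cand), ], rf$frames, clean)
  expect_s3_class(cl, "cm_loop_closure")
  expect_lt(max(abs(cl$residual[, 3])), 1.5)
  expect_lt(max(abs(cl$residual[, 1:2] - diag(2))), 1e-2)

  # textureless pair fails as a value
  gray_frames <- rf$frames
  gray_frames[[cand$index_a[1]]] <- new_frame(matrix(0.5, 256, 256), 0L)
  expect_failure_value(measure_loop_residual(cand[1, ], gray_frames, clean))

  # +0.2 px/step bias accumulates into the residual translation
  sc <- drift_scenario()
  cand2 <- find_spatial_neighbors(sc$map, min_gap = 10)
  k <- which.max(cand2$index_b - cand2$index_a)
  cl2 <- measure_loop_residual(cand2[k, ], sc$rf$frames, sc$map)
  gap <- cand2$index_b[k] - cand2$index_a[k]
  expected <- -0.2 * gap   # closed-form bias accumulation over the gap
  expect_lt(abs(cl2$residual[1, 3] - expected), 0.3 * abs(expected) + 0.5)
  expect_lt(abs(cl2$residual[2, 3]), 1.5)
})

test_that("identity residuals leave poses untouched (idempotence)", {
  map <- map25()
  # closure whose direct measurement is exactly consistent with the poses
  a <- 2L; b <- 20L
  direct <- tf_compose(tf_invert(map$poses[[a]]), map$poses[[b]])
  cl <- structure(list(index_a = a, index_b = b, direct = direct,
                       residual = tf_identity(), inlier_count = 99L),
                  class = "cm_loop_closure")
  m1 <- apply_drift_correction(map, list(cl))
  for (i in seq_along(map$poses)) {
    expect_lt(max(abs(tf_compose(tf_invert(m1$offset), m1$poses[[i]]) -
                        tf_compose(tf_invert(map$offset), map$poses[[i]]))),
              1e-9)
  }
  m2 <- apply_drift_correction(m1, list(cl))
  expect_equal(m2$poses, m1$poses, tolerance = 1e-9)
  expect_message(apply_drift_correction(map, list()), "no valid loop closures")
})

test_that("a pure-translation residual is distributed linearly along the chain", {
  map <- map25()
  a <- 1L; b <- 21L
  # direct measurement implying the chained pose of b is off by (6, 0)
  direct <- tf_compose(tf_invert(map$poses[[a]]),
                       tf_compose(tf_translation(6, 0), map$poses[[b]]))
  cl <- structure(list(index_a = a, index_b = b, direct = direct,
                       residual = tf_translation(6, 0), inlier_count = 99L),
                  class = "cm_loop_closure")
  m1 <- apply_drift_correction(map, list(cl))
  rel <- function(m, i) tf_compose(tf_invert(m$offset), m$poses[[i]])
  corr <- function(i) {
    d <- rel(m1, i)[, 3] - rel(map, i)[, 3]
    d
  }
  expect_equal(corr(11), c(3, 0), tolerance = 1e-6)   # halfway frame
  expect_equal(corr(21), c(6, 0), tolerance = 1e-6)   # closing frame
  expect_equal(corr(1), c(0, 0), tolerance = 1e-12)   # anchor untouched
})

test_that("drift correction reduces pose error and closure residuals", {
  sc <- drift_scenario()
  cand <- find_spatial_neighbors(sc$map)
  closures <- lapply(seq_len(nrow(cand)), function(i) {
    measure_loop_residual(cand[i, ], sc$rf$frames, sc$map)
  })
  ok <- Filter(function(x) inherits(x, "cm_loop_closure"), closures)
  expect_gt(length(ok), 0)
  pre <- mean(pose_errors(sc$map, sc$rf$truth_poses)[, "t_err"])
  corrected <- apply_drift_correction(sc$map, closures)
  post <- mean(pose_errors(corrected, sc$rf$truth_poses)[, "t_err"])
  expect_lt(post, pre)
  # non-worsening at closures, and first-frame anchoring
  frob <- function(m, cl) {
    sqrt(sum((cystomap:::closure_residual_now(m, cl) - tf_identity())^2))
  }
  pre_res <- vapply(ok, function(cl) frob(sc$map, cl), numeric(1))
  post_res <- vapply(ok, function(cl) frob(corrected, cl), numeric(1))
  expect_true(all(post_res <= pre_res + 1e-9))
  expect_equal(tf_compose(tf_invert(corrected$offset), corrected$poses[[1]]),
               tf_compose(tf_invert(sc$map$offset), sc$map$poses[[1]]),
               tolerance = 1e-12)
  expect_gte(corrected$stats$drift_seconds, 0)
})
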