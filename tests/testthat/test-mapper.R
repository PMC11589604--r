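test_that("global pose composition matches direct matrix algebra", {
  t1 <- tf_similarity(3, 4, 0.2, 1.05)
  expect_equal(compose_global_pose(tf_identity(), t1), t1)
  expect_equal(compose_global_pose(tf_translation(3, 0), tf_translation(0, 4)),
               tf_translation(3, 4))
})

blank_map <- function(h, w) {
  cystomap:::new_bladder_map(matrix(0, h, w), matrix(FALSE, h, w),
                             list(tf_identity()), "initial", list(NULL),
                             tf_identity(), NULL, list(), NULL)
}

test_that("canvas expansion is minimal and shifts poses consistently", {
  m <- blank_map(100, 100)
  expect_identical(expand_canvas(m, cbind(c(10, 90), c(10, 90))), m)

  m2 <- expand_canvas(m, cbind(149, 50))
  expect_equal(dim(m2$canvas), c(100, 150))
  expect_equal(m2$offset, tf_identity())

  m3 <- expand_canvas(m, cbind(50, -20))
  expect_equal(dim(m3$canvas), c(120, 100))
  expect_equal(m3$offset, tf_translation(0, 20))
  expect_equal(m3$poses[[1]], tf_translation(0, 20))
  expect_error(expand_canvas(m, cbind(NaN, 1)), "finite")
})

test_that("expansion preserves existing canvas content pixel-for-pixel", {
  m <- blank_map(50, 50)
  m$canvas <- matrix(runif(2500), 50, 50)
  m$canvas_mask <- m$canvas > 0.5
  m2 <- expand_canvas(m, cbind(c(-10, 60), c(-5, 55)))
  expect_equal(m2$canvas[6:55, 11:60], m$canvas)
  expect_equal(m2$canvas_mask[6:55, 11:60], m$canvas_mask)
})

test_that("compositing writes frames under their masks, last writer wins", {
  m <- blank_map(60, 60)
  px <- matrix(runif(400), 20, 20)
  f <- new_frame(px, 0L)
  m1 <- composite_frame(m, f, tf_identity())
  expect_equal(m1$canvas[1:20, 1:20], px, tolerance = 1e-12)
  expect_equal(sum(m1$canvas_mask), 400)

  m2 <- composite_frame(m1, new_frame(matrix(0.25, 20, 20), 1L),
                        tf_translation(40, 40))
  expect_equal(sum(m2$canvas_mask), 800)   # disjoint placements add up

  m3 <- composite_frame(m1, new_frame(matrix(0.25, 20, 20), 1L),
                        tf_translation(5, 0))
  expect_true(all(abs(m3$canvas[1:20, 6:25] - 0.25) < 1e-12))

  expect_error(composite_frame(m, f, tf_translation(55, 0)),
               "outside the canvas")
})

test_that("a single frame initializes the map", {
  fr <- rf25()$frames[[1]]
  m <- stitch_sequence(list(fr))
  expect_equal(m$canvas, fr$pixels, tolerance = 1e-12)
  expect_equal(m$poses[[1]], tf_identity())
  expect_equal(m$stats$n_estimated, 0)
  expect_equal(m$stats$n_inherited, 0)
  expect_error(stitch_sequence(list()), "empty")
})

test_that("stitching recovers ground-truth poses along the sweep", {
  map <- map25()
  err <- pose_errors(map, rf25()$truth_poses)
  expect_lt(max(err[, "t_err"]), 2)
  expect_lt(max(err[, "rot_err"]), 1)
  expect_lt(max(err[, "scale_err"]), 0.01)
})

test_that("stitch bookkeeping satisfies the conservation and offset invariants", {
  map <- map25()
  s <- map$stats
  expect_equal(s$n_frames, s$n_estimated + s$n_inherited + 1)
  expect_equal(s$success_fraction, (s$n_frames - s$n_inherited) / s$n_frames)
  expect_equal(map$poses[[1]], map$offset)
  fs <- cystomap:::map_frame_size(map)
  crn <- tf_apply(map$poses[[1]], frame_corners(fs[1], fs[2]))
  expect_true(all(crn[, 1] >= 0 & crn[, 1] <= ncol(map$canvas) - 1 &
                    crn[, 2] >= 0 & crn[, 2] <= nrow(map$canvas) - 1))
  # canvas minimality: some projected corner touches each canvas side
  all_crn <- do.call(rbind, lapply(map$poses, function(p) {
    tf_apply(p, frame_corners(fs[1], fs[2]))
  }))
  expect_lt(min(all_crn[, 1]), 1)
  expect_lt(min(all_crn[, 2]), 1)
  expect_gt(max(all_crn[, 1]), ncol(map$canvas) - 2)
  expect_gt(max(all_crn[, 2]), nrow(map$canvas) - 2)
})

test_that("coverage grows monotonically as frames are composited", {
  rf <- rf25()
  m <- stitch_sequence(rf$frames[1:2])
  cover <- sum(m$canvas_mask)
  for (i in 3:6) {
    m2 <- stitch_sequence(rf$frames[1:i])
    expect_gte(sum(m2$canvas_mask), cover)
    cover <- sum(m2$canvas_mask)
  }
})

test_that("featureless frames inherit the prior transform and are counted", {
  rf <- rf25()
  frames <- rf$frames
  gray <- matrix(0.5, 256, 256)
  frames[[10]] <- new_frame(gray, index = 9L)
  frames[[11]] <- new_frame(gray, index = 10L)
  map <- stitch_sequence(frames)
  expect_equal(map$stats$n_inherited, 2)
  expect_equal(map$provenance[10:11], c("inherited", "inherited"))
  expect_equal(map$stats$success_fraction, 23 / 25)
  # inherited transforms carry the previous accepted step
  expect_equal(map$pairwise[[10]]$provenance, "inherited")
  expect_equal(map$pairwise[[10]]$inlier_count, 0L)
  # the pipeline recovers after the gap
  err <- pose_errors(map, rf$truth_poses)
  expect_lt(max(err[13:25, "t_err"]), 2)
})

test_that("stitching is deterministic", {
  rf <- rf25()
  m1 <- stitch_sequence(rf$frames[1:6])
  m2 <- stitch_sequence(rf$frames[1:6])
  expect_identical(m1$canvas, m2$canvas)
  expect_identical(m1$poses, m2$poses)
})
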