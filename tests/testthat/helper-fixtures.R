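# Shared fixtures, built once per test run and memoised. Everything is
# generated in code from fixed seeds; there are no stored data files.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fx, inherits = FALSE)) {
    assign(name, builder(), envir = .fx)
  }
  get(name, envir = .fx, inherits = FALSE)
}

# 25-frame serpentine sweep over the seed-1 texture (the acceptance scene)
scene25 <- function() fixture("scene25", function() {
  synthetic_scene(seed = 1, n_frames = 25)
})

rf25 <- function() fixture("rf25", function() render_frames(scene25()))

map25 <- function() fixture("map25", function() {
  stitch_sequence(rf25()$frames)
})

# ground-truth canvas pose of frame i given the map's offset bookkeeping
truth_canvas_pose <- function(map, truth_poses, i) {
  tf_compose(map$offset,
             tf_compose(tf_invert(truth_poses[[1]]), truth_poses[[i]]))
}

# per-frame pose errors (translation at frame center, rotation, scale)
pose_errors <- function(map, truth_poses, poses = map$poses) {
  fs <- cystomap:::map_frame_size(map)
  ctr <- cbind((fs[1] - 1) / 2, (fs[2] - 1) / 2)
  t(vapply(seq_along(poses), function(i) {
    truth <- truth_canvas_pose(map, truth_poses, i)
    d <- tf_apply(truth, ctr) - tf_apply(poses[[i]], ctr)
    pe <- tf_decompose(tf_compose(poses[[i]], tf_invert(truth)))
    c(t_err = sqrt(sum(d^2)), rot_err = abs(pe$theta) * 180 / pi,
      scale_err = abs(pe$scale - 1))
  }, numeric(3)))
}

# footprint overlap fraction of pose b's frame inside pose a's frame,
# computed on a point grid (independent of the package's own overlap code)
overlap_fraction <- function(pose_a, pose_b, fw, fh, n = 20) {
  grid <- as.matrix(expand.grid(x = seq(0, fw - 1, length.out = n),
                                y = seq(0, fh - 1, length.out = n)))
  pts <- tf_apply(tf_compose(tf_invert(pose_a), pose_b), grid)
  mean(pts[, 1] >= 0 & pts[, 1] <= fw - 1 & pts[, 2] >= 0 & pts[, 2] <= fh - 1)
}

# drifted 30-frame loop-closing sweep: truth-chained poses perturbed by a
# +0.2 px/step translation bias (the drift-correction acceptance scenario)
drift_scenario <- function() fixture("drift_scenario", function() {
  scene <- synthetic_scene(seed = 1, n_frames = 30)
  rf <- render_frames(scene)
  map <- stitch_sequence(rf$frames)
  map$poses <- lapply(seq_along(rf$frames), function(i) {
    tf_compose(tf_translation(0.2 * (i - 1), 0),
               truth_canvas_pose(map, rf$truth_poses, i))
  })
  map <- cystomap:::rebuild_map(map)
  list(map = map, rf = rf)
})

# revisit sweep: new 2-row serpentine path (different wobble seed) over the
# same seed-1 texture that map25 was built from
revisit_frames <- function() fixture("revisit_frames", function() {
  scene <- scene25()
  scene$truth_poses <- generate_trajectory("serpentine", 20,
                                           scene$texture_size,
                                           scene$frame_size, seed = 77)
  scene$seed <- 5000L
  render_frames(scene)
})

# truth camera + rendered checkerboard views (the calibration scenario)
truth_camera <- function() {
  camera_model(fx = 500, fy = 500, cx = 319.5, cy = 239.5,
               dist = c(-0.2, 0, 0, 0, 0), image_size = c(640, 480))
}

calib_views <- function() fixture("calib_views", function() {
  generate_checkerboard_views(truth_camera(), n_views = 20, seed = 1)
})

calib_detections <- function() fixture("calib_detections", function() {
  lapply(calib_views()$images, detect_checkerboard)
})

# detections built from exact truth corner projections (noise-free input)
truth_detections <- function(views) {
  lapply(views$corners, function(cc) {
    structure(list(corners = cc, pattern_size = views$pattern_size),
              class = "cm_checkerboard")
  })
}

# corner comparison tolerant to the 180-degree board symmetry
corner_error <- function(detected, truth) {
  e1 <- max(sqrt(rowSums((detected - truth)^2)))
  e2 <- max(sqrt(rowSums((detected[rev(seq_len(nrow(detected))), ] - truth)^2)))
  min(e1, e2)
}

expect_failure_value <- function(x) {
  expect_s3_class(x, "cm_failure")
}
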