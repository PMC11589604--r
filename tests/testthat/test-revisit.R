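test_that("an exact map crop is localized at its known pose", {
  map <- map25()
  # crop the canvas itself: the true pose is a pure integer translation
  x0 <- 220L; y0 <- 60L
  crop <- map$canvas[(y0 + 1):(y0 + 256), (x0 + 1):(x0 + 256)]
  loc <- localize_first_frame(map, new_frame(crop, 0L))
  expect_s3_class(loc, "cm_localization")
  expect_equal(loc$status, "matched_to_map")
  d <- tf_apply(loc$pose, cbind(127.5, 127.5)) - cbind(x0 + 127.5, y0 + 127.5)
  expect_lt(sqrt(sum(d^2)), 1)
  expect_lt(abs(loc$rotation_deg), 0.5)
})

test_that("a 30-degree rotated revisit frame reports its rotation", {
  map <- map25()
  scene <- scene25()
  rf <- rf25()
  base <- rf$truth_poses[[13]]
  ctr <- tf_apply(base, cbind(127.5, 127.5))
  rot <- tf_compose(
    tf_compose(tf_translation(ctr[1], ctr[2]), tf_similarity(theta = 30 * pi / 180)),
    tf_compose(tf_translation(-ctr[1], -ctr[2]), base))
  scene$truth_poses <- list(rot)
  fr <- render_frames(scene)$frames[[1]]
  loc <- localize_first_frame(map, fr)
  expect_s3_class(loc, "cm_localization")
  truth_rot <- tf_decompose(truth_canvas_pose(map, list(rf$truth_poses[[1]], rot), 2))$theta * 180 / pi
  expect_lt(abs(loc$rotation_deg - truth_rot), 1)
})

test_that("frames from an unrelated texture are not localized", {
  map <- map25()
  other <- generate_texture(seed = 999, size = c(512, 512))
  fr <- new_frame(other[1:256, 1:256], 0L)
  expect_failure_value(localize_first_frame(map, fr))
  expect_error(track_revisit(map, list(fr)), "could not be localized")
})

test_that("self-revisit reproduces the stored map poses", {
  map <- map25()
  locs <- track_revisit(map, rf25()$frames)
  expect_equal(attr(locs, "matched_fraction"), 1)
  for (i in seq_along(locs)) {
    d <- tf_apply(locs[[i]]$pose, cbind(127.5, 127.5)) -
      tf_apply(map$poses[[i]], cbind(127.5, 127.5))
    expect_lt(sqrt(sum(d^2)), 1)
    dr <- tf_decompose(tf_compose(locs[[i]]$pose,
                                  tf_invert(map$poses[[i]])))$theta * 180 / pi
    expect_lt(abs(dr), 0.5)
  }
})

test_that("a new sweep is localized throughout with exact status accounting", {
  map <- map25()
  rf2 <- revisit_frames()
  locs <- track_revisit(map, rf2$frames)
  statuses <- vapply(locs, `[[`, character(1), "status")
  expect_equal(attr(locs, "n_matched"), sum(statuses == "matched_to_map"))
  expect_equal(attr(locs, "matched_fraction"),
               mean(statuses == "matched_to_map"))
  expect_gte(attr(locs, "matched_fraction"), 0.95)
  err <- vapply(seq_along(locs), function(i) {
    truth <- truth_canvas_pose(map, c(rf25()$truth_poses[1],
                                      rf2$truth_poses), i + 1)
    d <- tf_apply(truth, cbind(127.5, 127.5)) -
      tf_apply(locs[[i]]$pose, cbind(127.5, 127.5))
    sqrt(sum(d^2))
  }, numeric(1))
  expect_lt(max(err[statuses == "matched_to_map"]), 3)
})

test_that("degenerate revisit frames are tracked from the previous frame", {
  map <- map25()
  rf2 <- revisit_frames()
  frames <- rf2$frames[1:8]
  gray <- matrix(0.5, 256, 256)
  frames[[4]] <- new_frame(gray, index = 3L)
  frames[[5]] <- new_frame(gray, index = 4L)
  locs <- track_revisit(map, frames)
  statuses <- vapply(locs, `[[`, character(1), "status")
  expect_equal(statuses[4:5], rep("tracked_from_previous", 2))
  expect_equal(attr(locs, "matched_fraction"), 6 / 8)
  expect_false(is.null(locs[[4]]$pose))
})

test_that("the overlay draws the sweep path, positions and orientations", {
  map <- map25()
  h <- nrow(map$canvas); w <- ncol(map$canvas)
  mk_loc <- function(pose, status = "matched_to_map") {
    cystomap:::new_localization(0L, pose, status, map, 10L)
  }
  ctr_pose <- tf_translation((w - 1) / 2 - 127.5, (h - 1) / 2 - 127.5)
  img <- render_overlay(map, list(mk_loc(ctr_pose)))
  expect_equal(dim(img), c(h, w, 3))
  cy <- round((h - 1) / 2) + 1; cx <- round((w - 1) / 2) + 1
  expect_equal(as.numeric(img[cy, cx, ]), c(0.1, 0.9, 0.1))  # green dot
  # rotation 0: blue arrow extends toward +x of the dot
  expect_true(any(img[cy, (cx + 6):(cx + 20), 3] > 0.9))
  # rotation 90 deg: arrow points toward +y (downward)
  rot_pose <- tf_compose(ctr_pose, tf_similarity(theta = pi / 2))
  rot_pose <- tf_compose(tf_translation(
    (w - 1) / 2 - tf_apply(rot_pose, cbind(127.5, 127.5))[1],
    (h - 1) / 2 - tf_apply(rot_pose, cbind(127.5, 127.5))[2]), rot_pose)
  img2 <- render_overlay(map, list(mk_loc(rot_pose)))
  expect_true(any(img2[(cy + 6):(cy + 20), cx, 3] > 0.9))
  # two localizations: a red polyline joins the dots (vertical, so the
  # horizontal rotation-0 arrows do not overdraw it)
  p2 <- tf_compose(tf_translation(0, 60), ctr_pose)
  img3 <- render_overlay(map, list(mk_loc(ctr_pose), mk_loc(p2)))
  expect_true(any(img3[(cy + 25):(cy + 35), cx, 1] > 0.9 &
                    img3[(cy + 25):(cy + 35), cx, 2] < 0.3))
  expect_error(render_overlay(map, list(mk_loc(NULL, "failed"))), "failed")
})
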