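# Revisit relocalization: frames of a later cystoscopy are localized inside
# a previously built bladder map. The first frame is found by a global
# feature search over the map canvas; subsequent frames are matched to the
# map under a locality prior (previous footprint dilated by one frame
# size), falling back to frame-to-frame chaining when the map match fails.

#' Detect and cache features of the map canvas
#'
#' Features are detected once on the (possibly drift-corrected) canvas,
#' restricted to covered pixels; their coordinates are canvas coordinates.
#'
#' @param map a `bladder_map`
#' @param config a [feature_config()]
#' @param max_keypoints cap for the map-wide feature set (the canvas is much
#'   larger than one frame)
#' @return a `cm_features` object in canvas coordinates
#' @export
map_features <- function(map, config = feature_config(), max_keypoints = 4000) {
  cfg <- config
  cfg$max_keypoints <- max_keypoints
  detect_features(map$canvas, map$canvas_mask, cfg, frame_index = -1L)
}

subset_features <- function(fs, keep) {
  fs$keypoints <- fs$keypoints[keep, , drop = FALSE]
  fs$response <- fs$response[keep]
  fs$descriptors <- fs$descriptors[keep, , drop = FALSE]
  fs
}

#' Rotation of a pose relative to the map's initial frame
#'
#' @param map a `bladder_map`
#' @param pose 2x3 frame -> canvas transform
#' @return rotation in degrees, wrapped into `(-180, 180]`
#' @export
rotation_vs_initial <- function(map, pose) {
  th <- tf_decompose(pose)$theta - tf_decompose(map$poses[[1]])$theta
  wrap_deg(th * 180 / pi)
}

new_localization <- function(frame_index, pose, status, map, inlier_count) {
  structure(list(frame_index = as.integer(frame_index), pose = pose,
                 status = status,
                 rotation_deg = if (is.null(pose)) NA_real_ else rotation_vs_initial(map, pose),
                 inlier_count = as.integer(inlier_count)),
            class = "cm_localization")
}

#' @export
print.cm_localization <- function(x, ...) {
  if (is.null(x$pose)) {
    cat(sprintf("<cm_localization #%d: failed>\n", x$frame_index))
  } else {
    c0 <- tf_apply(x$pose, cbind(0, 0))
    cat(sprintf("<cm_localization #%d (%s): origin=(%.1f, %.1f) rot=%.1f deg, %d inliers>\n",
                x$frame_index, x$status, c0[1], c0[2], x$rotation_deg,
                x$inlier_count))
  }
  invisible(x)
}

#' Localize the first revisit frame by global map search
#'
#' Frame features are matched against the cached map-canvas features with no
#' position prior, and the frame -> canvas transform estimated robustly.
#'
#' @param map a `bladder_map`
#' @param frame a [new_frame()] object (already undistorted)
#' @param config a [feature_config()]
#' @param mfs optional precomputed [map_features()] cache
#' @return a `cm_localization` with status `"matched_to_map"`, or a
#'   [cm_failure()] carrying diagnostic match counts
#' @export
localize_first_frame <- function(map, frame, config = feature_config(), mfs = NULL) {
  if (!any(map$canvas_mask)) stop("map canvas is empty", call. = FALSE)
  if (is.null(mfs)) mfs <- map_features(map, config)
  ffs <- detect_features(frame$pixels, frame$mask, config,
                         frame_index = frame$index)
  mt <- match_features(ffs, mfs, config)
  est <- estimate_affine(mt, ffs, mfs, config)
  if (is_failure(est)) {
    est$n_frame_features <- n_features(ffs)
    est$n_map_features <- n_features(mfs)
    est$n_matches <- nrow(mt$pairs)
    return(est)
  }
  new_localization(frame$index, est$matrix, "matched_to_map", map,
                   est$inlier_count)
}

#' Track a revisit sweep through the map
#'
#' The first frame is localized globally; each later frame is matched to the
#' map features inside the previous footprint dilated by one frame size
#' (locality prior). If the map match fails, the frame is chained from the
#' previous localized frame via a direct frame-to-frame estimate; if that
#' also fails (e.g. a featureless frame) the prior motion is inherited, as
#' in stitching. Both fallbacks carry `status = "tracked_from_previous"`.
#'
#' @param map a `bladder_map`
#' @param frames ordered list of [new_frame()] objects
#' @param config a [feature_config()]
#' @return list of `cm_localization` with attributes `n_matched` (count of
#'   `matched_to_map`) and `matched_fraction`
#' @export
track_revisit <- function(map, frames, config = feature_config()) {
  if (length(frames) < 1) stop("empty revisit sequence", call. = FALSE)
  mfs <- map_features(map, config)
  first <- localize_first_frame(map, frames[[1]], config, mfs = mfs)
  if (is_failure(first)) {
    stop(sprintf(paste0("first revisit frame could not be localized ",
                        "(%s: %s frame features, %s map features, %s matches)"),
                 first$reason, first$n_frame_features %||% "?",
                 first$n_map_features %||% "?", first$n_matches %||% "?"),
         call. = FALSE)
  }
  out <- vector("list", length(frames))
  out[[1]] <- first
  prev_pose <- first$pose
  prior_step <- tf_identity()   # last frame-to-frame motion, for inheritance
  prev_fs <- NULL
  fw <- ncol(frames[[1]]$pixels); fh <- nrow(frames[[1]]$pixels)
  if (length(frames) > 1) {
    prev_fs <- detect_features(frames[[1]]$pixels, frames[[1]]$mask, config,
                               frame_index = frames[[1]]$index)
  }
  for (i in seq_along(frames)[-1]) {
    fr <- frames[[i]]
    ffs <- detect_features(fr$pixels, fr$mask, config, frame_index = fr$index)
    loc <- NULL
    # locality prior: map features within the previous footprint dilated by
    # one frame size
    crn <- tf_apply(prev_pose, frame_corners(fw, fh))
    keep <- mfs$keypoints[, 1] >= min(crn[, 1]) - fw &
      mfs$keypoints[, 1] <= max(crn[, 1]) + fw &
      mfs$keypoints[, 2] >= min(crn[, 2]) - fh &
      mfs$keypoints[, 2] <= max(crn[, 2]) + fh
    lfs <- subset_features(mfs, keep)
    est <- estimate_affine(match_features(ffs, lfs, config), ffs, lfs, config)
    if (!is_failure(est)) {
      loc <- new_localization(fr$index, est$matrix, "matched_to_map", map,
                              est$inlier_count)
    } else if (!is.null(prev_fs)) {
      # fall back to chaining from the previous localized frame
      est2 <- estimate_affine(match_features(ffs, prev_fs, config),
                              ffs, prev_fs, config)
      if (!is_failure(est2)) {
        loc <- new_localization(fr$index, tf_compose(prev_pose, est2$matrix),
                                "tracked_from_previous", map, est2$inlier_count)
      }
    }
    if (is.null(loc)) {
      # feature gate failed on both routes: inherit the prior motion, as in
      # stitching (the frame still gets a predicted position on the map)
      loc <- new_localization(fr$index, tf_compose(prev_pose, prior_step),
                              "tracked_from_previous", map, 0L)
    } else {
      prior_step <- tf_compose(tf_invert(prev_pose), loc$pose)
    }
    prev_pose <- loc$pose
    out[[i]] <- loc
    prev_fs <- ffs
  }
  statuses <- vapply(out, `[[`, character(1), "status")
  attr(out, "n_matched") <- sum(statuses == "matched_to_map")
  attr(out, "matched_fraction") <- mean(statuses == "matched_to_map")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

draw_disc <- function(img, x, y, r, col) {
  h <- dim(img)[1]; w <- dim(img)[2]
  for (yy in max(1, floor(y - r + 1)):min(h, ceiling(y + r + 1))) {
    for (xx in max(1, floor(x - r + 1)):min(w, ceiling(x + r + 1))) {
      if ((xx - 1 - x)^2 + (yy - 1 - y)^2 <= r^2) img[yy, xx, ] <- col
    }
  }
  img
}

draw_line <- function(img, x0, y0, x1, y1, col, width = 1) {
  n <- max(2, ceiling(2 * sqrt((x1 - x0)^2 + (y1 - y0)^2)))
  xs <- seq(x0, x1, length.out = n)
  ys <- seq(y0, y1, length.out = n)
  h <- dim(img)[1]; w <- dim(img)[2]
  r <- width / 2
  for (i in seq_len(n)) {
    for (dy in floor(-r):ceiling(r)) for (dx in floor(-r):ceiling(r)) {
      xx <- round(xs[i]) + dx + 1; yy <- round(ys[i]) + dy + 1
      if (xx >= 1 && xx <= w && yy >= 1 && yy <= h) img[yy, xx, ] <- col
    }
  }
  img
}

#' Render the revisit navigation overlay
#'
#' On a copy of the map canvas: a red polyline through the localized frame
#' centers (the revisit sweep pattern), a green dot at each localized
#' frame's predicted position, and a blue arrow per frame showing the
#' cystoscope rotation relative to the map's initial frame (arrows point in
#' the initial frame's +x direction when `rotation_deg` is 0).
#'
#' @param map a `bladder_map`
#' @param localizations a [track_revisit()] result (or list of
#'   `cm_localization`)
#' @return an H x W x 3 RGB array in `[0, 1]`
#' @export
render_overlay <- function(map, localizations) {
  locs <- Filter(function(l) !is.null(l$pose), localizations)
  if (length(locs) == 0) stop("all localizations failed", call. = FALSE)
  h <- nrow(map$canvas); w <- ncol(map$canvas)
  img <- array(rep(map$canvas, 3), dim = c(h, w, 3))
  red <- c(1, 0.1, 0.1); green <- c(0.1, 0.9, 0.1); blue <- c(0.15, 0.3, 1)
  fs <- map_frame_size(map)
  fw <- fs[1]; fh <- fs[2]
  ctr <- t(vapply(locs, function(l) {
    tf_apply(l$pose, cbind((fw - 1) / 2, (fh - 1) / 2))[1, ]
  }, numeric(2)))
  if (nrow(ctr) > 1) {
    for (i in seq_len(nrow(ctr) - 1)) {
      img <- draw_line(img, ctr[i, 1], ctr[i, 2], ctr[i + 1, 1], ctr[i + 1, 2],
                       red, width = 2)
    }
  }
  th0 <- tf_decompose(map$poses[[1]])$theta
  alen <- 0.22 * min(fw, fh)
  for (i in seq_along(locs)) {
    ang <- th0 + locs[[i]]$rotation_deg * pi / 180
    tip <- ctr[i, ] + alen * c(cos(ang), sin(ang))
    img <- draw_line(img, ctr[i, 1], ctr[i, 2], tip[1], tip[2], blue, width = 2)
    for (s in c(0.5, -0.5)) {
      barb <- tip + 0.35 * alen * c(cos(ang + pi + s), sin(ang + pi + s))
      img <- draw_line(img, tip[1], tip[2], barb[1], barb[2], blue, width = 2)
    }
    img <- draw_disc(img, ctr[i, 1], ctr[i, 2], 3, green)
  }
  img
}
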