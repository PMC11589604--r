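# Bladder map construction: chain pairwise transforms into global poses,
# grow the canvas as frames land outside it, and composite frames under
# their validity masks (last writer wins). The map's orientation is
# initialized by the first frame; all poses map frame pixel coordinates
# into canvas coordinates.

#' Compose a pairwise transform onto a global pose
#'
#' Given the previous frame's global pose (frame -> canvas) and the pairwise
#' transform of the new frame into the previous frame, returns the new
#' frame's global pose.
#'
#' @param prev_pose 2x3 global pose of the previous frame
#' @param pairwise a [estimate_affine()] result or a 2x3 matrix mapping the
#'   new frame's coordinates into the previous frame's coordinates
#' @return 2x3 global pose of the new frame
#' @export
compose_global_pose <- function(prev_pose, pairwise) {
  m <- if (inherits(pairwise, "cm_transform")) pairwise$matrix else pairwise
  tf_check(prev_pose, "prev_pose"); tf_check(m, "pairwise")
  if (abs(tf_det(prev_pose)) < 1e-12 || abs(tf_det(m)) < 1e-12) {
    stop("singular transform in pose composition", call. = FALSE)
  }
  tf_compose(prev_pose, m)
}

new_bladder_map <- function(canvas, canvas_mask, poses, provenance, pairwise,
                            offset, stats, frames, config) {
  structure(list(canvas = canvas, canvas_mask = canvas_mask, poses = poses,
                 provenance = provenance, pairwise = pairwise, offset = offset,
                 stats = stats, frames = frames, config = config),
            class = "bladder_map")
}

#' @export
print.bladder_map <- function(x, ...) {
  s <- x$stats
  cat(sprintf(paste0("<bladder_map: %d frames on a %dx%d canvas; ",
                     "%d estimated + %d inherited transforms (success %.0f%%)>\n"),
              s$n_frames, ncol(x$canvas), nrow(x$canvas),
              s$n_estimated, s$n_inherited, 100 * s$success_fraction))
  invisible(x)
}

#' Grow the map canvas to contain projected frame corners
#'
#' The canvas is enlarged minimally (integer pixels) so that all `corners`
#' fit. Growth toward negative coordinates shifts the coordinate origin: the
#' cumulative `offset` and every stored pose are translated consistently and
#' existing content is preserved pixel-for-pixel.
#'
#' @param map a `bladder_map`
#' @param corners n x 2 matrix of canvas-coordinate points that must fit
#' @return the (possibly grown) `bladder_map`
#' @export
expand_canvas <- function(map, corners) {
  corners <- rbind2cols(corners)
  if (!all(is.finite(corners))) stop("non-finite corners", call. = FALSE)
  h <- nrow(map$canvas); w <- ncol(map$canvas)
  grow_l <- max(0, -floor(min(corners[, 1])))
  grow_t <- max(0, -floor(min(corners[, 2])))
  grow_r <- max(0, ceiling(max(corners[, 1])) - (w - 1))
  grow_b <- max(0, ceiling(max(corners[, 2])) - (h - 1))
  if (grow_l + grow_t + grow_r + grow_b == 0) return(map)
  nh <- h + grow_t + grow_b; nw <- w + grow_l + grow_r
  canvas <- matrix(0, nh, nw)
  cmask <- matrix(FALSE, nh, nw)
  canvas[grow_t + seq_len(h), grow_l + seq_len(w)] <- map$canvas
  cmask[grow_t + seq_len(h), grow_l + seq_len(w)] <- map$canvas_mask
  map$canvas <- canvas
  map$canvas_mask <- cmask
  if (grow_l > 0 || grow_t > 0) {
    shift <- tf_translation(grow_l, grow_t)
    map$poses <- lapply(map$poses, function(p) tf_compose(shift, p))
    map$offset <- tf_compose(shift, map$offset)
  }
  map
}

#' Composite one frame into the map canvas
#'
#' The frame is warped by `pose` (backward mapping, bilinear) and written
#' into the canvas wherever its validity mask holds; overlapping content is
#' overwritten (last-writer-wins). The pose must already project the frame
#' inside the canvas — call [expand_canvas()] first.
#'
#' @param map a `bladder_map`
#' @param frame a [new_frame()] object
#' @param pose 2x3 frame -> canvas transform
#' @return the updated `bladder_map`
#' @export
composite_frame <- function(map, frame, pose) {
  tf_check(pose, "pose")
  fw <- ncol(frame$pixels); fh <- nrow(frame$pixels)
  crn <- tf_apply(pose, frame_corners(fw, fh))
  h <- nrow(map$canvas); w <- ncol(map$canvas)
  if (min(crn[, 1]) < -0.51 || min(crn[, 2]) < -0.51 ||
      max(crn[, 1]) > w - 0.49 || max(crn[, 2]) > h - 0.49) {
    stop("pose projects frame outside the canvas; expand_canvas first",
         call. = FALSE)
  }
  res <- cpp_warp_into(map$canvas, map$canvas_mask, frame$pixels,
                       frame_mask_or_full(frame), tf_invert(pose),
                       floor(min(crn[, 1])), floor(min(crn[, 2])),
                       ceiling(max(crn[, 1])), ceiling(max(crn[, 2])))
  map$canvas <- res$canvas
  map$canvas_mask <- res$mask
  map
}

#' Stitch an ordered frame sequence into a bladder map
#'
#' For each consecutive frame pair: detect features, brute-force match,
#' robustly estimate the pairwise similarity/affine. When the feature gate
#' or the inlier minimum fails, the prior accepted pairwise transform is
#' inherited (provenance `"inherited"`); pairwise transforms are chained
#' into global poses, the canvas grows as needed, and each frame is
#' composited. Run statistics (frame counts, estimated/inherited split,
#' stitch time) are recorded on the returned map.
#'
#' @param frames list of [new_frame()] objects, temporal order; frames are
#'   assumed already undistorted
#' @param config a [feature_config()]
#' @param verbose print one status line per frame
#' @return a `bladder_map`
#' @export
stitch_sequence <- function(frames, config = feature_config(), verbose = FALSE) {
  if (length(frames) < 1) stop("empty frame sequence", call. = FALSE)
  t0 <- proc.time()[["elapsed"]]
  f0 <- frames[[1]]
  map <- new_bladder_map(
    canvas = matrix(0, nrow(f0$pixels), ncol(f0$pixels)),
    canvas_mask = matrix(FALSE, nrow(f0$pixels), ncol(f0$pixels)),
    poses = list(tf_identity()), provenance = "initial", pairwise = list(NULL),
    offset = tf_identity(), stats = NULL, frames = frames, config = config)
  map$frame_size <- c(ncol(f0$pixels), nrow(f0$pixels))
  map <- composite_frame(map, f0, tf_identity())

  # the registration reference is the most recent successfully registered
  # frame (initially frame 0); degenerate frames never become the reference,
  # so the frame after a featureless stretch re-registers against the last
  # good frame and only the featureless frames count as "no transformation
  # found"
  ref_fs <- detect_features(f0$pixels, f0$mask, config, frame_index = f0$index)
  ref_i <- 1L
  prior_pairwise <- tf_identity()   # stationary assumption before any estimate
  log_rows <- list(data.frame(frame = f0$index, n_features = n_features(ref_fs),
                              n_matches = NA_integer_, n_inliers = NA_integer_,
                              provenance = "initial"))
  n_est <- 0L; n_inh <- 0L

  for (i in seq_along(frames)[-1]) {
    fr <- frames[[i]]
    fs <- detect_features(fr$pixels, fr$mask, config, frame_index = fr$index)
    mt <- match_features(fs, ref_fs, config)
    est <- estimate_pair(fs, ref_fs, config,
                         img_a = fr$pixels, img_b = frames[[ref_i]]$pixels)
    if (is_failure(est)) {
      prov <- "inherited"
      n_inh <- n_inh + 1L
      inl <- 0L
      pose <- compose_global_pose(map$poses[[i - 1]], prior_pairwise)
      tfobj <- structure(list(matrix = prior_pairwise, source_index = fr$index,
                              target_index = frames[[i - 1]]$index,
                              provenance = "inherited", inlier_count = 0L),
                         class = "cm_transform")
    } else {
      prov <- "estimated"
      n_est <- n_est + 1L
      inl <- est$inlier_count
      pose <- compose_global_pose(map$poses[[ref_i]], est$matrix)
      prior_pairwise <- tf_compose(tf_invert(map$poses[[i - 1]]), pose)
      tfobj <- est
      ref_fs <- fs
      ref_i <- i
    }
    map$poses[[i]] <- pose
    map$provenance[i] <- prov
    map$pairwise[[i]] <- tfobj
    crn <- tf_apply(pose, frame_corners(ncol(fr$pixels), nrow(fr$pixels)))
    map <- expand_canvas(map, crn)
    map <- composite_frame(map, fr, map$poses[[i]])
    log_rows[[i]] <- data.frame(frame = fr$index, n_features = n_features(fs),
                                n_matches = nrow(mt$pairs), n_inliers = inl,
                                provenance = prov)
    if (verbose) {
      message(sprintf("frame %d: %d features, %d matches, %d inliers [%s]",
                      fr$index, n_features(fs), nrow(mt$pairs), inl, prov))
    }
  }

  n <- length(frames)
  map$stats <- list(n_frames = n, n_estimated = n_est, n_inherited = n_inh,
                    success_fraction = (n - n_inh) / n,
                    stitch_seconds = proc.time()[["elapsed"]] - t0,
                    drift_seconds = 0)
  map$log <- do.call(rbind, log_rows)
  map
}

# Rebuild the canvas from the stored frames and (possibly corrected) poses.
# Poses are the source of truth; the canvas is derived from them.
rebuild_map <- function(map) {
  crn_all <- do.call(rbind, lapply(seq_along(map$frames), function(i) {
    fr <- map$frames[[i]]
    tf_apply(map$poses[[i]], frame_corners(ncol(fr$pixels), nrow(fr$pixels)))
  }))
  shift <- tf_translation(max(0, -floor(min(crn_all[, 1]))),
                          max(0, -floor(min(crn_all[, 2]))))
  poses <- lapply(map$poses, function(p) tf_compose(shift, p))
  map$offset <- tf_compose(shift, map$offset)
  crn_all <- tf_apply(shift, crn_all)
  w <- ceiling(max(crn_all[, 1])) + 1
  h <- ceiling(max(crn_all[, 2])) + 1
  map$canvas <- matrix(0, h, w)
  map$canvas_mask <- matrix(FALSE, h, w)
  map$poses <- poses
  for (i in seq_along(map$frames)) {
    map <- composite_frame(map, map$frames[[i]], map$poses[[i]])
  }
  map
}
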