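# Loop-closure drift correction. Chained pairwise registration accumulates
# small errors; closing loops between spatially adjacent but temporally
# distant frames measures the accumulated mismatch, which is then
# distributed back over the intervening chain. The first frame anchors the
# map and is never moved.

#' Find spatially adjacent, temporally distant frame pairs
#'
#' Candidate loop-closure pairs: projected frame centers within
#' `max_center_dist`, projected footprints overlapping by at least
#' `min_overlap`, and temporal separation of at least `min_gap` frames.
#' At most one candidate (the highest-overlap one) is kept per later frame
#' so that corrections stay independent.
#'
#' @param map a `bladder_map`
#' @param min_gap minimum `|index_a - index_b|`, frames
#' @param max_center_dist maximum projected center distance, pixels;
#'   default 1.5 x frame diagonal
#' @param min_overlap minimum fraction of the later frame's footprint that
#'   falls inside the earlier frame
#' @return data.frame with columns `index_a`, `index_b` (1-based positions
#'   into the map's frame list, `index_a < index_b`) and `overlap`
#' @export
find_spatial_neighbors <- function(map, min_gap = 10, max_center_dist = NULL,
                                   min_overlap = 0.25) {
  n <- length(map$frames)
  out <- data.frame(index_a = integer(), index_b = integer(), overlap = numeric())
  if (n < min_gap + 1) return(out)
  fs <- map_frame_size(map)
  fw <- fs[1]; fh <- fs[2]
  if (is.null(max_center_dist)) max_center_dist <- 1.5 * sqrt(fw^2 + fh^2)
  ctr <- t(vapply(map$poses, function(p) {
    tf_apply(p, cbind((fw - 1) / 2, (fh - 1) / 2))[1, ]
  }, numeric(2)))
  # overlap of b's footprint with a: sample a grid in b, pull back into a
  gx <- seq(0, fw - 1, length.out = 15)
  gy <- seq(0, fh - 1, length.out = 15)
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  overlap_frac <- function(a, b) {
    pts <- tf_apply(tf_compose(tf_invert(map$poses[[a]]), map$poses[[b]]), grid)
    mean(pts[, 1] >= 0 & pts[, 1] <= fw - 1 & pts[, 2] >= 0 & pts[, 2] <= fh - 1)
  }
  rows <- list()
  for (b in seq_len(n)) {
    cand <- which(seq_len(n) <= b - min_gap)
    if (length(cand) == 0) next
    d <- sqrt((ctr[cand, 1] - ctr[b, 1])^2 + (ctr[cand, 2] - ctr[b, 2])^2)
    cand <- cand[d <= max_center_dist]
    if (length(cand) == 0) next
    ov <- vapply(cand, overlap_frac, numeric(1), b = b)
    ok <- ov >= min_overlap
    if (!any(ok)) next
    best <- cand[ok][which.max(ov[ok])]
    rows[[length(rows) + 1]] <- data.frame(index_a = best, index_b = b,
                                           overlap = max(ov[ok]))
  }
  if (length(rows)) rbind(out, do.call(rbind, rows)) else out
}

#' Measure the loop-closure residual of a frame pair
#'
#' Registers frame `b` directly against frame `a` with the feature pipeline
#' and compares the result with the chained poses: the residual
#' `(pose_a o direct_ab) o pose_b^-1` is the canvas-space transform that
#' would move frame `b` from its chained position to its directly measured
#' one. Identity residual means no drift across the loop.
#'
#' @param pair list or one-row data.frame with `index_a`, `index_b`
#'   (1-based positions into `frames`)
#' @param frames the map's frame list
#' @param map the `bladder_map` holding the chained poses
#' @param config a [feature_config()]
#' @return object of class `cm_loop_closure` (fields `index_a`, `index_b`,
#'   `direct` (2x3, frame b -> frame a), `residual` (2x3), `inlier_count`)
#'   or a [cm_failure()] when matching fails
#' @export
measure_loop_residual <- function(pair, frames, map, config = feature_config()) {
  a <- as.integer(pair$index_a); b <- as.integer(pair$index_b)
  fa <- frames[[a]]; fb <- frames[[b]]
  est <- register_pair(fb$pixels, fa$pixels, config,
                       mask_a = fb$mask, mask_b = fa$mask)
  if (is_failure(est)) return(est)
  direct <- est$matrix   # frame b coords -> frame a coords
  residual <- tf_compose(tf_compose(map$poses[[a]], direct),
                         tf_invert(map$poses[[b]]))
  structure(list(index_a = a, index_b = b, direct = direct,
                 residual = residual, inlier_count = est$inlier_count),
            class = "cm_loop_closure")
}

#' @export
print.cm_loop_closure <- function(x, ...) {
  p <- tf_decompose(x$residual)
  cat(sprintf("<cm_loop_closure %d~%d: residual t=(%.2f, %.2f) rot=%.3f deg scale=%.4f>\n",
              x$index_a - 1L, x$index_b - 1L, p$tx, p$ty,
              p$theta * 180 / pi, p$scale))
  invisible(x)
}

closure_residual_now <- function(map, cl) {
  tf_compose(tf_compose(map$poses[[cl$index_a]], cl$direct),
             tf_invert(map$poses[[cl$index_b]]))
}

#' Distribute loop-closure residuals over the pose chain
#'
#' Closures are processed in increasing `index_b` order. For each closure
#' the residual is re-derived from the current (partially corrected) poses
#' using the stored direct measurement — so sequential closures do not
#' double-count — and distributed over the intervening chain by linear
#' interpolation in (tx, ty, rotation, log scale): frame `index_a` is
#' untouched, frame `index_b` receives the full residual, frames in between
#' receive proportional fractions. Frame 0 is never moved. The canvas is
#' re-rendered from the corrected poses and `drift_seconds` recorded.
#'
#' @param map a `bladder_map`
#' @param closures list of [measure_loop_residual()] results (failures are
#'   filtered out)
#' @return the corrected `bladder_map`; unchanged (with a message) when no
#'   valid closure is supplied
#' @export
apply_drift_correction <- function(map, closures) {
  closures <- Filter(function(x) inherits(x, "cm_loop_closure"), closures)
  if (length(closures) == 0) {
    message("no valid loop closures; map unchanged")
    return(map)
  }
  t0 <- proc.time()[["elapsed"]]
  ord <- order(vapply(closures, `[[`, integer(1), "index_b"))
  last_corrected <- 1L
  for (cl in closures[ord]) {
    a <- cl$index_a; b <- cl$index_b
    # frames up to the previous closure's end are already anchored; ramp the
    # remaining residual from there (or from a, whichever is later) to b
    start <- max(a, last_corrected)
    if (start >= b) next
    res <- closure_residual_now(map, cl)
    for (i in seq(start + 1L, b)) {
      f <- (i - start) / (b - start)
      map$poses[[i]] <- tf_compose(tf_frac(res, f), map$poses[[i]])
    }
    last_corrected <- b
  }
  map <- rebuild_map(map)
  if (!is.null(map$stats)) {
    map$stats$drift_seconds <- proc.time()[["elapsed"]] - t0
  }
  map
}
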