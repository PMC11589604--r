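# Feature detection, brute-force matching and robust similarity/affine
# estimation between frame pairs. The detector is a difference-of-Gaussian
# blob detector with gradient-orientation assignment and rotation/scale
# normalized patch descriptors: a SURF-class detector in the sense that it
# is scale- and rotation-invariant with floating-point descriptors. The
# exact detector is a pluggable policy; every downstream contract is posed
# in terms of recovered ground-truth poses, not descriptor internals.

#' Feature pipeline configuration
#'
#' @param n_scales number of difference-of-Gaussian layers
#' @param sigma0 base blur scale, pixels
#' @param dog_thresh absolute DoG response threshold (intensities in `[0,1]`)
#' @param max_keypoints keep at most this many strongest keypoints
#' @param descriptor `"grad_hist"` (gradient-orientation histograms over
#'   4x4 spatial cells, 128-d, the more discriminative default) or
#'   `"patch"` (normalized raw intensity patches)
#' @param patch_n descriptor sampling grid is `patch_n` x `patch_n`
#' @param patch_spacing sample spacing in units of keypoint scale
#' @param ratio Lowe ratio-test threshold for match filtering
#' @param cross_check require mutual nearest neighbours
#' @param model motion model fitted between frames: `"similarity"` (4-DOF
#'   translation + rotation + uniform zoom, the cystoscope motion model) or
#'   `"affine"` (full 6-DOF)
#' @param ransac list of RANSAC controls: `threshold_px` inlier reprojection
#'   threshold, `confidence`, `max_iters`, `min_inliers` (also the per-frame
#'   feature gate), `seed`
#' @param refine_thresholds decreasing inlier thresholds (px) for the
#'   staged least-squares polish after RANSAC; `NULL` disables
#' @param symmetric estimate each chained pair in both directions and
#'   average the two transforms (cancels direction-dependent localisation
#'   bias; used by the stitching/drift pipelines)
#' @param scale_range plausible bounds on the recovered similarity scale
#'   (zoom); candidate fits outside them are rejected as geometric
#'   coincidences. Endoscope zoom between registered views stays well
#'   within these bounds
#' @param lk_refine re-localise inlier correspondences by warp-compensated
#'   Lucas-Kanade before the final fit (see [refine_transform()])
#' @param lk_half_win half window of the photometric patches, pixels
#' @param lk_iters maximum Lucas-Kanade iterations
#' @return a list of class `cm_feature_config`
#' @export
feature_config <- function(n_scales = 6, sigma0 = 1.6, dog_thresh = 0.004,
                           max_keypoints = 600, descriptor = c("grad_hist", "patch"),
                           patch_n = 12, patch_spacing = 1.1,
                           ratio = 0.75, cross_check = FALSE,
                           model = c("similarity", "affine"),
                           ransac = list(), refine_thresholds = c(1.5, 0.8),
                           scale_range = c(0.75, 1.33),
                           symmetric = TRUE, lk_refine = TRUE,
                           lk_half_win = 6L, lk_iters = 15L) {
  model <- match.arg(model)
  descriptor <- match.arg(descriptor)
  rdef <- list(threshold_px = 3, confidence = 0.995, max_iters = 2000,
               min_inliers = 6, seed = 42L)
  rdef[names(ransac)] <- ransac
  structure(list(n_scales = n_scales, sigma0 = sigma0, dog_thresh = dog_thresh,
                 max_keypoints = max_keypoints, descriptor = descriptor,
                 patch_n = patch_n,
                 patch_spacing = patch_spacing, ratio = ratio,
                 cross_check = cross_check, model = model, ransac = rdef,
                 refine_thresholds = refine_thresholds,
                 scale_range = scale_range, symmetric = symmetric,
                 lk_refine = lk_refine, lk_half_win = as.integer(lk_half_win),
                 lk_iters = as.integer(lk_iters)),
            class = "cm_feature_config")
}

#' Typed pipeline failure
#'
#' Recoverable failures (feature gate not passed, too few inliers, board not
#' found) are values, not conditions, so callers can branch on them.
#'
#' @param reason short machine-readable reason string
#' @param ... extra diagnostic fields
#' @return an object of class `cm_failure`
#' @export
cm_failure <- function(reason, ...) {
  structure(list(reason = reason, ...), class = "cm_failure")
}

#' Test for a pipeline failure value
#' @param x object
#' @return `TRUE` for [cm_failure()] objects
#' @export
is_failure <- function(x) inherits(x, "cm_failure")

#' Detect scale/rotation-invariant features in one frame
#'
#' Difference-of-Gaussian extrema with sub-pixel quadratic localisation,
#' dominant-gradient orientation assignment, and normalized patch
#' descriptors. Deterministic for fixed input and config.
#'
#' @param image numeric matrix in `[0, 1]`
#' @param mask optional logical validity mask; keypoints outside it (or
#'   within one scale of its border) are dropped
#' @param config a [feature_config()]
#' @param frame_index stored into the result for bookkeeping
#' @return object of class `cm_features`: list with `keypoints`
#'   (n x 4 matrix: x, y, scale, orientation), `response`, `descriptors`
#'   (n x d matrix), `frame_index`
#' @export
detect_features <- function(image, mask = NULL, config = feature_config(),
                            frame_index = 0L) {
  h <- nrow(image); w <- ncol(image)
  k <- 2^(1 / 3)
  sigmas <- config$sigma0 * k^(0:config$n_scales)
  gs <- lapply(sigmas, function(s) cpp_gauss_blur(image, s))
  dogs <- lapply(seq_len(length(gs) - 1), function(i) gs[[i + 1]] - gs[[i]])
  cand <- cpp_dog_extrema(dogs, config$dog_thresh, border = 8L)
  desc_dim <- if (config$descriptor == "grad_hist") 128L else config$patch_n^2
  empty <- structure(list(keypoints = matrix(numeric(), 0, 4,
                                             dimnames = list(NULL, c("x", "y", "scale", "orientation"))),
                          response = numeric(), descriptors = matrix(numeric(), 0, desc_dim),
                          frame_index = as.integer(frame_index)),
                     class = "cm_features")
  if (nrow(cand) == 0) return(empty)

  # sub-pixel refinement: 2D quadratic fit on the extremum's DoG layer
  refine <- function(ci) {
    x <- cand[ci, 1]; y <- cand[ci, 2]; l <- cand[ci, 3]
    d <- dogs[[l]]
    r <- y + 1; c <- x + 1
    dx <- 0.5 * (d[r, c + 1] - d[r, c - 1])
    dy <- 0.5 * (d[r + 1, c] - d[r - 1, c])
    dxx <- d[r, c + 1] - 2 * d[r, c] + d[r, c - 1]
    dyy <- d[r + 1, c] - 2 * d[r, c] + d[r - 1, c]
    dxy <- 0.25 * (d[r + 1, c + 1] - d[r + 1, c - 1] - d[r - 1, c + 1] + d[r - 1, c - 1])
    det <- dxx * dyy - dxy^2
    off <- if (abs(det) > 1e-12) {
      c(-(dyy * dx - dxy * dy), -(dxx * dy - dxy * dx)) / det
    } else c(0, 0)
    off <- pmin(pmax(off, -0.6), 0.6)
    # suppress strong edge responses (one principal curvature ~ 0)
    edge_ok <- det > 0 || abs(det) / (dxx + dyy + 1e-12)^2 > 0.01
    c(x + off[1], y + off[2], edge_ok)
  }
  ref <- t(vapply(seq_len(nrow(cand)), refine, numeric(3)))
  scl <- sigmas[cand[, 3] + 1]  # scale of the DoG layer's finer Gaussian
  keep <- ref[, 3] > 0 &
    ref[, 1] >= 4 & ref[, 1] <= w - 5 & ref[, 2] >= 4 & ref[, 2] <= h - 5
  if (!is.null(mask)) {
    mi <- cbind(pmin(pmax(round(ref[, 2]) + 1, 1), h),
                pmin(pmax(round(ref[, 1]) + 1, 1), w))
    margin <- ceiling(scl * config$patch_spacing * config$patch_n / 2)
    inside <- mask[mi]
    # require the descriptor footprint to stay roughly in the valid field
    for (dxy in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      mj <- cbind(pmin(pmax(mi[, 1] + dxy[2] * margin, 1), h),
                  pmin(pmax(mi[, 2] + dxy[1] * margin, 1), w))
      inside <- inside & mask[mj]
    }
    keep <- keep & inside
  }
  if (!any(keep)) return(empty)
  cand <- cand[keep, , drop = FALSE]
  ref <- ref[keep, , drop = FALSE]
  scl <- scl[keep]
  resp <- abs(cand[, 4])
  ord <- order(resp, decreasing = TRUE)
  ord <- ord[seq_len(min(length(ord), config$max_keypoints))]
  xy <- ref[ord, 1:2, drop = FALSE]
  scl <- scl[ord]
  resp <- resp[ord]
  lay <- cand[ord, 3]
  # orientation and descriptor are computed on the Gaussian level nearest
  # the keypoint scale, which makes them scale-covariant
  theta <- numeric(length(ord))
  desc <- matrix(0, length(ord), desc_dim)
  desc_fun <- if (config$descriptor == "grad_hist") cpp_grad_descriptors else cpp_patch_descriptors
  desc_n <- if (config$descriptor == "grad_hist") 16L else config$patch_n
  for (l in sort(unique(lay))) {
    sel <- which(lay == l)
    g <- gs[[l]]
    kp3 <- cbind(xy[sel, 1], xy[sel, 2], scl[sel])
    th <- cpp_orientations(g, kp3)
    theta[sel] <- th
    desc[sel, ] <- desc_fun(g, cbind(kp3, th), desc_n, config$patch_spacing)
  }
  kp <- cbind(x = xy[, 1], y = xy[, 2], scale = scl, orientation = theta)
  structure(list(keypoints = kp, response = resp, descriptors = desc,
                 frame_index = as.integer(frame_index)),
            class = "cm_features")
}

#' @export
print.cm_features <- function(x, ...) {
  cat(sprintf("<cm_features frame %d: %d keypoints, %d-d descriptors>\n",
              x$frame_index, nrow(x$keypoints), ncol(x$descriptors)))
  invisible(x)
}

n_features <- function(fs) nrow(fs$keypoints)

#' Brute-force descriptor matching with ratio test
#'
#' Exhaustive nearest-neighbour search in descriptor space, filtered by the
#' Lowe ratio test (and optionally a mutual-nearest cross check). Inlier
#' flags are all `FALSE`; [estimate_affine()] sets them.
#'
#' @param a,b [detect_features()] results with equal descriptor dimension
#' @param config a [feature_config()]
#' @return object of class `cm_matches`: `pairs` (n x 2 index matrix into
#'   `a` and `b`), `distances`, `inlier_flags`
#' @export
match_features <- function(a, b, config = feature_config()) {
  empty <- structure(list(pairs = matrix(integer(), 0, 2), distances = numeric(),
                          inlier_flags = logical()), class = "cm_matches")
  if (n_features(a) == 0 || n_features(b) == 0) return(empty)
  if (ncol(a$descriptors) != ncol(b$descriptors)) {
    stop("descriptor dimensions differ", call. = FALSE)
  }
  # squared euclidean distances via the gram matrix
  d2 <- outer(rowSums(a$descriptors^2), rowSums(b$descriptors^2), "+") -
    2 * tcrossprod(a$descriptors, b$descriptors)
  d2[d2 < 0] <- 0
  nb <- ncol(d2)
  best <- max.col(-d2, ties.method = "first")
  bestd <- d2[cbind(seq_len(nrow(d2)), best)]
  if (nb >= 2) {
    d2b <- d2
    d2b[cbind(seq_len(nrow(d2)), best)] <- Inf
    second <- d2b[cbind(seq_len(nrow(d2)), max.col(-d2b, ties.method = "first"))]
    ok <- bestd <= (config$ratio^2) * second
  } else {
    ok <- rep(TRUE, nrow(d2))
  }
  if (config$cross_check && nrow(d2) >= 1) {
    back <- max.col(-t(d2), ties.method = "first")
    ok <- ok & (back[best] == seq_len(nrow(d2)))
  }
  idx <- which(ok)
  structure(list(pairs = cbind(idx, best[idx]), distances = sqrt(bestd[idx]),
                 inlier_flags = rep(FALSE, length(idx))),
            class = "cm_matches")
}

fit_similarity_ls <- function(src, dst) {
  # x' = a x - b y + tx ; y' = b x + a y + ty  (linear least squares)
  n <- nrow(src)
  A <- rbind(cbind(src[, 1], -src[, 2], 1, 0),
             cbind(src[, 2], src[, 1], 0, 1))
  rhs <- c(dst[, 1], dst[, 2])
  p <- tryCatch(qr.solve(A, rhs), error = function(e) NULL)
  if (is.null(p)) return(NULL)
  matrix(c(p[1], -p[2], p[3], p[2], p[1], p[4]), 2, 3, byrow = TRUE)
}

fit_affine_ls <- function(src, dst) {
  A <- cbind(src, 1)
  p <- tryCatch(qr.solve(A, dst), error = function(e) NULL)
  if (is.null(p)) return(NULL)
  t(p)[, c(1, 2, 3), drop = FALSE]
}

#' Robust transform estimation between two matched frames
#'
#' RANSAC over the candidate matches followed by a least-squares refit on
#' the inlier set. The per-frame feature gate (at least `min_inliers`
#' features in each frame) and the final inlier minimum both mirror the
#' six-feature rule of the stitching flowchart; failing either returns a
#' typed failure so the caller can fall back to the previous transform.
#'
#' @param matches a [match_features()] result
#' @param a,b the corresponding feature sets; the returned transform maps
#'   `a`-frame pixel coordinates into `b`-frame coordinates
#' @param config a [feature_config()]
#' @return object of class `cm_transform` (fields `matrix`, `source_index`,
#'   `target_index`, `provenance`, `inlier_count`) or a [cm_failure()]
#' @export
estimate_affine <- function(matches, a, b, config = feature_config()) {
  gate <- config$ransac$min_inliers
  if (n_features(a) < gate || n_features(b) < gate) {
    return(cm_failure("feature_gate", n_a = n_features(a), n_b = n_features(b)))
  }
  np <- nrow(matches$pairs)
  if (np < gate) {
    return(cm_failure("too_few_matches", n_matches = np))
  }
  src <- a$keypoints[matches$pairs[, 1], 1:2, drop = FALSE]
  dst <- b$keypoints[matches$pairs[, 2], 1:2, drop = FALSE]
  m <- if (config$model == "similarity") 2L else 3L
  fit_fun <- if (config$model == "similarity") fit_similarity_ls else fit_affine_ls
  th2 <- config$ransac$threshold_px^2

  res <- withr::with_seed(as.integer(config$ransac$seed), {
    best_inl <- NULL
    best_n <- -1L
    iters <- config$ransac$max_iters
    it <- 0L
    while (it < iters) {
      it <- it + 1L
      s <- sample.int(np, m)
      if (m == 2L && sum((src[s[1], ] - src[s[2], ])^2) < 4) next
      tf <- fit_fun(src[s, , drop = FALSE], dst[s, , drop = FALSE])
      if (is.null(tf) || !all(is.finite(tf))) next
      sc <- sqrt(abs(tf_det(tf)))
      if (sc < config$scale_range[1] || sc > config$scale_range[2]) next
      pr <- tf_apply(tf, src)
      err2 <- rowSums((pr - dst)^2)
      inl <- err2 <= th2
      ni <- sum(inl)
      if (ni > best_n) {
        best_n <- ni
        best_inl <- inl
        w <- ni / np
        if (w > 0) {
          need <- log(1 - config$ransac$confidence) / log(max(1e-12, 1 - w^m))
          iters <- min(iters, ceiling(need))
        }
      }
    }
    list(inl = best_inl, n = best_n)
  })

  if (is.null(res$inl) || res$n < config$ransac$min_inliers) {
    return(cm_failure("too_few_inliers", n_inliers = max(res$n, 0L), n_matches = np))
  }
  tf <- fit_fun(src[res$inl, , drop = FALSE], dst[res$inl, , drop = FALSE])
  if (is.null(tf) || !all(is.finite(tf)) || abs(tf_det(tf)) < 1e-9) {
    return(cm_failure("degenerate_fit"))
  }
  sc <- sqrt(abs(tf_det(tf)))
  if (sc < config$scale_range[1] || sc > config$scale_range[2]) {
    return(cm_failure("implausible_scale", scale = sc))
  }
  # staged polish: re-select inliers and refit at decreasing thresholds,
  # ending with the best-localised correspondences only
  inl <- res$inl
  for (th in c(config$ransac$threshold_px, config$refine_thresholds)) {
    sel <- rowSums((tf_apply(tf, src) - dst)^2) <= th^2
    if (sum(sel) < config$ransac$min_inliers) break
    tf2 <- fit_fun(src[sel, , drop = FALSE], dst[sel, , drop = FALSE])
    if (is.null(tf2) || !all(is.finite(tf2)) || abs(tf_det(tf2)) < 1e-9) break
    tf <- tf2
    inl <- sel
  }
  matches$inlier_flags <- as.logical(inl)
  structure(list(matrix = tf, source_index = a$frame_index,
                 target_index = b$frame_index, provenance = "estimated",
                 inlier_count = sum(inl), matches = matches,
                 inlier_src = src[inl, , drop = FALSE],
                 inlier_dst = dst[inl, , drop = FALSE]),
            class = "cm_transform")
}

#' @export
print.cm_transform <- function(x, ...) {
  p <- tf_decompose(x$matrix)
  cat(sprintf("<cm_transform %d->%d (%s): t=(%.2f, %.2f) rot=%.2f deg scale=%.4f, %d inliers>\n",
              x$source_index, x$target_index, x$provenance, p$tx, p$ty,
              p$theta * 180 / pi, p$scale, x$inlier_count))
  invisible(x)
}

# Estimate a -> b from two feature sets, optionally averaging with the
# inverse of the b -> a estimate (parameter-wise, in similarity space).
# Direction-dependent keypoint localisation bias largely cancels. When the
# two images are supplied, inlier correspondences are re-localised by
# warp-compensated Lucas-Kanade before the final fit.
estimate_pair <- function(fsa, fsb, config = feature_config(),
                          img_a = NULL, img_b = NULL) {
  est <- estimate_affine(match_features(fsa, fsb, config), fsa, fsb, config)
  if (is_failure(est)) return(est)
  if (isTRUE(config$symmetric)) {
    back <- estimate_affine(match_features(fsb, fsa, config), fsb, fsa, config)
    if (!is_failure(back)) {
      tf <- est$matrix
      est$matrix <- tf_compose(tf, tf_frac(tf_compose(tf_invert(tf),
                                                      tf_invert(back$matrix)), 0.5))
    }
  }
  if (isTRUE(config$lk_refine) && !is.null(img_a) && !is.null(img_b)) {
    est <- refine_transform(est, img_a, img_b, config)
  }
  est
}

#' Subpixel refinement of an estimated transform
#'
#' Re-localises the inlier correspondences of an accepted transform by
#' warp-compensated, translation-only Lucas-Kanade alignment of small image
#' patches, then refits the motion model on the refined correspondences.
#' Points whose alignment diverges or whose photometric residual stays high
#' are dropped from the refit.
#'
#' @param est a successful [estimate_affine()] result
#' @param img_a,img_b the two images the transform connects (`est` maps
#'   `img_a` coordinates into `img_b` coordinates)
#' @param config a [feature_config()]
#' @return `est` with its `matrix` refined (unchanged if refinement finds
#'   too few stable points)
#' @export
refine_transform <- function(est, img_a, img_b, config = feature_config()) {
  pts <- est$inlier_src
  if (is.null(pts) || nrow(pts) < config$ransac$min_inliers) return(est)
  r <- cpp_lk_refine(img_a, img_b, pts, est$matrix,
                     config$lk_half_win, config$lk_iters)
  ok <- r$rms >= 0 & r$rms < 0.12
  if (sum(ok) < config$ransac$min_inliers) return(est)
  fit_fun <- if (config$model == "similarity") fit_similarity_ls else fit_affine_ls
  tf <- fit_fun(pts[ok, , drop = FALSE], r$pts[ok, , drop = FALSE])
  if (is.null(tf) || !all(is.finite(tf)) || abs(tf_det(tf)) < 1e-9) return(est)
  # guard against pathological drift of the photometric alignment
  if (max(abs(tf - est$matrix)) > 3) return(est)
  est$matrix <- tf
  est
}

# Convenience: full detect -> match -> estimate between two images.
register_pair <- function(img_a, img_b, config = feature_config(),
                          mask_a = NULL, mask_b = NULL) {
  fa <- detect_features(img_a, mask_a, config, frame_index = 0L)
  fb <- detect_features(img_b, mask_b, config, frame_index = 1L)
  estimate_pair(fa, fb, config, img_a = img_a, img_b = img_b)
}
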