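# Pinhole camera calibration from planar checkerboard views (planar
# calibration: per-view homographies give a closed-form intrinsic estimate,
# refined jointly with per-view extrinsics and a 5-coefficient
# radial/tangential distortion model by minimizing the RMS reprojection
# error), plus frame undistortion. Only intrinsics + distortion are
# persisted; stitching needs nothing else.

#' Construct a camera model
#'
#' Pinhole intrinsics plus the standard 5-coefficient distortion vector
#' `(k1, k2, p1, p2, k3)`.
#'
#' @param fx,fy focal lengths, pixels (positive)
#' @param cx,cy principal point, pixels (inside the image)
#' @param dist numeric length-5 distortion coefficients
#' @param rms RMS reprojection error of the calibration, pixels
#' @param image_size `c(width, height)`, pixels
#' @return an object of class `cm_camera`
#' @export
camera_model <- function(fx, fy, cx, cy, dist = rep(0, 5), rms = 0,
                         image_size) {
  if (fx <= 0 || fy <= 0) stop("focal lengths must be positive", call. = FALSE)
  if (cx < 0 || cy < 0 || cx > image_size[1] - 1 || cy > image_size[2] - 1) {
    stop("principal point outside image bounds", call. = FALSE)
  }
  if (length(dist) != 5) stop("dist must have 5 coefficients", call. = FALSE)
  if (rms < 0) stop("rms must be >= 0", call. = FALSE)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy, dist = as.numeric(dist),
                 rms = rms, image_size = as.integer(image_size)),
            class = "cm_camera")
}

#' @export
print.cm_camera <- function(x, ...) {
  cat(sprintf("<cm_camera %dx%d: f=(%.1f, %.1f) c=(%.1f, %.1f) k1=%.4f rms=%.3f px>\n",
              x$image_size[1], x$image_size[2], x$fx, x$fy, x$cx, x$cy,
              x$dist[1], x$rms))
  invisible(x)
}

# --- rotation helpers -------------------------------------------------------

rodrigues_to_matrix <- function(rvec) {
  th <- sqrt(sum(rvec^2))
  if (th < 1e-12) return(diag(3))
  k <- rvec / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

matrix_to_rodrigues <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  th <- acos(ct)
  if (th < 1e-8) return(c(0, 0, 0))
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(th))
  ax * th
}

# --- distortion and projection ---------------------------------------------

distort_normalized <- function(xu, yu, dist) {
  k1 <- dist[1]; k2 <- dist[2]; p1 <- dist[3]; p2 <- dist[4]; k3 <- dist[5]
  r2 <- xu^2 + yu^2
  radial <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
  list(x = xu * radial + 2 * p1 * xu * yu + p2 * (r2 + 2 * xu^2),
       y = yu * radial + p1 * (r2 + 2 * yu^2) + 2 * p2 * xu * yu)
}

# Invert the distortion model by fixed-point iteration.
undistort_normalized <- function(xd, yd, dist, iters = 10) {
  xu <- xd; yu <- yd
  k1 <- dist[1]; k2 <- dist[2]; p1 <- dist[3]; p2 <- dist[4]; k3 <- dist[5]
  for (i in seq_len(iters)) {
    r2 <- xu^2 + yu^2
    radial <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
    xu <- (xd - (2 * p1 * xu * yu + p2 * (r2 + 2 * xu^2))) / radial
    yu <- (yd - (p1 * (r2 + 2 * yu^2) + 2 * p2 * xu * yu)) / radial
  }
  list(x = xu, y = yu)
}

# Project 3D world points through extrinsics + a camera model (or an
# equivalent parameter list with fields fx, fy, cx, cy, dist).
project_points <- function(world, R, tvec, model) {
  pc <- world %*% t(R)
  pc <- sweep(pc, 2, tvec, "+")
  xu <- pc[, 1] / pc[, 3]
  yu <- pc[, 2] / pc[, 3]
  d <- distort_normalized(xu, yu, model$dist)
  cbind(model$fx * d$x + model$cx, model$fy * d$y + model$cy)
}

# --- checkerboard detection -------------------------------------------------

# Subpixel X-corner refinement (gradient orthogonality): iteratively solve
# sum(G p) q = sum(G p p) over a window, the classic saddle refinement.
refine_corner_subpix <- function(gx, gy, x, y, win = 5, iters = 8) {
  h <- nrow(gx); w <- ncol(gx)
  for (it in seq_len(iters)) {
    xi <- round(x); yi <- round(y)
    if (xi < win + 1 || yi < win + 1 || xi > w - win - 2 || yi > h - win - 2) break
    rows <- (yi - win):(yi + win) + 1
    cols <- (xi - win):(xi + win) + 1
    GX <- gx[rows, cols]; GY <- gy[rows, cols]
    px <- matrix((xi - win):(xi + win), 2 * win + 1, 2 * win + 1, byrow = TRUE)
    py <- matrix((yi - win):(yi + win), 2 * win + 1, 2 * win + 1)
    wgt <- exp(-((px - x)^2 + (py - y)^2) / (2 * (0.6 * win)^2))
    a <- sum(wgt * GX * GX); b <- sum(wgt * GX * GY); c <- sum(wgt * GY * GY)
    bx <- sum(wgt * (GX * GX * px + GX * GY * py))
    by <- sum(wgt * (GX * GY * px + GY * GY * py))
    det <- a * c - b * b
    if (abs(det) < 1e-12) break
    nx <- (c * bx - b * by) / det
    ny <- (a * by - b * bx) / det
    if (!is.finite(nx) || !is.finite(ny)) break
    shift <- sqrt((nx - x)^2 + (ny - y)^2)
    x <- nx; y <- ny
    if (shift < 1e-4) break
  }
  c(x, y)
}

# Homography by normalized DLT from >= 4 correspondences.
fit_homography <- function(src, dst) {
  norm_pts <- function(p) {
    mu <- colMeans(p)
    sd <- mean(sqrt(rowSums(sweep(p, 2, mu)^2)))
    s <- sqrt(2) / max(sd, 1e-12)
    Tm <- matrix(c(s, 0, -s * mu[1], 0, s, -s * mu[2], 0, 0, 1), 3, 3, byrow = TRUE)
    list(T = Tm, p = cbind(s * (p[, 1] - mu[1]), s * (p[, 2] - mu[2])))
  }
  ns <- norm_pts(src); nd <- norm_pts(dst)
  s <- ns$p; d <- nd$p
  n <- nrow(s)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    X <- c(s[i, 1], s[i, 2], 1)
    A[2 * i - 1, ] <- c(-X, 0, 0, 0, d[i, 1] * X)
    A[2 * i, ] <- c(0, 0, 0, -X, d[i, 2] * X)
  }
  hvec <- svd(A, nu = 0, nv = 9)$v[, 9]
  H <- matrix(hvec, 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% H %*% ns$T
  H / H[3, 3]
}

apply_homography <- function(H, pts) {
  p <- cbind(pts, 1) %*% t(H)
  cbind(p[, 1] / p[, 3], p[, 2] / p[, 3])
}

#' Detect an inner-corner checkerboard grid in an image
#'
#' Finds the saddle-point (X-junction) corners of a planar checkerboard via
#' a Hessian-determinant response, refines them to sub-pixel precision, and
#' orders them row-major along the board axes by fitting a board-to-image
#' homography. Failure to find the board is a value ([cm_failure()]), not an
#' error.
#'
#' @param image numeric matrix in `[0, 1]`
#' @param pattern_size `c(cols, rows)` of inner corners
#' @return object of class `cm_checkerboard` (fields `corners` (n x 2,
#'   row-major from the board's top-left as detected), `pattern_size`) or a
#'   [cm_failure()]
#' @export
detect_checkerboard <- function(image, pattern_size = c(5, 7)) {
  if (!is.matrix(image) || min(dim(image)) < 16) {
    stop("degenerate image", call. = FALSE)
  }
  cols <- pattern_size[1]; rows <- pattern_size[2]
  n_need <- cols * rows
  g <- cpp_gauss_blur(image, 2)
  h <- nrow(g); w <- ncol(g)
  # Hessian by central differences; saddles have strongly negative det(H)
  shift <- function(m, dy, dx) {
    ys <- pmin(pmax(seq_len(h) + dy, 1), h)
    xs <- pmin(pmax(seq_len(w) + dx, 1), w)
    m[ys, xs]
  }
  ixx <- shift(g, 0, 1) - 2 * g + shift(g, 0, -1)
  iyy <- shift(g, 1, 0) - 2 * g + shift(g, -1, 0)
  ixy <- (shift(g, 1, 1) - shift(g, 1, -1) - shift(g, -1, 1) + shift(g, -1, -1)) / 4
  resp <- -(ixx * iyy - ixy^2)
  resp[1:4, ] <- 0; resp[(h - 3):h, ] <- 0
  resp[, 1:4] <- 0; resp[, (w - 3):w] <- 0
  mx <- max(resp)
  if (mx <= 1e-6) return(cm_failure("board_not_found", n_corners = 0L))
  # greedy non-maximum suppression
  cand <- which(resp > 0.12 * mx, arr.ind = TRUE)
  if (nrow(cand) == 0) return(cm_failure("board_not_found", n_corners = 0L))
  vals <- resp[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  # X-corner responses dominate board-boundary and background junctions, so
  # the strongest n_need non-maximum-suppressed peaks are the inner corners
  picked <- matrix(0, 0, 2)
  min_sep2 <- 36
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(picked) == 0 ||
        min((picked[, 1] - p[1])^2 + (picked[, 2] - p[2])^2) > min_sep2) {
      picked <- rbind(picked, p)
    }
    if (nrow(picked) == n_need) break
  }
  if (nrow(picked) < n_need) {
    return(cm_failure("board_not_found", n_corners = nrow(picked)))
  }
  pts <- cbind(x = picked[, 2] - 1, y = picked[, 1] - 1)  # 0-based (x, y)
  gx <- (shift(g, 0, 1) - shift(g, 0, -1)) / 2
  gy <- (shift(g, 1, 0) - shift(g, -1, 0)) / 2
  pts <- t(apply(pts, 1, function(p) refine_corner_subpix(gx, gy, p[1], p[2])))

  ordered <- order_board_corners(pts, cols, rows)
  if (is.null(ordered)) {
    return(cm_failure("board_not_found", n_corners = nrow(pts)))
  }
  structure(list(corners = ordered, pattern_size = pattern_size),
            class = "cm_checkerboard")
}

# Order detected corners row-major along the board axes: pick the 4 extreme
# grid corners from the convex hull (max-area quadrilateral), map the unit
# grid onto them by homography, assign detections to grid nodes by
# proximity, and refine the homography once to absorb lens distortion.
order_board_corners <- function(pts, cols, rows) {
  n_need <- cols * rows
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(hull) < 4) return(NULL)
  best <- NULL; best_area <- -1
  cmb <- utils::combn(hull, 4)
  for (j in seq_len(ncol(cmb))) {
    q <- cmb[, j]
    # keep hull order so the quad is convex
    q <- q[order(match(q, hull))]
    p <- pts[q, ]
    area <- abs(sum(p[, 1] * p[c(2, 3, 4, 1), 2] - p[c(2, 3, 4, 1), 1] * p[, 2])) / 2
    if (area > best_area) { best_area <- area; best <- q }
  }
  grid <- as.matrix(expand.grid(x = 0:(cols - 1), y = 0:(rows - 1)))
  grid <- grid[order(grid[, 2], grid[, 1]), ]
  quad_grid <- matrix(c(0, 0, cols - 1, 0, cols - 1, rows - 1, 0, rows - 1),
                      ncol = 2, byrow = TRUE)
  # try both traversal directions and the 4 cyclic labelings of the quad;
  # mirrored labelings are rejected by the orientation check (a front view
  # of the board preserves handedness), 90-degree ones by their misfit
  orientation_ok <- function(H) {
    p <- apply_homography(H, rbind(c(0, 0), c(1, 0), c(0, 1)))
    v1 <- p[2, ] - p[1, ]; v2 <- p[3, ] - p[1, ]
    (v1[1] * v2[2] - v1[2] * v2[1]) > 0
  }
  best_assign <- NULL; best_err <- Inf
  for (dir in 1:2) {
    quad <- if (dir == 1) best else rev(best)
    for (rot in 0:3) {
      idx <- ((seq_len(4) - 1 + rot) %% 4) + 1
      H <- tryCatch(fit_homography(quad_grid, pts[quad[idx], ]),
                    error = function(e) NULL)
      if (is.null(H) || !orientation_ok(H)) next
      pred <- apply_homography(H, grid)
      d2 <- outer(rowSums(pred^2), rowSums(pts^2), "+") - 2 * pred %*% t(pts)
      assign <- apply(d2, 1, which.min)
      if (length(unique(assign)) < n_need) next
      err <- sum(d2[cbind(seq_len(n_need), assign)])
      if (err < best_err) { best_err <- err; best_assign <- assign }
    }
  }
  if (is.null(best_assign)) return(NULL)
  # refine once with all correspondences (absorbs mild lens distortion)
  H2 <- tryCatch(fit_homography(grid, pts[best_assign, ]),
                 error = function(e) NULL)
  if (!is.null(H2)) {
    pred <- apply_homography(H2, grid)
    d2 <- outer(rowSums(pred^2), rowSums(pts^2), "+") - 2 * pred %*% t(pts)
    assign <- apply(d2, 1, which.min)
    if (length(unique(assign)) == n_need) best_assign <- assign
  }
  out <- pts[best_assign, , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

# --- calibration ------------------------------------------------------------

# Closed-form intrinsics from plane homographies (planar-calibration
# constraints on the image of the absolute conic, zero skew extraction).
zhang_init <- function(Hs) {
  vij <- function(H, i, j) {
    c(H[1, i] * H[1, j],
      H[1, i] * H[2, j] + H[2, i] * H[1, j],
      H[2, i] * H[2, j],
      H[3, i] * H[1, j] + H[1, i] * H[3, j],
      H[3, i] * H[2, j] + H[2, i] * H[3, j],
      H[3, i] * H[3, j])
  }
  V <- do.call(rbind, lapply(Hs, function(H) {
    rbind(vij(H, 1, 2), vij(H, 1, 1) - vij(H, 2, 2))
  }))
  b <- svd(V)$v[, 6]
  B11 <- b[1]; B12 <- b[2]; B22 <- b[3]; B13 <- b[4]; B23 <- b[5]; B33 <- b[6]
  cy <- (B12 * B13 - B11 * B23) / (B11 * B22 - B12^2)
  lambda <- B33 - (B13^2 + cy * (B12 * B13 - B11 * B23)) / B11
  fx <- sqrt(lambda / B11)
  fy <- sqrt(lambda * B11 / (B11 * B22 - B12^2))
  cx <- -B13 * fx^2 / lambda
  list(fx = fx, fy = fy, cx = cx, cy = cy)
}

extrinsics_from_homography <- function(H, K) {
  M <- solve(K) %*% H
  l <- (sqrt(sum(M[, 1]^2)) + sqrt(sum(M[, 2]^2))) / 2
  r1 <- M[, 1] / l; r2 <- M[, 2] / l
  t <- M[, 3] / l
  if (t[3] < 0) { r1 <- -r1; r2 <- -r2; t <- -t }
  r3 <- c(r1[2] * r2[3] - r1[3] * r2[2],
          r1[3] * r2[1] - r1[1] * r2[3],
          r1[1] * r2[2] - r1[2] * r2[1])
  R0 <- cbind(r1, r2, r3)
  sv <- svd(R0)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) R <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
  list(R = R, t = t)
}

#' Calibrate a camera from checkerboard detections
#'
#' Planar calibration: per-view homographies give closed-form initial
#' intrinsics and extrinsics, then all parameters (fx, fy, cx, cy, five
#' distortion coefficients, per-view rotation/translation) are refined
#' jointly by minimizing the total squared reprojection error.
#'
#' @param detections list of at least 3 [detect_checkerboard()] results
#'   (full corner sets) from views with varied poses
#' @param square_size physical square edge length (mm; only sets the world
#'   scale, intrinsics are unaffected)
#' @param image_size `c(width, height)` pixels
#' @param free_dist logical mask over `(k1, k2, p1, p2, k3)` selecting which
#'   distortion coefficients are estimated; fixed ones stay 0. `k3` is fixed
#'   by default: the sixth-order term is not identifiable from checkerboard
#'   views of ordinary field coverage and only soaks up corner noise
#' @return a [camera_model()] with `rms` set to the RMS reprojection error
#' @export
calibrate_camera <- function(detections, square_size = 10, image_size,
                             free_dist = c(TRUE, TRUE, TRUE, TRUE, FALSE)) {
  detections <- Filter(function(d) inherits(d, "cm_checkerboard"), detections)
  if (length(detections) < 3) {
    stop("calibration needs >= 3 full checkerboard detections", call. = FALSE)
  }
  ps <- detections[[1]]$pattern_size
  cols <- ps[1]; rows <- ps[2]
  grid <- as.matrix(expand.grid(x = (0:(cols - 1)) * square_size,
                                y = (0:(rows - 1)) * square_size))
  grid <- grid[order(grid[, 2], grid[, 1]), ]
  world <- cbind(grid, 0)
  Hs <- lapply(detections, function(d) fit_homography(grid, d$corners))
  # conditioning: identical poses give (near-)identical homographies and the
  # intrinsic constraints become rank-deficient
  Hflat <- do.call(rbind, lapply(Hs, function(H) as.vector(H / H[3, 3])))
  if (max(apply(Hflat, 2, stats::sd)) < 1e-6) {
    stop("degenerate calibration geometry: all views have identical poses",
         call. = FALSE)
  }
  init <- tryCatch(zhang_init(Hs), error = function(e) NULL)
  if (is.null(init) || !all(is.finite(unlist(init))) ||
      init$fx <= 0 || init$fy <= 0) {
    stop("degenerate calibration geometry (views too similar?)", call. = FALSE)
  }
  K <- matrix(c(init$fx, 0, init$cx, 0, init$fy, init$cy, 0, 0, 1), 3, 3,
              byrow = TRUE)
  ext <- lapply(Hs, extrinsics_from_homography, K = K)
  nv <- length(detections)
  npts <- nrow(world)
  n_obs <- nv * npts
  # joint Levenberg-Marquardt over intrinsics + distortion + per-view
  # extrinsics. The numeric Jacobian exploits sparsity: an extrinsic
  # parameter only touches its own view's residuals.
  p <- c(init$fx, init$fy, init$cx, init$cy, rep(0, 5),
         unlist(lapply(ext, function(e) c(matrix_to_rodrigues(e$R), e$t))))
  view_res <- function(intr, q, corners) {
    mod <- list(fx = intr[1], fy = intr[2], cx = intr[3], cy = intr[4],
                dist = intr[5:9])
    pr <- project_points(world, rodrigues_to_matrix(q[1:3]), q[4:6], mod)
    as.numeric(pr - corners)
  }
  residuals_all <- function(p) {
    unlist(lapply(seq_len(nv), function(v) {
      view_res(p[1:9], p[9 + (v - 1) * 6 + 1:6], detections[[v]]$corners)
    }))
  }
  np <- length(p)
  free <- c(rep(TRUE, 4), as.logical(free_dist), rep(TRUE, np - 9))
  r <- residuals_all(p)
  cost <- sum(r^2)
  lambda <- 1e-3
  for (it in seq_len(60)) {
    J <- matrix(0, 2 * n_obs, np)
    step <- pmax(1e-6, 1e-6 * abs(p))
    for (j in which(free[1:9])) {
      pj <- p; pj[j] <- pj[j] + step[j]
      J[, j] <- (residuals_all(pj) - r) / step[j]
    }
    for (v in seq_len(nv)) {
      rows <- (v - 1) * 2 * npts + seq_len(2 * npts)
      q <- p[9 + (v - 1) * 6 + 1:6]
      rv <- r[rows]
      for (k in 1:6) {
        qk <- q; qk[k] <- qk[k] + step[9 + (v - 1) * 6 + k]
        J[rows, 9 + (v - 1) * 6 + k] <-
          (view_res(p[1:9], qk, detections[[v]]$corners) - rv) /
          step[9 + (v - 1) * 6 + k]
      }
    }
    J <- J[, free, drop = FALSE]
    JtJ <- crossprod(J)
    g <- crossprod(J, r)
    improved <- FALSE
    for (try in seq_len(8)) {
      H <- JtJ + lambda * diag(diag(JtJ) + 1e-12)
      delta <- tryCatch(solve(H, -g), error = function(e) NULL)
      if (is.null(delta)) { lambda <- lambda * 10; next }
      p_new <- p
      p_new[free] <- p_new[free] + as.numeric(delta)
      r_new <- residuals_all(p_new)
      cost_new <- sum(r_new^2)
      if (is.finite(cost_new) && cost_new < cost) {
        rel <- (cost - cost_new) / max(cost, 1e-12)
        p <- p_new; r <- r_new; cost <- cost_new
        lambda <- max(lambda / 10, 1e-10)
        improved <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!improved || (exists("rel") && rel < 1e-10)) break
  }
  rms <- sqrt(cost / n_obs)
  camera_model(fx = p[1], fy = p[2], cx = p[3], cy = p[4], dist = p[5:9],
               rms = rms, image_size = image_size)
}

#' Undistort an image with a camera model
#'
#' Backward mapping: each output (undistorted) pixel samples the source
#' image at its forward-distorted position, bilinear interpolation;
#' out-of-source pixels are zero and excluded from the returned validity
#' mask. Deterministic, same output size as input.
#'
#' @param image numeric matrix matching `model$image_size`
#' @param model a [camera_model()]
#' @return list with `pixels` and `valid`
#' @export
undistort <- function(image, model) {
  stopifnot(inherits(model, "cm_camera"))
  h <- nrow(image); w <- ncol(image)
  if (w != model$image_size[1] || h != model$image_size[2]) {
    stop("image size does not match the camera model", call. = FALSE)
  }
  if (all(model$dist == 0)) {
    return(list(pixels = image, valid = matrix(TRUE, h, w)))
  }
  xs <- matrix(0:(w - 1), h, w, byrow = TRUE)
  ys <- matrix(0:(h - 1), h, w)
  xu <- (xs - model$cx) / model$fx
  yu <- (ys - model$cy) / model$fy
  d <- distort_normalized(xu, yu, model$dist)
  remap_image(image, model$fx * d$x + model$cx, model$fy * d$y + model$cy)
}

#' Undistort a Frame, updating its validity mask
#' @param frame a [new_frame()] object
#' @param model a [camera_model()]
#' @return a [new_frame()] object
#' @export
undistort_frame <- function(frame, model) {
  res <- undistort(frame$pixels, model)
  mask <- frame_mask_or_full(frame) & res$valid
  new_frame(res$pixels, index = frame$index, mask = mask,
            source_time = frame$source_time)
}

#' Save / load a camera model as JSON
#' @param model a [camera_model()]
#' @param path file path
#' @return `load_camera` returns a [camera_model()]
#' @export
save_camera <- function(model, path) {
  jsonlite::write_json(list(fx = model$fx, fy = model$fy, cx = model$cx,
                            cy = model$cy, dist = model$dist, rms = model$rms,
                            width = model$image_size[1],
                            height = model$image_size[2]),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_camera
#' @param path file path
#' @export
load_camera <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  camera_model(j$fx, j$fy, j$cx, j$cy, j$dist, j$rms, c(j$width, j$height))
}

# Max point-to-fitted-line residual over groups of nominally collinear
# points (board rows/columns); the straightness oracle for undistortion.
collinearity_residual <- function(pts, groups) {
  max(vapply(split(seq_len(nrow(pts)), groups), function(idx) {
    p <- pts[idx, , drop = FALSE]
    pc <- sweep(p, 2, colMeans(p))
    v <- svd(pc)$v[, 1]
    max(abs(pc[, 1] * v[2] - pc[, 2] * v[1]))
  }, numeric(1)))
}
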