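#' @useDynLib cystomap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# 2x3 affine transforms act on homogeneous column vectors (x, y, 1):
#   [x'] = [a b tx] [x y 1]^T
#   [y']   [c d ty]
# Pixel coordinates are 0-based, origin top-left, x rightward, y downward.

#' Identity 2x3 transform
#' @return a 2x3 matrix
#' @export
tf_identity <- function() {
  matrix(c(1, 0, 0, 0, 1, 0), nrow = 2, byrow = TRUE)
}

#' Pure translation transform
#' @param tx,ty translation in pixels
#' @return a 2x3 matrix
#' @export
tf_translation <- function(tx, ty) {
  matrix(c(1, 0, tx, 0, 1, ty), nrow = 2, byrow = TRUE)
}

#' Similarity transform from parameters
#'
#' Builds the 4-DOF similarity (rotation `theta`, uniform `scale`,
#' then translation) used as the default inter-frame motion model.
#'
#' @param tx,ty translation, pixels
#' @param theta rotation, radians (positive = x-axis toward y-axis,
#'   i.e. clockwise on screen with y pointing down)
#' @param scale uniform scale factor
#' @return a 2x3 matrix
#' @export
tf_similarity <- function(tx = 0, ty = 0, theta = 0, scale = 1) {
  a <- scale * cos(theta)
  b <- scale * sin(theta)
  matrix(c(a, -b, tx, b, a, ty), nrow = 2, byrow = TRUE)
}

tf_check <- function(m, arg = "transform") {
  if (!is.matrix(m) || !all(dim(m) == c(2, 3)) || !all(is.finite(m))) {
    stop(sprintf("%s must be a finite 2x3 matrix", arg), call. = FALSE)
  }
  invisible(m)
}

tf_det <- function(m) m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]

to3 <- function(m) rbind(m, c(0, 0, 1))

#' Compose two 2x3 transforms
#'
#' Returns the transform mapping `x` to `a(b(x))` (apply `b` first).
#'
#' @param a,b 2x3 matrices
#' @return a 2x3 matrix
#' @export
tf_compose <- function(a, b) {
  tf_check(a, "a"); tf_check(b, "b")
  (to3(a) %*% to3(b))[1:2, , drop = FALSE]
}

#' Invert a 2x3 transform
#' @param m 2x3 matrix with non-singular linear part
#' @return a 2x3 matrix
#' @export
tf_invert <- function(m) {
  tf_check(m)
  d <- tf_det(m)
  if (abs(d) < 1e-12) stop("transform linear part is singular", call. = FALSE)
  li <- matrix(c(m[2, 2], -m[1, 2], -m[2, 1], m[1, 1]), 2, 2, byrow = TRUE) / d
  cbind(li, -li %*% m[, 3])
}

#' Apply a 2x3 transform to points
#' @param m 2x3 matrix
#' @param pts n x 2 matrix of (x, y)
#' @return n x 2 matrix of transformed points
#' @export
tf_apply <- function(m, pts) {
  tf_check(m)
  pts <- rbind2cols(pts)
  cbind(m[1, 1] * pts[, 1] + m[1, 2] * pts[, 2] + m[1, 3],
        m[2, 1] * pts[, 1] + m[2, 2] * pts[, 2] + m[2, 3])
}

rbind2cols <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  pts
}

#' Decompose a similarity-like transform into parameters
#'
#' For a transform with (approximately) similarity structure, returns the
#' translation, the mean rotation angle and the scale `sqrt(|det|)`.
#'
#' @param m 2x3 matrix
#' @return list with `tx`, `ty`, `theta` (radians), `scale`
#' @export
tf_decompose <- function(m) {
  tf_check(m)
  list(tx = m[1, 3], ty = m[2, 3],
       theta = atan2(m[2, 1] - m[1, 2], m[1, 1] + m[2, 2]),
       scale = sqrt(abs(tf_det(m))))
}

#' Fractional similarity interpolation toward a transform
#'
#' Interpolates between the identity (`f = 0`) and `m` (`f = 1`)
#' parameter-wise in (tx, ty, theta, log scale). Used to distribute a
#' loop-closure residual along the intervening frame chain.
#'
#' @param m 2x3 similarity-like matrix
#' @param f fraction in `[0, 1]` (values outside are allowed and extrapolate)
#' @return a 2x3 matrix
#' @export
tf_frac <- function(m, f) {
  p <- tf_decompose(m)
  tf_similarity(tx = f * p$tx, ty = f * p$ty, theta = f * p$theta,
                scale = exp(f * log(p$scale)))
}

#' Corner coordinates of a w x h frame
#'
#' 0-based pixel-center corners, row-major order TL, TR, BR, BL.
#' @param w,h frame width and height in pixels
#' @return 4 x 2 matrix
#' @export
frame_corners <- function(w, h) {
  matrix(c(0, 0, w - 1, 0, w - 1, h - 1, 0, h - 1), ncol = 2, byrow = TRUE)
}

# Wrap degrees into (-180, 180]
wrap_deg <- function(d) {
  d <- (d + 180) %% 360 - 180
  d[d == -180] <- 180
  d
}
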