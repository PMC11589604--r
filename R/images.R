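# Image and Frame helpers. Images are numeric matrices in [0, 1],
# indexed mat[row, col] with pixel (x, y) at mat[y + 1, x + 1].

#' Construct a Frame
#'
#' A frame bundles one video image with its index and an optional validity
#' mask (the circular illuminated endoscope field; pixels outside it are
#' ignored by detection and compositing).
#'
#' @param pixels numeric matrix in `[0, 1]`
#' @param index integer frame index (0-based source position)
#' @param mask optional logical matrix, same shape as `pixels`
#' @param source_time optional timestamp, seconds
#' @return an object of class `cm_frame`
#' @export
new_frame <- function(pixels, index = 0L, mask = NULL, source_time = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric matrix", call. = FALSE)
  }
  if (!is.null(mask)) {
    if (!is.logical(mask) || !all(dim(mask) == dim(pixels))) {
      stop("mask must be a logical matrix matching pixels", call. = FALSE)
    }
  }
  structure(list(index = as.integer(index), pixels = pixels, mask = mask,
                 source_time = source_time),
            class = "cm_frame")
}

#' @export
print.cm_frame <- function(x, ...) {
  cat(sprintf("<cm_frame #%d  %dx%d px%s>\n", x$index,
              ncol(x$pixels), nrow(x$pixels),
              if (is.null(x$mask)) "" else sprintf(", mask %.0f%%",
                                                   100 * mean(x$mask))))
  invisible(x)
}

frame_mask_or_full <- function(frame) {
  if (is.null(frame$mask)) {
    matrix(TRUE, nrow(frame$pixels), ncol(frame$pixels))
  } else {
    frame$mask
  }
}

#' Circular field-of-view mask
#'
#' @param h,w mask dimensions
#' @param radius_frac radius as a fraction of `min(h, w) / 2`
#' @return logical matrix, `TRUE` inside the circle
#' @export
circular_mask <- function(h, w, radius_frac = 0.95) {
  cx <- (w - 1) / 2
  cy <- (h - 1) / 2
  r <- radius_frac * min(h, w) / 2
  xs <- matrix(0:(w - 1), h, w, byrow = TRUE)
  ys <- matrix(0:(h - 1), h, w)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

#' Resample an image at arbitrary coordinates
#'
#' Bilinear inverse-map sampling: output pixel `i` takes the value of
#' `src` at `(xmap[i], ymap[i])` (0-based coordinates). Out-of-source
#' samples get `fill` and are marked invalid.
#'
#' @param src source image matrix
#' @param xmap,ymap coordinate matrices defining the output grid
#' @param fill fill value for out-of-source samples
#' @return list with `pixels` (matrix) and `valid` (logical matrix)
#' @export
remap_image <- function(src, xmap, ymap, fill = 0) {
  stopifnot(all(dim(xmap) == dim(ymap)))
  cpp_remap(src, xmap, ymap, fill)
}

#' Warp an image by a 2x3 transform into a given output size
#'
#' `pose` maps output pixel coordinates to source coordinates
#' (inverse/backward warping).
#'
#' @param src source image
#' @param pose 2x3 transform output -> source
#' @param out_h,out_w output dimensions
#' @param fill fill value
#' @return list with `pixels` and `valid`
#' @export
warp_image <- function(src, pose, out_h, out_w, fill = 0) {
  tf_check(pose, "pose")
  xs <- matrix(0:(out_w - 1), out_h, out_w, byrow = TRUE)
  ys <- matrix(0:(out_h - 1), out_h, out_w)
  xmap <- pose[1, 1] * xs + pose[1, 2] * ys + pose[1, 3]
  ymap <- pose[2, 1] * xs + pose[2, 2] * ys + pose[2, 3]
  remap_image(src, xmap, ymap, fill)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)
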