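# Synthetic test substrate: vessel-textured phantom surfaces, scripted
# camera sweeps with ground-truth similarity poses, rendered frame
# sequences, and checkerboard calibration views. Everything is driven by
# explicit seeds so that identical inputs give byte-identical outputs.

#' Generate a vessel-textured phantom surface
#'
#' Draws branching, curvilinear vessel-like strokes over a mucosa-toned
#' background with smooth low-frequency shading, emulating the painted
#' vascular patterns of a bladder phantom. Contrast is chosen so that the
#' default feature detector finds well over the minimum six features in any
#' frame-sized crop (a verified property of the generator's own tests).
#'
#' @param seed integer RNG seed; identical seed + parameters give
#'   byte-identical textures
#' @param size `c(width, height)` in pixels, each at least 512
#' @param vessel_density vessel curves per megapixel
#' @return numeric matrix (height x width) in `[0, 1]`
#' @export
generate_texture <- function(seed = 1L, size = c(1024, 1024), vessel_density = 50) {
  size <- as.integer(size)
  if (length(size) != 2 || any(size < 512)) {
    stop("size must be c(width, height) with both >= 512", call. = FALSE)
  }
  w <- size[1]; h <- size[2]
  withr::with_seed(as.integer(seed), {
    # smooth background shading: coarse noise field upsampled bilinearly
    coarse <- matrix(stats::runif(24 * 24, -0.05, 0.05), 24, 24)
    sc <- tf_similarity(scale = 23 / max(w - 1, h - 1))
    bg <- 0.62 + warp_image(coarse, sc, h, w)$pixels
    tex <- bg
    n_curves <- max(0L, as.integer(round(vessel_density * w * h / 1e6)))
    draw_one <- function(x, y, heading, len, width, value, depth) {
      n_steps <- max(2L, as.integer(len))
      dh <- stats::rnorm(n_steps, 0, 0.06)
      hs <- heading + cumsum(dh)
      xs <- x + cumsum(cos(hs))
      ys <- y + cumsum(sin(hs))
      keep <- xs >= 1 & xs <= w - 2 & ys >= 1 & ys <= h - 2
      if (any(!keep)) {
        cut <- which(!keep)[1]
        if (cut < 3) return(invisible())
        xs <- xs[seq_len(cut - 1)]; ys <- ys[seq_len(cut - 1)]
        hs <- hs[seq_len(cut - 1)]
      }
      cpp_draw_curve(tex, xs, ys, width, value)
      # occasional branch from a point along the curve
      if (depth < 2 && stats::runif(1) < 0.4 && length(xs) > 20) {
        at <- sample(seq(10, length(xs) - 5), 1)
        side <- sample(c(-1, 1), 1)
        draw_one(xs[at], ys[at], hs[at] + side * stats::runif(1, 0.5, 1.1),
                 len * 0.5, width * 0.8, value, depth + 1)
      }
      invisible()
    }
    for (i in seq_len(n_curves)) {
      draw_one(stats::runif(1, 5, w - 6), stats::runif(1, 5, h - 6),
               stats::runif(1, 0, 2 * pi), stats::runif(1, 150, 450),
               stats::runif(1, 1.2, 3.0), stats::runif(1, 0.12, 0.38), 0)
    }
    cpp_gauss_blur(tex, 0.7)
  })
}

#' Generate a ground-truth camera sweep over a texture
#'
#' Produces a smooth sequence of frame-to-texture similarity poses along a
#' scripted pattern. Consecutive poses obey the smoothness bounds of a
#' hand-held sweep: translation at most 25\% of the frame width, rotation at
#' most 5 degrees per frame, scale within `[0.9, 1.1]`, and every frame
#' footprint stays inside the texture.
#'
#' @param pattern one of `"serpentine"` (rows swept alternately left/right),
#'   `"longitudinal"` (single top-to-bottom column) or `"rotational"`
#'   (in-place rotation sweep)
#' @param n_frames number of frames, at least 1
#' @param texture_size `c(width, height)` of the texture
#' @param frame_size `c(width, height)` of the rendered frames
#' @param seed RNG seed for the smooth wobble phases
#' @param n_rows serpentine row count
#' @param rot_amplitude_deg peak in-plane rotation wobble, degrees
#' @param scale_amplitude peak fractional zoom wobble
#' @param total_rotation_deg total sweep angle for `pattern = "rotational"`
#' @return list of 2x3 matrices mapping frame pixel coords to texture coords
#' @export
generate_trajectory <- function(pattern = c("serpentine", "longitudinal", "rotational"),
                                n_frames, texture_size = c(1024, 1024),
                                frame_size = c(256, 256), seed = 1L,
                                n_rows = 2L, rot_amplitude_deg = 3,
                                scale_amplitude = 0.03,
                                total_rotation_deg = 60) {
  pattern <- match.arg(pattern)
  n <- as.integer(n_frames)
  if (n < 1) stop("n_frames must be >= 1", call. = FALSE)
  tw <- texture_size[1]; th <- texture_size[2]
  fw <- frame_size[1]; fh <- frame_size[2]
  if (fw > tw || fh > th) stop("frame larger than texture", call. = FALSE)
  # keep footprints inside the texture allowing for rotation + zoom
  half_diag <- sqrt(fw^2 + fh^2) / 2 * (1 + scale_amplitude) + 4
  xlo <- half_diag; xhi <- tw - 1 - half_diag
  ylo <- half_diag; yhi <- th - 1 - half_diag
  if (xhi <= xlo || yhi <= ylo) stop("frame larger than texture", call. = FALSE)
  cx0 <- (tw - 1) / 2; cy0 <- (th - 1) / 2

  if (n == 1) {
    return(list(tf_compose(tf_translation(cx0, cy0),
                           tf_translation(-(fw - 1) / 2, -(fh - 1) / 2))))
  }

  withr::with_seed(as.integer(seed), {
    phase <- stats::runif(3, 0, 2 * pi)
    t01 <- seq(0, 1, length.out = n)
    if (pattern == "rotational") {
      centers <- cbind(rep(cx0, n), rep(cy0, n))
      thetas <- t01 * total_rotation_deg * pi / 180
      scales <- rep(1, n)
    } else {
      nr <- if (pattern == "longitudinal") 1L else max(1L, as.integer(n_rows))
      step_target <- 0.22 * fw
      row_gap <- if (nr > 1) min(0.5 * fh, (yhi - ylo) / (nr - 1)) else 0
      row_len <- ((n - 1) * step_target - (nr - 1) * row_gap) / nr
      row_len <- min(max(row_len, 0.3 * fw), xhi - xlo)
      x0 <- cx0 - row_len / 2
      ys <- cy0 - (nr - 1) * row_gap / 2 + (seq_len(nr) - 1) * row_gap
      # serpentine polyline through alternating rows
      verts <- do.call(rbind, lapply(seq_len(nr), function(r) {
        xs <- if (r %% 2 == 1) c(x0, x0 + row_len) else c(x0 + row_len, x0)
        rbind(c(xs[1], ys[r]), c(xs[2], ys[r]))
      }))
      if (pattern == "longitudinal") {
        span <- min((n - 1) * step_target, yhi - ylo)
        verts <- rbind(c(cx0, cy0 - span / 2), c(cx0, cy0 + span / 2))
      }
      seg <- diff(verts)
      seg_len <- sqrt(rowSums(seg^2))
      cum <- c(0, cumsum(seg_len))
      total <- cum[length(cum)]
      at <- t01 * total
      centers <- t(vapply(at, function(s) {
        k <- max(1, findInterval(s, cum, rightmost.closed = TRUE))
        k <- min(k, nrow(seg))
        f <- if (seg_len[k] > 0) (s - cum[k]) / seg_len[k] else 0
        verts[k, ] + f * seg[k, ]
      }, numeric(2)))
      # smooth lateral wobble, small enough to preserve overlap bounds
      centers[, 1] <- centers[, 1] + 2.5 * sin(2 * pi * t01 + phase[1])
      centers[, 2] <- centers[, 2] + 2.5 * sin(2 * pi * t01 * 1.7 + phase[2])
      thetas <- rot_amplitude_deg * pi / 180 * sin(2 * pi * t01 + phase[3])
      scales <- 1 + scale_amplitude * sin(4 * pi * t01 + phase[1])
    }
    centers[, 1] <- pmin(pmax(centers[, 1], xlo), xhi)
    centers[, 2] <- pmin(pmax(centers[, 2], ylo), yhi)
    lapply(seq_len(n), function(i) {
      tf_compose(tf_compose(tf_translation(centers[i, 1], centers[i, 2]),
                            tf_similarity(theta = thetas[i], scale = scales[i])),
                 tf_translation(-(fw - 1) / 2, -(fh - 1) / 2))
    })
  })
}

#' Assemble a synthetic scene
#'
#' Bundles a generated texture with a ground-truth trajectory and the render
#' parameters into one seeded, reproducible object.
#'
#' @inheritParams generate_texture
#' @inheritParams generate_trajectory
#' @param vignette render a circular endoscope field mask
#' @param noise_sd per-pixel Gaussian noise standard deviation (intensity
#'   units on `[0, 1]`; 0 disables)
#' @param ... passed on to [generate_trajectory()]
#' @return an object of class `cm_scene`
#' @export
synthetic_scene <- function(seed = 1L, pattern = "serpentine", n_frames = 25,
                            texture_size = c(1024, 1024), frame_size = c(256, 256),
                            vessel_density = 50, vignette = FALSE, noise_sd = 0,
                            ...) {
  seed <- as.integer(seed)
  texture <- generate_texture(seed, texture_size, vessel_density)
  poses <- generate_trajectory(pattern, n_frames, texture_size, frame_size,
                               seed = seed + 1000L, ...)
  structure(list(texture = texture, truth_poses = poses,
                 texture_size = texture_size, frame_size = frame_size,
                 vessel_density = vessel_density, pattern = pattern,
                 vignette = vignette, noise_sd = noise_sd, seed = seed),
            class = "cm_scene")
}

#' @export
print.cm_scene <- function(x, ...) {
  cat(sprintf("<cm_scene seed %d: %s sweep, %d frames %dx%d over %dx%d texture>\n",
              x$seed, x$pattern, length(x$truth_poses),
              x$frame_size[1], x$frame_size[2],
              x$texture_size[1], x$texture_size[2]))
  invisible(x)
}

#' Render the frames of a synthetic scene
#'
#' Samples each frame from the texture under its ground-truth pose with
#' bilinear interpolation, then optionally applies the circular vignette
#' mask and additive Gaussian noise.
#'
#' @param scene a [synthetic_scene()] object
#' @return list with `frames` (list of [new_frame()] objects) and
#'   `truth_poses` (list of 2x3 matrices, frame -> texture)
#' @export
render_frames <- function(scene) {
  stopifnot(inherits(scene, "cm_scene"))
  fw <- scene$frame_size[1]; fh <- scene$frame_size[2]
  mask <- if (scene$vignette) circular_mask(fh, fw) else NULL
  frames <- withr::with_seed(scene$seed + 2000L, {
    lapply(seq_along(scene$truth_poses), function(i) {
      pose <- scene$truth_poses[[i]]
      crn <- tf_apply(pose, frame_corners(fw, fh))
      if (any(crn[, 1] < 0 | crn[, 1] > scene$texture_size[1] - 1 |
              crn[, 2] < 0 | crn[, 2] > scene$texture_size[2] - 1)) {
        stop(sprintf("pose footprint of frame %d lies outside the texture", i - 1),
             call. = FALSE)
      }
      px <- warp_image(scene$texture, pose, fh, fw)$pixels
      if (scene$noise_sd > 0) {
        px <- clamp01(px + matrix(stats::rnorm(fh * fw, 0, scene$noise_sd), fh, fw))
      }
      if (!is.null(mask)) px[!mask] <- 0.02
      new_frame(px, index = i - 1L, mask = mask)
    })
  })
  list(frames = frames, truth_poses = scene$truth_poses)
}

#' Render synthetic checkerboard calibration views
#'
#' Renders a planar checkerboard under random plausible camera poses through
#' a known ("truth") camera model, including its lens distortion, and
#' returns the rendered images together with the exact projected positions
#' of the inner corners.
#'
#' @param truth_model a [camera_model()] to render through
#' @param n_views number of views, at least 3
#' @param seed RNG seed for the pose sampling
#' @param pattern_size `c(cols, rows)` of inner corners
#' @param square_mm physical square edge length, millimetres
#' @return list with `images` (list of matrices), `corners` (list of
#'   35 x 2 truth corner matrices, row-major from the board's top-left),
#'   `poses` (list of `list(R, t)`), plus the inputs
#' @export
generate_checkerboard_views <- function(truth_model, n_views = 20, seed = 1L,
                                        pattern_size = c(5, 7), square_mm = 10) {
  stopifnot(inherits(truth_model, "cm_camera"))
  if (n_views < 3) stop("n_views must be >= 3", call. = FALSE)
  cols <- pattern_size[1]; rows <- pattern_size[2]
  sq <- square_mm
  w <- truth_model$image_size[1]; h <- truth_model$image_size[2]
  # inner corners in board coordinates (mm), row-major from top-left
  grid <- expand.grid(x = (seq_len(cols) - 1) * sq, y = (seq_len(rows) - 1) * sq)
  inner <- as.matrix(grid[order(grid$y, grid$x), c("x", "y")])
  # outer board outline incl. the border squares, used for visibility checks
  outer <- matrix(c(-sq, -sq, cols * sq, -sq, cols * sq, rows * sq, -sq, rows * sq),
                  ncol = 2, byrow = TRUE)
  ctr <- c((cols - 1) * sq / 2, (rows - 1) * sq / 2, 0)

  withr::with_seed(as.integer(seed), {
    views <- vector("list", n_views)
    for (v in seq_len(n_views)) {
      repeat {
        ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
        ang <- stats::runif(1, 0.08, 0.5)
        R <- rodrigues_to_matrix(ax * ang)
        z <- stats::runif(1, 140, 260)
        # spread the board across the whole field of view: good calibration
        # practice places the target in the image corners too
        off_px <- c(stats::runif(1, -0.36, 0.36) * w,
                    stats::runif(1, -0.36, 0.36) * h)
        tvec <- c(off_px[1] * z / truth_model$fx, off_px[2] * z / truth_model$fy, z) -
          as.vector(R %*% ctr)
        crn <- project_points(cbind(outer, 0), R, tvec, truth_model)
        if (all(crn[, 1] > 12 & crn[, 1] < w - 13 & crn[, 2] > 12 & crn[, 2] < h - 13) &&
            (R %*% c(0, 0, 1))[3] > 0.5) break
      }
      img <- render_checkerboard(truth_model, R, tvec, cols, rows, sq)
      views[[v]] <- list(
        image = img,
        corners = project_points(cbind(inner, 0), R, tvec, truth_model),
        R = R, t = tvec)
    }
    list(images = lapply(views, `[[`, "image"),
         corners = lapply(views, `[[`, "corners"),
         poses = lapply(views, function(v) list(R = v$R, t = v$t)),
         pattern_size = pattern_size, square_mm = sq, model = truth_model)
  })
}

# Render one checkerboard view by inverse mapping each pixel through the
# lens model onto the board plane; 2x2 supersampling plus a light blur
# gives clean sub-pixel edges for corner detection.
render_checkerboard <- function(model, R, tvec, cols, rows, sq) {
  w <- model$image_size[1]; h <- model$image_size[2]
  Hpl <- cbind(R[, 1], R[, 2], tvec)       # board plane -> camera rays
  Hinv <- solve(Hpl)
  xs <- matrix(0:(w - 1), h, w, byrow = TRUE)
  ys <- matrix(0:(h - 1), h, w)
  acc <- matrix(0, h, w)
  for (off in list(c(-0.25, -0.25), c(0.25, -0.25), c(-0.25, 0.25), c(0.25, 0.25))) {
    xd <- (xs + off[1] - model$cx) / model$fx
    yd <- (ys + off[2] - model$cy) / model$fy
    und <- undistort_normalized(xd, yd, model$dist)
    denom <- Hinv[3, 1] * und$x + Hinv[3, 2] * und$y + Hinv[3, 3]
    X <- (Hinv[1, 1] * und$x + Hinv[1, 2] * und$y + Hinv[1, 3]) / denom
    Y <- (Hinv[2, 1] * und$x + Hinv[2, 2] * und$y + Hinv[2, 3]) / denom
    ix <- floor(X / sq); iy <- floor(Y / sq)
    on_board <- ix >= -1 & ix <= cols - 1 & iy >= -1 & iy <= rows - 1
    val <- ifelse(on_board, ifelse((ix + iy) %% 2 == 0, 0.1, 0.9), 0.5)
    acc <- acc + val
  }
  cpp_gauss_blur(acc / 4, 0.8)
}
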