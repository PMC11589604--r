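# Image/frame ingestion, map persistence and run manifests. Images travel
# as numeric matrices in [0, 1]; maps are persisted as PNG canvas + JSON
# poses/stats (versioned schema, row-major 6-element transforms).

POSE_SCHEMA_VERSION <- 1L
POSE_CONVENTION <- "row-major [a b tx c d ty]; 0-based pixel coords, x right, y down"

#' Read a grayscale image
#'
#' PNG and JPEG (luminance conversion for color inputs) plus plain PGM.
#'
#' @param path image file
#' @return numeric matrix in `[0, 1]`
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE)) {
      stop("jpeg package required for JPEG input", call. = FALSE)
    }
    img <- jpeg::readJPEG(path)
  } else if (ext == "pgm") {
    return(read_pgm(path))
  } else {
    stop(sprintf("unsupported image format '%s'", ext), call. = FALSE)
  }
  if (length(dim(img)) == 3) {
    if (dim(img)[3] >= 3) {
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  img
}

#' Write an image as PNG
#' @param img numeric matrix (grayscale) or H x W x 3 array (RGB) in `[0, 1]`
#' @param path output file
#' @export
write_image <- function(img, path) {
  png::writePNG(clamp01(img), path)
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, 1)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file", call. = FALSE)
  vals <- integer(0)
  hdr <- integer(0)
  while (length(hdr) < 3) {
    ln <- readLines(con, 1)
    ln <- sub("#.*", "", ln)
    hdr <- c(hdr, as.integer(strsplit(trimws(ln), "\\s+")[[1]]))
  }
  w <- hdr[1]; h <- hdr[2]; mx <- hdr[3]
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  } else {
    vals <- as.integer(readBin(con, "raw", w * h))
  }
  matrix(vals / mx, h, w, byrow = TRUE)
}

auto_field_mask <- function(img, thresh = 0.04) {
  cpp_gauss_blur(img, 2) > thresh
}

#' Read an ordered frame sequence from an image directory
#'
#' Files are taken in lexicographic order; `stride` subsamples them while
#' frame indices keep their source positions. An optional centered square
#' crop (the clinical preprocessing step) is applied before masking.
#'
#' @param path directory of PNG/JPEG/PGM files
#' @param stride keep every `stride`-th frame (>= 1)
#' @param crop optional side length of a centered square crop, pixels
#' @param mask `"none"` or `"auto"` (threshold the near-black border of the
#'   endoscope field)
#' @return list of [new_frame()] objects
#' @export
read_frames <- function(path, stride = 1L, crop = NULL, mask = c("none", "auto")) {
  mask <- match.arg(mask)
  if (!dir.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  if (stride < 1) stop("stride must be >= 1", call. = FALSE)
  files <- sort(list.files(path, pattern = "\\.(png|jpg|jpeg|pgm)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0) stop(sprintf("no images in '%s'", path), call. = FALSE)
  take <- seq(1, length(files), by = stride)
  lapply(take, function(i) {
    img <- read_image(files[i])
    if (!is.null(crop)) {
      if (crop > nrow(img) || crop > ncol(img)) {
        stop("crop larger than frame", call. = FALSE)
      }
      r0 <- floor((nrow(img) - crop) / 2)
      c0 <- floor((ncol(img) - crop) / 2)
      img <- img[r0 + seq_len(crop), c0 + seq_len(crop)]
    }
    m <- if (mask == "auto") auto_field_mask(img) else NULL
    new_frame(img, index = i - 1L, mask = m)
  })
}

#' Persist / load a bladder map directory
#'
#' Writes `canvas.png`, `mask.png`, `poses.json` (versioned schema: per
#' frame the row-major 6-element transform and provenance), `stats.json`
#' and `manifest.json`. `load_map(write_map(m))` reproduces poses exactly
#' and canvas bytes exactly; the frame pixel data itself is not persisted.
#'
#' @param map a `bladder_map`
#' @param dir output directory (created)
#' @param manifest optional named list recorded as the run manifest
#' @return `write_map` returns `dir`; `load_map` returns a `bladder_map`
#'   (with `frames = NULL`)
#' @export
write_map <- function(map, dir, manifest = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image(map$canvas, file.path(dir, "canvas.png"))
  write_image(map$canvas_mask * 1, file.path(dir, "mask.png"))
  poses <- lapply(seq_along(map$poses), function(i) {
    list(frame_index = i - 1L,
         matrix = as.numeric(t(map$poses[[i]])),
         provenance = map$provenance[i])
  })
  jsonlite::write_json(
    list(version = POSE_SCHEMA_VERSION, convention = POSE_CONVENTION,
         frame_size = map$frame_size,
         offset = as.numeric(t(map$offset)), poses = poses),
    file.path(dir, "poses.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(map$stats, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_map
#' @export
load_map <- function(dir) {
  need <- c("canvas.png", "mask.png", "poses.json", "stats.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop(sprintf("map directory '%s' is missing %s", dir,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  canvas <- read_image(file.path(dir, "canvas.png"))
  cmask <- read_image(file.path(dir, "mask.png")) > 0.5
  pj <- jsonlite::read_json(file.path(dir, "poses.json"), simplifyVector = TRUE)
  stats <- jsonlite::read_json(file.path(dir, "stats.json"), simplifyVector = TRUE)
  poses <- lapply(seq_len(nrow(pj$poses)), function(i) {
    matrix(as.numeric(unlist(pj$poses$matrix[i])), 2, 3, byrow = TRUE)
  })
  map <- new_bladder_map(canvas, cmask, poses, pj$poses$provenance,
                         pairwise = vector("list", length(poses)),
                         offset = matrix(pj$offset, 2, 3, byrow = TRUE),
                         stats = stats, frames = NULL, config = NULL)
  map$frame_size <- pj$frame_size
  map
}

map_frame_size <- function(map) {
  if (!is.null(map$frame_size)) return(map$frame_size)
  c(ncol(map$frames[[1]]$pixels), nrow(map$frames[[1]]$pixels))
}

#' Write localization results as JSON
#' @param locs a [track_revisit()] result
#' @param path output file
#' @export
write_localizations <- function(locs, path) {
  out <- lapply(locs, function(l) {
    list(frame_index = l$frame_index, status = l$status,
         matrix = if (is.null(l$pose)) NULL else as.numeric(t(l$pose)),
         rotation_deg = l$rotation_deg, inlier_count = l$inlier_count)
  })
  jsonlite::write_json(
    list(version = POSE_SCHEMA_VERSION, convention = POSE_CONVENTION,
         n_matched = attr(locs, "n_matched"),
         matched_fraction = attr(locs, "matched_fraction"),
         localizations = out),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
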