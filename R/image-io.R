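#' Gray-level image container
#'
#' Constructs the basic image object used throughout the package: a 2-D
#' integer matrix of gray levels in `[0, n_levels - 1]`. The pixel coordinate
#' convention is row-major, `(row, col)`, 1-based in R's matrix indexing with
#' the origin at the top-left; all offsets and regions of interest follow it.
#'
#' @param pixels integer (or whole-number numeric) matrix of gray levels.
#' @param n_levels number of gray levels `N_g`; pixel values must lie in
#'   `[0, n_levels - 1]`. Defaults to 256 (8-bit).
#' @param source_id free-text provenance label carried through the pipeline.
#' @return An object of class `gray_image`: a list with elements `pixels`
#'   (integer matrix), `n_levels`, `height`, `width`, `source_id`.
#' @examples
#' img <- gray_image(matrix(0:15, 4, 4), n_levels = 16)
#' img$height
#' @export
gray_image <- function(pixels, n_levels = 256L, source_id = "") {
  if (!is.matrix(pixels)) stop("'pixels' must be a matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("image must be non-empty")
  if (length(n_levels) != 1L || n_levels < 2L) stop("'n_levels' must be >= 2")
  px <- pixels
  storage.mode(px) <- "integer"
  if (anyNA(px) || any(px != pixels)) stop("pixel values must be whole numbers")
  if (any(px < 0L) || any(px > n_levels - 1L))
    stop("pixel values must lie in [0, n_levels - 1]")
  structure(
    list(pixels = px, n_levels = as.integer(n_levels),
         height = nrow(px), width = ncol(px),
         source_id = as.character(source_id)),
    class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, %d gray levels%s\n",
              x$height, x$width, x$n_levels,
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  invisible(x)
}

#' @export
plot.gray_image <- function(x, ...) {
  op <- graphics::par(mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(c(0, x$width), c(0, x$height), asp = 1)
  graphics::rasterImage(x$pixels / (x$n_levels - 1), 0, 0, x$width, x$height,
                        interpolate = FALSE)
  graphics::title(main = if (nzchar(x$source_id)) x$source_id else "gray_image")
  invisible(x)
}

png_bit_depth <- function(path) {
  # bit depth is byte 25 of a PNG stream (8-byte signature + IHDR offset 16)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 25L)
  if (length(hdr) < 25L) return(NA_integer_)
  as.integer(hdr[25L])
}

#' Load a micrograph as an 8-bit gray-level image
#'
#' Reads a PNG or TIFF file and converts it to the 8-bit grayscale
#' representation the texture statistics assume. Color images are converted
#' by Rec. 709 luminance (0.2126 R + 0.7152 G + 0.0722 B) and quantized to
#' 8-bit; 16-bit inputs are right-shifted to 8-bit with a warning. An alpha
#' channel, if present, is dropped.
#'
#' @param path path to a PNG (`.png`) or TIFF (`.tif`/`.tiff`) file.
#' @param roi optional region of interest `c(row0, col0, height, width)`,
#'   0-based, half-open, applied after loading.
#' @return A [gray_image] with `n_levels = 256` and `source_id` set to the
#'   file name.
#' @seealso [crop_image()], [load_sequence()]
#' @export
load_image <- function(path, roi = NULL) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    depth <- png_bit_depth(path)
    if (!is.na(depth) && depth > 8L)
      warning("16-bit image right-shifted to 8-bit: ", path)
    # readPNG scales to [0,1]; rounding back recovers 8-bit codes exactly and
    # right-shifts deeper inputs
    arr <- arr * 255
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, as.is = TRUE)
    if (max(arr) > 255) {
      warning("16-bit image right-shifted to 8-bit: ", path)
      arr <- arr / 256
    }
  } else {
    stop("unsupported image format (need PNG or TIFF): ", path)
  }
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3L]
    if (nc >= 3L) {
      arr <- 0.2126 * arr[, , 1L] + 0.7152 * arr[, , 2L] + 0.0722 * arr[, , 3L]
    } else {
      arr <- arr[, , 1L]
    }
  }
  px <- matrix(as.integer(pmin(pmax(round(arr), 0), 255)),
               nrow(arr), ncol(arr))
  img <- gray_image(px, 256L, source_id = basename(path))
  if (!is.null(roi)) img <- crop_image(img, roi)
  img
}

#' Crop a region of interest
#'
#' @param img a [gray_image].
#' @param roi `c(row0, col0, height, width)`, 0-based, half-open: the crop
#'   covers rows `row0 .. row0 + height - 1`.
#' @return The cropped [gray_image].
#' @export
crop_image <- function(img, roi) {
  stopifnot(inherits(img, "gray_image"))
  roi <- as.integer(roi)
  if (length(roi) != 4L) stop("'roi' must be c(row0, col0, height, width)")
  r0 <- roi[1L]; c0 <- roi[2L]; h <- roi[3L]; w <- roi[4L]
  if (h < 1L || w < 1L || r0 < 0L || c0 < 0L ||
      r0 + h > img$height || c0 + w > img$width)
    stop("roi outside image bounds")
  gray_image(img$pixels[(r0 + 1L):(r0 + h), (c0 + 1L):(c0 + w), drop = FALSE],
             img$n_levels, img$source_id)
}

#' Requantize an image to a smaller number of gray levels
#'
#' Uniformly bins `[0, img$n_levels - 1]` onto `[0, n_levels - 1]` by
#' `floor(v * n_levels / old_levels)`; the mapping is order-preserving and
#' is the identity when `n_levels` equals the current level count.
#'
#' @param img a [gray_image].
#' @param n_levels target number of gray levels, at least 2.
#' @return A [gray_image] with `n_levels` levels.
#' @export
requantize <- function(img, n_levels) {
  stopifnot(inherits(img, "gray_image"))
  n_levels <- as.integer(n_levels)
  if (length(n_levels) != 1L || is.na(n_levels) || n_levels < 2L)
    stop("'n_levels' must be an integer >= 2")
  px <- (img$pixels * n_levels) %/% img$n_levels
  px[px > n_levels - 1L] <- n_levels - 1L
  gray_image(px, n_levels, img$source_id)
}

#' Frame sequence container
#'
#' Holds an ordered evaporation time series of images sharing one geometry.
#'
#' @param frames list of [gray_image] objects with identical height, width
#'   and `n_levels`.
#' @param timestamps optional strictly increasing times (seconds or frame
#'   index); defaults to `0, 1, 2, ...`.
#' @return An object of class `frame_sequence`: list with `frames`,
#'   `timestamps`, `n_frames`.
#' @export
frame_sequence <- function(frames, timestamps = NULL) {
  if (!is.list(frames) || length(frames) < 1L)
    stop("'frames' must be a non-empty list of gray_image objects")
  ok <- vapply(frames, inherits, logical(1), "gray_image")
  if (!all(ok)) stop("all frames must be gray_image objects")
  ref <- frames[[1L]]
  for (f in frames)
    if (f$height != ref$height || f$width != ref$width ||
        f$n_levels != ref$n_levels)
      stop("frame shape/levels mismatch across sequence")
  if (is.null(timestamps)) {
    timestamps <- seq_along(frames) - 1
  } else {
    if (length(timestamps) != length(frames))
      stop("'timestamps' length must match number of frames")
    if (any(diff(timestamps) <= 0))
      stop("'timestamps' must be strictly increasing")
  }
  structure(list(frames = frames, timestamps = as.numeric(timestamps),
                 n_frames = length(frames)),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  f <- x$frames[[1L]]
  cat(sprintf("<frame_sequence> %d frames of %d x %d (%d levels)\n",
              x$n_frames, f$height, f$width, f$n_levels))
  invisible(x)
}

#' Load an ordered image sequence
#'
#' @param paths ordered character vector of PNG/TIFF paths.
#' @param roi optional region of interest passed to [load_image()] per frame.
#' @return A [frame_sequence] with timestamps `0, 1, 2, ...`.
#' @export
load_sequence <- function(paths, roi = NULL) {
  if (length(paths) < 1L) stop("need at least one path")
  frame_sequence(lapply(paths, load_image, roi = roi))
}
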