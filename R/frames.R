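# Frame-sequence ingest: decode image sequences, crop the informative region,
# tile frames into sliding windows.
#
# Conventions used throughout the package: pixels are HxWx3 numeric arrays
# holding 8-bit values in [0, 255]; coordinates are 0-based with
# (x, y) = (column, row); rectangles are half-open [x0, x0 + w) x [y0, y0 + h).

#' Construct a frame
#'
#' @param pixels HxWx3 numeric array, values in \[0, 255\].
#' @param index Nonnegative frame index within its sequence.
#' @param roi Rectangle `c(x0, y0, w, h)` recording where `pixels` sit in
#'   the decoded image (defaults to the full extent).
#' @return Object of class `polyp_frame`.
#' @export
frame <- function(pixels, index = 0L, roi = NULL) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3L] != 3L)
    stop("frame pixels must be an HxWx3 array", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  if (is.null(roi)) roi <- c(0L, 0L, d[2L], d[1L])
  structure(list(index = as.integer(index), pixels = pixels,
                 roi = as.integer(roi)),
            class = "polyp_frame")
}

#' Construct a window
#'
#' A square RGB sub-image cut from a frame, the classification unit of the
#' sliding-window detector.
#'
#' @param pixels size x size x 3 numeric array, values in \[0, 255\].
#' @param origin `c(x, y)` top-left corner in the parent frame (0-based).
#' @param frame_index Index of the parent frame.
#' @return Object of class `polyp_window`.
#' @export
window <- function(pixels, origin = c(0L, 0L), frame_index = 0L) {
  d <- dim(pixels)
  if (length(d) != 3L || d[1L] != d[2L] || d[3L] != 3L)
    stop("window pixels must be a square HxHx3 array", call. = FALSE)
  structure(list(pixels = pixels, origin = as.integer(origin),
                 frame_index = as.integer(frame_index)),
            class = "polyp_window")
}

window_pixels <- function(w) {
  if (inherits(w, "polyp_window") || inherits(w, "polyp_frame")) w$pixels else w
}

.read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("cannot decode '", path, "': unsupported image format '.", ext, "'",
         call. = FALSE))
  .to_rgb255(img, path)
}

.to_rgb255 <- function(img, path = "<image>") {
  if (is.list(img)) stop("'", path, "' holds multiple images", call. = FALSE)
  d <- dim(img)
  if (length(d) == 2L) img <- array(rep(img, 3L), c(d, 3L))     # grayscale
  if (dim(img)[3L] == 4L) img <- img[, , 1:3, drop = FALSE]      # drop alpha
  if (dim(img)[3L] == 2L) img <- array(rep(img[, , 1L], 3L), c(d[1:2], 3L))
  round(img * 255)
}

#' Read a frame sequence
#'
#' Decodes either a multi-frame TIFF file (the package's lossless video
#' container, as written by [write_video()] and [make_video()]) or a
#' directory of still images (PNG/JPEG/TIFF, ordered lexicographically).
#'
#' @param source Path to a multi-frame TIFF or to a directory of images.
#' @param kind `"auto"` (decide from the path), `"video"` (multi-frame
#'   TIFF), or `"image_dir"`.
#' @return List of [frame()] objects with indices `0, 1, ...` in
#'   temporal/lexicographic order.
#' @export
read_frames <- function(source, kind = c("auto", "video", "image_dir")) {
  kind <- match.arg(kind)
  if (!file.exists(source))
    stop("cannot decode '", source, "': no such file or directory", call. = FALSE)
  if (kind == "auto") kind <- if (dir.exists(source)) "image_dir" else "video"
  if (kind == "image_dir") {
    files <- sort(list.files(source, pattern = "\\.(png|jpe?g|tiff?)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L)
      stop("no decodable images in '", source, "'", call. = FALSE)
    imgs <- lapply(files, .read_image_file)
  } else {
    ext <- tolower(tools::file_ext(source))
    if (ext %in% c("avi", "mp4", "wmv"))
      stop("cannot decode '", source, "': compressed video containers are ",
           "not supported; supply a multi-frame TIFF or a frame directory",
           call. = FALSE)
    if (!ext %in% c("tif", "tiff"))
      stop("cannot decode '", source, "': expected a multi-frame TIFF",
           call. = FALSE)
    pages <- tiff::readTIFF(source, all = TRUE)
    if (length(pages) == 0L) stop("'", source, "' holds no frames", call. = FALSE)
    imgs <- lapply(pages, .to_rgb255, path = source)
  }
  mapply(function(px, i) frame(px, index = i), imgs,
         seq_along(imgs) - 1L, SIMPLIFY = FALSE)
}

#' Write a frame sequence as a multi-frame TIFF
#'
#' Lossless 8-bit storage; [read_frames()] recovers the exact pixel values
#' and frame count.
#'
#' @param frames List of [frame()] objects with a common size.
#' @param path Output path (`.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_video <- function(frames, path) {
  if (length(frames) == 0L) stop("no frames to write", call. = FALSE)
  dims <- vapply(frames, function(f) dim(f$pixels)[1:2], integer(2))
  if (any(dims != dims[, 1L]))
    stop("frames must share a common size", call. = FALSE)
  pages <- lapply(frames, function(f) f$pixels / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Crop a frame to its informative region
#'
#' With an explicit rectangle, returns exactly that sub-grid. In `"auto"`
#' mode, trims border rows and columns whose mean 8-bit intensity falls
#' below `darkness_threshold` — the usual black mask around the endoscope's
#' circular field of view.
#'
#' @param frm A [frame()].
#' @param roi `c(x0, y0, w, h)` (0-based, half-open) or `"auto"`.
#' @param darkness_threshold Mean-intensity cutoff for auto mode, on the
#'   0-255 scale (default 10).
#' @param min_size Smallest acceptable cropped extent; defaults to the
#'   227-pixel window size.
#' @return A new [frame()] whose `roi` records the crop.
#' @export
crop_roi <- function(frm, roi = "auto", darkness_threshold = 10,
                     min_size = 227L) {
  stopifnot(inherits(frm, "polyp_frame"))
  d <- dim(frm$pixels)
  H <- d[1L]; W <- d[2L]
  if (identical(roi, "auto")) {
    gray <- (frm$pixels[, , 1L] + frm$pixels[, , 2L] + frm$pixels[, , 3L]) / 3
    row_ok <- rowMeans(gray) >= darkness_threshold
    col_ok <- colMeans(gray) >= darkness_threshold
    if (!any(row_ok) || !any(col_ok))
      stop("auto crop found no informative region", call. = FALSE)
    y0 <- which(row_ok)[1L] - 1L
    y1 <- which(row_ok)[sum(row_ok)]         # 1-based last informative row
    x0 <- which(col_ok)[1L] - 1L
    x1 <- which(col_ok)[sum(col_ok)]
    roi <- c(x0, y0, x1 - x0, y1 - y0)
  }
  roi <- as.integer(roi)
  x0 <- roi[1L]; y0 <- roi[2L]; w <- roi[3L]; h <- roi[4L]
  if (x0 < 0L || y0 < 0L || w < 1L || h < 1L || x0 + w > W || y0 + h > H)
    stop("roi (", paste(roi, collapse = ", "), ") lies outside the ",
         W, "x", H, " frame", call. = FALSE)
  if (w < min_size || h < min_size)
    stop("cropped region ", w, "x", h, " is smaller than the ", min_size,
         "-pixel window size", call. = FALSE)
  frame(frm$pixels[(y0 + 1L):(y0 + h), (x0 + 1L):(x0 + w), , drop = FALSE],
        index = frm$index, roi = roi)
}

#' Tile a frame into sliding windows
#'
#' Slides a `size` x `size` window across the frame left to right, then top
#' to bottom. The final window along each axis is clamped so its far edge
#' coincides with the frame edge, guaranteeing full coverage with no
#' out-of-bounds reads; consequently every window is exactly `size` square.
#'
#' @param frm A [frame()].
#' @param size Window side length in pixels (default 227, the classifier's
#'   input size).
#' @param stride Step between window origins in pixels (default 32).
#' @return List of [window()] objects in row-major order.
#' @export
generate_windows <- function(frm, size = 227L, stride = 32L) {
  stopifnot(inherits(frm, "polyp_frame"), stride >= 1L)
  d <- dim(frm$pixels)
  H <- d[1L]; W <- d[2L]
  if (H < size || W < size)
    stop("frame ", W, "x", H, " is smaller than the ", size,
         "-pixel window size", call. = FALSE)
  axis_origins <- function(extent) {
    o <- seq.int(0L, extent - size, by = stride)
    if (o[length(o)] != extent - size) o <- c(o, extent - size)
    o
  }
  xs <- axis_origins(W); ys <- axis_origins(H)
  out <- vector("list", length(xs) * length(ys))
  k <- 1L
  for (y in ys) for (x in xs) {
    out[[k]] <- window(frm$pixels[(y + 1L):(y + size), (x + 1L):(x + size), ,
                                  drop = FALSE],
                       origin = c(x, y), frame_index = frm$index)
    k <- k + 1L
  }
  out
}

#' @export
print.polyp_frame <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<frame %d: %dx%d px, roi (%s)>\n", x$index, d[2L], d[1L],
              paste(x$roi, collapse = ", ")))
  invisible(x)
}

#' @export
print.polyp_window <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<window %dx%d at (%d, %d) of frame %d>\n", d[2L], d[1L],
              x$origin[1L], x$origin[2L], x$frame_index))
  invisible(x)
}
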