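# Image and contour I/O.  Images are numeric matrices [row, col] on a
# 0-255 intensity scale (8-bit equivalent); files read as [0, 1] doubles
# are rescaled on input.  Multi-channel frames are converted to
# luminance with Rec. 709 weights (0.2126 R + 0.7152 G + 0.0722 B).

#' Rectangular region of interest
#'
#' 1-based, inclusive pixel bounds: rows `row0:row1`, columns `col0:col1`.
#'
#' @param row0,col0 top-left pixel (1-based).
#' @param row1,col1 bottom-right pixel (inclusive).
#' @return an object of class `rect_roi`.
#' @export
rect_roi <- function(row0, col0, row1, col1) {
  v <- as.integer(c(row0, col0, row1, col1))
  if (anyNA(v)) stop("ROI bounds must be integers")
  if (v[1L] < 1L || v[2L] < 1L || v[3L] < v[1L] || v[4L] < v[2L])
    stop("invalid ROI: need 1 <= row0 <= row1 and 1 <= col0 <= col1")
  structure(list(row0 = v[1L], col0 = v[2L], row1 = v[3L], col1 = v[4L]),
            class = "rect_roi")
}

#' @export
format.rect_roi <- function(x, ...) {
  sprintf("rect_roi rows %d:%d cols %d:%d", x$row0, x$row1, x$col0, x$col1)
}

#' @export
print.rect_roi <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' @keywords internal
to_gray <- function(a) {
  if (is.matrix(a)) return(a)
  if (length(dim(a)) == 3L) {
    nc <- dim(a)[3L]
    if (nc == 1L) return(a[, , 1L])
    w <- c(0.2126, 0.7152, 0.0722)   # Rec. 709 luminance
    if (nc == 2L) return(a[, , 1L])  # gray + alpha
    return(w[1L] * a[, , 1L] + w[2L] * a[, , 2L] + w[3L] * a[, , 3L])
  }
  stop("unsupported image array with ", length(dim(a)), " dimensions")
}

#' @keywords internal
read_one_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    tif  = ,
    tiff = tiff::readTIFF(path, all = TRUE),
    png  = png::readPNG(path),
    stop("unsupported image format: ", path))
  if (is.list(a)) lapply(a, function(f) to_gray(f) * 255) else list(to_gray(a) * 255)
}

#' Read an image sequence
#'
#' Reads either a multi-page TIFF (frames in page order) or a directory of
#' single-channel TIFF/PNG files (frames in lexicographic filename order).
#' All frames must have the same shape.  Intensities are returned on the
#' 0-255 scale; color frames are converted to Rec. 709 luminance.
#'
#' @param path a TIFF/PNG file or a directory of such files.
#' @return list of numeric matrices (frames).
#' @export
read_sequence <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no TIFF/PNG files found in ", path)
    frames <- list(); src <- character()
    for (f in files) {
      fr <- read_one_image(f)
      frames <- c(frames, fr)
      src <- c(src, rep(f, length(fr)))
    }
  } else if (file.exists(path)) {
    frames <- read_one_image(path)
    src <- rep(path, length(frames))
  } else stop("path does not exist: ", path)
  if (!length(frames)) stop("empty image input: ", path)
  d1 <- dim(frames[[1L]])
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]), d1))
      stop("frame shape mismatch in '", src[i], "': ",
           paste(dim(frames[[i]]), collapse = "x"), " vs ",
           paste(d1, collapse = "x"))
  }
  frames
}

#' Crop an image to a rectangular ROI
#'
#' @param image numeric matrix.
#' @param roi a [rect_roi()].
#' @return the cropped matrix of shape `(row1-row0+1) x (col1-col0+1)`.
#' @export
crop <- function(image, roi) {
  stopifnot(is.matrix(image), inherits(roi, "rect_roi"))
  if (roi$row1 > nrow(image) || roi$col1 > ncol(image))
    stop("ROI exceeds image bounds (", nrow(image), "x", ncol(image), ")")
  image[roi$row0:roi$row1, roi$col0:roi$col1, drop = FALSE]
}

#' Write contours to CSV
#'
#' One row per point with columns `frame`, `point`, `x`, `y`
#' (x = column, y = row, 1-based, subpixel).
#'
#' @param contours a single contour (N x 2 matrix) or list of contours.
#' @param path output CSV path.
#' @export
write_contours <- function(contours, path) {
  if (is.matrix(contours)) contours <- list(contours)
  rows <- do.call(rbind, lapply(seq_along(contours), function(i) {
    p <- unclass(contours[[i]])
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 1L)
      stop("degenerate contour at index ", i)
    data.frame(frame = i, point = seq_len(nrow(p)),
               x = round(p[, 1L], 6), y = round(p[, 2L], 6))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read contours written by [write_contours()]
#' @param path CSV path.
#' @return list of N x 2 contour matrices, one per frame.
#' @export
read_contours <- function(path) {
  d <- utils::read.csv(path)
  lapply(split(d, d$frame), function(g) {
    g <- g[order(g$point), ]
    cbind(x = g$x, y = g$y)
  })
}

#' Write a binary mask as an 8-bit PNG (0/255)
#' @param mask 0/1 matrix.
#' @param path output PNG path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG((mask != 0) * 1.0, path)
  invisible(path)
}

#' Read a mask PNG back to a 0/1 matrix
#' @param path PNG path.
#' @export
read_mask <- function(path) {
  (to_gray(png::readPNG(path)) > 0.5) * 1L
}

#' Write an RGB overlay of a contour on a gray-scale frame
#'
#' The contour polyline is rasterized (densely sampled, rounded to the
#' nearest pixel) and drawn in red.
#'
#' @param image numeric matrix (0-255).
#' @param contour N x 2 matrix of (x, y) points.
#' @param path output PNG path.
#' @export
write_overlay <- function(image, contour, path) {
  g <- pmin(pmax(image / 255, 0), 1)
  rgb <- array(g, dim = c(nrow(g), ncol(g), 3L))
  p <- unclass(contour)
  q <- rbind(p, p[1L, ])
  for (i in seq_len(nrow(p))) {
    a <- q[i, ]; b <- q[i + 1L, ]
    n <- max(2L, ceiling(2 * sqrt(sum((b - a)^2))))
    t <- seq(0, 1, length.out = n)
    xs <- round(a[1L] + t * (b[1L] - a[1L]))
    ys <- round(a[2L] + t * (b[2L] - a[2L]))
    ok <- xs >= 1 & xs <= ncol(g) & ys >= 1 & ys <= nrow(g)
    idx <- cbind(ys[ok], xs[ok])
    rgb[cbind(idx, 1L)] <- 1; rgb[cbind(idx, 2L)] <- 0; rgb[cbind(idx, 3L)] <- 0
  }
  png::writePNG(rgb, path)
  invisible(path)
}

#' Write frames as a multi-page 16-bit TIFF
#' @param frames list of matrices (0-255).
#' @param path output TIFF path.
#' @export
write_sequence <- function(frames, path) {
  tiff::writeTIFF(lapply(frames, function(f) pmin(pmax(f / 255, 0), 1)),
                  path, bits.per.sample = 16L)
  invisible(path)
}
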