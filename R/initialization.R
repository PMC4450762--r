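# Initial contour extraction.  After hole filling, the cell body is an
# exactly flat plateau (every pixel raised to its basin's escape level),
# so the plateau level is the tallest histogram bin; a narrow intensity
# band around that level, cleaned by disk opening/closing, yields a
# coarse binary cell region whose outer boundary -- close to the phase
# halo -- initializes the snake.

#' Histogram-mode threshold
#'
#' Returns the intensity of the tallest bin of a fixed 256-bin histogram
#' over the image's intensity range (ties broken toward the lower
#' intensity).  Intended to be applied to the hole-filled ROI, where the
#' flattened cell body forms the dominant spike.
#'
#' @param roi numeric matrix.
#' @return scalar threshold intensity (bin center).
#' @export
histogram_threshold <- function(roi) {
  stopifnot(is.matrix(roi), length(roi) >= 1L)
  rng <- range(roi)
  if (diff(rng) == 0) return(rng[1L])
  breaks <- seq(rng[1L], rng[2L], length.out = 257L)
  counts <- tabulate(findInterval(roi, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = 256L)
  i <- which.max(counts)  # which.max takes the first (lowest) maximum
  (breaks[i] + breaks[i + 1L]) / 2
}

#' Estimate a tolerance band half-width from the histogram
#'
#' Half the distance from the main mode to the nearest other significant
#' local maximum (counts at least 5% of the mode), clamped to [5, 8]
#' intensity levels; 5 when no second mode is found.  The lower clamp
#' keeps the band above the noise scale; the upper clamp keeps it well
#' below the plateau-to-background gap so that the band does not creep
#' down weak halo flanks.
#' @keywords internal
estimate_threshold_tol <- function(roi, thr) {
  rng <- range(roi)
  if (diff(rng) == 0) return(5)
  breaks <- seq(rng[1L], rng[2L], length.out = 257L)
  counts <- tabulate(findInterval(roi, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = 256L)
  centers <- (breaks[-257L] + breaks[-1L]) / 2
  main <- which.min(abs(centers - thr))
  n <- length(counts)
  locmax <- which(counts >= c(-1, counts[-n]) & counts >= c(counts[-1L], -1) &
                    counts >= 0.05 * counts[main])
  locmax <- locmax[abs(locmax - main) > 3L]
  if (!length(locmax)) return(5)
  d <- min(abs(centers[locmax] - centers[main]))
  min(max(d / 2, 5), 8)
}

#' Band thresholding around an intensity level
#'
#' Marks pixels with `|I - thr| <= tol`.  `tol = 0` reproduces the
#' literal equality selection; `mode` switches to one-sided selection.
#'
#' @param roi numeric matrix.
#' @param thr threshold intensity.
#' @param tol band half-width (`NULL`: estimated from the histogram,
#'   minimum 5 levels).
#' @param mode `"band"` (default), `"le"` (`I <= thr + tol`) or
#'   `"ge"` (`I >= thr - tol`).
#' @return 0/1 matrix.
#' @export
binarize <- function(roi, thr, tol = NULL, mode = c("band", "le", "ge")) {
  mode <- match.arg(mode)
  tol <- tol %||% estimate_threshold_tol(roi, thr)
  stopifnot(tol >= 0)
  switch(mode,
    band = (abs(roi - thr) <= tol) * 1L,
    le   = (roi <= thr + tol) * 1L,
    ge   = (roi >= thr - tol) * 1L)
}

#' Trace the outer boundary of the largest foreground component
#'
#' Marching-squares tracing (0.5 level set) of the largest 8-connected
#' component, returning a closed subpixel contour with positive
#' orientation.
#'
#' @param binary 0/1 matrix.
#' @return N x 2 contour matrix.
#' @export
extract_boundary <- function(binary) {
  lab <- label_components(binary, 8L)
  if (max(lab) == 0L) stop("no foreground component to trace")
  sizes <- tabulate(lab[lab > 0L])
  comp <- (lab == which.max(sizes)) * 1.0
  if (sum(comp) < 4) stop("degenerate component: fewer than 4 pixels")
  # pad with a zero ring so the 0.5 level set is closed
  z <- matrix(0, nrow(comp) + 2L, ncol(comp) + 2L)
  z[2:(nrow(comp) + 1L), 2:(ncol(comp) + 1L)] <- comp
  cl <- grDevices::contourLines(x = seq_len(nrow(z)), y = seq_len(ncol(z)),
                                z = z, levels = 0.5)
  if (!length(cl)) stop("boundary tracing failed")
  # outer boundary = the line enclosing the largest area
  areas <- vapply(cl, function(l) {
    abs(contour_area(cbind(l$y, l$x)))
  }, numeric(1))
  l <- cl[[which.max(areas)]]
  # contourLines x follows matrix rows, y follows columns; undo padding
  as_contour(cbind(x = l$y - 1, y = l$x - 1))
}

#' Initial contour from a region of interest
#'
#' Pipeline: [fill_holes()] -> [histogram_threshold()] -> [binarize()]
#' -> [open_close()] (disk radius 3 by default) -> component selection
#' (centroid nearest the ROI center, ties by larger area) -> binary hole
#' fill -> [extract_boundary()] -> [resample_contour()].
#'
#' @param roi numeric matrix assumed to contain a single target cell.
#' @param config parameter list, see [default_config()]; keys used:
#'   `threshold_tol`, `init_disk_radius`, `min_component_size`,
#'   `target_spacing`.
#' @return N x 2 contour matrix in ROI coordinates.
#' @export
initial_contour <- function(roi, config = default_config()) {
  cfg <- default_config(config)
  filled <- fill_holes(roi)
  thr <- histogram_threshold(filled)
  # a reconstructed cell body is an exact plateau: its histogram spike
  # holds a large share of the ROI; featureless noise never does
  if (mean(abs(filled - thr) <= diff(range(filled)) / 512) < 0.1)
    stop("no object found in ROI: no dominant intensity plateau")
  b <- binarize(filled, thr, cfg$threshold_tol)
  b <- open_close(b, cfg$init_disk_radius)
  lab <- label_components(b, 8L)
  if (max(lab) == 0L) stop("no object found in ROI")
  sizes <- tabulate(lab[lab > 0L])
  ok <- which(sizes >= max(cfg$min_component_size, 4L))
  if (!length(ok)) stop("no object found in ROI")
  ctr <- c((1 + nrow(roi)) / 2, (1 + ncol(roi)) / 2)
  cent <- t(vapply(ok, function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    colMeans(w)
  }, numeric(2)))
  d <- sqrt((cent[, 1L] - ctr[1L])^2 + (cent[, 2L] - ctr[2L])^2)
  best <- ok[order(d, -sizes[ok])][1L]
  if (sizes[best] > 0.8 * length(roi))
    stop("no object found in ROI: thresholding selected nearly the whole ",
         "window (no distinct intensity mode)")
  comp <- (lab == best) * 1L
  comp <- (fill_holes(comp) > 0.5) * 1L   # solid region
  resample_contour(extract_boundary(comp), cfg$target_spacing)
}
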