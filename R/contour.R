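# Closed contours are N x 2 matrices of subpixel (x, y) points
# (x = column, y = row), implicitly closed (row N connects to row 1),
# oriented so the signed shoelace area in the (x, y) plane is positive
# ("counter-clockwise" in the package's axis convention).

#' Validate and normalize a closed contour
#'
#' Drops duplicate consecutive points (and a duplicated closing point),
#' enforces at least 4 vertices, and normalizes orientation to positive
#' signed area.
#'
#' @param points N x 2 matrix of (x, y) points.
#' @return normalized N x 2 contour matrix.
#' @export
as_contour <- function(points) {
  p <- as.matrix(points)
  if (ncol(p) != 2L) stop("a contour must be an N x 2 matrix of (x, y)")
  n <- nrow(p)
  if (n >= 2L && all(p[1L, ] == p[n, ])) p <- p[-n, , drop = FALSE]
  keep <- c(TRUE, rowSums(abs(diff(p))) > 0)
  p <- p[keep, , drop = FALSE]
  if (nrow(p) < 4L) stop("degenerate contour: fewer than 4 distinct points")
  if (contour_area(p, signed = TRUE) < 0) p <- p[rev(seq_len(nrow(p))), ]
  dimnames(p) <- list(NULL, c("x", "y"))
  p
}

#' Polygon area of a closed contour (shoelace formula)
#' @param contour N x 2 matrix.
#' @param signed return the signed area (positive = package CCW)?
#' @export
contour_area <- function(contour, signed = FALSE) {
  p <- as.matrix(contour)
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  a <- 0.5 * sum(x * yn - xn * y)
  if (signed) a else abs(a)
}

#' Perimeter of a closed contour
#' @param contour N x 2 matrix.
#' @export
contour_perimeter <- function(contour) {
  p <- as.matrix(contour)
  q <- rbind(p, p[1L, ])
  sum(sqrt(rowSums(diff(q)^2)))
}

#' Area centroid of a closed contour polygon
#' @param contour N x 2 matrix.
#' @return numeric (x, y).
#' @export
contour_centroid <- function(contour) {
  p <- as.matrix(contour)
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- 0.5 * sum(cr)
  if (abs(a) < 1e-12) return(colMeans(p))
  c(x = sum((x + xn) * cr) / (6 * a), y = sum((y + yn) * cr) / (6 * a))
}

#' Resample a closed contour to uniform arc-length spacing
#'
#' Points are redistributed at equal arc length along the closed
#' polyline; the number of points is recomputed as
#' `max(16, round(perimeter / target_spacing))` unless `n` is given.
#' The perimeter is preserved to within 1%.
#'
#' @param contour N x 2 matrix.
#' @param target_spacing desired point spacing in pixels (default 2).
#' @param n optional explicit number of points.
#' @return resampled contour matrix.
#' @export
resample_contour <- function(contour, target_spacing = 2, n = NULL) {
  p <- as_contour(contour)
  q <- rbind(p, p[1L, ])
  seg <- sqrt(rowSums(diff(q)^2))
  per <- sum(seg)
  if (per <= 0) stop("degenerate contour: zero perimeter")
  n <- as.integer(n %||% max(16L, round(per / target_spacing)))
  cum <- c(0, cumsum(seg))
  s <- seq(0, per, length.out = n + 1L)[-(n + 1L)]
  x <- stats::approx(cum, q[, 1L], xout = s, ties = "ordered")$y
  y <- stats::approx(cum, q[, 2L], xout = s, ties = "ordered")$y
  as_contour(cbind(x, y))
}
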