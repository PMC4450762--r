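# Feature maps driving the external force.  The traditional edge map is
# the gradient magnitude of a Gaussian-smoothed image.  The proposed
# sparse alternative ("MGRL" map) runs hole filling by gray-scale
# reconstruction, Laplacian-of-Gaussian filtering, zero-crossing
# detection with an amplitude gate, and small-component removal,
# yielding a binary map whose nonzero pixels sit only on significant
# edges.

#' Gradient-magnitude edge map
#'
#' `f(x, y) = |grad(G_sigma * I)|`: the image is smoothed with a Gaussian
#' of standard deviation `sigma` (default 3 pixels) and the central
#' difference gradient magnitude is returned.
#'
#' @param image numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return nonnegative matrix, same shape as `image`.
#' @export
gradient_edge_map <- function(image, sigma = 3) {
  stopifnot(sigma > 0)
  s <- gaussian_blur(image, sigma)
  gx <- (shift_mat(s, 0L, -1L, 0) - shift_mat(s, 0L, 1L, 0)) / 2
  gy <- (shift_mat(s, -1L, 0L, 0) - shift_mat(s, 1L, 0L, 0)) / 2
  # one-sided differences at the borders
  gx[, 1L] <- s[, 2L] - s[, 1L]; gx[, ncol(s)] <- s[, ncol(s)] - s[, ncol(s) - 1L]
  gy[1L, ] <- s[2L, ] - s[1L, ]; gy[nrow(s), ] <- s[nrow(s), ] - s[nrow(s) - 1L]
  sqrt(gx^2 + gy^2)
}

#' Discrete Laplacian-of-Gaussian kernel
#'
#' Standard LoG, mean-corrected so the entries sum to exactly zero
#' (a constant image then yields an all-zero response).
#'
#' @param sigma standard deviation in pixels (default 2).
#' @param size odd kernel side length (default 13).
#' @return `size` x `size` matrix summing to 0 (within 1e-12).
#' @export
log_kernel <- function(sigma = 2, size = 13L) {
  stopifnot(size %% 2L == 1L, size >= 3L, sigma > 0)
  r <- (size - 1L) %/% 2L
  xs <- seq.int(-r, r)
  x2 <- outer(rep(1, size), xs^2)
  y2 <- outer(xs^2, rep(1, size))
  g <- exp(-(x2 + y2) / (2 * sigma^2))
  k <- (x2 + y2 - 2 * sigma^2) / sigma^4 * g
  k - mean(k)
}

#' Laplacian-of-Gaussian response
#'
#' Convolution of the image with [log_kernel()] using reflected
#' boundaries.
#'
#' @param image numeric matrix.
#' @param sigma LoG standard deviation (default 2).
#' @param size odd kernel side (default 13).
#' @return signed response matrix, same shape as `image`.
#' @export
log_response <- function(image, sigma = 2, size = 13L) {
  conv2_reflect(image, log_kernel(sigma, size))
}

#' Zero-crossing edge detection with amplitude gating
#'
#' A pixel is marked as an edge iff its response is `>= 0`, at least one
#' 4-neighbor has a strictly negative response, and the response jump
#' `|r(p) - r(q)|` across that neighbor exceeds the amplitude threshold.
#' Marking a single polarity keeps the traced crossings about one pixel
#' thick.  With `amplitude_eps = NULL` the gate defaults to
#' `0.75 * mean(|response|)`, a conventional robust floor against
#' noise-induced sign flutter; an absolute floor of
#' `1e-9 * max(1, max|response|)` guards against marking pure numerical
#' residue (e.g. on constant images).
#'
#' @param response signed response matrix.
#' @param amplitude_eps amplitude gate; `NULL` for the robust default.
#' @return 0/1 matrix of edge pixels.
#' @export
zero_crossing_edges <- function(response, amplitude_eps = NULL) {
  stopifnot(is.matrix(response))
  eps <- amplitude_eps %||% (0.75 * mean(abs(response)))
  if (eps < 0) stop("amplitude_eps must be >= 0")
  eps <- max(eps, 1e-9 * max(1, max(abs(response))))
  pos <- response >= 0
  hit <- matrix(FALSE, nrow(response), ncol(response))
  for (o in neighbor_offsets(4L)) {
    nb <- shift_mat(response, o[1L], o[2L], 0)
    nbneg <- shift_mat(response < 0, o[1L], o[2L], FALSE) > 0
    hit <- hit | (pos & nbneg & abs(response - nb) > eps)
  }
  hit * 1L
}

#' Sparse binary feature map from reconstruction + LoG (MGRL map)
#'
#' Pipeline: [fill_holes()] (gray-scale reconstruction) ->
#' [log_response()] -> [zero_crossing_edges()] ->
#' [remove_small_components()].  The result is a binary map marking only
#' significant closed edge structures; interior edge fragments caused by
#' intensity inhomogeneity inside the cell are removed by the hole
#' filling, and short noise fragments by the component-size floor.
#'
#' @param roi numeric matrix (the cropped cell region).
#' @param config parameter list, see [default_config()]; keys used:
#'   `log_sigma`, `log_size`, `min_component_size`, `amplitude_eps`,
#'   `use_mgr` (set `FALSE` to skip the reconstruction stage, for
#'   ablation).
#' @return 0/1 matrix, same shape as `roi`.
#' @export
mgrl_feature_map <- function(roi, config = default_config()) {
  cfg <- default_config(config)
  base <- if (isTRUE(cfg$use_mgr)) fill_holes(roi) else roi
  resp <- log_response(base, cfg$log_sigma, cfg$log_size)
  edges <- zero_crossing_edges(resp, cfg$amplitude_eps)
  remove_small_components(edges, cfg$min_component_size)
}
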