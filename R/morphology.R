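# Morphological gray-scale reconstruction (MGR) and the binary cleanup
# operators used around it.  Reconstruction by dilation is the fixpoint
# of geodesic dilation of a marker under a mask; applied to the inverted
# image with a border-seeded marker it fills intensity "holes" --
# regional minima not connected to the image border -- which is how the
# phase-contrast cell body is flattened before thresholding and edge
# detection.

#' Morphological gray-scale reconstruction by dilation
#'
#' Iterates geodesic dilation (3x3 maximum filter followed by a pointwise
#' minimum with the mask) of `marker` under `mask` until stability.  The
#' result `R` satisfies `marker <= R <= mask` pointwise and is idempotent
#' as a marker.
#'
#' @param marker numeric matrix, pointwise `<= mask` (values above the
#'   mask are clamped with a warning).
#' @param mask numeric matrix, same shape as `marker`.
#' @param connectivity 4 or 8 (default 8).
#' @return the reconstructed matrix.
#' @export
grayscale_reconstruct <- function(marker, mask, connectivity = 8L) {
  stopifnot(is.matrix(marker), is.matrix(mask))
  if (!identical(dim(marker), dim(mask)))
    stop("marker and mask must have the same shape")
  if (any(marker > mask)) {
    warning("marker exceeds mask; clamping marker to mask")
    marker <- pmin(marker, mask)
  }
  offs <- neighbor_offsets(connectivity)
  lo <- min(marker)
  cur <- marker
  repeat {
    dil <- cur
    for (o in offs) dil <- pmax(dil, shift_mat(cur, o[1L], o[2L], lo))
    nxt <- pmin(dil, mask)
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  cur
}

#' Fill intensity holes by border-seeded reconstruction
#'
#' Raises every regional minimum not connected to the image border to the
#' level of its lowest escape route: the intensity complement is
#' reconstructed from a marker that equals the complement on the 1-pixel
#' border and the global minimum elsewhere, then complemented back.
#' Output is pointwise `>=` the input and border pixels are unchanged.
#'
#' @param image numeric matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return the hole-filled matrix.
#' @export
fill_holes <- function(image, connectivity = 8L) {
  stopifnot(is.matrix(image))
  if (nrow(image) < 3L || ncol(image) < 3L) return(image)
  m <- max(image)
  comp <- m - image
  marker <- matrix(min(comp), nrow(image), ncol(image))
  marker[1L, ] <- comp[1L, ]; marker[nrow(comp), ] <- comp[nrow(comp), ]
  marker[, 1L] <- comp[, 1L]; marker[, ncol(comp)] <- comp[, ncol(comp)]
  m - grayscale_reconstruct(marker, comp, connectivity)
}

#' Remove small connected foreground components
#'
#' Deletes every foreground component (8-connected by default) with fewer
#' than `min_size` pixels; larger components are untouched.  This is the
#' low-pass cleanup applied to the binary edge map, with the component
#' size floor conventionally in the 15-20 pixel range.
#'
#' @param binary 0/1 matrix.
#' @param min_size minimum component size in pixels (default 20).
#' @param connectivity 4 or 8 (default 8).
#' @return 0/1 matrix.
#' @export
remove_small_components <- function(binary, min_size = 20L, connectivity = 8L) {
  stopifnot(min_size >= 1L)
  lab <- label_components(binary, connectivity)
  if (max(lab) == 0L) return((binary != 0) * 1L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size)
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[lab %in% keep] <- 1L
  out
}

#' Binary opening followed by closing with a flat disk
#'
#' @param binary 0/1 matrix.
#' @param radius disk radius in pixels (default 3).
#' @return 0/1 matrix.
#' @export
open_close <- function(binary, radius = 3L) {
  stopifnot(radius >= 1L)
  b <- (binary != 0) * 1.0
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  out <- EBImage::closing(EBImage::opening(b, brush), brush)
  (as.matrix(out) > 0.5) * 1L
}
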