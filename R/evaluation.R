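# Segmentation evaluation: polygon rasterization and the Jaccard
# coefficient JC = |A n B| / |A u B| between a predicted and a ground
# truth mask, summarized per frame with mean and (sample) standard
# deviation.

#' Rasterize a closed contour to a binary mask
#'
#' A pixel is foreground iff its center (x = col, y = row, integer
#' coordinates) lies inside the polygon.
#'
#' @param contour N x 2 matrix of (x, y) points.
#' @param shape c(rows, cols) of the output mask.
#' @return 0/1 matrix.
#' @export
contour_to_mask <- function(contour, shape) {
  p <- as_contour(contour)
  nr <- shape[1L]; nc <- shape[2L]
  out <- matrix(0L, nr, nc)
  # restrict the point-in-polygon test to the bounding box
  cs <- max(1L, floor(min(p[, 1L]))):min(nc, ceiling(max(p[, 1L])))
  rs <- max(1L, floor(min(p[, 2L]))):min(nr, ceiling(max(p[, 2L])))
  if (min(p[, 1L]) > nc || max(p[, 1L]) < 1 ||
      min(p[, 2L]) > nr || max(p[, 2L]) < 1) return(out)
  pts <- cbind(rep(cs, each = length(rs)), rep(rs, times = length(cs)))
  bnd <- rbind(p, p[1L, ])
  inside <- mgcv::in.out(bnd, pts)
  out[cbind(pts[inside, 2L], pts[inside, 1L])] <- 1L
  out
}

#' Jaccard coefficient between two binary masks
#'
#' @param a,b 0/1 matrices of equal shape.
#' @return |A n B| / |A u B| in [0, 1]; an error if both masks are empty.
#' @export
jaccard <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks must have the same shape")
  A <- a != 0; B <- b != 0
  u <- sum(A | B)
  if (u == 0L) stop("Jaccard undefined: both masks are empty")
  sum(A & B) / u
}

#' Per-frame Jaccard evaluation of a segmentation run
#'
#' @param predictions a `track_result` (see [track()]) or a list of 0/1
#'   masks.
#' @param truths list of ground-truth 0/1 masks, same length.
#' @return list with `per_frame` (data.frame: frame, jaccard), `mean`,
#'   `sd` (sample standard deviation, `NA` for a single frame).
#' @export
evaluate_run <- function(predictions, truths) {
  if (inherits(predictions, "track_result"))
    predictions <- lapply(predictions$records, `[[`, "mask")
  if (!length(predictions)) stop("no predictions to evaluate")
  if (length(predictions) != length(truths))
    stop("predictions and truths differ in length (",
         length(predictions), " vs ", length(truths), ")")
  jc <- mapply(jaccard, predictions, truths)
  list(per_frame = data.frame(frame = seq_along(jc), jaccard = jc),
       mean = mean(jc), sd = stats::sd(jc))
}
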