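# Frame-to-frame tracking: segmentation is repeated on every frame with
# the final contour of the previous frame as the initial contour of the
# current one (cell displacement between successive frames is assumed
# small).  The ROI is fixed across frames.  If the snake collapses on a
# frame after the first, initialization is re-attempted once from
# scratch before aborting.

#' Track a single cell through an image sequence
#'
#' Frame 1 is initialized by the histogram/morphology procedure
#' ([initial_contour()]); every frame is segmented with the selected
#' force field; the resulting contour seeds the next frame.
#'
#' @param frames list of numeric matrices (same shape).
#' @param roi a [rect_roi()] valid for all frames.
#' @param config parameter list (see [default_config()]).
#' @param force_field `"vfc_mgrl"` (default), `"vfc_edge"` or `"gvf"`.
#' @param frame_interval optional frame interval in seconds, carried to
#'   the summary table as metadata.
#' @return list of class `track_result` with `records` (one per frame:
#'   `frame`, `contour` (full-image), `contour_roi`, `mask`,
#'   `iterations`, `converged`, `reinitialized`, `failed`), `roi`,
#'   `config`, `force_field`, `frame_interval`.
#' @export
track <- function(frames, roi, config = default_config(),
                  force_field = c("vfc_mgrl", "vfc_edge", "gvf"),
                  frame_interval = NA_real_) {
  force_field <- match.arg(force_field)
  cfg <- default_config(config)
  stopifnot(length(frames) >= 1L)
  records <- vector("list", length(frames))
  prev <- NULL
  for (i in seq_along(frames)) {
    reinit <- FALSE
    res <- if (is.null(prev)) {
      segment(frames[[i]], roi, cfg, force_field)   # frame 1: full init
    } else {
      tryCatch(segment(frames[[i]], roi, cfg, force_field, init = prev),
               error = function(e) e)
    }
    if (inherits(res, "error")) {
      message("frame ", i, ": evolution failed (", conditionMessage(res),
              "); re-initializing")
      reinit <- TRUE
      res <- segment(frames[[i]], roi, cfg, force_field)  # may abort
    }
    records[[i]] <- list(frame = i, contour = res$contour,
                         contour_roi = res$contour_roi, mask = res$mask,
                         iterations = res$iterations,
                         converged = res$converged,
                         reinitialized = reinit, failed = FALSE)
    prev <- res$contour_roi
  }
  structure(list(records = records, roi = roi, config = cfg,
                 force_field = force_field, frame_interval = frame_interval),
            class = "track_result")
}

#' Per-frame morphology summary of a tracking run
#'
#' @param result a `track_result`.
#' @return data.frame with frame index, time (s, if a frame interval is
#'   known), area (px^2), perimeter (px), centroid, iterations and
#'   convergence flag.
#' @export
summarize_track <- function(result) {
  stopifnot(inherits(result, "track_result"))
  if (!length(result$records)) stop("empty track result")
  rows <- lapply(result$records, function(r) {
    cen <- contour_centroid(r$contour)
    data.frame(frame = r$frame,
               time_s = if (is.na(result$frame_interval)) NA_real_
                        else (r$frame - 1L) * result$frame_interval,
               area = contour_area(r$contour),
               perimeter = contour_perimeter(r$contour),
               centroid_x = cen[1L], centroid_y = cen[2L],
               iterations = r$iterations, converged = r$converged,
               reinitialized = r$reinitialized)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.track_result <- function(x, ...) {
  cat("track_result:", length(x$records), "frames,", x$force_field,
      "snake, ROI", format(x$roi), "\n")
  invisible(x)
}
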