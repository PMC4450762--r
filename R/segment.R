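# End-to-end single-frame segmentation: crop the ROI, extract the
# initial contour, build the feature map and external force field, and
# evolve the snake.  Three force fields are supported: the sparse
# reconstruction+LoG VFC field (the method of interest), VFC on the
# traditional gradient edge map, and the GVF baseline.

#' @keywords internal
build_force_field <- function(roi_img, cfg,
                              force_field = c("vfc_mgrl", "vfc_edge", "gvf")) {
  force_field <- match.arg(force_field)
  if (force_field == "vfc_mgrl") {
    fmap <- mgrl_feature_map(roi_img, cfg)
    kernel <- make_vfc_kernel(cfg$vfc_radius, cfg$vfc_r, cfg$vfc_eps)
    field <- vfc_field(fmap, kernel)
  } else if (force_field == "vfc_edge") {
    fmap <- gradient_edge_map(roi_img, cfg$edge_sigma)
    kernel <- make_vfc_kernel(cfg$vfc_radius, cfg$vfc_r, cfg$vfc_eps)
    field <- vfc_field(fmap / max(max(fmap), 1e-12), kernel)
  } else {
    fmap <- gradient_edge_map(roi_img, cfg$edge_sigma)
    field <- gvf_field(fmap, cfg$gvf_mu, cfg$gvf_iters)
  }
  if (isTRUE(cfg$normalize_force)) field <- soft_normalize_field(field)
  list(fmap = fmap, field = field)
}

#' Segment a single cell in one frame
#'
#' Pipeline: [crop()] -> [initial_contour()] -> feature map ->
#' external force field -> [evolve()].  The returned contour and mask
#' are in full-image coordinates.
#'
#' @param image numeric matrix (full frame).
#' @param roi a [rect_roi()] containing the single target cell.
#' @param config parameter list (see [default_config()]); defaults are
#'   filled in for missing keys.
#' @param force_field `"vfc_mgrl"` (default), `"vfc_edge"` or `"gvf"`.
#' @param init optional initial contour in ROI coordinates (skips the
#'   histogram/morphology initialization; used by the tracking loop).
#' @return list of class `segment_result` with `contour` (full-image
#'   coordinates), `contour_roi`, `mask` (full-image 0/1), `initial`
#'   (initial contour, ROI coordinates), `fmap`, `iterations`,
#'   `converged`, `roi`, `config`, `force_field`.
#' @export
segment <- function(image, roi, config = default_config(),
                    force_field = c("vfc_mgrl", "vfc_edge", "gvf"),
                    init = NULL) {
  force_field <- match.arg(force_field)
  cfg <- default_config(config)
  roi_img <- crop(image, roi)
  init <- if (is.null(init)) initial_contour(roi_img, cfg) else as_contour(init)
  ff <- build_force_field(roi_img, cfg, force_field)
  ev <- evolve(init, ff$field, snake_params_from_config(cfg))
  offset <- c(roi$col0 - 1L, roi$row0 - 1L)
  global <- sweep(ev$contour, 2L, -offset)
  mask_roi <- contour_to_mask(ev$contour, dim(roi_img))
  mask <- matrix(0L, nrow(image), ncol(image))
  mask[roi$row0:roi$row1, roi$col0:roi$col1] <- mask_roi
  structure(list(contour = global, contour_roi = ev$contour, mask = mask,
                 initial = init, fmap = ff$fmap,
                 iterations = ev$iterations, converged = ev$converged,
                 roi = roi, config = cfg, force_field = force_field),
            class = "segment_result")
}

#' @export
print.segment_result <- function(x, ...) {
  cat("segment_result:", x$force_field, "snake,",
      nrow(x$contour), "points,", x$iterations, "iterations,",
      if (x$converged) "converged" else "not converged", "\n")
  cat(sprintf("  area %.1f px^2, perimeter %.1f px, centroid (%.1f, %.1f)\n",
              contour_area(x$contour), contour_perimeter(x$contour),
              contour_centroid(x$contour)[1L], contour_centroid(x$contour)[2L]))
  invisible(x)
}

#' Write the outputs of a segmentation or tracking run
#'
#' Writes contour CSV, per-frame mask and overlay PNGs, a summary CSV
#' (for tracking runs) and a JSON run log with all parameters.
#'
#' @param result a `segment_result` or `track_result`.
#' @param frames list of the input frames (for overlays); optional.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_run <- function(result, outdir, frames = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(result, "segment_result")) {
    records <- list(list(frame = 1L, contour = result$contour,
                         mask = result$mask, iterations = result$iterations,
                         converged = result$converged))
    cfg <- result$config
  } else {
    records <- result$records
    cfg <- result$config
  }
  write_contours(lapply(records, `[[`, "contour"),
                 file.path(outdir, "contours.csv"))
  for (rec in records) {
    tag <- sprintf("%04d", rec$frame)
    write_mask(rec$mask, file.path(outdir, paste0("mask_", tag, ".png")))
    if (!is.null(frames))
      write_overlay(frames[[rec$frame]], rec$contour,
                    file.path(outdir, paste0("overlay_", tag, ".png")))
  }
  if (inherits(result, "track_result"))
    utils::write.csv(summarize_track(result),
                     file.path(outdir, "summary.csv"), row.names = FALSE)
  log <- list(
    config = cfg[!vapply(cfg, is.null, logical(1))],
    frames = length(records),
    iterations = vapply(records, `[[`, integer(1), "iterations"),
    converged = vapply(records, `[[`, logical(1), "converged"))
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
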