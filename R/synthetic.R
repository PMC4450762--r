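# Synthetic phase-contrast-like single-cell scenes with ground truth.
# The model captures the features the segmentation pipeline relies on:
# a dark star-convex cell body with boundary harmonics (orders 2-6), a
# bright phase-halo ring just outside the boundary (sharp inner flank,
# gradual outer decay), dark interior patches (intensity
# inhomogeneity), angular arcs where the halo contrast is reduced
# (low-contrast edges), dark distractor blobs away from the cell, and
# additive Gaussian noise.  All randomness derives from one seed.

#' Specification of a synthetic cell scene
#'
#' Unset stochastic elements (harmonic coefficients, arc placement, hole
#' and distractor positions) are drawn deterministically from `seed` when
#' the scene is resolved.
#'
#' @param image_shape c(rows, cols), default c(192, 192).
#' @param cell_center (x, y) center, default image center.
#' @param base_radius mean cell radius in pixels (default 45, >= 8;
#'   a lymphocyte at high magnification spans on the order of a hundred
#'   pixels).
#' @param harmonics optional list with `amps` and `phases`, length-5
#'   vectors for boundary harmonic orders 2-6 (relative amplitudes).
#' @param body_level,background_level,halo_level intensities (defaults
#'   70, 120, 200); must satisfy body < background < halo.
#' @param halo_peak_offset radial offset of the halo peak outside the
#'   boundary (default 2 px; the halo is immediately adjacent to the
#'   membrane).
#' @param halo_sigma_in inner-flank Gaussian sigma (default 1 px).
#' @param halo_width radial FWHM of the halo ring (default 8 px); the
#'   outer-flank sigma is derived from it.
#' @param hole_spec list(count, radius, depth): interior dark patches
#'   (default 2 patches, radius 6, depth 40).
#' @param low_contrast_arcs either `NULL` (draw `n_arcs` arcs with spans
#'   40-60 degrees and contrast factors uniform in [0.25, 0.5]) or a
#'   matrix with columns start, span (radians), factor.  On these arcs
#'   both the halo amplitude and the rim (body-to-background) step are
#'   scaled by the factor, producing genuinely low-contrast edges.
#' @param rim_width width in pixels of the rim band over which the body
#'   fades toward background on low-contrast arcs (default 6).
#' @param n_arcs number of low-contrast arcs drawn when unset (default 2).
#' @param distractors list(count, radius, level): dark blobs placed
#'   outside the default ROI (default 2 blobs, radius 5, level 80).
#' @param noise_sigma additive Gaussian noise sd (default 3).
#' @param seed integer seed fixing all randomness (default 1).
#' @return list of class `scene_spec`.
#' @export
scene_spec <- function(image_shape = c(192L, 192L), cell_center = NULL,
                       base_radius = 45, harmonics = NULL,
                       body_level = 70, background_level = 120,
                       halo_level = 200, halo_peak_offset = 2,
                       halo_sigma_in = 1, halo_width = 8,
                       hole_spec = list(count = 2L, radius = 6, depth = 40),
                       low_contrast_arcs = NULL, n_arcs = 2L, rim_width = 6,
                       distractors = list(count = 2L, radius = 5, level = 80),
                       noise_sigma = 3, seed = 1L) {
  stopifnot(base_radius >= 8,
            body_level < background_level, background_level < halo_level,
            halo_width > 0, noise_sigma >= 0)
  structure(list(image_shape = as.integer(image_shape),
                 cell_center = cell_center, base_radius = base_radius,
                 harmonics = harmonics, body_level = body_level,
                 background_level = background_level, halo_level = halo_level,
                 halo_peak_offset = halo_peak_offset,
                 halo_sigma_in = halo_sigma_in, halo_width = halo_width,
                 hole_spec = hole_spec, low_contrast_arcs = low_contrast_arcs,
                 n_arcs = as.integer(n_arcs), rim_width = rim_width,
                 distractors = distractors,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "scene_spec")
}

# Materialize every stochastic element of a spec from its seed.
#' @keywords internal
resolve_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  s <- unclass(spec)
  if (is.null(s$cell_center))
    s$cell_center <- c((1 + s$image_shape[2L]) / 2, (1 + s$image_shape[1L]) / 2)
  with_seed(s$seed, {
    if (is.null(s$harmonics)) {
      caps <- c(0.05, 0.035, 0.025, 0.018, 0.012)   # orders 2-6
      s$harmonics <- list(amps = stats::runif(5L, 0, caps),
                          phases = stats::runif(5L, 0, 2 * pi))
    }
    if (is.null(s$low_contrast_arcs) && s$n_arcs > 0L) {
      span <- stats::runif(s$n_arcs, 40, 60) * pi / 180
      fac <- stats::runif(s$n_arcs, 0.25, 0.5)
      # place arcs without overlap (20 degree minimum separation):
      # partition the leftover circumference into random gaps
      sep <- 20 * pi / 180
      free <- 2 * pi - sum(span) - s$n_arcs * sep
      free <- max(free, 0)
      cuts <- if (s$n_arcs > 1L) sort(stats::runif(s$n_arcs - 1L, 0, free)) else numeric()
      gaps <- diff(c(0, cuts, free))
      base <- stats::runif(1L, 0, 2 * pi)
      start <- base + cumsum(gaps) + (seq_len(s$n_arcs) - 1L) * sep +
        c(0, cumsum(span))[seq_len(s$n_arcs)]
      s$low_contrast_arcs <- cbind(start = start %% (2 * pi),
                                   span = span, factor = fac)
    }
    hs <- s$hole_spec
    if (is.null(hs$pos) && hs$count > 0L) {
      hs$pos <- cbind(frac = stats::runif(hs$count, 0.3, 0.75),
                      angle = stats::runif(hs$count, 0, 2 * pi))
    }
    s$hole_spec <- hs
    ds <- s$distractors
    if (is.null(ds$pos) && ds$count > 0L) {
      ds$pos <- cbind(angle = stats::runif(ds$count, 0, 2 * pi),
                      jitter = stats::runif(ds$count, 0, 6))
    }
    s$distractors <- ds
  })
  s$halo_sigma_out <- max(1, s$halo_width / sqrt(2 * log(2)) - s$halo_sigma_in)
  s$rim_width <- s$rim_width %||% 6
  s$max_radius <- s$base_radius * (1 + sum(s$harmonics$amps))
  class(s) <- "scene_spec_resolved"
  s
}

#' @keywords internal
scene_radius_fun <- function(s) {
  function(theta) {
    r <- rep(s$base_radius, length(theta))
    mod <- 0
    for (k in 1:5)
      mod <- mod + s$harmonics$amps[k] * cos((k + 1) * theta + s$harmonics$phases[k])
    s$base_radius * (1 + mod)
  }
}

# Angular halo-contrast profile; the reduction tapers smoothly (cosine,
# ~10 degrees) into the surrounding full-contrast halo.
#' @keywords internal
arc_contrast <- function(theta, arcs, taper = 10 * pi / 180) {
  fac <- rep(1, length(theta))
  if (is.null(arcs) || nrow(arcs) == 0L) return(fac)
  for (i in seq_len(nrow(arcs))) {
    rel <- (theta - arcs[i, "start"]) %% (2 * pi)
    span <- arcs[i, "span"]
    # smooth dip: 0 outside [0, span], 1 on [taper, span - taper]
    w <- pmin(pmin(rel, span - rel) / taper, 1)
    w[rel < 0 | rel > span] <- 0
    fac <- pmin(fac, 1 - (1 - arcs[i, "factor"]) * w)
  }
  fac
}

#' Default tight ROI around the cell of a scene
#'
#' Covers the cell, its halo and a background margin; distractor blobs
#' are placed outside this window.
#'
#' @param spec a [scene_spec()] (or resolved scene).
#' @param margin extra margin beyond the halo extent (default 4 px).
#' @return a [rect_roi()].
#' @export
scene_roi <- function(spec, margin = 4) {
  s <- if (inherits(spec, "scene_spec_resolved")) spec else resolve_scene(spec)
  ext <- s$max_radius + s$halo_peak_offset + s$halo_width + margin
  rect_roi(max(1, floor(s$cell_center[2L] - ext)),
           max(1, floor(s$cell_center[1L] - ext)),
           min(s$image_shape[1L], ceiling(s$cell_center[2L] + ext)),
           min(s$image_shape[2L], ceiling(s$cell_center[1L] + ext)))
}

# Render a resolved scene; noise_seed fixes the noise realization.
#' @keywords internal
render_scene <- function(s, noise_seed = s$seed) {
  H <- s$image_shape[1L]; W <- s$image_shape[2L]
  cx <- s$cell_center[1L]; cy <- s$cell_center[2L]
  rfun <- scene_radius_fun(s)
  halo_ext <- s$halo_peak_offset + s$halo_width
  if (cx - s$max_radius - halo_ext < 1 || cx + s$max_radius + halo_ext > W ||
      cy - s$max_radius - halo_ext < 1 || cy + s$max_radius + halo_ext > H)
    stop("cell (including halo) exceeds image bounds")
  dx <- outer(rep(1, H), seq_len(W) - cx)
  dy <- outer(seq_len(H) - cy, rep(1, W))
  rho <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  d <- rho - rfun(theta)
  ain <- pmin(pmax(0.5 - d, 0), 1)          # body coverage, ~1 px soft edge
  fac <- arc_contrast(theta, s$low_contrast_arcs)
  # on low-contrast arcs the optically thin cell rim fades toward the
  # background, so the boundary step itself is weak there, not just the halo
  rim <- pmin(pmax(1 + d / s$rim_width, 0), 1)   # 0 deep inside -> 1 at edge
  body_eff <- s$body_level +
    (s$background_level - s$body_level) * (1 - fac) * rim
  img <- s$background_level + (body_eff - s$background_level) * ain
  hs <- s$hole_spec
  if (hs$count > 0L) {
    for (i in seq_len(hs$count)) {
      th <- hs$pos[i, "angle"]
      rr <- hs$pos[i, "frac"] * rfun(th)
      hx <- cx + rr * cos(th); hy <- cy + rr * sin(th)
      dh <- sqrt((dx - (hx - cx))^2 + (dy - (hy - cy))^2) - hs$radius
      img <- img - hs$depth * pmin(pmax(0.5 - dh, 0), 1) * ain
    }
  }
  sig <- ifelse(d < s$halo_peak_offset, s$halo_sigma_in, s$halo_sigma_out)
  halo <- (s$halo_level - s$background_level) * fac *
    exp(-0.5 * ((d - s$halo_peak_offset) / sig)^2)
  img <- img + halo * (1 - ain)
  ds <- s$distractors
  if (ds$count > 0L) {
    # keep distractors clear of the default ROI rectangle (and the frame)
    r0 <- scene_roi(s)
    for (i in seq_len(ds$count)) {
      th <- ds$pos[i, "angle"]
      placed <- FALSE
      for (rr in seq(s$max_radius + halo_ext + ds$radius + 6,
                     max(W, H), by = 2) + ds$pos[i, "jitter"]) {
        bx <- cx + rr * cos(th); by <- cy + rr * sin(th)
        clear_roi <- bx + ds$radius < r0$col0 - 2 ||
          bx - ds$radius > r0$col1 + 2 ||
          by + ds$radius < r0$row0 - 2 || by - ds$radius > r0$row1 + 2
        in_frame <- bx - ds$radius >= 2 && bx + ds$radius <= W - 1 &&
          by - ds$radius >= 2 && by + ds$radius <= H - 1
        if (clear_roi && in_frame) { placed <- TRUE; break }
        if (!in_frame && rr > s$max_radius + halo_ext) break
      }
      if (!placed) next   # no room outside the ROI: drop this blob
      db <- sqrt((dx - (bx - cx))^2 + (dy - (by - cy))^2) - ds$radius
      img <- img + (ds$level - s$background_level) *
        pmin(pmax(0.5 - db, 0), 1) * (1 - ain)
    }
  }
  if (s$noise_sigma > 0)
    img <- img + with_seed(noise_seed,
                           matrix(stats::rnorm(H * W, 0, s$noise_sigma), H, W))
  img <- pmin(pmax(img, 0), 255)
  mask <- (d <= 0) * 1L
  list(image = img, mask = mask)
}

#' Render a synthetic cell image with its ground-truth mask
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (matrix, 0-255), `mask` (0/1 matrix: the
#'   exact rendered cell region, holes counted as foreground), and
#'   `scene` (the resolved scene parameters).
#' @export
make_cell_image <- function(spec = scene_spec()) {
  s <- resolve_scene(spec)
  out <- render_scene(s)
  list(image = out$image, mask = out$mask, scene = s)
}

#' Specification of a synthetic cell sequence
#'
#' @param scene a [scene_spec()] for the base frame.
#' @param n_frames number of frames (default 30).
#' @param drift per-frame centroid drift (dx, dy) in pixels
#'   (default c(0.7, 0.4); keep below ~2 px/frame so that frame-to-frame
#'   contour propagation is valid).
#' @param walk_scale sd of the per-frame random-walk increments of the
#'   relative harmonic amplitudes (default 0.004; phases walk with sd
#'   `5 * walk_scale` radians).
#' @param frame_interval acquisition interval in seconds, carried as
#'   metadata (default 0.04).
#' @param seed integer seed (default: scene seed + 1000).
#' @return list of class `sequence_spec`.
#' @export
sequence_spec <- function(scene = scene_spec(), n_frames = 30L,
                          drift = c(0.7, 0.4), walk_scale = 0.004,
                          frame_interval = 0.04, seed = NULL) {
  stopifnot(n_frames >= 1L, length(drift) == 2L, walk_scale >= 0)
  structure(list(scene = scene, n_frames = as.integer(n_frames),
                 drift = drift, walk_scale = walk_scale,
                 frame_interval = frame_interval,
                 seed = as.integer(seed %||% (scene$seed + 1000L))),
            class = "sequence_spec")
}

#' Render a synthetic cell sequence with ground-truth masks
#'
#' The cell centroid drifts linearly (the path is centered so the mean
#' position is the base scene center); boundary harmonics follow a
#' seeded random walk (amplitudes reflected into [0, 0.08]); interior
#' holes and low-contrast arcs move with the cell; noise is drawn
#' independently per frame.
#'
#' @param spec a [sequence_spec()].
#' @return list with `frames` (list of matrices), `masks` (list of 0/1
#'   matrices), `roi` (a [rect_roi()] covering the cell in every frame),
#'   and `scenes` (per-frame resolved scenes).
#' @export
make_cell_sequence <- function(spec = sequence_spec()) {
  stopifnot(inherits(spec, "sequence_spec"))
  base <- resolve_scene(spec$scene)
  n <- spec$n_frames
  # center the drift path on the base center
  offs <- outer(seq_len(n) - (n + 1) / 2, spec$drift)
  walks <- with_seed(spec$seed, list(
    damp = matrix(stats::rnorm(n * 5L, 0, spec$walk_scale), n, 5L),
    dph = matrix(stats::rnorm(n * 5L, 0, 5 * spec$walk_scale), n, 5L)))
  amps <- base$harmonics$amps
  phases <- base$harmonics$phases
  frames <- vector("list", n); masks <- vector("list", n)
  scenes <- vector("list", n)
  static <- all(spec$drift == 0) && spec$walk_scale == 0
  lo <- hi <- NULL
  for (i in seq_len(n)) {
    if (i > 1L && !static) {
      amps <- amps + walks$damp[i, ]
      amps <- abs(amps)                       # reflect at 0
      amps <- 0.08 - abs(0.08 - amps)         # reflect at 0.08
      phases <- phases + walks$dph[i, ]
    }
    s <- base
    s$cell_center <- base$cell_center + offs[i, ]
    s$harmonics <- list(amps = amps, phases = phases)
    s$max_radius <- s$base_radius * (1 + sum(amps))
    # a strictly static sequence replicates the identical frame
    out <- render_scene(s, noise_seed = if (static) spec$seed + 104730L
                                        else spec$seed + 104729L + i)
    frames[[i]] <- out$image; masks[[i]] <- out$mask; scenes[[i]] <- s
    r <- scene_roi(s)
    if (is.null(lo)) { lo <- c(r$row0, r$col0); hi <- c(r$row1, r$col1) }
    lo <- pmin(lo, c(r$row0, r$col0)); hi <- pmax(hi, c(r$row1, r$col1))
  }
  list(frames = frames, masks = masks,
       roi = rect_roi(lo[1L], lo[2L], hi[1L], hi[2L]),
       frame_interval = spec$frame_interval, scenes = scenes)
}
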