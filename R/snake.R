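# Parametric snake evolution.  The discrete update per point i is
#
#   x_i <- x_i + gamma * (alpha * D2(x)_i / h^2 - beta * D4(x)_i / h^4 + u(x_i, y_i))
#
# (and likewise for y), where D2 and D4 are periodic central second and
# fourth differences and (u, v) is the external force sampled bilinearly
# at the subpixel point.  The default parameter spacing is h = 1 (index
# units): with unit spacing the tabulated weights (alpha = 2,
# beta = 0.2) balance external forces of order one, which is the
# standard practice for explicit snake schemes.

#' Snake evolution parameters
#'
#' @param alpha elasticity weight (default 2).
#' @param beta rigidity weight (default 0.2).
#' @param gamma time step (default 0.15, within the explicit stability
#'   bound for the default weights; halved adaptively when an iteration
#'   would move any point more than `2 * target_spacing`).
#' @param n_iter maximum iterations (default 100).
#' @param tol convergence tolerance: maximum per-point displacement in
#'   pixels below which the contour is flagged converged (default 0.05).
#' @param stop_on_converge stop early once converged? Default `FALSE`
#'   (a fixed iteration budget, matching the reference configuration).
#' @param resample_every resample to uniform arc length every this many
#'   iterations (default 5).
#' @param target_spacing point spacing for resampling in pixels
#'   (default 2).
#' @param h parameter spacing used in the difference quotients
#'   (default 1).
#' @return list of class `snake_params`.
#' @export
snake_params <- function(alpha = 2, beta = 0.2, gamma = 0.15, n_iter = 100L,
                         tol = 0.05, stop_on_converge = FALSE,
                         resample_every = 5L, target_spacing = 2, h = 1) {
  stopifnot(alpha >= 0, beta >= 0, gamma > 0, n_iter >= 1L, tol >= 0,
            resample_every >= 1L, target_spacing > 0, h > 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 n_iter = as.integer(n_iter), tol = tol,
                 stop_on_converge = isTRUE(stop_on_converge),
                 resample_every = as.integer(resample_every),
                 target_spacing = target_spacing, h = h),
            class = "snake_params")
}

#' Internal (smoothness) force of a closed contour
#'
#' Per-point vector `alpha * D2 / h^2 - beta * D4 / h^4` with periodic
#' indexing, where D2 and D4 are the central second and fourth
#' differences of the point coordinates.
#'
#' @param contour N x 2 matrix.
#' @param alpha elasticity weight.
#' @param beta rigidity weight.
#' @param h parameter spacing (default 1).
#' @return N x 2 matrix of force vectors.
#' @export
internal_force <- function(contour, alpha, beta, h = 1) {
  p <- as.matrix(contour)
  n <- nrow(p)
  ip <- c(2:n, 1L); im <- c(n, 1:(n - 1L))
  d2 <- p[ip, , drop = FALSE] - 2 * p + p[im, , drop = FALSE]
  d4 <- d2[ip, , drop = FALSE] - 2 * d2 + d2[im, , drop = FALSE]
  alpha * d2 / h^2 - beta * d4 / h^4
}

#' Bilinear sampling of a vector field at subpixel points
#'
#' Field component matrices are indexed `[row, col]` with the vector at
#' (x = col, y = row).  Query points outside the grid are clamped to the
#' border.
#'
#' @param field list with matrices `u`, `v`.
#' @param points N x 2 matrix of (x, y) query points.
#' @return N x 2 matrix of sampled (u, v) vectors.
#' @export
sample_field <- function(field, points) {
  p <- as.matrix(points)
  if (is.null(dim(p))) p <- matrix(p, ncol = 2L)
  nr <- nrow(field$u); nc <- ncol(field$u)
  x <- pmin(pmax(p[, 1L], 1), nc)
  y <- pmin(pmax(p[, 2L], 1), nr)
  x0 <- pmin(floor(x), nc - 1L); y0 <- pmin(floor(y), nr - 1L)
  if (nc == 1L) x0 <- rep(1, length(x))
  if (nr == 1L) y0 <- rep(1, length(y))
  fx <- x - x0; fy <- y - y0
  x1 <- pmin(x0 + 1L, nc); y1 <- pmin(y0 + 1L, nr)
  bl <- function(m) {
    m[cbind(y0, x0)] * (1 - fx) * (1 - fy) + m[cbind(y0, x1)] * fx * (1 - fy) +
    m[cbind(y1, x0)] * (1 - fx) * fy       + m[cbind(y1, x1)] * fx * fy
  }
  cbind(u = bl(field$u), v = bl(field$v))
}

#' One explicit snake update step
#'
#' @param contour N x 2 matrix.
#' @param field external force field (list `u`, `v`).
#' @param alpha,beta,gamma,h scheme parameters.
#' @return N x 2 updated contour (orientation untouched).
#' @keywords internal
snake_step <- function(contour, field, alpha, beta, gamma, h = 1) {
  p <- as.matrix(contour)
  sf <- sample_field(field, p)
  dimnames(sf) <- dimnames(p)
  p + gamma * (internal_force(p, alpha, beta, h) + sf)
}

#' Evolve a snake under an external force field
#'
#' Runs the explicit update for up to `n_iter` iterations with periodic
#' arc-length resampling.  A stability guard halves `gamma` and retries
#' whenever a step would displace any point by more than
#' `2 * target_spacing`.  The contour is flagged converged once the
#' maximum per-point displacement in one iteration falls below `tol`
#' (evolution continues to the full budget unless
#' `stop_on_converge = TRUE`).
#'
#' @param contour initial N x 2 contour.
#' @param field external force field (list `u`, `v`) covering the ROI.
#' @param params a [snake_params()] list.
#' @return list with elements `contour`, `iterations`, `converged`,
#'   `gamma` (final, possibly reduced), `gamma_halvings`.
#' @export
evolve <- function(contour, field, params = snake_params()) {
  stopifnot(inherits(params, "snake_params"))
  p <- as_contour(contour)
  gamma <- params$gamma
  halvings <- 0L
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(params$n_iter)) {
    repeat {
      q <- snake_step(p, field, params$alpha, params$beta, gamma, params$h)
      disp <- sqrt(rowSums((q - p)^2))
      if (max(disp) <= 2 * params$target_spacing || gamma <= 1e-8) break
      gamma <- gamma / 2
      halvings <- halvings + 1L
    }
    p <- q
    iters <- it
    if (contour_area(p) < 4)
      stop("contour collapsed; check force field / gamma")
    if (max(disp) < params$tol) {
      converged <- TRUE
      if (params$stop_on_converge) break
    }
    if (it %% params$resample_every == 0L)
      p <- resample_contour(p, params$target_spacing)
  }
  p <- as_contour(p)
  list(contour = p, iterations = iters, converged = converged,
       gamma = gamma, gamma_halvings = halvings)
}
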