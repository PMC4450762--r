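# External force fields for the snake.  The vector field convolution
# (VFC) force is the feature map convolved with a radially attracting
# kernel k(x, y) = (x^2 + y^2 + eps)^(-r) * n(x, y), where n points to
# the kernel origin.  The gradient vector flow (GVF) field -- the
# comparison baseline -- diffuses the edge-map gradient by explicit
# gradient descent on the usual regularized functional.

#' Vector field convolution kernel
#'
#' Builds the two kernel components on a `(2R+1) x (2R+1)` window.  The
#' magnitude is `(x^2 + y^2 + eps)^(-r)` and the direction is the unit
#' vector pointing to the origin; the origin entry is (0, 0).  When `R`
#' is `NULL` the radius is chosen so that the omitted tail magnitude is
#' below `1e-4` of the peak (i.e. `R >= 10^(2/r)`), clamped to
#' `[8, 128]`; an explicitly requested radius that leaves a heavier tail
#' triggers a warning.
#'
#' @param R kernel radius in pixels, or `NULL` for automatic.
#' @param r positive decay exponent (2 in the method description; 1 in
#'   the tabulated parameter set -- both are supported).
#' @param eps small positive regularizer.
#' @return list with components `kx`, `ky` (matrices), `R`, `r`, `eps`,
#'   of class `vfc_kernel`.
#' @export
make_vfc_kernel <- function(R = NULL, r = 2, eps = 1e-8) {
  stopifnot(r > 0, eps > 0)
  tail_of <- function(R) ((R^2 + eps) / (1 + eps))^(-r)
  auto_R <- max(8, min(128, ceiling(10^(2 / r))))
  while (tail_of(auto_R) >= 1e-4 && auto_R < 128) auto_R <- auto_R + 1L
  if (is.null(R)) R <- auto_R
  R <- as.integer(R)
  stopifnot(R >= 1L)
  # peak magnitude sits at distance 1; tail at distance R
  tail_ratio <- tail_of(R)
  if (tail_ratio >= 1e-4)
    warning(sprintf(
      "VFC kernel radius %d leaves a tail of %.2g of the peak (r = %g); consider R >= %d",
      R, tail_ratio, r, auto_R))
  xs <- seq.int(-R, R)
  x <- outer(rep(1, length(xs)), xs)   # column offset
  y <- outer(xs, rep(1, length(xs)))   # row offset
  d2 <- x^2 + y^2
  mag <- (d2 + eps)^(-r)
  len <- sqrt(d2)
  len[len == 0] <- 1
  kx <- mag * (-x / len)
  ky <- mag * (-y / len)
  kx[R + 1L, R + 1L] <- 0
  ky[R + 1L, R + 1L] <- 0
  structure(list(kx = kx, ky = ky, R = R, r = r, eps = eps),
            class = "vfc_kernel")
}

#' VFC force field
#'
#' Convolves the feature map with both kernel components (reflected
#' boundary).  For a single-point feature map the field is the kernel
#' translated to that point, so every vector attracts toward it.
#'
#' @param fmap feature-map matrix (binary or weighted).
#' @param kernel a [make_vfc_kernel()] object.
#' @return list with matrices `u` (x-component) and `v` (y-component).
#' @export
vfc_field <- function(fmap, kernel) {
  stopifnot(inherits(kernel, "vfc_kernel"), is.matrix(fmap))
  f <- fmap * 1.0
  list(u = conv2_reflect(f, kernel$kx), v = conv2_reflect(f, kernel$ky))
}

#' Gradient vector flow field
#'
#' Explicit gradient descent on the GVF functional
#' `integral mu |grad V|^2 + |grad f|^2 |V - grad f|^2`: the field is
#' initialized at `grad f` and iterated with
#' `V <- V + dt (mu lap V - |grad f|^2 (V - grad f))`.  The edge map is
#' rescaled to `[0, 1]` first (conventional), and the step size is set
#' internally for stability.
#'
#' @param edge_map nonnegative edge-map matrix.
#' @param mu regularization weight (default 0.1).
#' @param n_iter number of iterations (default 200).
#' @return list with matrices `u`, `v`.
#' @export
gvf_field <- function(edge_map, mu = 0.1, n_iter = 200L) {
  stopifnot(mu > 0, n_iter >= 1L)
  f <- edge_map
  rng <- range(f)
  if (diff(rng) > 0) f <- (f - rng[1L]) / diff(rng)
  fx <- (shift_rep(f, 0L, -1L) - shift_rep(f, 0L, 1L)) / 2
  fy <- (shift_rep(f, -1L, 0L) - shift_rep(f, 1L, 0L)) / 2
  b <- fx^2 + fy^2
  dt <- 0.9 / (4 * mu + max(b, 1e-12))
  lap <- function(z)
    shift_rep(z, 0L, -1L) + shift_rep(z, 0L, 1L) +
    shift_rep(z, -1L, 0L) + shift_rep(z, 1L, 0L) - 4 * z
  u <- fx; v <- fy
  for (i in seq_len(n_iter)) {
    u <- u + dt * (mu * lap(u) - b * (u - fx))
    v <- v + dt * (mu * lap(v) - b * (v - fy))
    if (!all(is.finite(u)) || !all(is.finite(v)))
      stop("GVF iteration diverged; reduce the internal step size or mu")
  }
  list(u = u, v = v)
}

#' GVF energy (used to verify descent)
#' @keywords internal
gvf_energy <- function(u, v, fx, fy, mu) {
  gx <- function(z) (shift_mat(z, 0L, -1L, 0) - shift_mat(z, 0L, 1L, 0)) / 2
  gy <- function(z) (shift_mat(z, -1L, 0L, 0) - shift_mat(z, 1L, 0L, 0)) / 2
  b <- fx^2 + fy^2
  sum(mu * (gx(u)^2 + gy(u)^2 + gx(v)^2 + gy(v)^2) +
        b * ((u - fx)^2 + (v - fy)^2))
}

#' Normalize a vector field to unit magnitude
#'
#' Each nonzero vector is scaled to length 1; zero vectors are left
#' unchanged.  Off by default in the snake pipeline.
#'
#' @param field list with matrices `u`, `v`.
#' @return list with matrices `u`, `v`.
#' @export
normalize_field <- function(field) {
  mag <- sqrt(field$u^2 + field$v^2)
  s <- ifelse(mag > 0, mag, 1)
  list(u = field$u / s, v = field$v / s)
}

#' Soft unit normalization of a force field
#'
#' Scales each vector by `1 / sqrt(|v|^2 + q^2)`: unit magnitude where
#' the field is strong, linearly vanishing where it is weak (near the
#' equilibrium between opposing attractors).  Unlike hard normalization
#' this leaves the evolution with a true fixed point, so the snake
#' settles instead of dithering at the edge.  The floor `q` defaults to
#' one tenth of the median nonzero field magnitude.
#'
#' @param field list with matrices `u`, `v`.
#' @param q magnitude floor; `NULL` for the default.
#' @return list with matrices `u`, `v`.
#' @export
soft_normalize_field <- function(field, q = NULL) {
  mag <- sqrt(field$u^2 + field$v^2)
  if (is.null(q)) {
    nz <- mag[mag > 0]
    q <- if (length(nz)) 0.1 * stats::median(nz) else 1
  }
  s <- sqrt(mag^2 + q^2)
  list(u = field$u / s, v = field$v / s)
}
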