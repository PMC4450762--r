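test_that("contours are normalized, measured, and resampled correctly", {
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  p <- as_contour(sq)
  expect_equal(contour_area(p), 100)
  expect_equal(contour_perimeter(p), 40)
  expect_equal(unname(contour_centroid(p)), c(5, 5))
  # orientation normalized: reversed input gives the same signed area
  expect_equal(contour_area(as_contour(sq[4:1, ]), signed = TRUE), 100)
  expect_error(as_contour(rbind(c(0, 0), c(1, 1), c(0, 0))), "degenerate")
  # duplicate consecutive points are merged
  expect_equal(nrow(as_contour(sq[c(1, 1, 2, 3, 3, 4), ])), 4L)
})

test_that("resampling yields uniform arc length and preserves the perimeter", {
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  circ <- cbind(50 + 50 * cos(th), 50 + 50 * sin(th))
  r <- resample_contour(circ, target_spacing = 2 * pi * 50 / 64)
  expect_equal(nrow(r), 64L)
  ang <- atan2(r[, 2] - 50, r[, 1] - 50)
  gaps <- diff(sort(ang))
  expect_true(all(abs(gaps - 2 * pi / 64) < 0.5 * pi / 180))
  expect_lt(abs(contour_perimeter(r) - contour_perimeter(circ)) /
              contour_perimeter(circ), 0.01)
  # already-uniform contour is a fixpoint
  r2 <- resample_contour(r, n = 64L)
  expect_lt(max(abs(r2 - r)), 1e-6)
})

test_that("internal force follows the periodic difference formulas", {
  # regular N-gon: all force vectors point radially inward, equal magnitude
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  poly <- cbind(20 * cos(th), 20 * sin(th))
  f <- internal_force(poly, alpha = 1.5, beta = 0, h = 1)
  rad <- -poly / sqrt(rowSums(poly^2))
  mags <- sqrt(rowSums(f^2))
  expect_equal(sd(mags) / mean(mags), 0, tolerance = 1e-10)
  dots <- rowSums(f * rad) / mags
  expect_equal(dots, rep(1, 12), tolerance = 1e-10)
  expect_equal(internal_force(poly, 0, 0), 0 * poly)
  # middle of three collinear equispaced points has zero second difference
  line <- rbind(c(0, 0), c(1, 0), c(2, 0), c(2, 2), c(0, 2))
  f2 <- internal_force(line, alpha = 1, beta = 0)
  expect_equal(unname(f2[2, ]), c(0, 0))
})

test_that("one explicit step on a square matches the hand formula with h = 1/3", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  field <- list(u = matrix(0, 3, 3), v = matrix(0, 3, 3))
  gamma <- 0.01; alpha <- 1; h <- 1 / 3
  stepped <- phasesnake:::snake_step(sq, field, alpha, 0, gamma, h)
  for (i in 1:4) {
    ip <- if (i == 4) 1 else i + 1
    im <- if (i == 1) 4 else i - 1
    expected <- sq[i, ] + gamma * alpha * (sq[ip, ] - 2 * sq[i, ] + sq[im, ]) / h^2
    expect_equal(unname(stepped[i, ]), unname(expected), tolerance = 1e-12)
  }
})

test_that("field sampling is bilinear with border clamping", {
  u <- matrix(0, 2, 2); u[1, 1] <- 1; u[1, 2] <- 0
  v <- matrix(0, 2, 2); v[1, 2] <- 1
  fld <- list(u = u, v = v)
  expect_equal(unname(sample_field(fld, cbind(1, 1))), cbind(1, 0))
  mid <- sample_field(fld, cbind(1.5, 1))
  expect_equal(unname(mid), cbind(0.5, 0.5))
  far <- sample_field(fld, cbind(100, -50))
  expect_equal(unname(far), unname(sample_field(fld, cbind(2, 1))))
})

test_that("a vectorized step equals the scalar-loop update to 1e-10", {
  set.seed(77)
  for (trial in 1:10) {
    p <- cbind(runif(32, 3, 18), runif(32, 3, 18))
    z <- matrix(rnorm(21 * 21), 21, 21)
    fld <- list(u = phasesnake:::gaussian_blur(z, 2),
                v = phasesnake:::gaussian_blur(matrix(rnorm(441), 21, 21), 2))
    a <- runif(1, 0, 3); b <- runif(1, 0, 0.5); g <- runif(1, 0.01, 0.3)
    expect_equal(phasesnake:::snake_step(p, fld, a, b, g),
                 oracle_snake_step(p, fld, a, b, g), tolerance = 1e-10)
  }
})

test_that("evolution contracts under pure tension and detects collapse", {
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  circ <- cbind(30 + 10 * cos(th), 30 + 10 * sin(th))
  zerof <- list(u = matrix(0, 60, 60), v = matrix(0, 60, 60))
  pars <- snake_params(alpha = 1, beta = 0, gamma = 0.1, n_iter = 20,
                       resample_every = 100)
  p <- circ
  per <- contour_perimeter(p)
  for (i in 1:5) {
    p <- phasesnake:::snake_step(p, zerof, 1, 0, 0.1)
    expect_lt(contour_perimeter(p), per)
    per <- contour_perimeter(p)
  }
  # running long enough collapses the contour below the area guard
  pars2 <- snake_params(alpha = 2, beta = 0, gamma = 0.15, n_iter = 2000,
                        resample_every = 5)
  expect_error(evolve(circ, zerof, pars2), "collapsed")
})

test_that("with rigidity only, bending energy is non-increasing", {
  set.seed(12)
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  p <- cbind(40 + 12 * cos(th) + rnorm(40, 0, 0.8),
             40 + 12 * sin(th) + rnorm(40, 0, 0.8))
  zerof <- list(u = matrix(0, 80, 80), v = matrix(0, 80, 80))
  bend <- function(q) {
    n <- nrow(q); ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
    sum((q[ip, ] - 2 * q + q[im, ])^2)
  }
  e <- bend(p)
  for (i in 1:30) {
    p <- phasesnake:::snake_step(p, zerof, 0, 0.2, 0.05)
    e2 <- bend(p)
    expect_lte(e2, e + 1e-9)
    e <- e2
  }
})

test_that("evolution is deterministic and the stability guard engages", {
  sc <- test_scene(seed = 5)
  roi <- scene_roi(sc$scene)
  ri <- crop(sc$image, roi)
  cfg <- preset_config("vfc_mgrl")
  init <- initial_contour(ri, cfg)
  ff <- phasesnake:::build_force_field(ri, cfg, "vfc_mgrl")
  pars <- phasesnake:::snake_params_from_config(cfg)
  e1 <- evolve(init, ff$field, pars)
  e2 <- evolve(init, ff$field, pars)
  expect_identical(e1$contour, e2$contour)
  # an unstable step size is halved rather than diverging
  pars_wild <- snake_params(alpha = 2, beta = 0.2, gamma = 2, n_iter = 30)
  ew <- evolve(init, ff$field, pars_wild)
  expect_gt(ew$gamma_halvings, 0)
  expect_lt(ew$gamma, 2)
  expect_true(all(is.finite(ew$contour)))
})
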