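test_that("the VFC kernel has the stated magnitude, direction and symmetry", {
  k <- make_vfc_kernel(R = 12, r = 2, eps = 1e-12)
  c0 <- 13L  # origin index
  expect_equal(k$kx[c0, c0], 0)
  expect_equal(k$ky[c0, c0], 0)
  # at (x = 1, y = 0): magnitude ~ 1, direction (-1, 0)
  expect_equal(k$kx[c0, c0 + 1L], -1, tolerance = 1e-6)
  expect_equal(k$ky[c0, c0 + 1L], 0)
  # antisymmetry k(-x, -y) = -k(x, y)
  expect_equal(k$kx, -k$kx[rev(seq_len(25)), rev(seq_len(25))])
  expect_equal(k$ky, -k$ky[rev(seq_len(25)), rev(seq_len(25))])
  # every off-origin vector points toward the origin
  xs <- outer(rep(1, 25), -12:12); ys <- outer(-12:12, rep(1, 25))
  dot <- k$kx * (-xs) + k$ky * (-ys)
  expect_true(all(dot[xs != 0 | ys != 0] > 0))
})

test_that("automatic kernel radius satisfies the truncation-tail bound", {
  for (r in c(1, 2)) {
    k <- make_vfc_kernel(NULL, r = r)
    tail_ratio <- ((k$R^2 + k$eps) / (1 + k$eps))^(-r)
    expect_lt(tail_ratio, 1e-4)
  }
  expect_gt(make_vfc_kernel(NULL, r = 1)$R, make_vfc_kernel(NULL, r = 2)$R)
  expect_warning(make_vfc_kernel(R = 5, r = 1), "tail")
})

test_that("VFC field of a delta is the translated kernel, and attracts everywhere", {
  k <- make_vfc_kernel(R = 12, r = 2)
  f <- matrix(0, 30, 34)
  f[14, 18] <- 1
  v <- vfc_field(f, k)
  for (dr in c(-5, -1, 0, 2, 6)) for (dc in c(-4, 0, 3)) {
    if (dr == 0 && dc == 0) next
    expect_lt(abs(v$u[14 + dr, 18 + dc] - k$kx[13 + dr, 13 + dc]), 1e-10)
    expect_lt(abs(v$v[14 + dr, 18 + dc] - k$ky[13 + dr, 13 + dc]), 1e-10)
  }
  xs <- outer(rep(1, 30), seq_len(34)) - 18
  ys <- outer(seq_len(30), rep(1, 34)) - 14
  dot <- v$u * (-xs) + v$v * (-ys)
  expect_true(all(dot > -1e-9))
})

test_that("VFC field is linear and translation-equivariant", {
  k <- make_vfc_kernel(R = 12, r = 2)
  set.seed(8)
  f1 <- matrix(rbinom(400, 1, 0.1), 20, 20)
  f2 <- matrix(rbinom(400, 1, 0.1), 20, 20)
  v1 <- vfc_field(f1, k); v2 <- vfc_field(f2, k); v12 <- vfc_field(f1 + f2, k)
  expect_equal(v12$u, v1$u + v2$u, tolerance = 1e-9)
  expect_equal(v12$v, v1$v + v2$v, tolerance = 1e-9)
  # shift the map by (2, 3): interior field shifts identically
  g <- matrix(0, 20, 20)
  g[9:12, 9:12] <- f1[7:10, 6:9]
  vg <- vfc_field(g, k)
  h <- matrix(0, 20, 20); h[7:10, 6:9] <- f1[7:10, 6:9]
  vh <- vfc_field(h, k)
  expect_equal(vg$u[11, 11], vh$u[9, 8], tolerance = 1e-8)
  expect_equal(vg$v[12, 10], vh$v[10, 7], tolerance = 1e-8)
})

test_that("GVF descends its energy and reproduces the edge gradient at ridges", {
  f <- matrix(0, 25, 25)
  f[, 13:25] <- 100
  # uniform map: zero field
  v0 <- gvf_field(matrix(5, 10, 10), 0.1, 5)
  expect_equal(max(abs(v0$u)), 0)
  expect_equal(max(abs(v0$v)), 0)
  # energy non-increasing over iterations
  fn <- f / max(f)
  fx <- (phasesnake:::shift_rep(fn, 0L, -1L) - phasesnake:::shift_rep(fn, 0L, 1L)) / 2
  fy <- (phasesnake:::shift_rep(fn, -1L, 0L) - phasesnake:::shift_rep(fn, 1L, 0L)) / 2
  energies <- vapply(c(1, 5, 20, 80), function(n) {
    v <- gvf_field(f, 0.1, n)
    phasesnake:::gvf_energy(v$u, v$v, fx, fy, 0.1)
  }, numeric(1))
  expect_true(all(diff(energies) <= 1e-9))
  # at the ridge the field is pinned: the run agrees with a much longer
  # run there (away from edges pure diffusion keeps spreading, by design)
  ridge <- abs(fx) > 0.9 * max(abs(fx))
  v1 <- gvf_field(f, 0.1, 400)
  v2 <- gvf_field(f, 0.1, 4000)
  expect_lt(max(abs(v1$u[ridge] - v2$u[ridge])), 0.02)
  # with weak regularization the converged field approximates grad f
  # at edge-ridge pixels (stronger mu trades fidelity for smoothness)
  vw <- gvf_field(f, 0.02, 2000)
  relerr <- abs(vw$u[ridge] - fx[ridge]) / abs(fx[ridge])
  expect_lt(max(relerr), 0.10)
})

test_that("field normalization is exact, idempotent, and soft variant bounded", {
  z <- list(u = matrix(0, 4, 4), v = matrix(0, 4, 4))
  expect_equal(normalize_field(z), z)
  f <- list(u = matrix(3, 2, 2), v = matrix(4, 2, 2))
  n1 <- normalize_field(f)
  expect_equal(n1$u[1, 1], 0.6)
  expect_equal(n1$v[1, 1], 0.8)
  expect_equal(normalize_field(n1), n1)
  s <- soft_normalize_field(f, q = 1)
  mag <- sqrt(s$u^2 + s$v^2)
  expect_true(all(mag <= 1))
  expect_gt(min(mag), 0.9)   # strong vectors stay near unit
})
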