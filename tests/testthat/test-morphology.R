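test_that("reconstruction satisfies the basic marker/mask identities", {
  I <- matrix(runif(49, 0, 100), 7, 7)
  expect_equal(grayscale_reconstruct(I, I), I)
  J <- matrix(10, 7, 7); M <- matrix(42, 7, 7)
  expect_equal(grayscale_reconstruct(J, M), J)   # flat marker stays flat
  expect_error(grayscale_reconstruct(J, matrix(42, 6, 7)), "same shape")
  expect_warning(out <- grayscale_reconstruct(M, J), "clamping")
  expect_equal(out, J)
})

test_that("reconstruction matches the brute-force geodesic fixpoint on a ring/well image", {
  # bright ring (200) enclosing a dark well (50) on background 100;
  # marker = image on the border, 0 inside
  I <- matrix(100, 7, 7)
  I[2:6, 2:6] <- 200
  I[3:5, 3:5] <- 200
  I[4, 4] <- 50
  J <- matrix(0, 7, 7)
  J[c(1, 7), ] <- I[c(1, 7), ]; J[, c(1, 7)] <- I[, c(1, 7)]
  expect_identical(grayscale_reconstruct(J, I), oracle_reconstruct(J, I))
})

test_that("reconstruction is increasing and anti-extensive w.r.t. the mask", {
  set.seed(31)
  I <- matrix(sample(0:50, 100, TRUE), 10, 10)
  J1 <- pmin(matrix(sample(0:50, 100, TRUE), 10, 10), I)
  J2 <- pmin(J1 + 3, I)     # larger marker
  r1 <- grayscale_reconstruct(J1, I)
  r2 <- grayscale_reconstruct(J2, I)
  expect_true(all(r1 <= I))
  expect_true(all(r1 >= J1))
  expect_true(all(r2 >= r1))
  # idempotent as a marker
  expect_identical(grayscale_reconstruct(r1, I), r1)
})

test_that("fill_holes raises enclosed minima and nothing else", {
  expect_equal(fill_holes(matrix(7, 6, 6)), matrix(7, 6, 6))
  # bright disk (200) containing a dark pit (50) on background 100
  I <- matrix(100, 11, 11)
  d <- sqrt(outer((1:11 - 6)^2, (1:11 - 6)^2, "+"))
  I[d <= 3.5] <- 200
  I[6, 6] <- 50
  out <- fill_holes(I)
  expect_equal(out[6, 6], 200)
  expect_true(all(out[d > 3.5] == 100))
  expect_identical(fill_holes(out), out)       # idempotent
  expect_true(all(out >= I))                   # never decreases
  expect_identical(out[1, ], I[1, ])           # border unchanged
})

test_that("remove_small_components enforces the size floor exactly", {
  z <- matrix(0L, 8, 8)
  expect_equal(remove_small_components(z, 15), z)
  # single 10-pixel component is removed at P = 15
  a <- matrix(0L, 8, 8); a[2:6, 3] <- 1L; a[2:6, 4] <- 1L
  expect_equal(sum(remove_small_components(a, 15)), 0)
  # components of sizes 14 and 20: only the 20-pixel one survives
  b <- matrix(0L, 12, 12)
  b[2:8, 2:3] <- 1L            # 14 px
  b[10:11, 1:10] <- 1L         # 20 px
  out <- remove_small_components(b, 15)
  expect_equal(sum(out), 20)
  expect_true(all(out[10:11, 1:10] == 1L))
  # never adds pixels; all surviving components >= P
  set.seed(41)
  for (i in 1:5) {
    r <- matrix(rbinom(15 * 15, 1, 0.4), 15, 15)
    o <- remove_small_components(r, 5)
    expect_true(all(o <= r))
    lab <- label_components(o)
    if (max(lab) > 0) expect_true(all(tabulate(lab[lab > 0]) >= 5))
  }
})

test_that("open_close removes specks, keeps large blobs, and is idempotent", {
  big <- matrix(0L, 31, 31)
  d <- sqrt(outer((1:31 - 16)^2, (1:31 - 16)^2, "+"))
  big[d <= 11] <- 1L
  out <- open_close(big, 3)
  expect_gt(jaccard(out, big), 0.97)           # near-invariant smooth object
  pt <- matrix(0L, 15, 15); pt[8, 8] <- 1L
  expect_equal(sum(open_close(pt, 3)), 0)      # lone pixel erased by opening
  mixed <- big; mixed[2, 2] <- 1L
  expect_identical(open_close(open_close(mixed, 3), 3), open_close(mixed, 3))
})

test_that("reconstruction equals the brute-force fixpoint on random images", {
  set.seed(99)
  for (i in 1:30) {
    I <- matrix(sample(0:30, 144, TRUE), 12, 12)
    J <- pmin(matrix(sample(0:30, 144, TRUE), 12, 12), I)
    expect_identical(grayscale_reconstruct(J, I), oracle_reconstruct(J, I))
  }
})
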