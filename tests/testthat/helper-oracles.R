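# Independent brute-force oracles: deliberately scalar (double for-loops,
# no vectorization) so they share no code path with the implementation.

# Reconstruction by dilation: iterate per-pixel geodesic dilation of the
# marker under the mask until the fixpoint.
oracle_reconstruct <- function(marker, mask, connectivity = 8L) {
  nr <- nrow(marker); nc <- ncol(marker)
  offs <- if (connectivity == 8L) {
    list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,0), c(0,1), c(1,-1), c(1,0), c(1,1))
  } else {
    list(c(-1,0), c(0,-1), c(0,0), c(0,1), c(1,0))
  }
  cur <- pmin(marker, mask)
  repeat {
    nxt <- cur
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      m <- -Inf
      for (o in offs) {
        rr <- r + o[1]; cc <- c + o[2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && cur[rr, cc] > m)
          m <- cur[rr, cc]
      }
      nxt[r, c] <- min(m, mask[r, c])
    }
    if (all(nxt == cur)) return(cur)
    cur <- nxt
  }
}

# One explicit snake step: scalar loop with its own bilinear
# sampler and periodic differences.
oracle_snake_step <- function(p, field, alpha, beta, gamma, h = 1) {
  n <- nrow(p)
  nr <- nrow(field$u); nc <- ncol(field$u)
  sample1 <- function(m, x, y) {
    x <- min(max(x, 1), nc); y <- min(max(y, 1), nr)
    x0 <- floor(x); y0 <- floor(y)
    if (x0 >= nc) x0 <- nc - 1
    if (y0 >= nr) y0 <- nr - 1
    if (nc == 1) x0 <- 1
    if (nr == 1) y0 <- 1
    fx <- x - x0; fy <- y - y0
    x1 <- min(x0 + 1, nc); y1 <- min(y0 + 1, nr)
    m[y0, x0] * (1 - fx) * (1 - fy) + m[y0, x1] * fx * (1 - fy) +
      m[y1, x0] * (1 - fx) * fy + m[y1, x1] * fx * fy
  }
  out <- p
  for (i in seq_len(n)) {
    ip <- if (i == n) 1L else i + 1L
    im <- if (i == 1L) n else i - 1L
    ipp <- if (ip == n) 1L else ip + 1L
    imm <- if (im == 1L) n else im - 1L
    for (k in 1:2) {
      d2 <- (p[ip, k] - 2 * p[i, k] + p[im, k]) / h^2
      d4 <- (p[ipp, k] - 4 * p[ip, k] + 6 * p[i, k] - 4 * p[im, k] + p[imm, k]) / h^4
      f <- if (k == 1) sample1(field$u, p[i, 1], p[i, 2])
           else sample1(field$v, p[i, 1], p[i, 2])
      out[i, k] <- p[i, k] + gamma * (alpha * d2 - beta * d4 + f)
    }
  }
  out
}

# Scalar crossing-number point-in-polygon pixel counter.
oracle_polygon_pixels <- function(poly, shape) {
  count <- 0L
  n <- nrow(poly)
  for (r in seq_len(shape[1])) for (c in seq_len(shape[2])) {
    x <- c; y <- r; inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      if ((poly[i, 2] > y) != (poly[j, 2] > y)) {
        xint <- poly[i, 1] + (y - poly[i, 2]) / (poly[j, 2] - poly[i, 2]) *
          (poly[j, 1] - poly[i, 1])
        if (x < xint) inside <- !inside
      }
      j <- i
    }
    if (inside) count <- count + 1L
  }
  count
}

hausdorff <- function(a, b) {
  max(pracma::hausdorff_dist(as.matrix(a), as.matrix(b)))
}

# Standard test fixtures ----------------------------------------------------

# Small, fast default cell image for unit tests.
test_scene <- function(seed = 1L, ...) make_cell_image(scene_spec(seed = seed, ...))

# Fixture set used by the hole-robustness checks: pronounced interior
# patches, a single low-contrast arc.
hole_scene <- function(seed) {
  make_cell_image(scene_spec(n_arcs = 1L,
                             hole_spec = list(count = 3L, radius = 6, depth = 40),
                             seed = seed))
}
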