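# Internal numerical utilities: padded 2-D convolution, connected-component
# labeling, and a local-RNG helper.  Images are plain numeric matrices,
# indexed [row, col]; the point convention everywhere is x = column,
# y = row, both 1-based, pixel centers at integer coordinates.

#' @keywords internal
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  # symmetric (half-sample) reflection: ... 3 2 1 | 1 2 ... n | n n-1 ...
  j <- ((i - 1L) %% (2L * n) + 2L * n) %% (2L * n)
  as.integer(ifelse(j < n, j + 1L, 2L * n - j))
}

#' @keywords internal
pad_reflect <- function(x, pr, pc) {
  x[reflect_index(seq.int(1L - pr, nrow(x) + pr), nrow(x)),
    reflect_index(seq.int(1L - pc, ncol(x) + pc), ncol(x)),
    drop = FALSE]
}

#' 2-D convolution with reflected boundary
#'
#' True convolution (the kernel is flipped relative to cross-correlation)
#' of an image with an odd-sized kernel, computed via FFT on a
#' reflect-padded copy so that no artificial border response is created.
#' Output has the shape of the input.
#'
#' @param x numeric matrix.
#' @param k numeric kernel matrix with odd dimensions.
#' @return numeric matrix, same shape as `x`.
#' @keywords internal
conv2_reflect <- function(x, k) {
  stopifnot(is.matrix(x), is.matrix(k),
            nrow(k) %% 2L == 1L, ncol(k) %% 2L == 1L)
  kr <- (nrow(k) - 1L) %/% 2L
  kc <- (ncol(k) - 1L) %/% 2L
  p <- pad_reflect(x, kr, kc)
  nr <- nrow(p); nc <- ncol(p)
  # embed the kernel so its center sits at index (1, 1) with wrap-around
  kb <- matrix(0, nr, nc)
  ri <- ((seq_len(nrow(k)) - kr - 1L) %% nr) + 1L
  ci <- ((seq_len(ncol(k)) - kc - 1L) %% nc) + 1L
  kb[ri, ci] <- k
  out <- Re(stats::fft(stats::fft(p) * stats::fft(kb), inverse = TRUE)) / (nr * nc)
  out[(kr + 1L):(kr + nrow(x)), (kc + 1L):(kc + ncol(x)), drop = FALSE]
}

#' @keywords internal
gaussian_kernel_1d <- function(sigma, radius = ceiling(3 * sigma)) {
  g <- exp(-0.5 * (seq.int(-radius, radius) / sigma)^2)
  g / sum(g)
}

#' Separable Gaussian smoothing with reflected boundary
#' @keywords internal
gaussian_blur <- function(x, sigma) {
  g <- gaussian_kernel_1d(sigma)
  x <- conv2_reflect(x, matrix(g, ncol = 1L))
  conv2_reflect(x, matrix(g, nrow = 1L))
}

# Shift a matrix by (dr, dc) padding with `fill`; used by morphological
# dilation and neighbor scans.
#' @keywords internal
shift_mat <- function(x, dr, dc, fill) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) < 1L || length(cs) < 1L) return(out)
  out[rs, cs] <- x[rs - dr, cs - dc, drop = FALSE]
  out
}

# Shift with replicated (clamped) borders: finite differences built from
# it satisfy Neumann boundary conditions.
#' @keywords internal
shift_rep <- function(x, dr, dc) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  x[ri, ci, drop = FALSE]
}

#' @keywords internal
neighbor_offsets <- function(connectivity = 8L) {
  if (connectivity == 4L) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else if (connectivity == 8L) {
    list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
         c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  } else stop("connectivity must be 4 or 8")
}

#' Label connected foreground components
#'
#' 8-connected (default) labeling by iterated label propagation: every
#' foreground pixel starts with a unique label and repeatedly takes the
#' maximum label among its foreground neighbors until stable.  Labels are
#' then renumbered 1..n_components in first-pixel order.
#'
#' @param binary matrix of 0/1 (or logical).
#' @param connectivity 4 or 8.
#' @return integer matrix of labels, 0 = background.
#' @export
label_components <- function(binary, connectivity = 8L) {
  b <- (binary != 0)
  lab <- matrix(0, nrow(b), ncol(b))
  lab[b] <- which(b)            # unique seed labels
  offs <- neighbor_offsets(connectivity)
  repeat {
    new <- lab
    for (o in offs) new <- pmax(new, shift_mat(lab, o[1L], o[2L], 0))
    new[!b] <- 0
    if (identical(new, lab)) break
    lab <- new
  }
  u <- sort(unique(lab[lab > 0]))
  out <- matrix(0L, nrow(b), ncol(b))
  if (length(u)) out[lab > 0] <- match(lab[lab > 0], u)
  out
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
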