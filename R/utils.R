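# Internal numerical helpers shared across modules.

#' @importFrom stats rnorm sd var cor fft optim quantile median runif
#' @importFrom utils head tail
NULL

# Integer Fourier frequencies for an n-point DFT, in R's fft() ordering:
# 0, 1, ..., floor(n/2), -(ceiling(n/2)-1), ..., -1.
fft_freq <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# 2D rotation matrix, angle in degrees, counter-clockwise.
rot2 <- function(theta_deg) {
  t <- deg2rad(theta_deg)
  matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2)
}

# 3x3 rotation about a unit axis by angle (degrees), Rodrigues form.
rot3_axis <- function(axis, theta_deg) {
  u <- axis / sqrt(sum(axis^2))
  t <- deg2rad(theta_deg)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(t) * K + (1 - cos(t)) * (K %*% K)
}

# Trilinear interpolation of a 3D array at fractional (1-based) coordinates.
# coords: n x 3 matrix. Out-of-range samples return `fill`.
trilinear <- function(arr, coords, fill = 0) {
  d <- dim(arr)
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  out <- rep(fill, nrow(coords))
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(floor(x), d[1] - 1); y0 <- pmin(floor(y), d[2] - 1)
  z0 <- pmin(floor(z), d[3] - 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  idx <- function(i, j, k) (k - 1) * d[1] * d[2] + (j - 1) * d[1] + i
  v <- arr[idx(x0,     y0,     z0)]     * (1 - fx) * (1 - fy) * (1 - fz) +
       arr[idx(x0 + 1, y0,     z0)]     * fx       * (1 - fy) * (1 - fz) +
       arr[idx(x0,     y0 + 1, z0)]     * (1 - fx) * fy       * (1 - fz) +
       arr[idx(x0,     y0,     z0 + 1)] * (1 - fx) * (1 - fy) * fz +
       arr[idx(x0 + 1, y0 + 1, z0)]     * fx       * fy       * (1 - fz) +
       arr[idx(x0 + 1, y0,     z0 + 1)] * fx       * (1 - fy) * fz +
       arr[idx(x0,     y0 + 1, z0 + 1)] * (1 - fx) * fy       * fz +
       arr[idx(x0 + 1, y0 + 1, z0 + 1)] * fx       * fy       * fz
  out[ok] <- v
  out
}

# Bilinear "splat" of unit masses at fractional pixel positions onto an
# n1 x n2 image (1-based coordinates); the adjoint of bilinear interpolation.
bilinear_splat <- function(n1, n2, x, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  img <- matrix(0, n1, n2)
  keep <- x >= 1 & x < n1 & y >= 1 & y < n2
  x <- x[keep]; y <- y[keep]; w <- w[keep]
  if (!length(x)) return(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  add <- function(i, j, val) {
    ij <- (j - 1) * n1 + i
    acc <- tapply(val, ij, sum)
    img[as.integer(names(acc))] <<- img[as.integer(names(acc))] + as.numeric(acc)
  }
  add(x0,     y0,     w * (1 - fx) * (1 - fy))
  add(x0 + 1, y0,     w * fx * (1 - fy))
  add(x0,     y0 + 1, w * (1 - fx) * fy)
  add(x0 + 1, y0 + 1, w * fx * fy)
  img
}

# Circular shift of an array along one dimension (positive = toward higher
# indices), used for finite-difference stencils with periodic boundaries.
cshift <- function(a, by, dim) {
  d <- base::dim(a)
  n <- d[dim]
  idx <- ((seq_len(n) - 1 - by) %% n) + 1
  args <- rep(list(quote(expr = )), length(d))
  args[[dim]] <- idx
  do.call(`[`, c(list(a), args, list(drop = FALSE)))
}

# fftshift for matrices (move DC to the centre).
fftshift2 <- function(m) {
  d <- dim(m)
  s1 <- floor(d[1] / 2); s2 <- floor(d[2] / 2)
  m[c((s1 + 1):d[1], 1:s1), c((s2 + 1):d[2], 1:s2)]
}

# Quadratic sub-pixel refinement of a peak at integer position (i, j) of
# matrix m; returns c(di, dj) offsets in (-0.5, 0.5).
subpixel_peak <- function(m, i, j) {
  off <- function(a, b, c) {
    den <- a - 2 * b + c
    if (abs(den) < .Machine$double.eps) return(0)
    d <- 0.5 * (a - c) / den
    max(min(d, 0.5), -0.5)
  }
  di <- if (i > 1 && i < nrow(m)) off(m[i - 1, j], m[i, j], m[i + 1, j]) else 0
  dj <- if (j > 1 && j < ncol(m)) off(m[i, j - 1], m[i, j], m[i, j + 1]) else 0
  c(di, dj)
}
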