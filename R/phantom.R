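# Synthetic 3D ground-truth objects: compact asymmetric subunit phantoms,
# tilt-limited projections, and missing-cone volumes with independent
# half-map noise.

#' Noise specification
#'
#' @param snr signal-to-noise ratio, defined as signal variance over noise
#'   variance (> 0).
#' @param seed integer RNG seed for the noise realization.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(snr, seed = 1L) {
  if (!is.numeric(snr) || snr <= 0) stop("`snr` must be > 0")
  structure(list(snr = snr, seed = as.integer(seed)), class = "noise_spec")
}

#' Tilt scheme
#'
#' The set of stage tilt angles (degrees, about a fixed in-plane axis) of a
#' limited-tilt collection. The default is the scheme used for 2D lattice
#' data collection: 0, 15, 30, 35, 40, 45, 50 and 60 degrees.
#'
#' @param tilt_angles numeric vector of tilts in degrees, each in
#'   \[-70, 70\].
#' @return An object of class `tilt_scheme`.
#' @export
tilt_scheme <- function(tilt_angles = c(0, 15, 30, 35, 40, 45, 50, 60)) {
  if (any(abs(tilt_angles) > 70)) stop("tilt angles must lie in [-70, 70] degrees")
  structure(list(tilt_angles = as.numeric(tilt_angles)), class = "tilt_scheme")
}

# Random compact Gaussian-blob parameters used by both the 3D phantom and the
# 2D lattice motif. Centres fill an anisotropic ellipsoid so the motif has the
# elongated ~60 x 40 A footprint of a single lattice subunit.
.random_blobs <- function(seed, n_blobs, half_extent, sigma_range, dim3 = TRUE) {
  with_seed(seed, {
    k <- 0
    centers <- NULL
    while (k < n_blobs) {  # rejection-sample inside the ellipsoid
      p <- runif(3, -1, 1)
      if (sum(p^2) <= 1) {
        centers <- rbind(centers, p * half_extent)
        k <- k + 1
      }
    }
    data.frame(x = centers[, 1], y = centers[, 2],
               z = if (dim3) centers[, 3] else 0,
               sigma = runif(n_blobs, sigma_range[1], sigma_range[2]),
               amp = runif(n_blobs, 0.5, 1))
  })
}

#' Generate a compact asymmetric subunit phantom
#'
#' A reproducible, non-negative Gaussian-mixture density standing in for a
#' single ~60 x 40 A lattice subunit. Blob centres are drawn without any
#' imposed point symmetry, so the motif has no internal rotational symmetry
#' (verified by rotational self-correlation in the test-suite).
#'
#' @param seed integer RNG seed; identical seeds give bitwise identical
#'   volumes.
#' @param extent box edge length in Angstrom (>= 20).
#' @param voxel_size voxel edge in Angstrom; must satisfy
#'   `voxel_size <= extent / 8`.
#' @param n_blobs number of Gaussian blobs.
#' @return A [density_volume]; the blob parameters are attached as
#'   `attr(, "blobs")`.
#' @export
make_subunit_phantom <- function(seed, extent = 64, voxel_size = 2,
                                 n_blobs = 8) {
  if (extent < 20) stop("`extent` must be at least 20 A")
  if (voxel_size > extent / 8)
    stop(sprintf("voxel_size %.2f A too coarse to resolve a %.0f A motif", voxel_size, extent))
  n <- ceiling(extent / voxel_size)
  if (n %% 2 == 1) n <- n + 1
  ax <- (seq_len(n) - n / 2 - 0.5) * voxel_size
  gx <- rep(ax, times = n * n)
  gy <- rep(rep(ax, each = n), times = n)
  gz <- rep(ax, each = n * n)
  # blob widths at protein secondary-structure scale (absolute, Angstrom);
  # asymmetry is a postcondition, so draws whose 180-degree-rotated copy
  # correlates too strongly with the motif are rejected deterministically
  for (attempt in 0:19) {
    blobs <- .random_blobs(seed + 7919L * attempt, n_blobs,
                           half_extent = c(0.24, 0.16, 0.16) * extent,
                           sigma_range = c(4, 8))
    grid <- array(0, c(n, n, n))
    for (i in seq_len(nrow(blobs))) {
      r2 <- (gx - blobs$x[i])^2 + (gy - blobs$y[i])^2 + (gz - blobs$z[i])^2
      grid <- grid + blobs$amp[i] * exp(-r2 / (2 * blobs$sigma[i]^2))
    }
    # the relevant axis for lattice work is z (the projection and
    # plane-group symmetry axis)
    rot_cor <- cor(as.numeric(grid), as.numeric(grid[n:1, n:1, ]))
    if (rot_cor < 0.75) break
  }
  out <- density_volume(grid, voxel_size)
  attr(out, "blobs") <- blobs
  out
}

# Exact quarter-turn rotations of a cubic array in the plane of two axes,
# about the grid centre (index permutation plus reversals).
.rot90_plane <- function(vol, ax1, ax2, quarters) {
  quarters <- quarters %% 4
  for (q in seq_len(quarters)) {
    perm <- 1:3
    perm[c(ax1, ax2)] <- c(ax2, ax1)
    vol <- aperm(vol, perm)
    idx <- rep(list(quote(expr = )), 3)
    idx[[ax1]] <- dim(vol)[ax1]:1
    vol <- do.call(`[`, c(list(vol), idx, list(drop = FALSE)))
  }
  vol
}

# Shear a cubic array along `axis` by `amount` per voxel offset along
# `by_axis`, about the grid centre, via Fourier phase ramps (exact for
# band-limited content; wraps circularly at the edges).
.shear_fourier <- function(vol, axis, by_axis, amount) {
  d <- dim(vol)
  n <- d[axis]
  perm <- c(axis, setdiff(1:3, axis))
  A <- aperm(vol, perm)
  M <- matrix(A, n, prod(d) / n)
  rest_dims <- dim(A)[2:3]
  by_pos <- which(perm == by_axis) - 1          # position of by_axis in rest
  ctr <- (d[by_axis] + 1) / 2
  off <- (seq_len(d[by_axis]) - ctr) * amount
  s_col <- if (by_pos == 1) rep(off, times = rest_dims[2])
           else rep(off, each = rest_dims[1])
  k <- fft_freq(n)
  phase <- exp(-2i * pi * outer(k, s_col) / n)
  FM <- stats::mvfft(M)
  out <- Re(stats::mvfft(FM * phase, inverse = TRUE)) / n
  aperm(array(out, dim(A)), order(perm))
}

# Rotation of a cubic array in the plane (ax1, ax2) about the grid centre by
# an arbitrary angle: exact quarter turns plus a three-shear residual
# rotation (Paeth decomposition), spectrally accurate for compact content.
.rotate_plane <- function(vol, ax1, ax2, theta_deg) {
  theta_deg <- ((theta_deg + 45) %% 360) - 45
  q <- round(theta_deg / 90)
  resid <- theta_deg - 90 * q
  vol <- .rot90_plane(vol, ax1, ax2, q)
  if (abs(resid) > 1e-9) {
    t2 <- -tan(deg2rad(resid) / 2)
    s <- sin(deg2rad(resid))
    vol <- .shear_fourier(vol, ax1, ax2, t2)
    vol <- .shear_fourier(vol, ax2, ax1, s)
    vol <- .shear_fourier(vol, ax1, ax2, t2)
  }
  vol
}

#' Project a volume at a tilt / in-plane rotation
#'
#' Line-integral projection of a cubic volume after rotating it by
#' `in_plane_rotation` about z and then `tilt` about the y axis; by the
#' Fourier projection theorem the transform of the projection equals the
#' central slice of the volume transform at that orientation. Rotations are
#' carried out spectrally (quarter turns plus three Fourier shears), which
#' is exact for band-limited compact content; edge content wraps
#' circularly.
#'
#' @param vol a cubic [density_volume].
#' @param tilt tilt angle in degrees about the y axis.
#' @param in_plane_rotation rotation in degrees about the z axis, applied
#'   before the tilt.
#' @return A [micrograph_image] with the volume's voxel size as pixel size.
#' @export
project_volume <- function(vol, tilt = 0, in_plane_rotation = 0) {
  d <- dim(vol$grid)
  if (length(unique(d)) != 1) stop("volume must be cubic")
  n <- d[1]
  g <- vol$grid
  # rotate the volume by R = Ry(tilt) Rz(rot): content at p moves to R p
  if (abs(in_plane_rotation) > 1e-12)
    g <- .rotate_plane(g, 1, 2, in_plane_rotation)   # about z
  if (abs(tilt) > 1e-12)
    g <- .rotate_plane(g, 3, 1, tilt)                # about y
  img <- rowSums(matrix(g, n * n, n), dims = 1)
  micrograph_image(matrix(img, n, n) * vol$voxel_size, vol$voxel_size)
}

#' Apply a missing Fourier cone and generate noisy half-maps
#'
#' Emulates the anisotropic information loss of tilt-limited data collection:
#' a maximum stage tilt of `max_tilt` degrees leaves a double cone of
#' half-angle `90 - max_tilt` degrees about the z axis unsampled in Fourier
#' space. The signal's amplitudes inside that cone are set to zero; two
#' half-maps then carry independent white Gaussian reconstruction-noise
#' realizations (seeds `seed` and `seed + 1`) present at all frequencies,
#' as in a real-space reconstruction from noisy projections. The full map is
#' the half-map average.
#'
#' @param vol a [density_volume] (ground truth).
#' @param max_tilt maximum tilt in degrees, `0 < max_tilt <= 90`; 90 means no
#'   missing cone.
#' @param noise a [noise_spec], or `NULL` for noiseless output.
#' @return A list with elements `volume`, `half1`, `half2` (all
#'   [density_volume]) and `cone_half_angle` in degrees.
#' @export
make_missing_cone_volume <- function(vol, max_tilt = 60, noise = NULL) {
  if (max_tilt <= 0 || max_tilt > 90) stop("`max_tilt` must be in (0, 90]")
  alpha <- 90 - max_tilt
  d <- dim(vol$grid)
  sig_sd <- sd(as.numeric(vol$grid))
  signal <- .apply_cone_zero(vol$grid, alpha)
  mk_half <- function(seed_off) {
    g <- signal
    if (!is.null(noise)) {
      nsd <- sig_sd / sqrt(noise$snr)
      g <- g + with_seed(noise$seed + seed_off,
                         array(rnorm(prod(d), sd = nsd), d))
    }
    g
  }
  h1 <- mk_half(0)
  h2 <- if (is.null(noise)) h1 else mk_half(1)
  list(volume = density_volume((h1 + h2) / 2, vol$voxel_size, vol$origin),
       half1 = density_volume(h1, vol$voxel_size, vol$origin),
       half2 = density_volume(h2, vol$voxel_size, vol$origin),
       cone_half_angle = alpha)
}

# Zero Fourier amplitudes within `alpha` degrees of the +-z axis (DC kept).
.apply_cone_zero <- function(grid, alpha) {
  if (alpha <= 0) return(grid)
  d <- dim(grid)
  mask <- .cone_mask(d, alpha)
  F <- fft(grid)
  F[mask] <- 0
  Re(fft(F, inverse = TRUE)) / prod(d)
}

.cone_mask <- function(d, alpha) {
  kx <- fft_freq(d[1]) / d[1]
  ky <- fft_freq(d[2]) / d[2]
  kz <- fft_freq(d[3]) / d[3]
  KX <- rep(kx, times = d[2] * d[3])
  KY <- rep(rep(ky, each = d[1]), times = d[3])
  KZ <- rep(kz, each = d[1] * d[2])
  r <- sqrt(KX^2 + KY^2 + KZ^2)
  ang <- rep(90, length(r))          # DC: angle undefined, keep
  nz <- r > 0
  ang[nz] <- rad2deg(acos(pmin(1, abs(KZ[nz]) / r[nz])))
  array(ang < alpha, d)
}
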