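# Synthetic plane-group lattice micrographs with known ground truth.
#
# A 2D crystal is rendered as a sum over symmetry operators g of
#   (lattice comb at nodes + shift_g)  (x)  motif rotated by g,
# evaluated by bilinear delta splatting followed by FFT convolution with an
# analytically rasterized Gaussian-blob motif. p2 places the motif at the
# lattice nodes and its 180 deg copy at the cell centre; p4 places four
# 90 deg-rotated copies around the node (a tetramer-like ring).

#' Lattice specification
#'
#' Plane group and 2D unit-cell geometry of a synthetic crystal patch.
#'
#' @param plane_group one of `"p1"`, `"p2"`, `"p4"`.
#' @param a_len,b_len basis vector lengths in Angstrom (> 0); p4 requires
#'   `a_len == b_len`.
#' @param gamma inter-axis angle in degrees, `0 < gamma < 180`; p4 requires
#'   90.
#' @param in_plane_rotation rotation of the whole crystal in degrees.
#' @param distortion_amplitude dimensionless amplitude of an optional smooth
#'   lattice displacement field (0 = perfect crystal).
#' @return An object of class `lattice_spec`.
#' @export
lattice_spec <- function(plane_group = c("p2", "p1", "p4"),
                         a_len, b_len = a_len, gamma = 90,
                         in_plane_rotation = 0, distortion_amplitude = 0) {
  plane_group <- match.arg(plane_group)
  if (a_len <= 0 || b_len <= 0) stop("cell lengths must be positive")
  if (gamma <= 0 || gamma >= 180) stop("gamma must lie in (0, 180) degrees")
  if (plane_group == "p4" && (abs(a_len - b_len) > 1e-9 || abs(gamma - 90) > 1e-9))
    stop("p4 requires a square cell: a_len = b_len and gamma = 90")
  structure(list(plane_group = plane_group, a_len = a_len, b_len = b_len,
                 gamma = gamma, in_plane_rotation = in_plane_rotation,
                 distortion_amplitude = distortion_amplitude),
            class = "lattice_spec")
}

#' Named lattice presets
#'
#' The four observed PhuN unit cells: in vitro p2 (120 A, 100 deg), in vitro
#' p4 (120 A, 90 deg), isolated-fragment p2 (120 A, 120 deg) and
#' isolated-fragment p4 (110 A, 90 deg).
#'
#' @param name one of `"p2-invitro"`, `"p4-invitro"`, `"p2-fragment"`,
#'   `"p4-fragment"`.
#' @param ... further arguments passed to [lattice_spec()]
#'   (e.g. `in_plane_rotation`).
#' @return A [lattice_spec].
#' @export
lattice_preset <- function(name = c("p2-invitro", "p4-invitro",
                                    "p2-fragment", "p4-fragment"), ...) {
  name <- match.arg(name)
  switch(name,
    "p2-invitro"  = lattice_spec("p2", 120, 120, 100, ...),
    "p4-invitro"  = lattice_spec("p4", 120, 120, 90, ...),
    "p2-fragment" = lattice_spec("p2", 120, 120, 120, ...),
    "p4-fragment" = lattice_spec("p4", 110, 110, 90, ...))
}

#' Generate a random asymmetric 2D motif
#'
#' Gaussian-blob motif with the ~60 x 40 A footprint of a single lattice
#' subunit and no internal point symmetry. The default blob count gives the
#' projection the feature density of a two-domain ~600-residue protein at
#' secondary-structure scale, so renderings carry a realistic number of
#' significant lattice reflections.
#'
#' @param seed integer RNG seed.
#' @param n_blobs number of blobs.
#' @return A data.frame of class `motif2d` with columns `x`, `y`, `sigma`,
#'   `amp` (Angstrom units).
#' @export
make_motif2d <- function(seed, n_blobs = 12) {
  # asymmetry is a postcondition (a near-centrosymmetric motif would make a
  # p2 lattice look period-halved): reject draws whose 180-degree-rotated
  # raster correlates too strongly
  for (attempt in 0:19) {
    b <- .random_blobs(seed + 7919L * attempt, n_blobs,
                       half_extent = c(28, 18, 0),
                       sigma_range = c(4.5, 8), dim3 = FALSE)
    out <- b[, c("x", "y", "sigma", "amp")]
    class(out) <- c("motif2d", "data.frame")
    ras <- .raster_motif(out, 0, 2)$patch
    np <- nrow(ras)
    if (cor(as.numeric(ras), as.numeric(ras[np:1, np:1])) < 0.7) break
  }
  out
}

# Symmetry operators as (rotation deg, fractional shift) pairs.
.plane_group_ops <- function(group) {
  switch(group,
    p1 = list(list(rot = 0, shift = c(0, 0))),
    p2 = list(list(rot = 0, shift = c(0, 0)),
              list(rot = 180, shift = c(0.5, 0.5))),
    p4 = lapply(0:3, function(k) list(rot = 90 * k, shift = c(0, 0))))
}

# Rasterize a rotated Gaussian-blob motif on a (2P+1)^2 patch (pixel units).
.raster_motif <- function(motif, rot_deg, pixel_size) {
  R <- rot2(rot_deg)
  ctr <- as.matrix(motif[, c("x", "y")]) %*% t(R)
  P <- ceiling((max(sqrt(rowSums(ctr^2))) + 4 * max(motif$sigma)) / pixel_size)
  ax <- (-P:P) * pixel_size
  np <- 2 * P + 1
  gx <- rep(ax, times = np)
  gy <- rep(ax, each = np)
  patch <- numeric(np * np)
  for (i in seq_len(nrow(motif))) {
    r2 <- (gx - ctr[i, 1])^2 + (gy - ctr[i, 2])^2
    patch <- patch + motif$amp[i] * exp(-r2 / (2 * motif$sigma[i]^2))
  }
  list(patch = matrix(patch, np, np), P = P)
}

# Embed a centred (2P+1)^2 kernel into an n1 x n2 circular kernel (DC at [1,1]).
.wrap_kernel <- function(patch, P, n1, n2) {
  K <- matrix(0, n1, n2)
  idx1 <- ((-P:P) %% n1) + 1
  idx2 <- ((-P:P) %% n2) + 1
  K[idx1, idx2] <- patch
  K
}

.fft_conv2 <- function(delta, K) {
  Re(fft(fft(delta) * fft(K), inverse = TRUE)) / length(delta)
}

# NUFFT-style Gaussian gridding of a delta comb at continuous positions:
# each point is splatted with a truncated Gaussian kernel, whose transform
# is divided out again in Fourier space, leaving a near-exact comb spectrum
# (bilinear splatting leaves ~1% phase/amplitude artifacts at high orders).
.grid_sigma <- 0.7
.grid_half <- 5L

.gauss_splat <- function(n1, n2, x, y) {
  img <- matrix(0, n1, n2)
  h <- .grid_half
  x0 <- round(x); y0 <- round(y)
  for (di in -h:h) for (dj in -h:h) {
    ix <- x0 + di; iy <- y0 + dj
    keep <- ix >= 1 & ix <= n1 & iy >= 1 & iy <= n2
    if (!any(keep)) next
    w <- exp(-((ix[keep] - x[keep])^2 + (iy[keep] - y[keep])^2) /
               (2 * .grid_sigma^2))
    idx <- (iy[keep] - 1) * n1 + ix[keep]
    acc <- rowsum(w, as.integer(idx))
    ii <- as.integer(rownames(acc))
    img[ii] <- img[ii] + as.numeric(acc)
  }
  img
}

.grid_kernel_hat <- function(n1, n2) {
  h <- .grid_half
  kk <- exp(-((-h):h)^2 / (2 * .grid_sigma^2))
  fft(.wrap_kernel(outer(kk, kk), h, n1, n2))
}

# Render one crystal patch. Returns the signal image and the Angstrom node
# positions actually placed.
.render_patch <- function(spec, motif, n1, n2, pixel_size,
                          region = NULL, offset_px = NULL) {
  th <- spec$in_plane_rotation
  av <- spec$a_len / pixel_size * c(cos(deg2rad(th)), sin(deg2rad(th)))
  bv <- spec$b_len / pixel_size *
        c(cos(deg2rad(th + spec$gamma)), sin(deg2rad(th + spec$gamma)))
  if (is.null(offset_px)) offset_px <- c(n1 / 2 + 0.5, n2 / 2 + 0.5)
  nmax <- ceiling(sqrt(n1^2 + n2^2) / min(spec$a_len, spec$b_len) * pixel_size) + 2
  nm <- expand.grid(n = -nmax:nmax, m = -nmax:nmax)
  base <- cbind(offset_px[1] + nm$n * av[1] + nm$m * bv[1],
                offset_px[2] + nm$n * av[2] + nm$m * bv[2])
  if (spec$distortion_amplitude > 0) {
    L1 <- n1 / 2; L2 <- n2 / 2
    amp <- spec$distortion_amplitude * spec$a_len / pixel_size
    base[, 1] <- base[, 1] + amp * sin(2 * pi * base[, 2] / L2)
    base[, 2] <- base[, 2] + amp * sin(2 * pi * base[, 1] / L1)
  }
  ops <- .plane_group_ops(spec$plane_group)
  rasters <- lapply(ops, function(op) .raster_motif(motif, th + op$rot, pixel_size))
  Pmax <- max(vapply(rasters, `[[`, 0, "P"))
  inside <- function(p) {
    ok <- p[, 1] >= Pmax + 1 & p[, 1] <= n1 - Pmax &
          p[, 2] >= Pmax + 1 & p[, 2] <= n2 - Pmax
    if (!is.null(region)) {
      xA <- (p[, 1] - 1) * pixel_size
      yA <- (p[, 2] - 1) * pixel_size
      ok <- ok & xA >= region[1] & xA <= region[2] &
                 yA >= region[3] & yA <= region[4]
    }
    ok
  }
  keep <- inside(base)
  Ghat <- .grid_kernel_hat(n1, n2)
  signal_hat <- matrix(0 + 0i, n1, n2)
  for (k in seq_along(ops)) {
    sh <- ops[[k]]$shift
    pos <- cbind(base[, 1] + sh[1] * av[1] + sh[2] * bv[1],
                 base[, 2] + sh[1] * av[2] + sh[2] * bv[2])[keep, , drop = FALSE]
    if (!nrow(pos)) next
    delta <- .gauss_splat(n1, n2, pos[, 1], pos[, 2])
    K <- .wrap_kernel(rasters[[k]]$patch, rasters[[k]]$P, n1, n2)
    signal_hat <- signal_hat + fft(delta) / Ghat * fft(K)
  }
  signal <- Re(fft(signal_hat, inverse = TRUE)) / (n1 * n2)
  nodes <- (base[keep, , drop = FALSE] - 1) * pixel_size
  list(signal = signal, nodes = nodes,
       basis_A = cbind(a = av * pixel_size, b = bv * pixel_size))
}

#' Render a plane-group lattice micrograph
#'
#' Tiles a symmetric arrangement of the motif over the image according to the
#' lattice specification and adds white Gaussian noise at the stated
#' signal-to-noise ratio.
#'
#' @param spec a [lattice_spec]; the unit cell must fit at least 5 times
#'   across the image.
#' @param motif a `motif2d` (see [make_motif2d()]), or a [density_volume]
#'   which is projected along z and used as the subunit footprint; `NULL`
#'   defaults to `make_motif2d(seed = 1)`.
#' @param image_size image edge in pixels (scalar or length 2).
#' @param pixel_size pixel edge in Angstrom.
#' @param noise a [noise_spec] or `NULL` for a noiseless rendering.
#' @return A list with `image` (a [micrograph_image]) and `ground_truth`
#'   (a [lattice_model] holding the true basis).
#' @export
render_lattice_image <- function(spec, motif = NULL, image_size = 1024,
                                 pixel_size = 4, noise = NULL) {
  stopifnot(inherits(spec, "lattice_spec"))
  if (is.null(motif)) motif <- make_motif2d(1)
  if (inherits(motif, "density_volume")) motif <- .volume_to_motif(motif)
  n1 <- if (length(image_size) == 1) image_size else image_size[1]
  n2 <- if (length(image_size) == 1) image_size else image_size[2]
  if (min(n1, n2) * pixel_size < 5 * max(spec$a_len, spec$b_len))
    stop("unit cell must fit at least 5 times across the image")
  rp <- .render_patch(spec, motif, n1, n2, pixel_size)
  img <- rp$signal
  if (!is.null(noise)) {
    nsd <- sd(as.numeric(img)) / sqrt(noise$snr)
    img <- img + with_seed(noise$seed, matrix(rnorm(n1 * n2, sd = nsd), n1, n2))
  }
  gt <- lattice_model(rp$basis_A[, 1], rp$basis_A[, 2],
                      assigned_group = spec$plane_group)
  list(image = micrograph_image(img, pixel_size), ground_truth = gt)
}

# Fallback: turn a 3D phantom into a blob motif via its attached parameters,
# or fit nothing and use the projected centroid spread.
.volume_to_motif <- function(vol) {
  b <- attr(vol, "blobs")
  if (is.null(b))
    stop("density_volume motifs require blob parameters (see make_subunit_phantom)")
  out <- data.frame(x = b$x, y = b$y, sigma = b$sigma, amp = b$amp * b$sigma)
  class(out) <- c("motif2d", "data.frame")
  out
}

#' Render a micrograph with several lattice patches
#'
#' Each patch region (an axis-aligned rectangle in Angstrom) is tiled with
#' its own lattice specification; regions must not overlap. Every placed
#' lattice node is reported in the returned particle table with its true
#' symmetry label and patch id.
#'
#' @param patches list of `list(spec = <lattice_spec>, region = c(xmin, xmax,
#'   ymin, ymax))` entries (Angstrom coordinates).
#' @param motif,image_size,pixel_size,noise as in [render_lattice_image()];
#'   `motif` may also be a list of motifs, one per patch.
#' @return A list with `image` (a [micrograph_image]) and `particles`
#'   (a [particle_table] with a `patch_id` column).
#' @export
render_multi_patch_micrograph <- function(patches, motif = NULL,
                                          image_size = 1024, pixel_size = 4,
                                          noise = NULL) {
  if (!length(patches)) stop("at least one patch required")
  regs <- lapply(patches, `[[`, "region")
  np <- length(patches)
  if (np > 1) {
    for (i in 1:(np - 1)) for (j in (i + 1):np) {
      a <- regs[[i]]; b <- regs[[j]]
      if (a[1] < b[2] && b[1] < a[2] && a[3] < b[4] && b[3] < a[4])
        stop(sprintf("patch regions %d and %d overlap", i, j))
    }
  }
  n1 <- if (length(image_size) == 1) image_size else image_size[1]
  n2 <- if (length(image_size) == 1) image_size else image_size[2]
  if (is.null(motif)) motif <- make_motif2d(1)
  motifs <- if (inherits(motif, "motif2d")) rep(list(motif), np) else motif
  img <- matrix(0, n1, n2)
  parts <- NULL
  for (i in seq_len(np)) {
    rp <- .render_patch(patches[[i]]$spec, motifs[[i]], n1, n2, pixel_size,
                        region = regs[[i]])
    img <- img + rp$signal
    if (nrow(rp$nodes))
      parts <- rbind(parts, data.frame(x = rp$nodes[, 1], y = rp$nodes[, 2],
                                       sym = patches[[i]]$spec$plane_group,
                                       patch = i))
  }
  if (!is.null(noise)) {
    nsd <- sd(as.numeric(img)) / sqrt(noise$snr)
    img <- img + with_seed(noise$seed, matrix(rnorm(n1 * n2, sd = nsd), n1, n2))
  }
  pt <- particle_table(parts$x, parts$y, class_label = parts$patch,
                       symmetry_label = parts$sym,
                       bounds = c(n1, n2) * pixel_size,
                       extra = data.frame(patch_id = parts$patch))
  list(image = micrograph_image(img, pixel_size), particles = pt)
}
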