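# Synthetic-data generators: phantoms, lattice renderings, tilt projections
# and missing-cone volumes.

test_that("subunit phantoms are seed-deterministic, compact and asymmetric", {
  p1 <- make_subunit_phantom(5, extent = 60, voxel_size = 2)
  p2 <- make_subunit_phantom(5, extent = 60, voxel_size = 2)
  expect_identical(p1$grid, p2$grid)
  expect_true(all(p1$grid >= 0))
  expect_true(all(dim(p1$grid) >= 30))

  # no internal 2-fold: correlation with the 180-degree rotated copy stays low
  for (s in c(2, 5, 9)) {
    g <- make_subunit_phantom(s, extent = 60, voxel_size = 2)$grid
    d <- dim(g)
    rot <- g[d[1]:1, d[2]:1, ]          # 180 deg about z through the centre
    expect_lt(cor(as.numeric(g), as.numeric(rot)), 0.8)
  }

  expect_error(make_subunit_phantom(1, extent = 60, voxel_size = 10), "coarse")
})

test_that("lattice renderings are deterministic and carry ground truth", {
  spec <- lattice_preset("p2-invitro")
  r1 <- render_lattice_image(spec, make_motif2d(3), 512, 4, noise_spec(0.3, 5))
  r2 <- render_lattice_image(spec, make_motif2d(3), 512, 4, noise_spec(0.3, 5))
  expect_identical(r1$image$pixels, r2$image$pixels)
  expect_equal(coef(r1$ground_truth),
               c(a_len = 120, b_len = 120, gamma = 100), tolerance = 1e-9)

  # zero-noise limit: the noiseless rendering is the deterministic tiling
  n0 <- render_lattice_image(spec, make_motif2d(3), 512, 4, NULL)
  n0b <- render_lattice_image(spec, make_motif2d(3), 512, 4, NULL)
  expect_identical(n0$image$pixels, n0b$image$pixels)

  expect_error(render_lattice_image(spec, image_size = 64, pixel_size = 4),
               "at least 5 times")
  expect_error(lattice_spec("p4", 120, 110, 90), "square")
})

test_that("p2 rendering shows autocorrelation peaks at the basis vectors", {
  r <- render_lattice_image(lattice_preset("p2-invitro"), make_motif2d(3),
                            1024, 4, NULL)
  A <- phunlattice:::.autocorr2(r$image$pixels)
  c0 <- floor(1024 / 2) + 1
  # a = (30, 0) px; peak within 1 px of the prediction, clearly above background
  win <- A[(c0 + 29):(c0 + 31), (c0 - 1):(c0 + 1)]
  ann <- A[(c0 - 45):(c0 + 45), (c0 - 45):(c0 + 45)]
  expect_gt(max(win), stats::quantile(ann, 0.9))
})

test_that("plane-group symmetry of renderings holds under their generators", {
  # p2: rotate about a 2-fold position. The 2-folds of the rendered
  # arrangement (motif at the node, rotated copy at the cell centre) sit at
  # quarter-cell positions, so the patch is rendered with its origin offset
  # so that a 2-fold lands exactly on the matrix centre.
  spec <- lattice_preset("p2-invitro")
  n <- 512
  av <- spec$a_len / 4 * c(cos(0), sin(0))
  bv <- spec$b_len / 4 * c(cos(spec$gamma * pi / 180),
                           sin(spec$gamma * pi / 180))
  off <- (n + 1) / 2 - (av + bv) / 4
  rp <- phunlattice:::.render_patch(spec, make_motif2d(3), n, n, 4,
                                    offset_px = off)
  I <- rp$signal - mean(rp$signal)
  rot180 <- I[n:1, n:1]
  ctr <- 128:384
  expect_gt(cor(as.numeric(I[ctr, ctr]), as.numeric(rot180[ctr, ctr])), 0.99)

  # p4: 90-degree rotation about the central lattice node
  r4 <- render_lattice_image(lattice_preset("p4-invitro"), make_motif2d(5),
                             512, 4, NULL)
  I4 <- r4$image$pixels - mean(r4$image$pixels)
  rot90 <- t(I4)[ncol(I4):1, ]
  ctr <- 128:384                       # central region, away from edge margins
  expect_gt(cor(as.numeric(I4[ctr, ctr]), as.numeric(rot90[ctr, ctr])), 0.95)
})

test_that("multi-patch micrographs label particles by patch and symmetry", {
  one <- render_multi_patch_micrograph(
    list(list(spec = lattice_preset("p2-invitro"), region = c(0, 4096, 0, 4096))),
    make_motif2d(3), 1024, 4)
  expect_true(all(one$particles$symmetry_label == "p2"))

  two <- render_multi_patch_micrograph(
    list(list(spec = lattice_preset("p2-invitro"), region = c(0, 1900, 0, 4096)),
         list(spec = lattice_preset("p4-invitro"), region = c(2200, 4096, 0, 4096))),
    make_motif2d(3), 1024, 4)
  p <- two$particles
  expect_setequal(unique(p$symmetry_label), c("p2", "p4"))
  expect_true(all(p$symmetry_label[p$patch_id == 1] == "p2"))
  expect_true(all(p$symmetry_label[p$patch_id == 2] == "p4"))
  expect_true(all(p$x[p$patch_id == 1] <= 1900))
  expect_true(all(p$x[p$patch_id == 2] >= 2200))

  expect_error(render_multi_patch_micrograph(
    list(list(spec = lattice_preset("p2-invitro"), region = c(0, 3000, 0, 4096)),
         list(spec = lattice_preset("p4-invitro"), region = c(2000, 4096, 0, 4096))),
    make_motif2d(3), 1024, 4), "overlap")
})

test_that("per-patch indexing recovers three distinct orientations", {
  rots <- c(0, 22, 45)
  patches <- lapply(seq_along(rots), function(i)
    list(spec = lattice_spec("p2", 120, 120, 100, in_plane_rotation = rots[i]),
         region = c(0, 4096, (i - 1) * 1366, i * 1366 - 40)))
  mp <- render_multi_patch_micrograph(patches, make_motif2d(3), 1024, 4)
  basis_angles <- lapply(seq_along(rots), function(i) {
    reg <- patches[[i]]$region
    rows <- max(1, floor(reg[3] / 4) + 1):min(1024, floor(reg[4] / 4))
    sub <- micrograph_image(mp$image$pixels[, rows], 4)
    m <- index_lattice(sub)
    c(atan2(m$basis[2, 1], m$basis[1, 1]),
      atan2(m$basis[2, 2], m$basis[1, 2])) * 180 / pi
  })
  # relative patch rotation: some pairing of basis-vector directions (mod
  # 180, since +-v describe the same lattice vector) must match the preset
  rel_rot <- function(b1, b2, expected) {
    cand <- as.numeric(outer(b2, b1, "-")) %% 180
    err <- pmin(abs(cand - expected), abs(cand - expected + 180),
                abs(cand - expected - 180))
    min(err)
  }
  expect_lt(rel_rot(basis_angles[[1]], basis_angles[[2]], 22), 1.5)
  expect_lt(rel_rot(basis_angles[[1]], basis_angles[[3]], 45), 1.5)
})

test_that("missing-cone geometry follows the solid-angle formula", {
  ph <- make_subunit_phantom(1, extent = 128, voxel_size = 2)

  # no cone at 90-degree tilt
  id <- make_missing_cone_volume(ph, max_tilt = 90)
  expect_equal(id$volume$grid, ph$grid, tolerance = 1e-10)
  expect_equal(make_missing_cone_volume(ph, 60)$cone_half_angle, 30)

  mc <- make_missing_cone_volume(ph, max_tilt = 60)    # noiseless
  Fin <- Mod(fft(ph$grid))
  Fout <- Mod(fft(mc$volume$grid))
  si <- phunlattice:::.shell_index(dim(ph$grid))
  ball <- si$r > 0 & si$r <= 0.5
  frac <- mean(Fout[ball] < 1e-6 * Fin[ball])
  expect_equal(frac, 1 - cos(30 * pi / 180), tolerance = 0.02)
})

test_that("half-maps carry independent noise realizations", {
  ph <- make_subunit_phantom(2, extent = 128, voxel_size = 2)
  mc <- make_missing_cone_volume(ph, 60, noise_spec(3, seed = 7))
  nn1 <- mc$half1$grid - phunlattice:::.apply_cone_zero(ph$grid, 30)
  nn2 <- mc$half2$grid - phunlattice:::.apply_cone_zero(ph$grid, 30)
  expect_lt(abs(cor(as.numeric(nn1), as.numeric(nn2))), 0.05)
  # and per Fourier shell beyond the signal band
  F1 <- fft(nn1); F2 <- fft(nn2)
  si <- phunlattice:::.shell_index(dim(ph$grid))
  for (sh in c(22, 26, 30)) {
    sel <- si$shell == sh
    r <- sum(Re(F1[sel] * Conj(F2[sel]))) /
      sqrt(sum(Mod(F1[sel])^2) * sum(Mod(F2[sel])^2))
    expect_lt(abs(r), 0.05)
  }
})

test_that("projection obeys the Fourier slice theorem", {
  ph <- make_subunit_phantom(4, extent = 64, voxel_size = 2)
  n <- dim(ph$grid)[1]

  # tilt 0 is the plain z sum
  p0 <- project_volume(ph, 0, 0)
  expect_equal(p0$pixels, apply(ph$grid, c(1, 2), sum) * ph$voxel_size,
               tolerance = 1e-8)

  # a centred sphere projects identically at every orientation
  ax <- (seq_len(n) - n / 2 - 0.5) * 2
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  sph <- density_volume(array(exp(-r2 / (2 * 10^2)), c(n, n, n)), 2)
  ps <- lapply(list(c(0, 0), c(30, 0), c(45, 60)), function(a)
    project_volume(sph, a[1], a[2])$pixels)
  expect_lt(max(abs(ps[[2]] - ps[[1]])) / max(ps[[1]]), 0.01)
  expect_lt(max(abs(ps[[3]] - ps[[1]])) / max(ps[[1]]), 0.01)

  # central-slice check: FT of the tilted projection equals the central
  # slice of the volume FT at that orientation. A compact smooth random
  # phantom keeps the (de-ramped) spectrum interpolable.
  tilt <- 25
  blob <- with_seed(8, data.frame(x = runif(4, -4, 4), y = runif(4, -4, 4),
                                  z = runif(4, -4, 4),
                                  s = runif(4, 12, 16), a = runif(4, 0.5, 1)))
  axs <- (seq_len(n) - n / 2 - 0.5) * 2
  gsm <- array(0, c(n, n, n))
  for (i in 1:4)
    gsm <- gsm + blob$a[i] * exp(-((rep(axs, n * n) - blob$x[i])^2 +
      (rep(rep(axs, each = n), n) - blob$y[i])^2 +
      (rep(axs, each = n * n) - blob$z[i])^2) / (2 * blob$s[i]^2))
  ph <- density_volume(gsm, 2)
  pr <- project_volume(ph, tilt, 0)
  Fp <- fft(pr$pixels / ph$voxel_size)
  Fv <- fft(ph$grid)
  shift3 <- function(a) {
    s <- dim(a) %/% 2
    a[c((s[1] + 1):dim(a)[1], 1:s[1]),
      c((s[2] + 1):dim(a)[2], 1:s[2]),
      c((s[3] + 1):dim(a)[3], 1:s[3])]
  }
  k <- phunlattice:::fft_freq(n)
  R <- phunlattice:::rot3_axis(c(0, 1, 0), tilt)
  sel <- expand.grid(ix = which(abs(k) <= 4), iy = which(abs(k) <= 4))
  kmat <- rbind(k[sel$ix], k[sel$iy], 0)
  kv <- t(t(R) %*% kmat)                # slice frequency of each 2D mode
  # exact off-grid transform values by separable direct DFT
  dft_at <- function(vol, q) {
    idx <- 0:(n - 1)
    vx <- exp(-2i * pi * q[1] * idx / n)
    vy <- exp(-2i * pi * q[2] * idx / n)
    vz <- exp(-2i * pi * q[3] * idx / n)
    t1 <- colSums(vol * vx)             # recycle along the first axis
    sum(colSums(t1 * vy) * vz)
  }
  slice0 <- vapply(seq_len(nrow(kv)), function(j)
    dft_at(ph$grid, kv[j, ]), complex(1))
  # rotation about the grid centre adds exp(-2 pi i k . (I - R) c0 / n)
  c0 <- rep((n - 1) / 2, 3)
  dphase <- as.numeric(t(kmat) %*% ((diag(3) - R) %*% c0)) / n
  slice <- slice0 * exp(-2i * pi * dphase)
  proj <- Fp[cbind(sel$ix, sel$iy)]
  expect_lt(sqrt(sum(Mod(proj - slice)^2) / sum(Mod(proj)^2)), 0.02)
})

test_that("projection templates follow the bracketed angle grid", {
  ph <- make_subunit_phantom(1, extent = 32, voxel_size = 2)
  single <- generate_projection_templates(ph, 40, tilt_sweep = 0,
                                          z_range = c(0, 0), compute = FALSE)
  expect_equal(single$count, 1)

  full <- generate_projection_templates(ph, 40, compute = FALSE)
  # independent enumeration of the angle grid
  offs <- seq(-5, 5, by = 3)
  zr <- seq(0, 180, by = 3)
  expect_equal(full$count, length(offs) * length(zr))
  expect_equal(full$count, 244)
  expect_setequal(unique(full$angles$tilt), 40 + offs)

  expect_error(generate_projection_templates(ph, 40, tilt_step = -1),
               "positive")
  rendered <- generate_projection_templates(ph, 30, tilt_sweep = 0,
                                            z_range = c(0, 90), z_step = 90)
  expect_equal(length(rendered$templates), 2)
  expect_s3_class(rendered$templates[[1]], "micrograph_image")
})
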