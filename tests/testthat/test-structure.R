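# Structural comparison metrics: superposition, selection RMSD, simulated
# density, rigid-body fitting, lattice expansion, channel geometry,
# inter-assembly rotation, contacts and sequence mass.

test_that("Kabsch superposition recovers known transforms", {
  X <- with_seed(3, matrix(rnorm(60), 20, 3))
  fit0 <- superpose_kabsch(X, X)
  expect_lt(fit0$rmsd, 1e-12)
  expect_equal(fit0$transform$rotation, diag(3), tolerance = 1e-9)

  R <- phunlattice:::rot3_axis(c(1, 2, 3), 37)
  tv <- c(4, -2, 7)
  Y <- sweep(X %*% t(R), 2, -tv)
  fit <- superpose_kabsch(Y, X)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(fit$transform$rotation, R, tolerance = 1e-9)

  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(superpose_kabsch(line, line), "degenerate")

  # RMSD invariance under a common rigid transform of both sets
  Q <- phunlattice:::rot3_axis(c(0, 1, 1), 61)
  X2 <- with_seed(4, X + matrix(rnorm(60, sd = 0.5), 20, 3))
  r1 <- superpose_kabsch(X, X2)$rmsd
  r2 <- superpose_kabsch(X %*% t(Q), X2 %*% t(Q))$rmsd
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("selection RMSD aligns on one selection and reports on others", {
  m <- dimer_model(2)
  same <- rmsd_on_selection(m, c("A", "B"), 1:40, list(all = 1:40))
  expect_equal(unname(same["all"]), unname(same["align"]), tolerance = 1e-9)

  # displaced loop: report >= align
  m2 <- m
  loop <- m2$atoms$chain == "B" & m2$atoms$resno > 30
  m2$atoms$x[loop] <- m2$atoms$x[loop] + 5
  r <- rmsd_on_selection(m2, c("A", "B"), 1:30, list(all = 1:40))
  expect_gte(r["all"], r["align"] - 1e-12)

  # analytic two-domain construction: domain 2 rotated about a known axis
  coords <- with_seed(7, matrix(rnorm(240, sd = 8), 80, 3))
  dom2 <- 41:80
  R10 <- phunlattice:::rot3_axis(c(0, 0, 1), 10)
  ctr2 <- colMeans(coords[dom2, ])
  moved <- coords
  moved[dom2, ] <- sweep(sweep(coords[dom2, ], 2, ctr2) %*% t(R10), 2, -ctr2)
  mm <- atomic_model(rbind(
    data.frame(chain = "A", resno = 1:80, resname = "ALA", elety = "CA",
               element = "C", x = coords[, 1], y = coords[, 2], z = coords[, 3]),
    data.frame(chain = "B", resno = 1:80, resname = "ALA", elety = "CA",
               element = "C", x = moved[, 1], y = moved[, 2], z = moved[, 3])))
  got <- rmsd_on_selection(mm, c("A", "B"), 1:40, list(dom2 = dom2))
  disp <- sweep(coords[dom2, ], 2, ctr2)
  rperp2 <- disp[, 1]^2 + disp[, 2]^2        # rotation about z
  expected <- 2 * sin(10 * pi / 360) * sqrt(mean(rperp2))
  expect_equal(unname(got["dom2"]), expected, tolerance = 1e-6)
  expect_error(rmsd_on_selection(mm, c("A", "B"), integer()), "selection")
})

test_that("simulated density is a calibrated Gaussian per atom", {
  one <- ca_model(matrix(c(0, 0, 0), 1))
  v <- simulate_density(one, resolution = 6, voxel_size = 1.5, pad = 12)
  w <- which(v$grid == max(v$grid), arr.ind = TRUE)[1, ]
  pos <- (w - 1) * v$voxel_size + v$origin
  expect_lt(sqrt(sum(pos^2)), v$voxel_size)
  # isotropy of the profile
  d <- dim(v$grid)
  expect_equal(v$grid[w[1] + 2, w[2], w[3]], v$grid[w[1], w[2] + 2, w[3]],
               tolerance = 1e-6)

  # additivity for well-separated atoms
  two <- ca_model(rbind(c(0, 0, 0), c(30, 0, 0)))
  v2 <- simulate_density(two, resolution = 6, voxel_size = 1.5, pad = 12)
  expect_equal(sum(v2$grid) * v2$voxel_size^3, 2 * sum(v$grid) * v$voxel_size^3,
               tolerance = 1e-4)

  # width calibration: the amplitude at s = 1/d has decayed to exp(-2)
  si <- phunlattice:::.shell_index(dim(v$grid))
  amp <- Mod(fft(v$grid))
  s <- si$r / v$voxel_size
  band <- abs(s - 1 / 6) < 0.005
  expect_equal(mean(amp[band]) / amp[1, 1, 1], exp(-2), tolerance = 0.15)

  expect_error(simulate_density(one, resolution = 2, voxel_size = 1.5),
               "sampling")
})

test_that("rigid-body fitting recovers identity and displaced poses", {
  coords <- with_seed(5, matrix(rnorm(150, sd = 8), 50, 3))
  mdl <- ca_model(coords)
  map <- simulate_density(mdl, resolution = 6, voxel_size = 2, pad = 12)

  fit0 <- fit_model_in_map(mdl, map, rot_range = 0)
  expect_gte(fit0$masked_cc, 0.99)
  ang0 <- acos(pmin(1, (sum(diag(fit0$transform$rotation)) - 1) / 2)) * 180 / pi
  expect_lt(ang0, 1)
  expect_lt(sqrt(sum(fit0$transform$translation^2)), 0.5)

  R <- phunlattice:::rot3_axis(c(0, 0, 1), 15)
  ctr <- colMeans(coords)
  disp <- sweep(sweep(coords, 2, ctr) %*% t(R), 2, -(ctr + c(8, 0, 0)))
  fit1 <- fit_model_in_map(ca_model(disp), map, rot_range = 20, rot_step = 10)
  moved <- apply_transform(disp, fit1$transform)
  expect_lt(sqrt(mean(rowSums((moved - coords)^2))), 0.5)
  expect_gte(fit1$masked_cc, 0.99)
})

test_that("masked correlation is invariant under joint 90-degree rotation", {
  coords <- with_seed(6, matrix(rnorm(90, sd = 6), 30, 3))
  mdl <- ca_model(coords)
  map <- simulate_density(mdl, resolution = 6, voxel_size = 2, pad = 10)
  sim <- simulate_density(mdl, 6, like = map)
  mask <- phunlattice:::make_soft_mask(sim)
  cc0 <- phunlattice:::.masked_cc(map$grid, sim$grid, mask)
  rot <- function(a) aperm(a, c(2, 1, 3))[dim(a)[2]:1, , , drop = FALSE]
  cc1 <- phunlattice:::.masked_cc(rot(map$grid), rot(sim$grid), rot(mask))
  expect_equal(cc1, cc0, tolerance = 1e-6)
})

test_that("lattice expansion copies the assembly on the unit cell", {
  m <- dimer_model(3)
  one <- expand_lattice_assembly(m, c(120, 0), c(-20.8, 118.2), 1, 1)
  expect_equal(nrow(one$atoms), nrow(m$atoms))

  four <- expand_lattice_assembly(m, c(120, 0), c(-20.8, 118.2), 2, 2)
  expect_equal(length(unique(four$atoms$chain)), 8)   # 2 chains x 4 copies
  expect_equal(nrow(four$atoms), 4 * nrow(m$atoms))
  cent <- t(vapply(split(seq_len(nrow(four$atoms)),
                         sub("^.*\\.(\\d+\\.\\d+)$", "\\1", four$atoms$chain)),
                   function(i) colMeans(as.matrix(four$atoms[i, c("x", "y", "z")])),
                   numeric(3)))
  expect_equal(nrow(unique(round(cent, 3))), 4)

  expect_error(expand_lattice_assembly(m, c(120, 0), c(240, 0), 2, 2),
               "degenerate")
  expect_warning(expand_lattice_assembly(m, c(0.4, 0), c(0, 0.4), 2, 2),
                 "clash")
})

test_that("an expanded lattice indexes back to its basis", {
  m <- dimer_model(4, n = 10)
  big <- expand_lattice_assembly(m, c(120, 0), c(120 * cos(100 * pi / 180),
                                                 120 * sin(100 * pi / 180)),
                                 8, 8)
  cent <- t(vapply(split(seq_len(nrow(big$atoms)),
                         sub("^.*\\.(\\d+\\.\\d+)$", "\\1", big$atoms$chain)),
                   function(i) colMeans(as.matrix(big$atoms[i, c("x", "y", "z")])),
                   numeric(3)))
  px <- 4
  img <- phunlattice:::bilinear_splat(512, 512, (cent[, 1] + 500) / px,
                                      (cent[, 2] + 300) / px)
  # soften the deltas so peaks are interpolable
  q <- phunlattice:::fft_freq(512) / 512
  G <- exp(-2 * pi^2 * 1.5^2 * outer(q^2, q^2, "+"))
  img <- Re(fft(fft(img) * G, inverse = TRUE)) / 512^2
  m2 <- index_lattice(micrograph_image(img, px), peak_zmin = 4)
  expect_lt(abs(m2$a_len - 120) / 120, 0.02)
  expect_lt(abs(m2$gamma - 100), 2)
})

test_that("channel diagonals are centroid distances of opposing corners", {
  sq <- ca_model(rbind(c(0, 0, 0), c(3, 0, 0), c(3, 3, 0), c(0, 3, 0)))
  corners <- lapply(1:4, function(i) list(chain = "A", resno = i))
  d <- channel_geometry(sq, corners)
  expect_equal(unname(d), rep(3 * sqrt(2), 2), tolerance = 1e-12)

  rect <- ca_model(rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0), c(0, 4, 0)))
  d2 <- channel_geometry(rect, corners)
  expect_equal(unname(d2), c(5, 5), tolerance = 1e-12)

  expect_error(channel_geometry(sq, corners[1:3]), "4 corners")
  expect_error(channel_geometry(sq, c(corners[1:3],
                                      list(list(chain = "Z", resno = 99)))),
               "empty corner")
})

test_that("inter-assembly rotation measures the quaternary difference", {
  A1 <- ca_model(with_seed(11, matrix(rnorm(45, sd = 7), 15, 3)), "A")
  B1 <- ca_model(with_seed(12, matrix(rnorm(45, sd = 7), 15, 3)) + 30, "B")
  as1 <- atomic_model(rbind(A1$atoms, B1$atoms))
  expect_equal(inter_assembly_rotation(as1, as1)$angle, 0, tolerance = 1e-9)

  Rx30 <- phunlattice:::rot3_axis(c(1, 0, 0), 30)
  cb <- colMeans(as.matrix(B1$atoms[, c("x", "y", "z")]))
  B2 <- B1
  B2$atoms[, c("x", "y", "z")] <-
    sweep(sweep(as.matrix(B1$atoms[, c("x", "y", "z")]), 2, cb) %*% t(Rx30),
          2, -cb)
  as2 <- atomic_model(rbind(A1$atoms, B2$atoms))
  r12 <- inter_assembly_rotation(as1, as2)
  expect_equal(r12$angle, 30, tolerance = 0.1)
  expect_equal(r12$axis_to_normal, 90, tolerance = 1)  # in-plane axis
  r21 <- inter_assembly_rotation(as2, as1)
  expect_equal(r12$angle, r21$angle, tolerance = 1e-6)
})

test_that("contact maps group interface contacts by region pairs", {
  regions <- region_annotations()
  mk <- function(chain, resno, x) {
    data.frame(chain = chain, resno = resno, resname = "ALA", elety = "CA",
               element = "C", x = x, y = 0, z = 0)
  }
  two <- atomic_model(rbind(mk("A", 120, 0), mk("B", 115, 3)), regions)
  cm <- contact_map(two, 4.5)
  expect_equal(nrow(cm), 1)
  expect_identical(cm$interface, "closed_hairpin")

  far <- atomic_model(rbind(mk("A", 120, 0), mk("B", 115, 5)), regions)
  expect_equal(nrow(contact_map(far, 4.5)), 0)

  # monotone non-decreasing in cutoff
  mixed <- atomic_model(rbind(mk("A", 120, 0), mk("B", 115, 3.2),
                              mk("B", 300, 4.4), mk("B", 20, 5.5)), regions)
  n1 <- nrow(contact_map(mixed, 3.5))
  n2 <- nrow(contact_map(mixed, 4.5))
  n3 <- nrow(contact_map(mixed, 6))
  expect_true(n1 <= n2 && n2 <= n3)

  # open hairpin: hairpin against core; diamond: N-tail involvement
  oh <- atomic_model(rbind(mk("A", 120, 0), mk("B", 200, 3)), regions)
  expect_identical(contact_map(oh, 4.5)$interface, "open_hairpin")
  dm <- atomic_model(rbind(mk("A", 10, 0), mk("B", 200, 3)), regions)
  expect_identical(contact_map(dm, 4.5)$interface, "diamond")
  lp <- atomic_model(rbind(mk("A", 280, 0), mk("B", 281, 3)), regions)
  expect_identical(contact_map(lp, 4.5)$interface, "loop")

  expect_error(contact_map(atomic_model(mk("A", 1, 0)), 4.5), "two chains")
  expect_error(contact_map(two, 10), "cutoff")
})

test_that("sequence masses follow the residue table", {
  expect_equal(sequence_mass("G"), 0.07507, tolerance = 1e-4)
  expect_equal(sequence_mass("GG"), 0.13212, tolerance = 1e-4)
  # additivity: peptide bond releases one water per join
  m1 <- sequence_mass("ACDEFGHIKLMNPQRSTVWY")
  expect_equal(m1 * 1000,
               sum(phunlattice:::.residue_mass) + 18.01528, tolerance = 1e-6)
  expect_error(sequence_mass("ACZ"), "alphabet error.*Z")
})
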