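# Shared fixtures built in code: small atomic models, isotropy helpers and
# an independent brute-force FSC oracle.

# Minimal single-chain model from a coordinate matrix (CA atoms).
ca_model <- function(coords, chain = "A", resno = seq_len(nrow(coords)),
                     regions = list()) {
  atomic_model(data.frame(chain = chain, resno = resno, resname = "ALA",
                          elety = "CA", element = "C",
                          x = coords[, 1], y = coords[, 2], z = coords[, 3],
                          stringsAsFactors = FALSE),
               regions = regions)
}

# Two-chain synthetic dimer with a known relative transform.
dimer_model <- function(seed = 1, n = 40, rot = diag(3), shift = c(25, 0, 0)) {
  coords <- with_seed(seed, matrix(rnorm(3 * n, sd = 6), n, 3))
  b <- sweep(coords %*% t(rot), 2, -shift)
  atomic_model(rbind(
    data.frame(chain = "A", resno = seq_len(n), resname = "ALA", elety = "CA",
               element = "C", x = coords[, 1], y = coords[, 2], z = coords[, 3]),
    data.frame(chain = "B", resno = seq_len(n), resname = "ALA", elety = "CA",
               element = "C", x = b[, 1], y = b[, 2], z = b[, 3])))
}

with_seed <- phunlattice:::with_seed

# Brute-force FSC: explicit per-voxel loop accumulating shell sums, with
# transforms done by direct DFT matrix contraction (independent of the
# fft-based implementation path).
brute_fsc <- function(g1, g2, half_space = FALSE, directions = NULL,
                      cone_half_angle = 20) {
  d <- dim(g1)
  dft1 <- function(n) {
    w <- exp(-2i * pi * outer(0:(n - 1), 0:(n - 1)) / n)
    w
  }
  dft3 <- function(g) {
    W1 <- dft1(d[1]); W2 <- dft1(d[2]); W3 <- dft1(d[3])
    G <- array(0i, d)
    # transform axis by axis via explicit matrix products
    tmp <- array(0i, d)
    for (k in 1:d[3]) tmp[, , k] <- W1 %*% g[, , k] %*% t(W2)
    M <- matrix(tmp, d[1] * d[2], d[3])
    G <- array(M %*% t(W3), d)
    G
  }
  F1 <- dft3(g1); F2 <- dft3(g2)
  n <- min(d)
  nshell <- n %/% 2
  fr <- function(nn) { k <- 0:(nn - 1); k[k > nn / 2] <- k[k > nn / 2] - nn; k }
  kx <- fr(d[1]) / d[1]; ky <- fr(d[2]) / d[2]; kz <- fr(d[3]) / d[3]
  ndir <- if (is.null(directions)) 1 else nrow(directions)
  num <- matrix(0, nshell, ndir); p1 <- matrix(0, nshell, ndir)
  p2 <- matrix(0, nshell, ndir); cnt <- matrix(0L, nshell, ndir)
  cosa <- cos(cone_half_angle * pi / 180)
  for (iz in 1:d[3]) for (iy in 1:d[2]) for (ix in 1:d[1]) {
    vx <- kx[ix]; vy <- ky[iy]; vz <- kz[iz]
    r <- sqrt(vx^2 + vy^2 + vz^2)
    s <- as.integer(round(r * n))
    if (s < 1 || s > nshell) next
    if (half_space &&
        !(vz > 0 || (vz == 0 && (vy > 0 || (vy == 0 && vx > 0))))) next
    f1 <- F1[ix, iy, iz]; f2 <- F2[ix, iy, iz]
    for (j in seq_len(ndir)) {
      if (!is.null(directions)) {
        dt <- abs(vx * directions[j, 1] + vy * directions[j, 2] +
                    vz * directions[j, 3]) / r
        if (dt < cosa) next
      }
      num[s, j] <- num[s, j] + Re(f1 * Conj(f2))
      p1[s, j] <- p1[s, j] + Mod(f1)^2
      p2[s, j] <- p2[s, j] + Mod(f2)^2
      cnt[s, j] <- cnt[s, j] + 1L
    }
  }
  fsc <- num / sqrt(p1 * p2)
  fsc[cnt == 0] <- NA
  list(fsc = fsc, n = cnt)
}
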