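# Lattice indexing: accuracy, canonicalization, equivariance, and the
# exhaustive peak-pair oracle.

test_that("noiseless p4 rendering indexes to a square cell", {
  r <- render_lattice_image(lattice_preset("p4-invitro"), make_motif2d(5),
                            1024, 4, NULL)
  m <- index_lattice(r$image)
  expect_lt(abs(m$a_len - m$b_len) / m$a_len, 0.01)
  expect_lt(abs(m$gamma - 90), 0.5)
})

test_that("p2 in vitro cell is recovered within the accuracy contract", {
  r <- render_lattice_image(lattice_preset("p2-invitro"), make_motif2d(3),
                            1024, 4, noise_spec(0.3, 7))
  m <- index_lattice(r$image)
  expect_lt(abs(m$a_len - 120) / 120, 0.02)
  expect_lt(abs(m$b_len - 120) / 120, 0.02)
  expect_lt(abs(m$gamma - 100), 1.5)
})

test_that("basis reduction canonicalizes any basis of the same lattice", {
  base_a <- c(130, 0)
  base_b <- 115 * c(cos(100 * pi / 180), sin(100 * pi / 180))
  ref <- reduce_basis(base_a, base_b)
  for (i in 1:20) {
    U <- with_seed(i, {
      repeat {
        u <- matrix(sample(-3:3, 4, TRUE), 2)
        if (abs(u[1, 1] * u[2, 2] - u[1, 2] * u[2, 1]) == 1) break
      }
      u
    })
    v1 <- U[1, 1] * base_a + U[1, 2] * base_b
    v2 <- U[2, 1] * base_a + U[2, 2] * base_b
    rb <- reduce_basis(v1, v2)
    expect_equal(c(rb$a_len, rb$b_len, rb$gamma),
                 c(ref$a_len, ref$b_len, ref$gamma), tolerance = 1e-9)
  }
  expect_error(reduce_basis(c(1, 0), c(2, 0)), "linearly dependent")
})

test_that("indexing is equivariant under in-plane rotation", {
  m0 <- index_lattice(render_lattice_image(
    lattice_spec("p2", 120, 120, 100), make_motif2d(3), 1024, 4, NULL)$image)
  m17 <- index_lattice(render_lattice_image(
    lattice_spec("p2", 120, 120, 100, in_plane_rotation = 17),
    make_motif2d(3), 1024, 4, NULL)$image)
  expect_equal(coef(m17), coef(m0), tolerance = 0.01)
  # the rotation must map some basis-vector direction pairing (mod 180,
  # since +-v are the same lattice vector, and a/b may swap on a
  # near-square cell) onto a 17 degree offset
  angs <- function(m) c(atan2(m$basis[2, 1], m$basis[1, 1]),
                        atan2(m$basis[2, 2], m$basis[1, 2])) * 180 / pi
  cand <- as.numeric(outer(angs(m17), angs(m0), "-")) %% 180
  err <- pmin(abs(cand - 17), abs(cand - 17 + 180), abs(cand - 17 - 180))
  expect_lt(min(err), 1)
})

test_that("pure noise raises a no-lattice error", {
  img <- micrograph_image(with_seed(4, matrix(rnorm(1024^2), 1024)), 4)
  expect_error(index_lattice(img), "no significant periodic signal")
})

test_that("indexing agrees with an exhaustive peak-pair search oracle", {
  # oracle: try every non-collinear pair of strong autocorrelation peaks as
  # a basis, reduce it, and keep the pair explaining the most peaks with
  # the smallest cell
  oracle_basis <- function(img) {
    px <- img$pixel_size
    n1 <- nrow(img$pixels)
    A <- phunlattice:::.whitened_autocorr2(img$pixels)
    c0 <- floor(n1 / 2) + 1
    rmax <- min(floor(n1 / 2) - 2, ceiling(300 / px))
    S <- A[(c0 - rmax):(c0 + rmax), (c0 - rmax):(c0 + rmax)]
    ns <- 2 * rmax + 1
    dx <- matrix(rep(-rmax:rmax, ns), ns, ns); dy <- t(dx)
    rr <- sqrt(dx^2 + dy^2)
    ann <- rr >= floor(40 / px) & rr <= rmax
    is_max <- matrix(TRUE, ns, ns)
    for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                    c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
      is_max <- is_max & (S > phunlattice:::cshift(
        phunlattice:::cshift(S, sh[1], 1), sh[2], 2))
    mu <- median(S[ann]); sg <- stats::mad(S[ann])
    cand <- which(is_max & ann & (S - mu) / sg >= 5, arr.ind = TRUE)
    pk <- data.frame(x = cand[, 1] - rmax - 1, y = cand[, 2] - rmax - 1,
                     v = S[cand])
    pk <- head(pk[order(-pk$v), ], 25)
    # sub-pixel peak positions by parabolic interpolation
    for (r in seq_len(nrow(pk))) {
      sp <- phunlattice:::subpixel_peak(S, pk$x[r] + rmax + 1,
                                        pk$y[r] + rmax + 1)
      pk$xr[r] <- pk$x[r] + sp[1]
      pk$yr[r] <- pk$y[r] + sp[2]
    }
    # every non-collinear pair is a candidate; a candidate is scored by the
    # total peak value it explains, and among near-ties the coarsest cell
    # (largest area) wins, so pseudo-fine lattices do not
    cands <- list()
    for (i in seq_len(nrow(pk))) for (j in seq_len(nrow(pk))) {
      if (j <= i) next
      v1 <- c(pk$xr[i], pk$yr[i]); v2 <- c(pk$xr[j], pk$yr[j])
      if (abs(v1[1] * v2[2] - v1[2] * v2[1]) < 1e-9) next
      cands[[length(cands) + 1]] <- reduce_basis(v1, v2)
    }
    ev <- vapply(cands, function(rb) {
      hk <- solve(cbind(rb$a, rb$b), t(as.matrix(pk[, c("xr", "yr")])))
      sum(pk$v[colSums(abs(hk - round(hk))) < 0.2])
    }, 0)
    area <- vapply(cands, function(rb)
      abs(rb$a[1] * rb$b[2] - rb$a[2] * rb$b[1]), 0)
    qualifying <- which(ev >= 0.6 * sum(pk$v))
    if (!length(qualifying)) qualifying <- which(ev >= 0.97 * max(ev))
    best <- cands[[qualifying[which.max(area[qualifying])]]]
    # polish with an unweighted least squares over the explained peaks
    hk <- solve(cbind(best$a, best$b), t(as.matrix(pk[, c("xr", "yr")])))
    expl <- colSums(abs(hk - round(hk))) < 0.2
    if (sum(expl) >= 4) {
      X <- t(round(hk[, expl, drop = FALSE]))
      Y <- as.matrix(pk[expl, c("xr", "yr")])
      B <- t(solve(crossprod(X), crossprod(X, Y)))
      best <- reduce_basis(B[, 1], B[, 2])
    }
    c(best$a_len, best$b_len, best$gamma) * c(px, px, 1)
  }
  agree <- 0
  for (i in 1:50) {
    spec <- with_seed(3000 + i, {
      a <- runif(1, 80, 160); b <- runif(1, 80, a); g <- runif(1, 90, 130)
      lattice_spec("p2", a, b, g, in_plane_rotation = runif(1, 0, 90))
    })
    r <- render_lattice_image(spec, make_motif2d(i), 640, 4,
                              noise_spec(0.5, 5000 + i))
    m <- tryCatch(index_lattice(r$image), error = function(e) NULL)
    o <- tryCatch(oracle_basis(r$image), error = function(e) NULL)
    if (is.null(m) || is.null(o)) next
    ok <- abs(m$a_len - o[1]) / o[1] < 0.02 &&
      abs(m$b_len - o[2]) / o[2] < 0.02 && abs(m$gamma - o[3]) < 2
    agree <- agree + ok
  }
  expect_gte(agree, 48)
})
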