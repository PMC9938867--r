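# Lattice indexing from micrograph autocorrelation, basis reduction, and
# plane-group symmetry scoring.

#' Lattice model
#'
#' The fitted 2D lattice of a micrograph: a reduced basis (two shortest
#' linearly independent lattice vectors, in Angstrom), the derived cell
#' parameters with the inter-axis angle reported in \[90, 150\] degrees, and
#' optional plane-group symmetry scores.
#'
#' @param a,b 2D basis vectors in Angstrom; they are Lagrange-reduced and
#'   canonicalized on construction.
#' @param plane_group_scores named numeric vector of scores in \[-1, 1\] for
#'   p1/p2/p4.
#' @param assigned_group assigned plane group label.
#' @return An object of class `lattice_model`.
#' @export
lattice_model <- function(a, b,
                          plane_group_scores = c(p1 = NA_real_, p2 = NA_real_,
                                                 p4 = NA_real_),
                          assigned_group = "unassigned") {
  rb <- reduce_basis(a, b)
  structure(list(basis = cbind(a = rb$a, b = rb$b),
                 a_len = rb$a_len, b_len = rb$b_len, gamma = rb$gamma,
                 plane_group_scores = plane_group_scores,
                 assigned_group = assigned_group),
            class = "lattice_model")
}

#' @export
print.lattice_model <- function(x, ...) {
  cat(sprintf("<lattice_model> a = %.2f A, b = %.2f A, gamma = %.2f deg",
              x$a_len, x$b_len, x$gamma))
  cat(sprintf("  [%s]\n", x$assigned_group))
  if (!all(is.na(x$plane_group_scores)))
    cat("  plane-group scores:",
        paste(sprintf("%s = %.3f", names(x$plane_group_scores),
                      x$plane_group_scores), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.lattice_model <- function(object, ...) {
  cat("2D lattice model\n")
  cat(sprintf("  unit cell: a = %.3f A, b = %.3f A, gamma = %.3f deg\n",
              object$a_len, object$b_len, object$gamma))
  cat(sprintf("  basis a = (%.2f, %.2f) A, b = (%.2f, %.2f) A\n",
              object$basis[1, 1], object$basis[2, 1],
              object$basis[1, 2], object$basis[2, 2]))
  cat(sprintf("  cell area: %.0f A^2\n",
              abs(object$basis[1, 1] * object$basis[2, 2] -
                  object$basis[2, 1] * object$basis[1, 2])))
  cat(sprintf("  assigned plane group: %s\n", object$assigned_group))
  if (!all(is.na(object$plane_group_scores)))
    cat("  scores:", paste(sprintf("%s = %.3f",
        names(object$plane_group_scores), object$plane_group_scores),
        collapse = ", "), "\n")
  invisible(object)
}

#' @export
coef.lattice_model <- function(object, ...) {
  c(a_len = object$a_len, b_len = object$b_len, gamma = object$gamma)
}

#' @export
plot.lattice_model <- function(x, n_cells = 3, ...) {
  a <- x$basis[, 1]; b <- x$basis[, 2]
  nm <- expand.grid(n = 0:n_cells, m = 0:n_cells)
  pts <- cbind(nm$n * a[1] + nm$m * b[1], nm$n * a[2] + nm$m * b[2])
  plot(pts, asp = 1, pch = 19, xlab = "x (A)", ylab = "y (A)",
       main = sprintf("%s lattice: %.1f x %.1f A, %.1f deg",
                      x$assigned_group, x$a_len, x$b_len, x$gamma), ...)
  graphics::arrows(0, 0, a[1], a[2], length = 0.1, col = 2)
  graphics::arrows(0, 0, b[1], b[2], length = 0.1, col = 4)
  invisible(x)
}

#' Reduce a 2D lattice basis to canonical form
#'
#' Lagrange reduction to the two shortest linearly independent lattice
#' vectors, followed by the reporting convention `a_len >= b_len` and
#' inter-axis angle in \[90, 150\] degrees (the sign of `b` is flipped when
#' the reduced angle is acute). Any valid basis of the same lattice maps to
#' the same `(a_len, b_len, gamma)` triple.
#'
#' @param a,b length-2 numeric lattice vectors.
#' @return List with canonical `a`, `b`, `a_len`, `b_len`, `gamma`.
#' @export
reduce_basis <- function(a, b) {
  v1 <- as.numeric(a); v2 <- as.numeric(b)
  if (abs(v1[1] * v2[2] - v1[2] * v2[1]) < 1e-12)
    stop("basis vectors are linearly dependent")
  repeat {
    if (sum(v2^2) < sum(v1^2)) { tmp <- v1; v1 <- v2; v2 <- tmp }
    mu <- round(sum(v1 * v2) / sum(v1^2))
    if (mu == 0) break
    v2 <- v2 - mu * v1
  }
  # v1 is now the shortest vector; convention: a is the longer one
  aa <- v2; bb <- v1
  ga <- rad2deg(acos(max(-1, min(1, sum(aa * bb) /
                                    sqrt(sum(aa^2) * sum(bb^2))))))
  if (ga < 90) { bb <- -bb; ga <- 180 - ga }
  list(a = aa, b = bb, a_len = sqrt(sum(aa^2)), b_len = sqrt(sum(bb^2)),
       gamma = ga)
}

# Shifted autocorrelation of a centred image (DC moved to the matrix centre).
.autocorr2 <- function(pixels) {
  I <- pixels - mean(pixels)
  A <- Re(fft(Mod(fft(I))^2, inverse = TRUE)) / length(I)
  fftshift2(A)
}

# Whitened autocorrelation: the image power spectrum is flattened by its
# radial mean before back-transforming, which collapses the broad motif
# self-correlation into near-delta lattice peaks on a flat background. A
# mild Gaussian roll-off keeps the peaks ~2 px wide so parabolic sub-pixel
# interpolation stays well conditioned.
.whitened_autocorr2 <- function(pixels, rolloff = 0.35) {
  n1 <- nrow(pixels); n2 <- ncol(pixels)
  I <- pixels - mean(pixels)
  P <- Mod(fft(I))^2
  fx <- fft_freq(n1) / n1
  fy <- fft_freq(n2) / n2
  R <- sqrt(outer(fx^2, fy^2, "+"))
  nb <- 256
  bin <- as.integer(pmin(floor(R / (0.5 / nb)), nb - 1) + 1)
  cnt <- tabulate(bin, nb)
  sums <- rowsum(as.numeric(P), bin)
  prof <- numeric(nb)
  prof[as.integer(rownames(sums))] <- sums
  prof <- prof / pmax(cnt, 1)
  prof <- pmax(prof, 1e-9 * max(prof))  # guard against empty/denormal bins
  W <- P / prof[bin]
  W <- W * exp(-(R / rolloff)^2)
  W[R > 0.5] <- 0                       # corners beyond Nyquist
  dim(W) <- c(n1, n2)
  fftshift2(Re(fft(W, inverse = TRUE)) / length(I))
}

#' Index a lattice image
#'
#' Estimates the 2D unit cell of a crystalline micrograph from the peaks of
#' its autocorrelation. The two strongest short non-collinear peaks seed a
#' basis, which is Lagrange-reduced and then refined to sub-pixel precision
#' by walking out to high-order autocorrelation peaks (peak position at
#' `k * v` divided by `k`). Optionally the plane-group symmetry of the
#' lattice-averaged motif is scored afterwards.
#'
#' @param img a [micrograph_image] showing at least 5 x 5 unit cells.
#' @param min_spacing,max_spacing Angstrom bounds on the expected basis
#'   vector lengths.
#' @param peak_zmin minimum autocorrelation peak z-score (versus the search
#'   annulus) for a peak to count as significant; if no peak reaches it a
#'   no-lattice error is raised.
#' @param score_groups if `TRUE`, run [score_plane_group()] on the result.
#' @return A [lattice_model]; the detected peak table is attached as
#'   `attr(, "peaks")`.
#' @export
index_lattice <- function(img, min_spacing = 40, max_spacing = 300,
                          peak_zmin = 5, score_groups = FALSE) {
  stopifnot(inherits(img, "micrograph_image"))
  px <- img$pixel_size
  n1 <- nrow(img$pixels); n2 <- ncol(img$pixels)
  A <- .whitened_autocorr2(img$pixels)
  c1 <- floor(n1 / 2) + 1; c2 <- floor(n2 / 2) + 1
  rmin <- max(3, floor(min_spacing / px))
  rmax <- min(floor(min(n1, n2) / 2) - 2, ceiling(max_spacing / px))
  if (rmax <= rmin) stop("image too small for the requested spacing range")
  ix <- (c1 - rmax):(c1 + rmax)
  iy <- (c2 - rmax):(c2 + rmax)
  S <- A[ix, iy]
  ns <- 2 * rmax + 1
  dx <- matrix(rep(-rmax:rmax, ns), ns, ns)
  dy <- t(dx)
  r <- sqrt(dx^2 + dy^2)
  annulus <- r >= rmin & r <= rmax
  # robust background stats: the lattice peaks themselves live in the
  # annulus and would otherwise inflate the scale estimate
  mu <- median(S[annulus])
  sg <- stats::mad(S[annulus])
  if (sg == 0) sg <- sd(S[annulus])
  # strict local maxima over the 8-neighbourhood
  is_max <- matrix(TRUE, ns, ns)
  for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                  c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
    nb <- cshift(cshift(S, sh[1], 1), sh[2], 2)
    is_max <- is_max & (S > nb)
  }
  cand <- which(is_max & annulus & (S - mu) / sg >= peak_zmin, arr.ind = TRUE)
  if (!nrow(cand))
    stop(sprintf("no significant periodic signal (no autocorrelation peak with z-score >= %g)", peak_zmin))
  peaks <- data.frame(dx = cand[, 1] - rmax - 1, dy = cand[, 2] - rmax - 1,
                      value = S[cand])
  peaks$z <- (peaks$value - mu) / sg
  peaks$radius <- sqrt(peaks$dx^2 + peaks$dy^2)
  peaks <- peaks[order(-peaks$value), , drop = FALSE]
  top <- head(peaks, 12)
  ord <- order(top$radius)
  v1 <- v2 <- NULL
  for (i in ord) {
    v <- c(top$dx[i], top$dy[i])
    if (is.null(v1)) { v1 <- v; next }
    sin_ang <- abs(v1[1] * v[2] - v1[2] * v[1]) /
      (sqrt(sum(v1^2)) * sqrt(sum(v^2)))
    if (sin_ang > sin(deg2rad(20))) { v2 <- v; break }
  }
  if (is.null(v2))
    stop("no second non-collinear lattice peak found")
  rb0 <- reduce_basis(v1, v2)
  # sublattice guard: if a strong detected peak has non-integer indices in
  # the candidate basis, the basis spans a sublattice; augment it with that
  # peak and re-reduce (classic indexing refinement)
  pk_m <- as.matrix(top[, c("dx", "dy")])
  pk_v <- top$value
  explained_value <- function(rb) {
    hk <- solve(cbind(rb$a, rb$b), t(pk_m))
    sum(pk_v[colSums(abs(hk - round(hk))) < 0.25])
  }
  for (aug in 1:3) {
    hk <- solve(cbind(rb0$a, rb0$b), t(pk_m))
    resid <- colSums(abs(hk - round(hk)))
    bad <- which(resid > 0.25 & pk_v > 0.3 * max(pk_v))
    if (!length(bad)) break
    cands <- list()
    for (b_i in bad) {
      p <- pk_m[b_i, ]
      cands <- c(cands,
                 list(tryCatch(reduce_basis(rb0$a, p), error = function(e) NULL),
                      tryCatch(reduce_basis(rb0$b, p), error = function(e) NULL)))
    }
    cands <- Filter(Negate(is.null), cands)
    if (!length(cands)) break
    ev <- vapply(cands, explained_value, 0)
    if (max(ev) <= explained_value(rb0)) break
    rb0 <- cands[[which.max(ev)]]
  }
  rr <- floor(min(n1, n2) / 2) - 5  # refinement can use peaks out to the edge
  B <- .refine_basis_lsq(A, c1, c2, cbind(rb0$a, rb0$b), rr, mu, sg,
                         zmin = peak_zmin)
  model <- lattice_model(B[, 1] * px, B[, 2] * px)
  attr(model, "peaks") <- peaks
  if (score_groups) model <- score_plane_group(img, model)
  model
}

# Sub-pixel refinement of the full basis by weighted least squares over all
# predicted autocorrelation peaks within radius `rmax`: each integer order
# (h, k) predicts a peak at h*a + k*b; located peaks (sub-pixel parabolic
# interpolation) with significant z-scores are fit back to the basis.
.refine_basis_lsq <- function(A, c1, c2, B0, rmax, bg_mu, bg_sg, zmin = 5,
                              window = 3) {
  hmax <- ceiling(rmax / sqrt(min(colSums(B0^2))))
  hk <- as.matrix(expand.grid(h = -hmax:hmax, k = -hmax:hmax))
  hk <- hk[!(hk[, 1] == 0 & hk[, 2] == 0), , drop = FALSE]
  pred <- hk %*% t(B0)
  rad <- sqrt(rowSums(pred^2))
  keep <- rad >= 4 & rad <= rmax &
    abs(pred[, 1]) < c1 - window - 2 & abs(pred[, 2]) < c2 - window - 2
  hk <- hk[keep, , drop = FALSE]; pred <- pred[keep, , drop = FALSE]
  obs <- matrix(NA_real_, nrow(pred), 2)
  wt <- numeric(nrow(pred))
  for (i in seq_len(nrow(pred))) {
    ip <- round(pred[i, ])
    i0 <- c1 + ip[1]; j0 <- c2 + ip[2]
    W <- A[(i0 - window):(i0 + window), (j0 - window):(j0 + window)]
    w <- which(W == max(W), arr.ind = TRUE)[1, ]
    ii <- i0 + (w[1] - window - 1); jj <- j0 + (w[2] - window - 1)
    z <- (A[ii, jj] - bg_mu) / bg_sg
    if (z < zmin) next
    sp <- subpixel_peak(A, ii, jj)
    obs[i, ] <- c(ii - c1 + sp[1], jj - c2 + sp[2])
    wt[i] <- z
  }
  ok <- which(wt > 0)
  if (length(ok) < 8) return(B0)      # too few confirmable peaks: keep seed
  fit <- function(sel) {
    X <- hk[sel, , drop = FALSE] * sqrt(wt[sel])
    Yv <- obs[sel, , drop = FALSE] * sqrt(wt[sel])
    t(solve(crossprod(X), crossprod(X, Yv)))  # 2x2, columns a, b
  }
  B <- fit(ok)
  # one outlier-trimmed re-fit (peaks landing on neighbours or noise)
  res <- sqrt(rowSums((obs[ok, , drop = FALSE] -
                         hk[ok, , drop = FALSE] %*% t(B))^2))
  good <- ok[res < stats::quantile(res, 0.9) + 0.25]
  if (length(good) >= 8) B <- fit(good)
  B
}

# Lattice-average the image into an N x N fractional-coordinate motif on
# the given pixel-space basis (columns a, b). The motif is sampled by
# bilinear interpolation at the same fractional grid in every unit cell and
# averaged over cells: identical sample positions per cell keep the average
# free of the asymmetric binning error that pixel-to-bin accumulation would
# introduce.
.cell_average <- function(pixels, basis_px, N) {
  n1 <- nrow(pixels); n2 <- ncol(pixels)
  B <- basis_px
  # fractional sample grid (bin centres)
  uu <- rep((seq_len(N) - 0.5) / N, times = N)
  vv <- rep((seq_len(N) - 0.5) / N, each = N)
  sx <- B[1, 1] * uu + B[1, 2] * vv
  sy <- B[2, 1] * uu + B[2, 2] * vv
  # cells whose sample points stay inside the image
  nmax <- ceiling((n1 + n2) / sqrt(min(colSums(B^2)))) + 2
  nm <- expand.grid(n = -nmax:nmax, m = -nmax:nmax)
  ox <- 1 + nm$n * B[1, 1] + nm$m * B[1, 2]
  oy <- 1 + nm$n * B[2, 1] + nm$m * B[2, 2]
  keep <- ox > 1 - min(sx) + 1 & oy > 1 - min(sy) + 1 &
    ox < n1 - max(sx) - 1 & oy < n2 - max(sy) - 1
  ox <- ox[keep]; oy <- oy[keep]
  if (!length(ox)) stop("motif extraction window exceeds the image")
  acc <- numeric(N * N)
  chunk <- max(1L, floor(2e6 / (N * N)))
  for (start in seq(1, length(ox), by = chunk)) {
    j <- start:min(start + chunk - 1, length(ox))
    PX <- outer(sx, ox[j], "+")
    PY <- outer(sy, oy[j], "+")
    x0 <- floor(PX); y0 <- floor(PY)
    fx <- as.numeric(PX - x0); fy <- as.numeric(PY - y0)
    # plain linear indices (a 2-column index matrix would be interpreted
    # as (row, col) pairs)
    i00 <- as.numeric((y0 - 1) * n1 + x0)
    vals <- pixels[i00] * (1 - fx) * (1 - fy) +
      pixels[i00 + 1] * fx * (1 - fy) +
      pixels[i00 + n1] * (1 - fx) * fy +
      pixels[i00 + n1 + 1] * fx * fy
    acc <- acc + rowSums(matrix(vals, N * N))
  }
  M <- matrix(acc / length(ox), N, N)
  M - mean(M)
}

#' Score plane-group symmetry of an indexed lattice
#'
#' Averages the image over all unit cells (fractional-coordinate binning on
#' the indexed basis) and measures the phase agreement of the averaged
#' motif's significant Fourier orders with their copies transformed by the
#' group generator: 180 degree rotation for p2, 90 degree rotation for p4.
#' Reflections are selected in a frequency band against a high-order noise
#' floor and equal-weighted (phase-only correlation), the classic
#' significant-reflection practice of 2D electron crystallography; the
#' unknown symmetry-axis position is handled by maximizing over the phase
#' origin (circular cross-correlation plus continuous sub-bin refinement).
#' Raw maxima are calibrated against a phase-randomized null so an
#' asymmetric motif scores near 0 rather than at the chance level of the
#' maximum statistic.
#'
#' The assigned group is the highest-order group whose own score exceeds
#' `tau` and whose cell constraints hold (p4 requires a near-square cell);
#' when no symmetric group clears the threshold the lattice is reported as
#' p1. Because p4 contains the p2 generator, a p4 lattice legitimately
#' scores high for both groups and no margin between the two is required.
#'
#' @param img the [micrograph_image] that was indexed.
#' @param model the [lattice_model] returned by [index_lattice()].
#' @param n_grid motif sampling grid per cell edge.
#' @param band frequency band in cycles per cell considered for scoring.
#' @param tau score threshold for assigning a symmetric group.
#' @return The `model` with `plane_group_scores` and `assigned_group` filled.
#' @export
score_plane_group <- function(img, model, n_grid = 96, band = c(1.5, 16),
                              tau = 0.5) {
  stopifnot(inherits(img, "micrograph_image"), inherits(model, "lattice_model"))
  px <- img$pixel_size
  n1 <- nrow(img$pixels); n2 <- ncol(img$pixels)
  if (max(model$a_len, model$b_len) > min(n1, n2) * px)
    stop("motif extraction window exceeds the image")
  N <- n_grid
  q <- fft_freq(N)
  Q <- sqrt(outer(q^2, q^2, "+"))
  whiten <- function(M) {
    Fa <- fft(M)
    P <- Mod(Fa)^2
    floor_noise <- median(P[Q > 0.2 * N & Q < 0.42 * N])
    sel <- Q >= band[1] & Q <= band[2] &
      P > pmax(10 * floor_noise, 1e-4 * max(P[Q >= band[1] & Q <= band[2]]))
    Fw <- matrix(0 + 0i, N, N)
    Fw[sel] <- Fa[sel] / Mod(Fa[sel])
    list(Fw = Fw, n = sum(sel))
  }
  raw_max <- function(wm, wt) {
    CF <- wm$Fw * Conj(wt$Fw)
    cc <- Re(fft(CF, inverse = TRUE))
    w <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    sig <- which(Mod(CF) > 0, arr.ind = TRUE)
    if (!nrow(sig)) return(0)
    qx <- q[sig[, 1]]; qy <- q[sig[, 2]]
    cf <- CF[sig]
    f <- function(s) sum(Re(cf * exp(2i * pi * (qx * s[1] + qy * s[2]) / N)))
    s0 <- c(w[1] - 1, w[2] - 1)
    best <- f(s0)
    step <- 0.5
    while (step > 0.01) {
      repeat {
        moved <- FALSE
        for (d in list(c(step, 0), c(-step, 0), c(0, step), c(0, -step))) {
          val <- f(s0 + d)
          if (val > best) { best <- val; s0 <- s0 + d; moved <- TRUE }
        }
        if (!moved) break
      }
      step <- step / 2
    }
    best / sqrt(max(wm$n, 1) * max(wt$n, 1))
  }
  score_vs <- function(M, Mt) {
    wm <- whiten(M); wt <- whiten(Mt)
    if (wm$n < 6 || wt$n < 6) return(NA_real_)
    raw <- raw_max(wm, wt)
    # null: same maximum statistic with the transformed phases randomized
    null <- with_seed(7, {
      mean(vapply(1:3, function(i) {
        wr <- wt
        nz <- which(Mod(wr$Fw) > 0)
        wr$Fw[nz] <- exp(2i * pi * runif(length(nz)))
        raw_max(wm, wr)
      }, 0))
    })
    (raw - null) / (1 - null)
  }
  basis_px <- model$basis / px
  # focus polish: residual isotropic scale error in the basis blurs the
  # lattice average; pick the scale maximizing the band power (sharpness)
  # of the fold by a three-point parabola
  Ns <- 48                              # coarser grid suffices for sharpness
  qs <- fft_freq(Ns)
  Qs <- sqrt(outer(qs^2, qs^2, "+"))
  band_s <- Qs >= band[1] & Qs <= min(band[2], Ns / 2 - 4)
  sharpness <- function(B) {
    P <- Mod(fft(.cell_average(img$pixels, B, Ns)))^2
    fl <- median(P[Qs > 0.35 * Ns & Qs < 0.46 * Ns])
    sum(P[band_s & P > 10 * fl])
  }
  scales <- c(0.9975, 1, 1.0025)
  sv <- vapply(scales, function(s) sharpness(s * basis_px), 0)
  ds <- 0.0025 * max(min(0.5 * (sv[1] - sv[3]) /
                           (sv[1] - 2 * sv[2] + sv[3] +
                              .Machine$double.xmin), 1), -1)
  s_star <- 1 + if (is.finite(ds) && sv[2] >= max(sv[1], sv[3])) ds
                else 0.0025 * (which.max(sv) - 2)
  basis_px <- s_star * basis_px
  M <- .cell_average(img$pixels, basis_px, N)
  wrap_neg <- c(1, N:2)
  s2 <- score_vs(M, M[wrap_neg, wrap_neg])
  # p4 generator is a true rigid rotation only on a square cell: score on the
  # symmetrized (mean length, 90 degree) basis when the cell is near-square
  square_ok <- abs(model$a_len - model$b_len) / model$a_len <= 0.05 &&
    abs(model$gamma - 90) <= 3
  idx_neg <- ((-(0:(N - 1))) %% N) + 1
  if (square_ok) {
    len <- s_star * (model$a_len + model$b_len) / 2 / px
    ang <- atan2(model$basis[2, 1], model$basis[1, 1])
    Bsq <- len * cbind(c(cos(ang), sin(ang)),
                       c(-sin(ang), cos(ang)))
    M4 <- .cell_average(img$pixels, Bsq, N)
    s4 <- score_vs(M4, t(M4)[idx_neg, ])
  } else {
    s4 <- score_vs(M, t(M)[idx_neg, ])
  }
  scores <- c(p1 = 1, p2 = s2, p4 = s4)
  # p4 contains the p2 generator, so on a genuine p4 lattice both scores are
  # high and a winner-vs-runner-up margin cannot discriminate nested groups.
  # The assignment climbs to the highest-order group whose own score clears
  # tau and whose cell constraints hold.
  assigned <- "p1"
  if (is.finite(s2) && s2 >= tau) assigned <- "p2"
  if (is.finite(s4) && s4 >= tau && square_ok) assigned <- "p4"
  model$plane_group_scores <- scores
  model$assigned_group <- assigned
  model
}
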