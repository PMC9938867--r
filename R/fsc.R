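# Global and directional Fourier shell correlation between half-maps, and
# resolution estimation at a threshold.

#' Fourier shell correlation curve
#'
#' @param shell integer shell indices (1 = first non-DC shell).
#' @param freq shell-centre spatial frequencies in 1/Angstrom.
#' @param fsc correlation values in \[-1, 1\] (NA where undefined).
#' @param n_voxels voxels contributing per shell.
#' @return An object of class `fsc_curve` (a data.frame).
#' @export
fsc_curve <- function(shell, freq, fsc, n_voxels) {
  out <- data.frame(shell = shell, freq = freq, fsc = fsc,
                    n_voxels = n_voxels)
  class(out) <- c("fsc_curve", "data.frame")
  out
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("<fsc_curve> %d shells, freq %.4f-%.4f 1/A\n",
              nrow(x), min(x$freq), max(x$freq)))
  res <- resolution_at_threshold(x, 0.143)
  cat(sprintf("  resolution at FSC = 0.143: %.2f A%s\n", res$resolution,
              if (res$crossed) "" else " (no crossing; Nyquist)"))
  invisible(x)
}

#' @export
plot.fsc_curve <- function(x, threshold = 0.143, ...) {
  plot(x$freq, x$fsc, type = "l", xlab = "spatial frequency (1/A)",
       ylab = "FSC", ylim = c(min(0, min(x$fsc, na.rm = TRUE)), 1), ...)
  graphics::abline(h = threshold, lty = 2, col = 2)
  invisible(x)
}

# Shell index for every Fourier voxel (0 = DC) and frequencies, shared by the
# FSC routines. Shells are one Fourier voxel wide.
.shell_index <- function(d) {
  kx <- fft_freq(d[1]) / d[1]
  ky <- fft_freq(d[2]) / d[2]
  kz <- fft_freq(d[3]) / d[3]
  KX <- rep(kx, times = d[2] * d[3])
  KY <- rep(rep(ky, each = d[1]), times = d[3])
  KZ <- rep(kz, each = d[1] * d[2])
  r <- sqrt(KX^2 + KY^2 + KZ^2)
  n <- min(d)
  list(shell = as.integer(round(r * n)), KX = KX, KY = KY, KZ = KZ, r = r,
       nshell = n %/% 2)
}

.check_same_grid <- function(half1, half2) {
  if (!identical(dim(half1$grid), dim(half2$grid)))
    stop("half-maps have different grid dimensions")
  if (abs(half1$voxel_size - half2$voxel_size) > 1e-6)
    stop("half-maps have different voxel sizes")
}

#' Global Fourier shell correlation
#'
#' `FSC(s) = Re(sum F1 F2*) / sqrt(sum |F1|^2 sum |F2|^2)` over spherical
#' Fourier shells of width one Fourier voxel, up to Nyquist.
#'
#' @param half1,half2 two [density_volume]s on identical grids.
#' @return An [fsc_curve].
#' @export
global_fsc <- function(half1, half2) {
  .check_same_grid(half1, half2)
  d <- dim(half1$grid)
  F1 <- fft(half1$grid)
  F2 <- fft(half2$grid)
  si <- .shell_index(d)
  nshell <- si$nshell
  sh <- si$shell
  keep <- sh >= 1 & sh <= nshell
  sh <- sh[keep]
  num <- Re(F1[keep] * Conj(F2[keep]))
  p1 <- Mod(F1[keep])^2
  p2 <- Mod(F2[keep])^2
  sum_by <- function(x) {
    s <- rowsum(x, sh)
    out <- numeric(nshell)
    out[as.integer(rownames(s))] <- s
    out
  }
  ns <- tabulate(sh, nshell)
  fsc <- sum_by(num) / sqrt(pmax(sum_by(p1) * sum_by(p2), .Machine$double.xmin))
  fsc[ns == 0] <- NA
  n <- min(d)
  fsc_curve(seq_len(nshell), seq_len(nshell) / (n * half1$voxel_size),
            fsc, ns)
}

#' Near-uniform directions on the hemisphere
#'
#' Fibonacci-spiral sampling of the upper hemisphere (z >= 0), used for
#' directional FSC cones.
#'
#' @param n number of directions.
#' @return `n x 3` matrix of unit vectors.
#' @export
fibonacci_hemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n                       # uniform in cos(theta) over the hemisphere
  phi <- 2 * pi * i * (1 + sqrt(5)) / 2
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Directional Fourier shell correlation
#'
#' FSC restricted, per direction, to the Fourier voxels within a cone of
#' half-angle `cone_half_angle` about that direction. Directions sample the
#' hemisphere (Friedel mates are counted once by restricting to a Fourier
#' half-space); cones may overlap, and a voxel contributes to every cone
#' containing it. Shell/cone intersections with no voxels are reported as
#' `NA` (undefined), never as zero.
#'
#' @param half1,half2 two [density_volume]s on identical grids.
#' @param cone_half_angle cone half-angle in degrees, in \[10, 45\].
#' @param n_directions number of hemisphere directions.
#' @return An object of class `dfsc_result`: list with `directions`,
#'   `cone_half_angle`, `curves` (shell x direction matrix), `freq`,
#'   `n_voxels` (shell x direction counts) and `global` (an [fsc_curve]).
#' @export
directional_fsc <- function(half1, half2, cone_half_angle = 20,
                            n_directions = 48) {
  .check_same_grid(half1, half2)
  if (cone_half_angle < 10 || cone_half_angle > 45)
    stop("`cone_half_angle` must lie in [10, 45] degrees")
  d <- dim(half1$grid)
  F1 <- fft(half1$grid)
  F2 <- fft(half2$grid)
  si <- .shell_index(d)
  nshell <- si$nshell
  # Friedel half-space: kz > 0, plus half of the kz = 0 plane
  half_space <- si$KZ > 0 | (si$KZ == 0 & (si$KY > 0 | (si$KY == 0 & si$KX > 0)))
  keep <- si$shell >= 1 & si$shell <= nshell & half_space
  sh <- si$shell[keep]
  kx <- si$KX[keep]; ky <- si$KY[keep]; kz <- si$KZ[keep]
  rr <- si$r[keep]
  num <- Re(F1[keep] * Conj(F2[keep]))
  p1 <- Mod(F1[keep])^2
  p2 <- Mod(F2[keep])^2
  dirs <- fibonacci_hemisphere(n_directions)
  cosang <- cos(deg2rad(cone_half_angle))
  curves <- matrix(NA_real_, nshell, n_directions)
  counts <- matrix(0L, nshell, n_directions)
  for (j in seq_len(n_directions)) {
    dt <- abs(kx * dirs[j, 1] + ky * dirs[j, 2] + kz * dirs[j, 3]) / rr
    inc <- dt >= cosang
    shj <- sh[inc]
    sum_by <- function(x) {
      s <- rowsum(x, shj)
      out <- numeric(nshell)
      out[as.integer(rownames(s))] <- s
      out
    }
    nsj <- tabulate(shj, nshell)
    den <- sum_by(p1[inc]) * sum_by(p2[inc])
    fj <- ifelse(nsj > 0 & den > 0,
                 sum_by(num[inc]) / sqrt(pmax(den, .Machine$double.xmin)),
                 NA_real_)
    curves[, j] <- fj
    counts[, j] <- nsj
  }
  n <- min(d)
  structure(list(directions = dirs, cone_half_angle = cone_half_angle,
                 curves = curves,
                 freq = seq_len(nshell) / (n * half1$voxel_size),
                 n_voxels = counts,
                 global = global_fsc(half1, half2)),
            class = "dfsc_result")
}

#' @export
print.dfsc_result <- function(x, ...) {
  res <- apply(x$curves, 2, function(f)
    resolution_at_threshold(fsc_curve(seq_along(f), x$freq, f,
                                      rep(1, length(f))), 0.143)$resolution)
  cat(sprintf("<dfsc_result> %d directions, cone half-angle %.0f deg, %d shells\n",
              nrow(x$directions), x$cone_half_angle, nrow(x$curves)))
  cat(sprintf("  directional resolution at FSC = 0.143: %.2f-%.2f A (worst/best)\n",
              max(res), min(res)))
  worst <- which.max(res)
  cat(sprintf("  worst direction: (%.2f, %.2f, %.2f); anisotropy ratio %.2f\n",
              x$directions[worst, 1], x$directions[worst, 2],
              x$directions[worst, 3], max(res) / min(res)))
  invisible(x)
}

#' @export
plot.dfsc_result <- function(x, threshold = 0.143, ...) {
  graphics::matplot(x$freq, x$curves, type = "l", lty = 1,
                    col = grDevices::adjustcolor(4, 0.3),
                    xlab = "spatial frequency (1/A)", ylab = "FSC", ...)
  graphics::lines(x$global$freq, x$global$fsc, lwd = 2)
  graphics::abline(h = threshold, lty = 2, col = 2)
  invisible(x)
}

#' Export a directional FSC result as a tidy table
#'
#' @param x a `dfsc_result`.
#' @return data.frame with one row per (direction, shell).
#' @export
dfsc_table <- function(x) {
  stopifnot(inherits(x, "dfsc_result"))
  nd <- nrow(x$directions); ns <- nrow(x$curves)
  data.frame(direction = rep(seq_len(nd), each = ns),
             dx = rep(x$directions[, 1], each = ns),
             dy = rep(x$directions[, 2], each = ns),
             dz = rep(x$directions[, 3], each = ns),
             shell = rep(seq_len(ns), nd),
             freq = rep(x$freq, nd),
             fsc = as.numeric(x$curves),
             n_voxels = as.integer(x$n_voxels))
}

#' Resolution at an FSC threshold
#'
#' Linear interpolation between the last shell above and the first shell
#' below the threshold. If the curve never drops below the threshold the
#' Nyquist frequency is returned with `crossed = FALSE`.
#'
#' @param curve an [fsc_curve] (or anything with `freq` and `fsc` columns).
#' @param threshold FSC threshold (default 0.143).
#' @return List with `freq` (1/Angstrom), `resolution` (Angstrom) and
#'   `crossed`.
#' @export
resolution_at_threshold <- function(curve, threshold = 0.143) {
  f <- curve$fsc; q <- curve$freq
  ok <- !is.na(f)
  f <- f[ok]; q <- q[ok]
  if (!length(f)) stop("empty FSC curve")
  below <- which(f < threshold)
  if (!length(below))
    return(list(freq = q[length(q)], resolution = 1 / q[length(q)],
                crossed = FALSE))
  i <- below[1]
  if (i == 1)
    return(list(freq = q[1], resolution = 1 / q[1], crossed = TRUE))
  # interpolate between shells i-1 (above) and i (below)
  t <- (f[i - 1] - threshold) / (f[i - 1] - f[i])
  fr <- q[i - 1] + t * (q[i] - q[i - 1])
  list(freq = fr, resolution = 1 / fr, crossed = TRUE)
}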