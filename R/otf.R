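# Optical transfer function built from directional FSC: Fourier-space
# weights in [0, 1] encoding the orientation anisotropy of a reconstruction.

#' OTF volume
#'
#' Fourier-grid transfer weights `H(k)` in \[0, 1\] with `H(0) = 1` and
#' Friedel symmetry `H(-k) = H(k)`, on the grid of the target volume.
#'
#' @param weights 3D array of weights (fft layout, DC at index 1).
#' @param voxel_size voxel size of the target volume in Angstrom.
#' @return An object of class `otf_volume`.
#' @export
otf_volume <- function(weights, voxel_size) {
  if (!is.array(weights) || length(dim(weights)) != 3)
    stop("`weights` must be a 3D array")
  if (any(weights < -1e-9) || any(weights > 1 + 1e-9))
    stop("OTF weights must lie in [0, 1]")
  weights[] <- pmin(pmax(weights, 0), 1)
  structure(list(weights = weights, voxel_size = voxel_size),
            class = "otf_volume")
}

#' @export
print.otf_volume <- function(x, ...) {
  d <- dim(x$weights)
  cat(sprintf("<otf_volume> %d x %d x %d, mean weight %.3f, %.1f%% below 0.1\n",
              d[1], d[2], d[3], mean(x$weights),
              100 * mean(x$weights < 0.1)))
  invisible(x)
}

# Index permutation mapping every Fourier voxel to its Friedel mate -k.
.friedel_index <- function(d) {
  ix <- c(1L, d[1]:2L)
  iy <- c(1L, d[2]:2L)
  iz <- c(1L, d[3]:2L)
  IX <- rep(ix, times = d[2] * d[3])
  IY <- rep(rep(iy, each = d[1]), times = d[3])
  IZ <- rep(iz, each = d[1] * d[2])
  (IZ - 1L) * d[1] * d[2] + (IY - 1L) * d[1] + IX
}

#' Build an OTF from a directional FSC result
#'
#' Every Fourier voxel receives the directional FSC value at its (direction,
#' radius): shell curves are interpolated radially and combined over the
#' direction samples with cone-windowed weights (a voxel direction within
#' the cone half-angle of several samples blends them; outside every cone it
#' falls back to the nearest sample). Undefined dFSC bins along a direction
#' are filled from the nearest defined shell and the fill count is recorded
#' in `attr(, "n_filled")`. Negative values clamp to 0, the result is
#' Friedel-symmetrized exactly, and `H(0) = 1`.
#'
#' @param dfsc a `dfsc_result` from [directional_fsc()].
#' @param dim target grid dimensions (length 3); shell count must match the
#'   dFSC shell grid.
#' @param voxel_size target voxel size in Angstrom.
#' @return An [otf_volume].
#' @export
build_otf_from_dfsc <- function(dfsc, dim, voxel_size) {
  stopifnot(inherits(dfsc, "dfsc_result"))
  si <- .shell_index(dim)
  nshell <- nrow(dfsc$curves)
  if (si$nshell != nshell)
    stop(sprintf("dFSC shell grid (%d shells) incompatible with target grid (%d shells)",
                 nshell, si$nshell))
  ndir <- nrow(dfsc$directions)
  # fill undefined bins from the nearest defined shell, per direction
  curves <- dfsc$curves
  n_filled <- 0L
  for (j in seq_len(ndir)) {
    v <- curves[, j]
    if (anyNA(v)) {
      def <- which(!is.na(v))
      if (!length(def)) stop(sprintf("direction %d has no defined dFSC bins", j))
      na <- which(is.na(v))
      n_filled <- n_filled + length(na)
      v[na] <- v[def[vapply(na, function(i) which.min(abs(def - i)), 0L)]]
      curves[, j] <- v
    }
  }
  rvox <- si$r * min(dim)               # continuous shell coordinate
  nz <- si$r > 0
  ux <- si$KX[nz] / si$r[nz]
  uy <- si$KY[nz] / si$r[nz]
  uz <- si$KZ[nz] / si$r[nz]
  cosa <- cos(deg2rad(dfsc$cone_half_angle))
  num <- numeric(sum(nz))
  den <- numeric(sum(nz))
  best <- rep(-Inf, sum(nz))
  nearest <- numeric(sum(nz))
  shell_grid <- seq_len(nshell)
  rv <- pmin(pmax(rvox[nz], 1), nshell)
  for (j in seq_len(ndir)) {
    vj <- stats::approx(shell_grid, curves[, j], xout = rv, rule = 2)$y
    dt <- abs(ux * dfsc$directions[j, 1] + uy * dfsc$directions[j, 2] +
                uz * dfsc$directions[j, 3])
    # cubed cone window: concentrates the blend on the nearest direction
    # samples, keeping the angular response sharper than the aperture
    w <- pmax(dt - cosa, 0)^3
    num <- num + w * vj
    den <- den + w
    upd <- dt > best
    best[upd] <- dt[upd]
    nearest[upd] <- vj[upd]
  }
  h <- ifelse(den > 0, num / den, nearest)
  H <- numeric(prod(dim))
  H[nz] <- h
  H[!nz] <- 1                            # DC
  H <- pmin(pmax(H, 0), 1)
  H <- (H + H[.friedel_index(dim)]) / 2  # exact Friedel symmetry
  out <- otf_volume(array(H, dim), voxel_size)
  attr(out, "n_filled") <- n_filled
  out
}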