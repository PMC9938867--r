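#' Gridded density volume
#'
#' Container for a 3D density map on a cubic-voxel grid, the central data
#' structure of the pipeline. Values are stored in an `[x, y, z]` array
#' (first index fastest, matching MRC column order); `voxel_size` is the
#' isotropic voxel edge in Angstrom and `origin` the Angstrom offset of the
#' first voxel.
#'
#' @param grid 3D numeric array of density values; all dimensions must be >= 2.
#' @param voxel_size voxel edge length in Angstrom (> 0).
#' @param origin numeric length-3 Angstrom offset of the first voxel.
#' @return An object of class `density_volume`.
#' @export
density_volume <- function(grid, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(grid) || length(dim(grid)) != 3)
    stop("`grid` must be a 3D array")
  if (any(dim(grid) < 2)) stop("all grid dimensions must be >= 2")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number")
  if (any(!is.finite(grid))) stop("grid values must be finite")
  structure(list(grid = grid, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<density_volume> %d x %d x %d voxels @ %.4f A/voxel (%.0f x %.0f x %.0f A)\n",
              d[1], d[2], d[3], x$voxel_size,
              d[1] * x$voxel_size, d[2] * x$voxel_size, d[3] * x$voxel_size))
  cat(sprintf("  density range [%.4g, %.4g], mean %.4g\n",
              min(x$grid), max(x$grid), mean(x$grid)))
  invisible(x)
}

#' Micrograph image
#'
#' A 2D real-space image with a physical pixel size. Pixels are stored as a
#' matrix `[x, y]` with the origin at the lower-left corner; coordinates used
#' throughout the package are Angstrom from that origin.
#'
#' @param pixels numeric matrix of image values (finite).
#' @param pixel_size pixel edge in Angstrom (> 0).
#' @return An object of class `micrograph_image`.
#' @export
micrograph_image <- function(pixels, pixel_size) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (any(!is.finite(pixels))) stop("pixel values must be finite")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number")
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "micrograph_image")
}

#' @export
print.micrograph_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<micrograph_image> %d x %d px @ %.3f A/px (%.0f x %.0f A)\n",
              d[1], d[2], x$pixel_size, d[1] * x$pixel_size, d[2] * x$pixel_size))
  invisible(x)
}

#' @export
plot.micrograph_image <- function(x, ...) {
  graphics::image(z = x$pixels, col = grDevices::gray.colors(256),
                  useRaster = TRUE, asp = 1, axes = FALSE, ...)
  invisible(x)
}

# ---------------------------------------------------------------------------
# MRC2014 I/O. Mode 2 (32-bit IEEE float), little-endian, x fastest.
# The 1024-byte header is parsed word-by-word; axis permutations recorded in
# mapc/mapr/maps are normalized to (x, y, z) order at read time.
# ---------------------------------------------------------------------------

.mrc_read <- function(path) {
  raw <- readBin(path, what = "raw", n = file.size(path))
  if (length(raw) < 1024) stop("malformed MRC header: file shorter than 1024 bytes")
  ints <- readBin(raw, integer(), n = 256, size = 4, endian = "little")
  flts <- readBin(raw, numeric(), n = 256, size = 4, endian = "little")
  h <- list(nx = ints[1], ny = ints[2], nz = ints[3], mode = ints[4],
            mx = ints[8], my = ints[9], mz = ints[10],
            cella = flts[11:13],
            mapc = ints[17], mapr = ints[18], maps = ints[19],
            nsymbt = ints[24],
            origin = flts[50:52])
  if (h$nx <= 0 || h$ny <= 0 || h$nz <= 0 || h$mode < 0 || h$mode > 16)
    stop("malformed MRC header: implausible dimensions or mode")
  if (h$mode != 2)
    stop(sprintf("unsupported MRC mode %d (only mode 2, 32-bit float)", h$mode))
  if (h$mx <= 0 || h$my <= 0 || h$mz <= 0 || any(h$cella <= 0))
    stop("malformed MRC header: missing sampling/cell information")
  vox <- h$cella / c(h$mx, h$my, h$mz)
  if (max(vox) - min(vox) > 1e-4)
    stop(sprintf("anisotropic voxel sizes unsupported: %.5f/%.5f/%.5f A",
                 vox[1], vox[2], vox[3]))
  nvox <- as.double(h$nx) * h$ny * h$nz
  start <- 1024 + h$nsymbt
  if (length(raw) < start + 4 * nvox)
    stop("truncated MRC file: data section shorter than header promises")
  vals <- readBin(raw[(start + 1):(start + 4 * nvox)], numeric(),
                  n = nvox, size = 4, endian = "little")
  arr <- array(vals, dim = c(h$nx, h$ny, h$nz))
  crs <- c(h$mapc, h$mapr, h$maps)
  if (!all(sort(crs) == 1:3)) stop("malformed MRC header: invalid mapc/mapr/maps")
  if (!all(crs == 1:3)) arr <- aperm(arr, match(1:3, crs))
  list(grid = arr, voxel_size = mean(vox), origin = h$origin)
}

.mrc_write <- function(grid, voxel_size, origin, path) {
  d <- dim(grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                       # nx ny nz
  wi(2)                       # mode 2 = float32
  wi(c(0, 0, 0))              # nxstart nystart nzstart
  wi(d)                       # mx my mz
  wf(d * voxel_size)          # cella
  wf(c(90, 90, 90))           # cellb
  wi(c(1, 2, 3))              # mapc mapr maps
  wf(c(min(grid), max(grid), mean(grid)))
  wi(if (d[3] > 1) 1 else 0)  # ispg: volume vs image
  wi(0)                       # nsymbt
  wi(rep(0, 25))              # extra words 26-49
  wf(origin)                  # origin x y z
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian machine stamp
  wf(sd(as.numeric(grid)))
  wi(1)                       # nlabl
  writeChar(sprintf("%-80s", "phunlattice"), con, nchars = 80, eos = NULL)
  writeChar(paste(rep(" ", 720), collapse = ""), con, nchars = 720, eos = NULL)
  writeBin(as.numeric(grid), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC2014 volume
#'
#' Reads a mode-2 (32-bit float) MRC file into a [density_volume]. The voxel
#' size is taken from the header cell dimensions divided by the grid sampling
#' and must be isotropic to 1e-4 Angstrom; `mapc/mapr/maps` axis permutations
#' are normalized so the returned grid is always in (x, y, z) order.
#'
#' @param path path to an MRC file.
#' @return A [density_volume].
#' @export
read_volume <- function(path) {
  m <- .mrc_read(path)
  density_volume(m$grid, m$voxel_size, m$origin)
}

#' Write an MRC2014 volume
#'
#' Writes a [density_volume] as a standards-compliant mode-2 MRC file with
#' cell dimensions `voxel_size * dim` and a correct machine stamp. Values are
#' stored as 32-bit floats; data already at float precision round-trip
#' bit-exactly.
#'
#' @param vol a [density_volume].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "density_volume"))
  .mrc_write(vol$grid, vol$voxel_size, vol$origin, path)
}

#' Read a 2D image (MRC or TIFF)
#'
#' MRC images are read with the pixel size from the header; TIFF images carry
#' no physical calibration, so `pixel_size` must be supplied.
#'
#' @param path path to a 2D MRC (nz = 1) or TIFF file.
#' @param pixel_size pixel size in Angstrom; required for TIFF.
#' @return A [micrograph_image].
#' @export
read_image <- function(path, pixel_size = NULL) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("package 'tiff' required to read TIFF images")
    if (is.null(pixel_size)) stop("`pixel_size` must be given for TIFF input")
    px <- tiff::readTIFF(path)
    if (length(dim(px)) == 3) px <- px[, , 1]
    # readTIFF is row-major with top-left origin; transpose to [x, y] lower-left
    return(micrograph_image(t(px[nrow(px):1, , drop = FALSE]), pixel_size))
  }
  m <- .mrc_read(path)
  if (dim(m$grid)[3] != 1) stop("not a 2D image: nz > 1")
  micrograph_image(m$grid[, , 1], m$voxel_size)
}

#' Write a 2D image as MRC
#'
#' @param img a [micrograph_image].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "micrograph_image"))
  .mrc_write(array(img$pixels, dim = c(dim(img$pixels), 1)),
             img$pixel_size, c(0, 0, 0), path)
}
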