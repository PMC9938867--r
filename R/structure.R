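# Structural comparison operations: rigid superposition, model-in-map
# fitting with masked correlation, lattice expansion, channel geometry,
# inter-assembly rotation, interface contacts and sequence mass.

#' Rigid transform
#'
#' A proper rotation plus translation in Angstrom.
#'
#' @param rotation 3x3 proper orthogonal matrix (det = +1).
#' @param translation length-3 Angstrom translation.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation matrix is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation matrix is not proper (det != 1)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param coords n x 3 matrix of Angstrom coordinates.
#' @param transform a [rigid_transform].
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, transform) {
  sweep(coords %*% t(transform$rotation), 2, -transform$translation)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' paired coordinate sets, `R %*% mov + t ~ ref`.
#'
#' @param coords_ref,coords_mov paired n x 3 coordinate matrices, n >= 3,
#'   not collinear.
#' @return List with `transform` (a [rigid_transform]) and `rmsd` in
#'   Angstrom.
#' @export
superpose_kabsch <- function(coords_ref, coords_mov) {
  coords_ref <- as.matrix(coords_ref); coords_mov <- as.matrix(coords_mov)
  n <- nrow(coords_ref)
  if (n != nrow(coords_mov)) stop("coordinate sets must be paired")
  if (n < 3) stop("need at least 3 paired points")
  cr <- colMeans(coords_ref); cm <- colMeans(coords_mov)
  A <- sweep(coords_ref, 2, cr); B <- sweep(coords_mov, 2, cm)
  sv_check <- svd(A)$d
  if (sv_check[2] < 1e-9 * max(sv_check[1], 1))
    stop("degenerate (collinear or duplicate) coordinate set")
  C <- crossprod(B, A)                 # 3x3
  sv <- svd(C)
  s <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
  tr <- cr - as.numeric(R %*% cm)
  moved <- sweep(coords_mov %*% t(R), 2, -tr)
  list(transform = rigid_transform(R, tr),
       rmsd = sqrt(mean(rowSums((moved - coords_ref)^2))))
}

# Paired C-alpha coordinates of two chains over a residue selection.
.paired_ca <- function(model, chain1, chain2, resno = NULL) {
  a <- model$atoms
  ca1 <- a[a$chain == chain1 & a$elety == "CA", ]
  ca2 <- a[a$chain == chain2 & a$elety == "CA", ]
  common <- intersect(ca1$resno, ca2$resno)
  if (!is.null(resno)) common <- intersect(common, resno)
  common <- sort(common)
  if (!length(common)) stop("selection error: no common C-alpha residues")
  list(ref = as.matrix(ca1[match(common, ca1$resno), c("x", "y", "z")]),
       mov = as.matrix(ca2[match(common, ca2$resno), c("x", "y", "z")]),
       resno = common)
}

#' RMSD over report selections after aligning on another selection
#'
#' Superposes chain `chains[2]` onto `chains[1]` using C-alpha atoms of
#' `align_selection` only, then reports the RMSD over each report selection
#' without re-fitting — the protocol behind domain-based comparisons of
#' quasi-equivalent subunits.
#'
#' @param model an [atomic_model] containing both chains.
#' @param chains length-2 chain ids (reference, mobile).
#' @param align_selection residue numbers used for the superposition.
#' @param report_selections named list of residue-number vectors to report
#'   RMSD over (`NULL` entries mean all common residues).
#' @return Named numeric vector of RMSDs in Angstrom (first element
#'   `align`, then one per report selection).
#' @export
rmsd_on_selection <- function(model, chains, align_selection,
                              report_selections = list(all = NULL)) {
  if (!length(align_selection)) stop("selection error: empty align selection")
  al <- .paired_ca(model, chains[1], chains[2], align_selection)
  fit <- superpose_kabsch(al$ref, al$mov)
  out <- c(align = fit$rmsd)
  for (nm in names(report_selections)) {
    sel <- report_selections[[nm]]
    if (!is.null(sel) && !length(sel)) stop("selection error: empty report selection")
    pr <- .paired_ca(model, chains[1], chains[2], sel)
    moved <- apply_transform(pr$mov, fit$transform)
    out[nm] <- sqrt(mean(rowSums((moved - pr$ref)^2)))
  }
  out
}

.element_z <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16, SE = 34, FE = 26,
                MG = 12, ZN = 30, CA = 20, MN = 25, NA. = 11, K = 19, CL = 17)

#' Simulate a density map from an atomic model
#'
#' Sum of per-atom Gaussians with real-space width `sigma = resolution / pi`
#' (amplitude proportional to atomic number), sampled on a cubic-voxel grid.
#'
#' @param model an [atomic_model].
#' @param resolution target resolution in Angstrom (>= 2 voxels).
#' @param voxel_size grid voxel in Angstrom (default `resolution / 3`).
#' @param like optional [density_volume] whose grid (dimensions, voxel size
#'   and origin) the simulation should match.
#' @param pad box padding around the model in Angstrom when `like` is NULL.
#' @return A [density_volume].
#' @export
simulate_density <- function(model, resolution, voxel_size = resolution / 3,
                             like = NULL, pad = 8) {
  if (!nrow(model$atoms)) stop("model is empty")
  if (!is.null(like)) {
    voxel_size <- like$voxel_size
    dims <- dim(like$grid)
    origin <- like$origin
  }
  if (resolution < 2 * voxel_size)
    stop(sprintf("sampling error: resolution %.2f A below Nyquist (%.2f A)",
                 resolution, 2 * voxel_size))
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  if (is.null(like)) {
    lo <- apply(xyz, 2, min) - pad
    hi <- apply(xyz, 2, max) + pad
    dims <- pmax(ceiling((hi - lo) / voxel_size), 8L)
    origin <- lo
  }
  sigma <- resolution / pi
  half <- ceiling(4 * sigma / voxel_size)
  z <- .element_z[toupper(model$atoms$element)]
  z[is.na(z)] <- 6
  grid <- array(0, dims)
  for (i in seq_len(nrow(xyz))) {
    c_vox <- (xyz[i, ] - origin) / voxel_size + 1
    i0 <- pmax(floor(c_vox) - half, 1)
    i1 <- pmin(floor(c_vox) + half + 1, dims)
    if (any(i0 > i1)) next
    ax <- (i0[1]:i1[1] - c_vox[1]) * voxel_size
    ay <- (i0[2]:i1[2] - c_vox[2]) * voxel_size
    az <- (i0[3]:i1[3] - c_vox[3]) * voxel_size
    gx <- exp(-ax^2 / (2 * sigma^2))
    gy <- exp(-ay^2 / (2 * sigma^2))
    gz <- exp(-az^2 / (2 * sigma^2))
    blk <- (z[i] * gx) %o% gy %o% gz
    grid[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <-
      grid[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] + blk
  }
  density_volume(grid, voxel_size, origin)
}

# Soft mask: simulated density thresholded at `nsigma` standard deviations
# above the mean, with a cosine edge of `edge` voxels (approximated by a
# Gaussian smoothing of the binary mask).
make_soft_mask <- function(vol, nsigma = 1, edge = 6) {
  g <- vol$grid
  bin <- g > mean(g) + nsigma * sd(as.numeric(g))
  if (!any(bin)) stop("mask error: empty mask")
  d <- dim(g)
  kx <- fft_freq(d[1]) / d[1]; ky <- fft_freq(d[2]) / d[2]
  kz <- fft_freq(d[3]) / d[3]
  K2 <- outer(outer(kx^2, ky^2, "+"), kz^2, "+")
  sm <- Re(fft(fft(bin + 0) * exp(-2 * pi^2 * (edge / 2)^2 * K2),
               inverse = TRUE)) / prod(d)
  pmin(pmax(sm, 0), 1)
}

# Pearson correlation weighted by a (soft) mask.
.masked_cc <- function(a, b, w) {
  sw <- sum(w)
  if (sw <= 0) stop("mask error: empty mask")
  ma <- sum(w * a) / sw; mb <- sum(w * b) / sw
  va <- sum(w * (a - ma)^2); vb <- sum(w * (b - mb)^2)
  sum(w * (a - ma) * (b - mb)) / sqrt(va * vb)
}

#' Fit result
#' @export
print.fit_result <- function(x, ...) {
  ang <- rad2deg(acos(pmin(1, pmax(-1, (sum(diag(x$transform$rotation)) - 1) / 2))))
  cat(sprintf("<fit_result> masked cc = %.4f, rotation %.2f deg, shift (%.2f, %.2f, %.2f) A%s\n",
              x$masked_cc, ang, x$transform$translation[1],
              x$transform$translation[2], x$transform$translation[3],
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Rigid-body fit of an atomic model into a density map
#'
#' Maximizes the masked real-space correlation between the map and the
#' simulated density of the transformed model, by a coarse orientational
#' grid search (translations solved by FFT cross-correlation at each
#' orientation) followed by local Nelder-Mead refinement of all six rigid
#' degrees of freedom. Rotations act about the model centroid.
#'
#' @param model an [atomic_model].
#' @param map target [density_volume].
#' @param mask optional soft-mask array on the map grid; by default a soft
#'   mask is built from the model's simulated density at the start pose
#'   (threshold 1 sigma, 6-voxel soft edge).
#' @param resolution resolution of the simulated model density in Angstrom
#'   (default 3 voxels).
#' @param rot_range,rot_step coarse search bracket and step, degrees, about
#'   each axis (0 range = local refinement only).
#' @return An object of class `fit_result`: `transform` ([rigid_transform],
#'   mapping input model coordinates to fitted coordinates), `masked_cc`,
#'   `converged`, and the search metadata.
#' @export
fit_model_in_map <- function(model, map, mask = NULL,
                             resolution = 3 * map$voxel_size,
                             rot_range = 20, rot_step = 10) {
  xyz0 <- as.matrix(model$atoms[, c("x", "y", "z")])
  ctr <- colMeans(xyz0)
  pose_model <- function(rv, tv) {
    R <- if (sum(rv^2) < 1e-12) diag(3) else rot3_axis(rv, sqrt(sum(rv^2)))
    m <- model
    m$atoms[, c("x", "y", "z")] <-
      sweep(sweep(xyz0, 2, ctr) %*% t(R), 2, -(ctr + tv))
    m
  }
  sim0 <- simulate_density(pose_model(c(0, 0, 0), c(0, 0, 0)),
                           resolution, like = map)
  if (is.null(mask)) mask <- make_soft_mask(sim0, 1, 6)
  score <- function(par) {
    sim <- simulate_density(pose_model(par[1:3], par[4:6]), resolution,
                            like = map)
    .masked_cc(map$grid, sim$grid, mask)
  }
  # coarse orientational search; translation by unmasked FFT correlation
  best <- c(rep(0, 6))
  best_cc <- -Inf
  angs <- if (rot_range > 0) seq(-rot_range, rot_range, by = rot_step) else 0
  Fm <- fft(map$grid)
  d <- dim(map$grid)
  for (ax in angs) for (ay in angs) for (az in angs) {
    rv0 <- c(ax, ay, az)
    sim <- simulate_density(pose_model(rv0, c(0, 0, 0)), resolution, like = map)
    cc <- Re(fft(Fm * Conj(fft(sim$grid)), inverse = TRUE))
    w <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    sh <- (w - 1)
    sh[sh > d / 2] <- sh[sh > d / 2] - d[sh > d / 2]
    par <- c(rv0, sh * map$voxel_size)
    v <- score(par)
    if (v > best_cc) { best_cc <- v; best <- par }
  }
  opt <- stats::optim(best, function(p) -score(p), method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-7))
  par <- opt$par
  R <- if (sum(par[1:3]^2) < 1e-12) diag(3) else
    rot3_axis(par[1:3], sqrt(sum(par[1:3]^2)))
  # full transform: x -> R (x - ctr) + ctr + t
  tr <- rigid_transform(R, as.numeric(ctr + par[4:6] - R %*% ctr))
  structure(list(transform = tr, masked_cc = -opt$value,
                 converged = opt$convergence == 0,
                 search = list(rot_range = rot_range, rot_step = rot_step,
                               resolution = resolution)),
            class = "fit_result")
}

#' Expand a tetramer into an n x m lattice assembly
#'
#' Deterministic translation of the assembly by integer combinations of the
#' 2D unit-cell basis (embedded at z = 0), with distinct chain identifiers
#' per copy. A clash fraction above 5% (heavy-atom pairs across copies
#' closer than 1.5 Angstrom) raises a geometry warning.
#'
#' @param model an [atomic_model] (e.g. one tetramer).
#' @param a,b unit-cell basis vectors, length 2 or 3, Angstrom.
#' @param n,m number of copies along `a` and `b`.
#' @return An [atomic_model] with `n * m` copies; chains renamed
#'   `<chain>.<i>.<j>`.
#' @export
expand_lattice_assembly <- function(model, a, b, n = 2, m = 2) {
  a3 <- c(a, 0)[1:3]; b3 <- c(b, 0)[1:3]
  if (abs(a3[1] * b3[2] - a3[2] * b3[1]) +
      abs(a3[1] * b3[3] - a3[3] * b3[1]) +
      abs(a3[2] * b3[3] - a3[3] * b3[2]) < 1e-9)
    stop("degenerate lattice basis")
  copies <- vector("list", n * m)
  k <- 0
  for (i in 0:(n - 1)) for (j in 0:(m - 1)) {
    k <- k + 1
    at <- model$atoms
    shift <- i * a3 + j * b3
    at$x <- at$x + shift[1]; at$y <- at$y + shift[2]; at$z <- at$z + shift[3]
    at$chain <- sprintf("%s.%d.%d", at$chain, i, j)
    copies[[k]] <- at
  }
  atoms <- do.call(rbind, copies)
  out <- atomic_model(atoms, model$regions)
  # clash check on a heavy-atom subsample
  heavy <- atoms[atoms$element != "H", ]
  if (nrow(heavy) > 4000) heavy <- heavy[seq(1, nrow(heavy), length.out = 4000), ]
  copy_id <- sub("^.*\\.(\\d+\\.\\d+)$", "\\1", heavy$chain)
  xyz <- as.matrix(heavy[, c("x", "y", "z")])
  n_clash <- 0L
  ids <- unique(copy_id)
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    A <- xyz[copy_id == ids[i], , drop = FALSE]
    B <- xyz[copy_id == ids[j], , drop = FALSE]
    for (r in seq_len(nrow(A))) {
      d2 <- (B[, 1] - A[r, 1])^2 + (B[, 2] - A[r, 2])^2 + (B[, 3] - A[r, 3])^2
      n_clash <- n_clash + sum(d2 < 1.5^2)
    }
  }
  if (n_clash / nrow(heavy) > 0.05)
    warning(sprintf("geometry warning: clash fraction %.1f%% across copies",
                    100 * n_clash / nrow(heavy)))
  out
}

#' Channel diagonals across four corner selections
#'
#' The diagonals of a lattice channel, measured between the C-alpha
#' centroids of opposing corner selections (1-3 and 2-4).
#'
#' @param model an [atomic_model].
#' @param corners list of exactly four selections, each a
#'   `list(chain =, resno =)` pair in channel order.
#' @return Named numeric `c(short =, long =)` in Angstrom.
#' @export
channel_geometry <- function(model, corners) {
  if (length(corners) != 4) stop("channel spec error: need exactly 4 corners")
  cent <- lapply(corners, function(sel) {
    xyz <- model_coords(model, chain = sel$chain, resno = sel$resno,
                        elety = "CA")
    if (!nrow(xyz))
      xyz <- model_coords(model, chain = sel$chain, resno = sel$resno)
    if (!nrow(xyz)) stop("channel spec error: empty corner selection")
    colMeans(xyz)
  })
  d13 <- sqrt(sum((cent[[1]] - cent[[3]])^2))
  d24 <- sqrt(sum((cent[[2]] - cent[[4]])^2))
  c(short = min(d13, d24), long = max(d13, d24))
}

#' Rotation between the quaternary arrangements of two assemblies
#'
#' Superposes the anchor chains of both assemblies, then measures the
#' residual rigid rotation relating the second chain pair:
#' `angle = acos((trace(R) - 1) / 2)`. The rotation axis and its angle to
#' the lattice normal (z) are reported so the out-of-plane character of the
#' rotation can be inspected.
#'
#' @param assembly1,assembly2 [atomic_model]s with corresponding chains.
#' @param anchor length-2 chain ids of the anchor chain in each assembly.
#' @param second length-2 chain ids of the chain whose relative rotation is
#'   measured.
#' @return List with `angle` (degrees), `axis` (unit 3-vector) and
#'   `axis_to_normal` (degrees between axis and z).
#' @export
inter_assembly_rotation <- function(assembly1, assembly2,
                                    anchor = c("A", "A"),
                                    second = c("B", "B")) {
  an <- .paired_ca_models(assembly1, assembly2, anchor[1], anchor[2])
  fit_anchor <- superpose_kabsch(an$ref, an$mov)
  sc <- .paired_ca_models(assembly1, assembly2, second[1], second[2])
  mov2 <- apply_transform(sc$mov, fit_anchor$transform)
  fit2 <- superpose_kabsch(sc$ref, mov2)
  R <- fit2$transform$rotation
  cosang <- (sum(diag(R)) - 1) / 2
  angle <- rad2deg(acos(pmin(1, pmax(-1, cosang))))
  ev <- eigen(R)
  axis <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  axis <- axis / sqrt(sum(axis^2))
  list(angle = angle, axis = axis,
       axis_to_normal = rad2deg(acos(min(1, abs(axis[3])))))
}

.paired_ca_models <- function(m1, m2, chain1, chain2) {
  a1 <- m1$atoms[m1$atoms$chain == chain1 & m1$atoms$elety == "CA", ]
  a2 <- m2$atoms[m2$atoms$chain == chain2 & m2$atoms$elety == "CA", ]
  common <- sort(intersect(a1$resno, a2$resno))
  if (length(common) < 3)
    stop("mapping error: fewer than 3 common C-alpha residues")
  list(ref = as.matrix(a1[match(common, a1$resno), c("x", "y", "z")]),
       mov = as.matrix(a2[match(common, a2$resno), c("x", "y", "z")]))
}

# Region name of a residue under the model's annotations ("core" if none).
.residue_region <- function(resno, regions) {
  for (nm in names(regions)) {
    r <- regions[[nm]]
    if (resno >= r[1] && resno <= r[2]) return(nm)
  }
  "core"
}

#' Inter-chain residue contacts grouped into lattice interfaces
#'
#' Heavy-atom contacts across chains within a distance cutoff, tagged with
#' the region annotations of both partners and grouped into the four named
#' lattice interfaces by region-pair rules: hairpin-hairpin contacts form
#' the Closed Hairpin interface, hairpin-core contacts the Open Hairpin
#' channel wall, loop-loop contacts the Loop interface, and contacts
#' involving the N-terminal tail the Diamond (domain-swap) interface.
#'
#' @param model an [atomic_model] with at least two chains.
#' @param cutoff heavy-atom distance cutoff in Angstrom, within \[3, 6\].
#' @return data.frame of residue-pair contacts with columns `chain1`,
#'   `resno1`, `region1`, `chain2`, `resno2`, `region2`, `min_dist`,
#'   `interface`.
#' @export
contact_map <- function(model, cutoff = 4.5) {
  if (cutoff < 3 || cutoff > 6) stop("cutoff must lie in [3, 6] Angstrom")
  a <- model$atoms[model$atoms$element != "H", ]
  chains <- unique(a$chain)
  if (length(chains) < 2) stop("input error: need at least two chains")
  out <- NULL
  for (i in seq_along(chains)) for (j in seq_along(chains)) {
    if (j <= i) next
    A <- a[a$chain == chains[i], ]
    B <- a[a$chain == chains[j], ]
    for (r in unique(A$resno)) {
      Ar <- A[A$resno == r, c("x", "y", "z")]
      d2min <- rep(Inf, nrow(B))
      for (k in seq_len(nrow(Ar)))
        d2min <- pmin(d2min, (B$x - Ar$x[k])^2 + (B$y - Ar$y[k])^2 +
                        (B$z - Ar$z[k])^2)
      hit <- d2min < cutoff^2
      if (!any(hit)) next
      hres <- unique(B$resno[hit])
      for (r2 in hres) {
        md <- sqrt(min(d2min[B$resno == r2]))
        out <- rbind(out, data.frame(chain1 = chains[i], resno1 = r,
                                     chain2 = chains[j], resno2 = r2,
                                     min_dist = md))
      }
    }
  }
  if (is.null(out))
    return(data.frame(chain1 = character(), resno1 = integer(),
                      region1 = character(), chain2 = character(),
                      resno2 = integer(), region2 = character(),
                      min_dist = numeric(), interface = character()))
  out$region1 <- vapply(out$resno1, .residue_region, "", regions = model$regions)
  out$region2 <- vapply(out$resno2, .residue_region, "", regions = model$regions)
  classify <- function(r1, r2) {
    rs <- sort(c(r1, r2))
    if (all(rs == "beta_hairpin")) return("closed_hairpin")
    if ("beta_hairpin" %in% rs && any(rs %in% c("core", "C_tail", "structured_loop")))
      return("open_hairpin")
    if (all(rs == "loop")) return("loop")
    if ("N_tail" %in% rs) return("diamond")
    "other"
  }
  out$interface <- mapply(classify, out$region1, out$region2)
  out[, c("chain1", "resno1", "region1", "chain2", "resno2", "region2",
          "min_dist", "interface")]
}

.residue_mass <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

#' Average molecular mass of a protein sequence
#'
#' Sum of average (not monoisotopic) amino-acid residue masses plus one
#' water, in kilodalton. Selenomethionine should be given as `M`.
#'
#' @param sequence one-letter amino-acid string (length >= 1).
#' @return Mass in kDa.
#' @export
sequence_mass <- function(sequence) {
  aa <- strsplit(toupper(gsub("\\s", "", sequence)), "")[[1]]
  if (!length(aa)) stop("empty sequence")
  bad <- setdiff(unique(aa), names(.residue_mass))
  if (length(bad))
    stop("alphabet error: unknown residue letter(s) ", paste(bad, collapse = ", "))
  (sum(.residue_mass[aa]) + 18.01528) / 1000
}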