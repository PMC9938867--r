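#' Atomic model container
#'
#' Chains, residues and atoms of a macromolecular model in Angstrom
#' coordinates, with optional named region annotations (residue ranges such as
#' the N-terminal tail or the lateral beta-hairpin of a lattice subunit).
#'
#' @param atoms data.frame with columns `chain`, `resno`, `insert`, `resname`,
#'   `elety` (atom name), `element`, `x`, `y`, `z`, `b`, `occ`, `het`.
#' @param regions named list of `c(start, end)` residue ranges.
#' @return An object of class `atomic_model`.
#' @export
atomic_model <- function(atoms, regions = list()) {
  need <- c("chain", "resno", "resname", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table missing column(s): ", paste(miss, collapse = ", "))
  if (!("insert" %in% names(atoms))) atoms$insert <- ""
  if (!("element" %in% names(atoms)))
    atoms$element <- toupper(substr(gsub("[0-9]", "", atoms$elety), 1, 1))
  if (!("b" %in% names(atoms))) atoms$b <- 0
  if (!("occ" %in% names(atoms))) atoms$occ <- 1
  if (!("het" %in% names(atoms))) atoms$het <- FALSE
  if (any(!is.finite(atoms$x)) || any(!is.finite(atoms$y)) || any(!is.finite(atoms$z)))
    stop("atom coordinates must be finite")
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom name) keys in model")
  if (length(regions)) {
    if (is.null(names(regions)) || anyDuplicated(names(regions)))
      stop("region names must be unique")
  }
  structure(list(atoms = atoms, regions = regions), class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  cat(sprintf("<atomic_model> %d atoms, %d chains (%s), %d residues\n",
              nrow(x$atoms), length(ch), paste(head(ch, 8), collapse = ","),
              length(unique(paste(x$atoms$chain, x$atoms$resno)))))
  if (length(x$regions))
    cat("  regions:", paste(sprintf("%s[%d-%d]", names(x$regions),
        vapply(x$regions, `[`, 0, 1), vapply(x$regions, `[`, 0, 2)),
        collapse = " "), "\n")
  invisible(x)
}

#' Default PhuN region annotations
#'
#' Named residue ranges of the flexible elements that mediate lattice
#' contacts: N-terminal tail (1-37), lateral beta-hairpin (111-126), large
#' loop (272-291), structured loop (245-258) and C-terminal tail (556-602).
#'
#' @return Named list of `c(start, end)` integer ranges.
#' @export
region_annotations <- function() {
  list(N_tail          = c(1L, 37L),
       beta_hairpin    = c(111L, 126L),
       loop            = c(272L, 291L),
       structured_loop = c(245L, 258L),
       C_tail          = c(556L, 602L))
}

#' Read an atomic model from PDB or mmCIF
#'
#' Parsing is delegated to bio3d; the result is normalized into the package's
#' [atomic_model] container. Chain iteration order is file order; insertion
#' codes are preserved and HETATM records flagged.
#'
#' @param path path to a `.pdb` or `.cif` file.
#' @param regions named list of region annotations to attach
#'   (default [region_annotations()]).
#' @return An [atomic_model].
#' @export
read_model <- function(path, regions = region_annotations()) {
  is_cif <- grepl("\\.cif$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) bio3d::read.cif(path) else bio3d::read.pdb(path),
    error = function(e) stop(sprintf("cannot parse model file '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  a <- pdb$atom
  atoms <- data.frame(
    chain   = as.character(a$chain),
    resno   = as.integer(a$resno),
    insert  = ifelse(is.na(a$insert), "", as.character(a$insert)),
    resname = as.character(a$resid),
    elety   = as.character(a$elety),
    element = if (!is.null(a$elesy)) toupper(as.character(a$elesy))
              else toupper(substr(gsub("[0-9]", "", a$elety), 1, 1)),
    x = a$x, y = a$y, z = a$z,
    b = ifelse(is.na(a$b), 0, a$b),
    occ = ifelse(is.na(a$o), 1, a$o),
    het = a$type == "HETATM",
    stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- " "
  # group atoms by chain in file-appearance order (stable)
  atoms <- atoms[order(match(atoms$chain, unique(atoms$chain))), , drop = FALSE]
  rownames(atoms) <- NULL
  atomic_model(atoms, regions)
}

# Coordinates of a selection as an n x 3 matrix.
model_coords <- function(model, chain = NULL, resno = NULL, elety = NULL,
                         heavy_only = FALSE) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  if (heavy_only) keep <- keep & a$element != "H"
  as.matrix(a[keep, c("x", "y", "z")])
}
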