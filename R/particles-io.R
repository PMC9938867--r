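#' Particle table
#'
#' Table of picked lattice particles: position in Angstrom from the
#' micrograph's lower-left origin, a 2D class label, a plane-group symmetry
#' label from the closed vocabulary `p1/p2/p4/unassigned`, and the micrograph
#' identifier.
#'
#' @param x,y numeric Angstrom coordinates.
#' @param class_label integer or character 2D class labels.
#' @param symmetry_label character, one of `"p1"`, `"p2"`, `"p4"`,
#'   `"unassigned"`.
#' @param micrograph_id character micrograph identifiers.
#' @param bounds optional `c(width, height)` in Angstrom; coordinates are
#'   checked against it when given.
#' @param extra optional data.frame of additional columns (e.g. ground-truth
#'   patch ids) carried along.
#' @return A data.frame of class `particle_table`.
#' @export
particle_table <- function(x, y, class_label = 1L,
                           symmetry_label = "unassigned",
                           micrograph_id = "mg1",
                           bounds = NULL, extra = NULL) {
  n <- length(x)
  df <- data.frame(x = as.numeric(x), y = as.numeric(y),
                   class_label = rep_len(as.character(class_label), n),
                   symmetry_label = rep_len(as.character(symmetry_label), n),
                   micrograph_id = rep_len(as.character(micrograph_id), n),
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$symmetry_label), c("p1", "p2", "p4", "unassigned"))
  if (length(bad))
    stop("symmetry labels outside closed vocabulary: ", paste(bad, collapse = ", "))
  if (!is.null(bounds)) {
    if (any(df$x < 0 | df$x > bounds[1] | df$y < 0 | df$y > bounds[2]))
      stop("particle coordinates outside micrograph bounds")
  }
  if (!is.null(extra)) df <- cbind(df, extra)
  class(df) <- c("particle_table", "data.frame")
  df
}

.pt_columns <- c(x = "_pt_x_angstrom", y = "_pt_y_angstrom",
                 class_label = "_pt_class", symmetry_label = "_pt_symmetry",
                 micrograph_id = "_pt_micrograph")

#' Write a particle table as a STAR-like text file
#'
#' Whitespace-delimited table with a named column header block
#' (`loop_` followed by one `_pt_*` tag per column). Coordinates are written
#' with 1e-4 Angstrom precision.
#'
#' @param particles a [particle_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_particles <- function(particles, path) {
  stopifnot(inherits(particles, "data.frame"))
  cols <- names(.pt_columns)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("data_particles", "", "loop_",
               sprintf("%s #%d", .pt_columns, seq_along(.pt_columns))), con)
  if (nrow(particles)) {
    rows <- sprintf("%.4f %.4f %s %s %s",
                    particles$x, particles$y, particles$class_label,
                    particles$symmetry_label, particles$micrograph_id)
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a STAR-like particle table
#'
#' @param path path to a file written by [write_particles()] (or any
#'   whitespace-delimited table with the same `_pt_*` header tags).
#' @return A [particle_table].
#' @export
read_particles <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  loop_at <- which(lines == "loop_")
  if (!length(loop_at)) stop("schema error: no loop_ block found")
  i <- loop_at[1] + 1
  tags <- character()
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    tags <- c(tags, sub("\\s+#\\d+$", "", lines[i]))
    i <- i + 1
  }
  miss <- setdiff(unname(.pt_columns), tags)
  if (length(miss))
    stop("schema error: missing required column ", paste(miss, collapse = ", "))
  body <- if (i > length(lines)) character() else lines[i:length(lines)]
  body <- body[nzchar(body)]
  if (!length(body))
    return(particle_table(numeric(), numeric(), character(),
                          character(), character()))
  fields <- strsplit(body, "\\s+")
  nf <- lengths(fields)
  if (any(nf != length(tags)))
    stop(sprintf("malformed row %d: expected %d fields, got %d",
                 which(nf != length(tags))[1], length(tags),
                 nf[nf != length(tags)][1]))
  m <- do.call(rbind, fields)
  colnames(m) <- tags
  particle_table(as.numeric(m[, .pt_columns[["x"]]]),
                 as.numeric(m[, .pt_columns[["y"]]]),
                 m[, .pt_columns[["class_label"]]],
                 m[, .pt_columns[["symmetry_label"]]],
                 m[, .pt_columns[["micrograph_id"]]])
}
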