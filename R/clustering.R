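# Mapping symmetry labels back to micrographs: density-based spatial
# clustering of particles and label-homogeneity (purity) summaries.

# Plain DBSCAN with on-demand neighbour queries (no stored distance matrix).
.dbscan <- function(xy, eps, min_pts) {
  n <- nrow(xy)
  labels <- rep(NA_integer_, n)   # NA = unvisited, 0 = noise
  eps2 <- eps^2
  neighbours <- function(i) {
    d2 <- (xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2
    which(d2 <= eps2)
  }
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i])) next
    nb <- neighbours(i)
    if (length(nb) < min_pts) { labels[i] <- 0L; next }
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb, i)
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (!is.na(labels[j]) && labels[j] != 0L) next
      expand <- is.na(labels[j])
      labels[j] <- cl
      if (expand) {
        nbj <- neighbours(j)
        if (length(nbj) >= min_pts)
          queue <- c(queue, nbj[is.na(labels[nbj])])
      }
    }
  }
  labels
}

#' Cluster labelled particles on a micrograph
#'
#' Performs density-based spatial clustering (DBSCAN) of picked particles,
#' reproducing the mapping of plane-group symmetry labels back onto
#' micrographs: symmetry domains appear as distinct spatial clusters. Two
#' clusterings are computed: per symmetry label (the reported cluster map)
#' and label-agnostic (used to measure how label-homogeneous the spatial
#' clusters are). The purity statistic is the particle-weighted mean, over
#' label-agnostic clusters, of the majority symmetry-label fraction; when a
#' ground-truth `patch_id` column is present a patch purity is reported the
#' same way.
#'
#' @param particles a [particle_table] with symmetry labels (>= 3 particles).
#' @param eps neighbour radius in Angstrom; default `1.5 * a_len`.
#' @param min_pts DBSCAN core-point threshold (default 4).
#' @param a_len unit-cell length in Angstrom used for the default `eps`.
#' @return An object of class `symmetry_cluster_map`: the particle table with
#'   `cluster` (per-label clustering; 0 = noise) and `spatial_cluster`
#'   columns, plus cluster centroids, sizes, and purity statistics.
#' @export
assign_and_cluster <- function(particles, eps = NULL, min_pts = 4,
                               a_len = NULL) {
  if (nrow(particles) < 3)
    stop("degenerate input: need at least 3 particles to cluster")
  if (is.null(eps)) {
    if (is.null(a_len)) stop("give either `eps` or `a_len`")
    eps <- 1.5 * a_len
  }
  xy <- as.matrix(particles[, c("x", "y")])
  labs <- particles$symmetry_label
  cluster <- rep(0L, nrow(particles))
  offset <- 0L
  for (L in unique(labs)) {
    sel <- which(labs == L)
    cl <- .dbscan(xy[sel, , drop = FALSE], eps, min_pts)
    cl[cl > 0] <- cl[cl > 0] + offset
    offset <- offset + max(0L, cl)
    cluster[sel] <- cl
  }
  spatial <- .dbscan(xy, eps, min_pts)
  purity_of <- function(assign, truth) {
    keep <- assign > 0
    if (!any(keep)) return(NA_real_)
    tab <- table(assign[keep], truth[keep])
    sum(apply(tab, 1, max)) / sum(tab)
  }
  out <- particles
  out$cluster <- cluster
  out$spatial_cluster <- spatial
  ids <- sort(unique(cluster[cluster > 0]))
  centroids <- do.call(rbind, lapply(ids, function(k) {
    sel <- cluster == k
    data.frame(cluster = k, x = mean(xy[sel, 1]), y = mean(xy[sel, 2]),
               n = sum(sel), symmetry = labs[which(sel)[1]])
  }))
  structure(list(particles = out,
                 centroids = centroids,
                 n_clusters = length(ids),
                 label_purity = purity_of(spatial, labs),
                 patch_purity = if ("patch_id" %in% names(particles))
                   purity_of(spatial, particles$patch_id) else NA_real_),
            class = "symmetry_cluster_map")
}

#' @export
print.symmetry_cluster_map <- function(x, ...) {
  cat(sprintf("<symmetry_cluster_map> %d particles, %d clusters",
              nrow(x$particles), x$n_clusters))
  cat(sprintf("  label purity %.3f", x$label_purity))
  if (!is.na(x$patch_purity)) cat(sprintf(", patch purity %.3f", x$patch_purity))
  cat("\n")
  if (!is.null(x$centroids)) {
    cat("  clusters:\n")
    print(x$centroids, row.names = FALSE)
  }
  invisible(x)
}
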