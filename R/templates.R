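# Projection template generation for picking particles on tilted
# micrographs.

#' Generate projection templates for a tilted dataset
#'
#' Projects a reference volume over a grid of orientations bracketing the
#' stage tilt used at data collection: tilt offsets within `+-tilt_sweep`
#' degrees of the collection tilt in `tilt_step` steps (inclusive start), and
#' in-plane z rotations over `z_range` in `z_step` steps (inclusive ends).
#' The defaults (+-5 deg in 3 deg steps, i.e. offsets -5, -2, +1, +4;
#' z 0-180 deg in 3 deg steps, 61 rotations) give 244 templates per tilted
#' dataset.
#'
#' @param vol cubic reference [density_volume].
#' @param collection_tilt stage tilt of the dataset in degrees.
#' @param tilt_sweep half-width of the tilt bracket in degrees.
#' @param tilt_step tilt step in degrees (> 0).
#' @param z_range length-2 range of z rotations in degrees.
#' @param z_step z rotation step in degrees (> 0).
#' @param compute if `FALSE`, only the angle table and count are returned
#'   (no projections rendered).
#' @return An object of class `template_stack`: list with `angles` (data.frame
#'   of tilt and z rotation per template), `count`, and `templates` (list of
#'   [micrograph_image], or `NULL` if `compute = FALSE`).
#' @export
generate_projection_templates <- function(vol, collection_tilt,
                                          tilt_sweep = 5, tilt_step = 3,
                                          z_range = c(0, 180), z_step = 3,
                                          compute = TRUE) {
  if (tilt_step <= 0 || z_step <= 0) stop("angle steps must be positive")
  offsets <- seq(-tilt_sweep, tilt_sweep, by = tilt_step)
  zrots <- seq(z_range[1], z_range[2], by = z_step)
  if (!length(offsets) || !length(zrots)) stop("empty angle set")
  angles <- expand.grid(tilt = collection_tilt + offsets, z_rot = zrots)
  templates <- NULL
  if (compute) {
    templates <- vector("list", nrow(angles))
    for (i in seq_len(nrow(angles)))
      templates[[i]] <- project_volume(vol, tilt = angles$tilt[i],
                                       in_plane_rotation = angles$z_rot[i])
  }
  structure(list(angles = angles, count = nrow(angles), templates = templates),
            class = "template_stack")
}

#' @export
print.template_stack <- function(x, ...) {
  cat(sprintf("<template_stack> %d templates (%d tilts x %d z-rotations)%s\n",
              x$count, length(unique(x$angles$tilt)),
              length(unique(x$angles$z_rot)),
              if (is.null(x$templates)) " [angles only]" else ""))
  invisible(x)
}

#' Write a template stack as a single MRC stack
#'
#' @param stack a `template_stack` with rendered templates.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_template_stack <- function(stack, path) {
  if (is.null(stack$templates)) stop("stack has no rendered templates")
  n <- dim(stack$templates[[1]]$pixels)
  arr <- array(0, c(n[1], n[2], length(stack$templates)))
  for (i in seq_along(stack$templates)) arr[, , i] <- stack$templates[[i]]$pixels
  .mrc_write(arr, stack$templates[[1]]$pixel_size, c(0, 0, 0), path)
}
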