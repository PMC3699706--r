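#' Set of 2-D parallel-beam projections
#'
#' @param projections numeric 3-D array `nu x nv x n_views` of line-integral
#'   (or count) images; `nu` spans the detector transverse coordinate, `nv`
#'   the axial (slice) coordinate.
#' @param angles_deg view angles in degrees (one per view). The view at angle
#'   `theta` measures line integrals along the in-plane direction
#'   `(-sin theta, cos theta)`; the detector coordinate of a point `(x, y)`
#'   (mm, relative to the grid centre) is `x cos theta + y sin theta`.
#' @param pixel_size detector pixel size, mm (length 1 or 2).
#' @param frame_index cardiac frame the projections belong to, or `NA`.
#' @return An object of class `projection_set`.
#' @export
projection_set <- function(projections, angles_deg, pixel_size,
                           frame_index = NA_integer_) {
  stopifnot(is.array(projections), length(dim(projections)) == 3)
  if (dim(projections)[3] != length(angles_deg))
    stop("number of views must match length(angles_deg)", call. = FALSE)
  if (any(projections < 0))
    stop("projection counts must be non-negative", call. = FALSE)
  structure(list(projections = projections,
                 angles_deg = as.numeric(angles_deg),
                 pixel_size = rep_len(as.numeric(pixel_size), 2L),
                 frame_index = as.integer(frame_index)),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$projections)
  cat(sprintf(
    "<projection_set> %d views of %d x %d, angles %.1f..%.1f deg, total %.4g\n",
    d[3], d[1], d[2], min(x$angles_deg), max(x$angles_deg),
    sum(x$projections)))
  invisible(x)
}

#' Default 180-degree SPECT orbit
#'
#' 32 views over a 180-degree arc starting at the 45-degree right anterior
#' oblique position.
#'
#' @param n_views number of views.
#' @param arc_deg arc length in degrees.
#' @param start_deg first view angle in degrees.
#' @return Numeric vector of view angles, degrees.
#' @export
default_angles <- function(n_views = 32L, arc_deg = 180, start_deg = -45) {
  start_deg + (seq_len(n_views) - 1) * arc_deg / n_views
}

# single-view parallel projection: rotate so the view direction aligns with
# +y, then sum along y. cpp_rotate_z(gather) with angle theta samples
# in(centre + R(theta) p), so content at offset q lands at R(-theta) q and
# the detector coordinate is x cos(theta) + y sin(theta).
project_one <- function(grid, theta_rad) {
  rot <- cpp_rotate_z(grid, theta_rad, FALSE)
  colSums(aperm(rot, c(2, 1, 3)))
}

backproject_one <- function(proj2d, theta_rad, dim3) {
  # broadcast proj2d (nu x nv) along y into nu x ny x nv, then apply the
  # exact adjoint of the gather rotation used in project_one
  smear <- aperm(array(proj2d, dim = c(dim3[1], dim3[3], dim3[2])),
                 c(1, 3, 2))
  cpp_rotate_z(smear, theta_rad, TRUE)
}

#' Forward-project an activity volume
#'
#' Depth-independent parallel-beam line integrals at each view angle,
#' optionally followed by a Gaussian detector-response blur of the projection
#' images. Counts are conserved per view (each view sums the whole volume).
#'
#' @param activity an [activity_volume()].
#' @param angles_deg view angles in degrees (see [default_angles()]).
#' @param resolution_fwhm detector blur FWHM in mm (0 = none).
#' @return A [projection_set()].
#' @export
forward_project <- function(activity, angles_deg = default_angles(),
                            resolution_fwhm = 0) {
  stopifnot(inherits(activity, "activity_volume"))
  if (length(angles_deg) == 0) stop("angles_deg must be non-empty",
                                    call. = FALSE)
  d <- dim(activity$grid)
  proj <- array(0, c(d[1], d[3], length(angles_deg)))
  for (v in seq_along(angles_deg))
    proj[, , v] <- project_one(activity$grid, angles_deg[v] * pi / 180)
  if (resolution_fwhm > 0) {
    sig <- fwhm_to_sigma(resolution_fwhm) /
      c(activity$voxel_size[1], activity$voxel_size[3], Inf)
    proj <- cpp_gauss_sep(proj, c(sig[1], sig[2], 0))
  }
  proj[proj < 0] <- 0
  projection_set(proj, angles_deg,
                 pixel_size = activity$voxel_size[c(1, 3)],
                 frame_index = activity$frame_index)
}

#' Add Poisson counting noise to projections
#'
#' Scales the projection set so its expected total equals
#' `target_total_counts`, then draws independent Poisson counts per pixel.
#' Reproducible for a fixed seed; the caller's RNG state is untouched.
#'
#' @param projections a [projection_set()].
#' @param target_total_counts expected total counts over all views (> 0).
#' @param seed integer RNG seed.
#' @return A [projection_set()] of integer-valued counts; attribute
#'   `scale` holds the applied scale factor.
#' @export
add_poisson_noise <- function(projections, target_total_counts, seed) {
  stopifnot(inherits(projections, "projection_set"))
  if (target_total_counts <= 0)
    stop("target_total_counts must be > 0", call. = FALSE)
  tot <- sum(projections$projections)
  if (tot <= 0) stop("cannot scale an all-zero projection set", call. = FALSE)
  sc <- target_total_counts / tot
  lam <- projections$projections * sc
  noisy <- with_seed(as.integer(seed),
                     array(rpois(length(lam), lam), dim = dim(lam)))
  out <- projection_set(noisy, projections$angles_deg,
                        projections$pixel_size, projections$frame_index)
  attr(out, "scale") <- sc
  out
}
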