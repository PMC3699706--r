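#' OSEM reconstruction settings
#'
#' @param iterations full OSEM iterations (>= 1). Default 4.
#' @param subsets number of ordered subsets; must divide the number of views.
#'   Default 8.
#' @param postfilter_fwhm FWHM of the isotropic Gaussian post-filter, mm.
#'   Default 10.
#' @param collimator_fwhm optional depth-independent Gaussian resolution model
#'   (mm FWHM) included in the projector/backprojector pair; `NULL` disables
#'   resolution modelling (the clinical default emulated here).
#' @return An object of class `recon_settings`.
#' @export
recon_settings <- function(iterations = 4L, subsets = 8L,
                           postfilter_fwhm = 10, collimator_fwhm = NULL) {
  if (iterations < 1) stop("iterations must be >= 1", call. = FALSE)
  if (subsets < 1) stop("subsets must be >= 1", call. = FALSE)
  structure(list(iterations = as.integer(iterations),
                 subsets = as.integer(subsets),
                 postfilter_fwhm = postfilter_fwhm,
                 collimator_fwhm = collimator_fwhm),
            class = "recon_settings")
}

#' Ordered-subsets expectation-maximization reconstruction
#'
#' Multiplicative EM updates over view subsets interleaved by stride
#' (subset `s` holds views `s, s + subsets, ...`), with a matched
#' projector/backprojector pair (the backprojector is the exact adjoint of the
#' rotation-based parallel-beam projector). The reconstruction grid equals the
#' projection grid in-plane (`nu x nu x nv`).
#'
#' @param projections a [projection_set()].
#' @param settings a [recon_settings()] (the post-filter is *not* applied
#'   here; see [gaussian_postfilter()]).
#' @return An [activity_volume()] of non-negative voxel values.
#' @export
osem_reconstruct <- function(projections, settings = recon_settings()) {
  stopifnot(inherits(projections, "projection_set"),
            inherits(settings, "recon_settings"))
  p <- projections$projections
  d <- dim(p)
  nv <- d[3]
  if (nv %% settings$subsets != 0)
    stop("subsets must divide the number of views", call. = FALSE)
  dim3 <- c(d[1], d[1], d[2])
  vox <- c(projections$pixel_size[1], projections$pixel_size[1],
           projections$pixel_size[2])
  if (sum(p) <= 0) {
    warning("zero-count projection set: returning zero volume",
            call. = FALSE)
    return(activity_volume(array(0, dim3), vox,
                           frame_index = projections$frame_index))
  }
  theta <- projections$angles_deg * pi / 180
  blur_sig <- if (!is.null(settings$collimator_fwhm) &&
                  settings$collimator_fwhm > 0)
    fwhm_to_sigma(settings$collimator_fwhm) /
      c(vox[1], vox[3]) else NULL
  blur2d <- function(img) {
    if (is.null(blur_sig)) return(img)
    a <- array(img, c(dim(img), 1L))
    cpp_gauss_sep(a, c(blur_sig, 0))[, , 1]
  }
  subsets <- lapply(seq_len(settings$subsets), function(s)
    seq(s, nv, by = settings$subsets))
  # subset sensitivity images (adjoint of a unit projection)
  ones <- matrix(1, d[1], d[2])
  sens <- lapply(subsets, function(vs) {
    acc <- array(0, dim3)
    for (v in vs) acc <- acc + backproject_one(blur2d(ones), theta[v], dim3)
    acc
  })
  eps <- 1e-10
  est <- array(sum(p) / (nv * prod(dim3)), dim3)
  for (it in seq_len(settings$iterations)) {
    for (s in seq_along(subsets)) {
      acc <- array(0, dim3)
      for (v in subsets[[s]]) {
        fp <- blur2d(project_one(est, theta[v]))
        ratio <- p[, , v] / pmax(fp, eps)
        ratio[p[, , v] == 0 & fp <= eps] <- 0
        acc <- acc + backproject_one(blur2d(ratio), theta[v], dim3)
      }
      est <- est * acc / pmax(sens[[s]], eps)
    }
  }
  est[est < 0] <- 0
  activity_volume(est, vox, frame_index = projections$frame_index)
}

#' Isotropic Gaussian post-filter
#'
#' Separable Gaussian convolution with `sigma = fwhm / 2.3548` on each axis;
#' counts are conserved up to truncation at the grid boundary (< 0.1 % for
#' centred activity).
#'
#' @param volume an [activity_volume()].
#' @param fwhm full-width at half-maximum, mm (0 = identity).
#' @return Filtered [activity_volume()].
#' @export
gaussian_postfilter <- function(volume, fwhm) {
  stopifnot(inherits(volume, "activity_volume"))
  if (fwhm < 0) stop("fwhm must be >= 0", call. = FALSE)
  if (fwhm == 0) return(volume)
  sig <- fwhm_to_sigma(fwhm) / volume$voxel_size
  volume$grid <- cpp_gauss_sep(volume$grid, sig)
  volume
}

# minimal rotation taking unit vector a onto unit vector b (Rodrigues)
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth < -1 + 1e-12) {          # antiparallel: rotate pi about any normal
    axis <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- axis - sum(axis * a) * a
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + cth)
}

#' Reorient a volume to short-axis slices
#'
#' Trilinear resampling so that the LV long axis (pointing from apex towards
#' the base) aligns with the +z slice normal and the LV centre lands at the
#' grid centre, giving apex-first slice ordering.
#'
#' @param volume an [activity_volume()].
#' @param lv_axis unit vector along the LV long axis, apex to base, in the
#'   input grid's world frame.
#' @param lv_centre LV centre, mm.
#' @return A resampled [activity_volume()] on the same grid dimensions.
#' @export
reorient_short_axis <- function(volume, lv_axis, lv_centre) {
  stopifnot(inherits(volume, "activity_volume"))
  n <- sqrt(sum(lv_axis^2))
  if (n == 0) stop("lv_axis must be non-zero", call. = FALSE)
  lv_axis <- lv_axis / n
  # output voxel p maps to input voxel centre_in + R^T (p - centre_out),
  # where R rotates lv_axis onto e_z; isotropy of in-plane vs axial voxel
  # size is required for a pure rotation to be geometry-preserving
  if (max(abs(diff(volume$voxel_size))) > 1e-9)
    stop("reorientation requires isotropic voxels", call. = FALSE)
  R <- rotation_between(lv_axis, c(0, 0, 1))
  d <- dim(volume$grid)
  centre_out <- (d - 1) / 2
  centre_in <- lv_centre / volume$voxel_size
  grid <- cpp_resample_affine(volume$grid, t(R), centre_out, centre_in,
                              as.integer(d))
  grid[grid < 0] <- 0
  out <- activity_volume(grid, volume$voxel_size,
                         frame_index = volume$frame_index)
  attr(out, "rotation") <- R
  out
}
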