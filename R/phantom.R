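#' Virtual-patient phantom specification
#'
#' Parameterizes one virtual patient: a beating, breathing left ventricle
#' modelled as a half prolate spheroid shell (cavity plus a myocardial wall of
#' constant thickness, closed at the base by a flat valve plane), voxelized on
#' a SPECT-sized grid. The defaults reproduce the simulation conditions used
#' for the eight-virtual-patient recovery experiment: 8 cardiac frames at
#' 60 beats/min, 5 merged breathing positions, a 128 x 128 matrix with 4.8 mm
#' pixels, and uniform background activity at one tenth of the myocardial
#' concentration.
#'
#' @param true_edv true end-diastolic cavity volume, mL.
#' @param true_ef true ejection fraction, in (0, 1).
#' @param wall_thickness myocardial wall thickness, mm (held constant over the
#'   cycle).
#' @param axis_ratio centre-to-pole distance divided by equatorial radius of
#'   the endocardial half-spheroid.
#' @param n_frames cardiac frames per cycle (8 or 16).
#' @param heart_rate beats per minute (sets the R-R interval).
#' @param breathing_amplitude peak-to-peak cranio-caudal breathing excursion,
#'   mm.
#' @param breathing_positions number of breathing positions merged per frame.
#' @param matrix_size in-plane matrix size (voxels per side).
#' @param n_slices number of axial slices (the grid is
#'   `matrix_size x matrix_size x n_slices`).
#' @param pixel_size isotropic voxel size, mm.
#' @param myocardium_to_background_ratio myocardial over background activity
#'   concentration.
#' @param total_heart_counts expected myocardium-originating counts summed
#'   over all projections and frames (the calibration knob standing in for
#'   administered activity, uptake and acquisition time).
#' @param systole_fraction fraction of the cycle occupied by contraction
#'   (end-systole falls at `systole_fraction * n_frames + 1`-th frame).
#' @param tilt_deg angle between the LV long axis and the grid z-axis,
#'   degrees.
#' @param rng_seed integer seed for Poisson noise downstream.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(true_edv = 80, true_ef = 0.65, wall_thickness = 10,
                         axis_ratio = 1.2, n_frames = 8L, heart_rate = 60,
                         breathing_amplitude = 15, breathing_positions = 5L,
                         matrix_size = 128L, n_slices = 48L, pixel_size = 4.8,
                         myocardium_to_background_ratio = 10,
                         total_heart_counts = 4e6, systole_fraction = 0.375,
                         tilt_deg = 40, rng_seed = 1L) {
  if (true_edv <= 0) stop("true_edv must be > 0", call. = FALSE)
  if (true_ef <= 0 || true_ef >= 1)
    stop("true_ef must lie strictly in (0, 1)", call. = FALSE)
  if (wall_thickness <= 0) stop("wall_thickness must be > 0", call. = FALSE)
  if (!n_frames %in% c(8L, 16L))
    stop("n_frames must be 8 or 16", call. = FALSE)
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  if (breathing_positions < 1)
    stop("breathing_positions must be >= 1", call. = FALSE)
  structure(list(true_edv = true_edv, true_ef = true_ef,
                 wall_thickness = wall_thickness, axis_ratio = axis_ratio,
                 n_frames = as.integer(n_frames), heart_rate = heart_rate,
                 breathing_amplitude = breathing_amplitude,
                 breathing_positions = as.integer(breathing_positions),
                 matrix_size = as.integer(matrix_size),
                 n_slices = as.integer(n_slices), pixel_size = pixel_size,
                 myocardium_to_background_ratio = myocardium_to_background_ratio,
                 total_heart_counts = total_heart_counts,
                 systole_fraction = systole_fraction, tilt_deg = tilt_deg,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' Volume of half a prolate spheroid
#'
#' Closed form `(2/3) * pi * a^2 * c`, converted from mm^3 to mL. With an
#' equatorial radius of 25 mm and a centre-to-pole distance of 30 mm this is
#' 39.27 mL; shortening both semi-axes by 2 mm drops it to 31.0 mL, a 21 %
#' loss — the geometric heart of the small-heart partial-volume problem.
#'
#' @param equatorial_radius equatorial semi-axis `a`, mm.
#' @param centre_to_pole polar semi-axis `c`, mm.
#' @return Volume in mL.
#' @export
half_prolate_spheroid_volume <- function(equatorial_radius, centre_to_pole) {
  if (any(equatorial_radius < 0) || any(centre_to_pole < 0))
    stop("spheroid semi-axes must be non-negative", call. = FALSE)
  (2 / 3) * pi * equatorial_radius^2 * centre_to_pole / 1000
}

#' Solve half-spheroid semi-axes for a prescribed volume
#'
#' Inverts [half_prolate_spheroid_volume()] under a fixed polar-to-equatorial
#' axis ratio, so phantoms of exactly known cavity volume can be built.
#'
#' @param target_volume cavity volume, mL (> 0).
#' @param axis_ratio `centre_to_pole / equatorial_radius` (> 0).
#' @return Named numeric vector `c(equatorial_radius, centre_to_pole)` in mm.
#' @export
solve_spheroid_axes <- function(target_volume, axis_ratio) {
  if (target_volume <= 0 || axis_ratio <= 0)
    stop("target_volume and axis_ratio must be > 0", call. = FALSE)
  a <- (3 * target_volume * 1000 / (2 * pi * axis_ratio))^(1 / 3)
  c(equatorial_radius = a, centre_to_pole = axis_ratio * a)
}

#' Per-frame endocardial volume curve of the beating phantom
#'
#' Raised-cosine contraction over `systole_fraction` of the cycle followed by
#' raised-cosine relaxation. Frame `j` samples the curve at phase
#' `(j-1)/n_frames`, so frame 1 is end-diastole exactly; when
#' `systole_fraction * n_frames` is an integer (the default 3/8 with 8 or 16
#' frames) the end-systolic frame hits the true ESV exactly and the recomputed
#' (max-min)/max equals `true_ef` to machine precision.
#'
#' @param true_edv end-diastolic volume, mL.
#' @param true_ef ejection fraction in (0, 1).
#' @param n_frames number of frames (>= 4).
#' @param systole_fraction fraction of the cycle spent contracting.
#' @return Numeric vector of per-frame endocardial volumes, mL.
#' @export
cardiac_volume_curve <- function(true_edv, true_ef, n_frames,
                                 systole_fraction = 0.375) {
  if (true_ef <= 0 || true_ef >= 1)
    stop("true_ef must lie strictly in (0, 1)", call. = FALSE)
  if (n_frames < 4) stop("need at least 4 frames", call. = FALSE)
  if (systole_fraction <= 0 || systole_fraction >= 1)
    stop("systole_fraction must lie in (0, 1)", call. = FALSE)
  esv <- true_edv * (1 - true_ef)
  sv <- true_edv - esv
  tau <- (seq_len(n_frames) - 1) / n_frames
  ifelse(tau <= systole_fraction,
         true_edv - sv / 2 * (1 - cos(pi * tau / systole_fraction)),
         esv + sv / 2 * (1 - cos(pi * (tau - systole_fraction) /
                                   (1 - systole_fraction))))
}

# Fixed LV placement for a phantom spec: base (valve-plane) centre and unit
# apex direction, chosen so the end-diastolic shell is centred in the grid.
# The valve plane stays fixed in space over the cycle; the apex moves.
phantom_geometry <- function(spec) {
  t <- spec$tilt_deg * pi / 180
  apex_dir <- c(sin(t), 0, -cos(t))
  ed <- solve_spheroid_axes(spec$true_edv, spec$axis_ratio)
  c_epi_ed <- ed[["centre_to_pole"]] + spec$wall_thickness
  gc <- c(spec$matrix_size - 1, spec$matrix_size - 1, spec$n_slices - 1) / 2 *
    spec$pixel_size
  list(base_centre = gc - 0.5 * c_epi_ed * apex_dir, apex_dir = apex_dir)
}

#' Build the activity distribution of one cardiac frame
#'
#' Voxelizes (by subvoxel sampling) the myocardial shell between the
#' endocardial half-spheroid of that frame's cavity volume and the epicardial
#' half-spheroid obtained by adding the wall thickness to both semi-axes, both
#' truncated at the fixed basal valve plane. Myocardial activity is 1;
#' background activity at `1 / myocardium_to_background_ratio` fills a torso
#' cylinder around the heart (soft-tissue/liver crosstalk).
#'
#' @param spec a [phantom_spec()].
#' @param frame_index frame to build, in `1..n_frames`.
#' @param nsub subvoxel samples per axis (>= 2).
#' @return An [activity_volume()]; attribute `true_cavity_ml` carries the
#'   frame's analytic endocardial volume and `geometry` the spheroid axes and
#'   placement.
#' @export
build_frame_activity <- function(spec, frame_index, nsub = 2L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (frame_index < 1 || frame_index > spec$n_frames)
    stop("frame_index out of range", call. = FALSE)
  vols <- cardiac_volume_curve(spec$true_edv, spec$true_ef, spec$n_frames,
                               spec$systole_fraction)
  v_frame <- vols[frame_index]
  endo <- solve_spheroid_axes(v_frame, spec$axis_ratio)
  a_en <- endo[["equatorial_radius"]]
  c_en <- endo[["centre_to_pole"]]
  a_ep <- a_en + spec$wall_thickness
  c_ep <- c_en + spec$wall_thickness
  if (spec$wall_thickness < spec$pixel_size)
    warning("myocardial shell thinner than one voxel", call. = FALSE)
  geo <- phantom_geometry(spec)
  dim3 <- c(spec$matrix_size, spec$matrix_size, spec$n_slices)
  vox <- rep(spec$pixel_size, 3)
  f_epi <- cpp_voxelize_halfspheroid(dim3, vox, geo$base_centre, geo$apex_dir,
                                     a_ep, c_ep, as.integer(nsub))
  f_endo <- cpp_voxelize_halfspheroid(dim3, vox, geo$base_centre,
                                      geo$apex_dir, a_en, c_en,
                                      as.integer(nsub))
  myo <- f_epi - f_endo
  myo[myo < 0] <- 0
  bg_conc <- if (is.finite(spec$myocardium_to_background_ratio) &&
                 spec$myocardium_to_background_ratio > 0)
    1 / spec$myocardium_to_background_ratio else 0
  grid <- myo
  if (bg_conc > 0) {
    torso_r <- min(0.42 * spec$matrix_size * spec$pixel_size, 150)
    cx <- (spec$matrix_size - 1) / 2 * spec$pixel_size
    x <- ((seq_len(spec$matrix_size) - 1) * spec$pixel_size - cx)
    r2 <- outer(x^2, x^2, "+")
    torso <- array(rep(r2 <= torso_r^2, spec$n_slices), dim = dim3)
    grid <- myo + bg_conc * torso * (1 - myo)
  }
  out <- activity_volume(grid, vox, frame_index = frame_index)
  attr(out, "true_cavity_ml") <- v_frame
  attr(out, "heart_activity") <- sum(myo)
  attr(out, "geometry") <- c(geo, list(a_endo = a_en, c_endo = c_en,
                                       a_epi = a_ep, c_epi = c_ep))
  attr(out, "cavity_fraction") <- f_endo
  out
}

# Linear-interpolation shift of a 3-D array along z by dz voxels (zero fill).
shift_z <- function(grid, dz) {
  k0 <- floor(dz)
  f <- dz - k0
  nz <- dim(grid)[3]
  pick <- function(shift) {
    src <- seq_len(nz) - shift
    ok <- src >= 1 & src <= nz
    out <- array(0, dim(grid))
    out[, , ok] <- grid[, , src[ok]]
    out
  }
  if (f == 0) pick(k0) else (1 - f) * pick(k0) + f * pick(k0 + 1)
}

#' Merge breathing positions into each cardiac frame
#'
#' Each output frame is the equal-weight average of the input frame translated
#' along the cranio-caudal (z) axis to `n_positions` positions sampled
#' uniformly in time over one sinusoidal breathing cycle of the given
#' peak-to-peak amplitude. Total activity is conserved up to interpolation
#' loss at the grid boundary (< 0.1 % for a centred heart).
#'
#' @param frames list of [activity_volume()] objects (or a single one).
#' @param amplitude peak-to-peak excursion, mm.
#' @param n_positions number of breathing positions (>= 1).
#' @return List of merged `activity_volume` objects (or a single one, matching
#'   the input shape).
#' @export
apply_breathing <- function(frames, amplitude, n_positions) {
  single <- inherits(frames, "activity_volume")
  if (single) frames <- list(frames)
  if (n_positions < 1) stop("n_positions must be >= 1", call. = FALSE)
  out <- lapply(frames, function(fr) {
    if (amplitude == 0 || n_positions == 1) return(fr)
    dz_mm <- amplitude / 2 * sin(2 * pi * (seq_len(n_positions) - 1) /
                                   n_positions)
    acc <- array(0, dim(fr$grid))
    for (dz in dz_mm) acc <- acc + shift_z(fr$grid, dz / fr$voxel_size[3])
    fr$grid <- acc / n_positions
    fr
  })
  if (single) out[[1]] else out
}

#' Simulate the gated activity series of one virtual patient
#'
#' Builds all cardiac frames of the phantom and merges the breathing
#' positions, returning a [gated_series()] with the R-R interval implied by
#' the heart rate. Deterministic: no noise is involved at this stage.
#'
#' @param spec a [phantom_spec()].
#' @param nsub subvoxel samples per axis for voxelization.
#' @return A [gated_series()]; each frame keeps its `true_cavity_ml`
#'   attribute.
#' @export
simulate_gated_phantom <- function(spec, nsub = 2L) {
  frames <- lapply(seq_len(spec$n_frames), function(j)
    build_frame_activity(spec, j, nsub = nsub))
  frames <- apply_breathing(frames, spec$breathing_amplitude,
                            spec$breathing_positions)
  gated_series(frames, rr_ms = 60000 / spec$heart_rate,
               meta = list(phantom = unclass(spec)))
}
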