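# Shared fixtures, all built in code.

# A mid-surface model lying exactly on the half prolate spheroid with
# equatorial radius a and centre-to-pole distance c_ (base at the equator),
# matching the package's station layout (wall levels over the basal 75 % of
# the extent, cap sectors at 45 deg, pole on the axis).
hemi_model <- function(a, c_, na = 16L, nc = 32L, base = c(0, 0, 0),
                       axis = c(0, 0, 1)) {
  wf <- 0.75
  d_l <- wf * c_ * (na - seq_len(na)) / (na - 1)
  r_l <- a * sqrt(pmax(1 - (d_l / c_)^2, 1e-9))
  d1 <- wf * c_
  f <- function(r) (r / sqrt(2) / a)^2 + ((d1 + r / sqrt(2)) / c_)^2 - 1
  rc <- uniroot(f, c(1e-6, 2 * a + c_))$root
  mid_surface_model(base, axis, c_, matrix(r_l, na, nc),
                    cap_radii = rep(rc, 6), pole_radius = c_ - d1)
}

# Small noise-free phantom frame reconstructed to short axis; cached per
# session because several segmentation tests share it.
local({
  cache <- new.env()
  recon_sa_fixture <<- function() {
    if (!is.null(cache$sa)) return(cache$sa)
    spec <- phantom_spec(true_edv = 40, true_ef = 0.65, matrix_size = 64L,
                         n_slices = 48L, breathing_amplitude = 0)
    fr <- build_frame_activity(spec, 1)
    ps <- forward_project(fr, default_angles(), resolution_fwhm = 8)
    rec <- gaussian_postfilter(osem_reconstruct(ps, recon_settings(4, 8, 10)),
                               10)
    loc <- locate_lv(rec)
    sa <- reorient_short_axis(rec, loc$long_axis,
                              (loc$apex_point + loc$base_point) / 2)
    cache$sa <- list(sa = sa, spec = spec, frame = fr)
    cache$sa
  }
})

# An analytically blurred shell volume (no tomography): myocardial shell of
# a half spheroid, axis-aligned, plus Gaussian blur. Ground truth mid
# surface is the endo half-spheroid grown by half the wall thickness.
blurred_shell_fixture <- function(edv = 40, wall = 10, blur_fwhm = 10,
                                  n = 72L, vox = 2.4) {
  ax <- solve_spheroid_axes(edv, 1.2)
  a_en <- ax[["equatorial_radius"]]; c_en <- ax[["centre_to_pole"]]
  dim3 <- c(n, n, n)
  base <- c((n - 1) / 2 * vox, (n - 1) / 2 * vox, (n - 1) / 2 * vox + 15)
  apex_dir <- c(0, 0, -1)
  f_ep <- smallheart:::cpp_voxelize_halfspheroid(dim3, rep(vox, 3), base,
                                                 apex_dir, a_en + wall,
                                                 c_en + wall, 2L)
  f_en <- smallheart:::cpp_voxelize_halfspheroid(dim3, rep(vox, 3), base,
                                                 apex_dir, a_en, c_en, 2L)
  vol <- activity_volume(pmax(f_ep - f_en, 0), vox)
  vol <- gaussian_postfilter(vol, blur_fwhm)
  list(vol = vol, base = base, axis = c(0, 0, 1), a_mid = a_en + wall / 2,
       c_mid = c_en + wall / 2)
}
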