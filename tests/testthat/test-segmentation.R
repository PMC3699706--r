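test_that("profile_peak finds and refines the count maximum", {
  expect_equal(profile_peak(c(1, 2, 5, 2, 1), 1)$offset, 0)
  p <- profile_peak(c(1, 2, 5, 4, 1), 1)
  expect_true(p$confident)
  # closed-form parabola vertex through (−1,2),(0,5),(1,4)
  expect_equal(p$offset, 0.25)
  expect_gt(p$offset, 0)
  expect_lt(p$offset, 1)
  flat <- profile_peak(rep(3, 7), 1)
  expect_equal(flat$offset, 0)
  expect_false(flat$confident)
  # maximum at the boundary is flagged
  edge <- profile_peak(c(5, 4, 3, 2, 1), 1)
  expect_false(edge$confident)
  # ties broken towards zero offset
  tie <- profile_peak(c(1, 5, 2, 5, 1), 2)
  expect_lte(abs(tie$offset), 2)
  expect_error(profile_peak(c(1, 2), 1), "3 samples")
})

test_that("locate_lv recovers centre and axis of a synthetic shell", {
  bs <- blurred_shell_fixture()
  loc <- locate_lv(bs$vol)
  expect_equal(abs(sum(loc$long_axis * bs$axis)), 1, tolerance = 0.01)
  # centre lies on the long axis within one voxel
  d <- loc$centre - bs$base
  perp <- d - sum(d * bs$axis) * bs$axis
  expect_lt(sqrt(sum(perp^2)), 2.4)
  expect_error(locate_lv(activity_volume(array(0, c(8, 8, 8)), 4.8)),
               "localization")
})

test_that("locate_lv breaks ties towards the grid centre", {
  g <- array(0, c(40, 40, 20))
  blob <- function(cx, cy) {
    for (i in -2:2) for (j in -2:2) for (k in -1:1)
      g[cx + i, cy + j, 10 + k] <<- 1
  }
  blob(19, 19)  # nearer the grid centre (19.5, 19.5)
  blob(33, 33)
  loc1 <- locate_lv(activity_volume(g, 4))
  loc2 <- locate_lv(activity_volume(g, 4))
  expect_identical(loc1$centre, loc2$centre)
  expect_lt(sqrt(sum((loc1$centre[1:2] - c(18, 18) * 4)^2)), 10)
})

test_that("profiles are flat on uniform volumes and peak on the shell", {
  u <- activity_volume(array(7, c(32, 32, 32)), 4)
  m <- hemi_model(25, 30, na = 8L, nc = 12L, base = c(62, 62, 80),
                  axis = c(0, 0, 1))
  prof <- sample_profiles(u, m, half_length = 10, spacing = 2)
  inside <- !prof$out_of_grid
  expect_true(any(inside))
  expect_true(all(apply(prof$samples[inside, , drop = FALSE], 1,
                        function(s) diff(range(s))) < 1e-9))
  # on a blurred shell, profiles centred on the true mid surface peak at 0
  bs <- blurred_shell_fixture()
  loc <- locate_lv(bs$vol)
  axis_ab <- if (sum(loc$long_axis * c(0, 0, 1)) > 0) c(0, 0, 1) else
    c(0, 0, -1)
  mt <- hemi_model(bs$a_mid, bs$c_mid, na = 10L, nc = 16L, base = bs$base,
                   axis = axis_ab)
  pt <- sample_profiles(bs$vol, mt, half_length = 12, spacing = 1)
  pk <- smallheart:::peak_offsets(pt)
  mid_levels <- 3:8  # away from base and cap
  is_mid_wall <- c(rep(seq_len(10), each = 16) %in% mid_levels,
                   rep(FALSE, 7))  # cap sectors + pole excluded
  sel <- is_mid_wall & pk$confident
  expect_lt(median(abs(pk$offset[sel])), 1.5)
})

test_that("fit_mid_surface recovers a blurred shell within half a voxel RMS", {
  bs <- blurred_shell_fixture()
  fit <- fit_mid_surface(bs$vol)
  # compare fitted wall radii with the true mid-surface ellipse at each level
  nodes <- smallheart:::model_nodes(fit)
  wall <- nodes$pos[seq_len(fit$n_axial * fit$n_circ), ]
  dz <- sweep(wall, 2, bs$base)
  zeta <- abs(dz[, 3])
  rho <- sqrt(dz[, 1]^2 + dz[, 2]^2)
  r_true <- bs$a_mid * sqrt(pmax(1 - (zeta / bs$c_mid)^2, 0))
  rms <- sqrt(mean((rho - r_true)^2))
  expect_lt(rms, 0.5 * 2.4)
  # volume against the analytic mid-surface volume
  v_fit <- enclosed_volume(surface_mesh(fit))
  v_true <- half_prolate_spheroid_volume(bs$a_mid, bs$c_mid)
  expect_lt(abs(v_fit - v_true) / v_true, 0.08)
})

test_that("refitting from a converged fit is a fixed point for the volume", {
  bs <- blurred_shell_fixture()
  fit1 <- fit_mid_surface(bs$vol)
  fit2 <- fit_mid_surface(bs$vol, init = fit1, max_iter = 5L)
  v1 <- enclosed_volume(surface_mesh(fit1))
  v2 <- enclosed_volume(surface_mesh(fit2))
  expect_lt(abs(v2 - v1) / v1, 0.01)
})

test_that("fit is deterministic and stable across noise realizations", {
  x <- recon_sa_fixture()
  f1 <- fit_mid_surface(x$sa)
  f2 <- fit_mid_surface(x$sa)
  expect_identical(f1$wall_radii, f2$wall_radii)
  # two independent Poisson realizations give EDVs within 5 %
  fr <- x$frame
  ps <- forward_project(fr, default_angles(), resolution_fwhm = 8)
  edvs <- vapply(c(11L, 99L), function(s) {
    noisy <- add_poisson_noise(ps, 5e5, seed = s)
    rec <- gaussian_postfilter(osem_reconstruct(noisy, recon_settings(4, 8)),
                               10)
    loc <- locate_lv(rec)
    sa <- reorient_short_axis(rec, loc$long_axis,
                              (loc$apex_point + loc$base_point) / 2)
    enclosed_volume(derive_surfaces(fit_mid_surface(sa), 5)$endo)
  }, 1)
  expect_lt(abs(edvs[1] - edvs[2]) / mean(edvs), 0.05)
})

test_that("derive_surfaces places endo and epi symmetrically", {
  m <- hemi_model(25, 30)
  sp <- derive_surfaces(m, 5)
  d_endo <- sqrt(rowSums((sp$mid_mesh$vertices - sp$endo$vertices)^2))
  d_epi <- sqrt(rowSums((sp$epi$vertices - sp$mid_mesh$vertices)^2))
  moved <- rowSums(abs(sp$normals)) > 0
  expect_true(all(abs(d_endo[moved] - 5) < 1e-6 |
                    d_endo[moved] < 5 + 1e-6)) # clamped vertices move less
  expect_equal(d_epi[moved], rep(5, sum(moved)), tolerance = 1e-9)
  # equatorial endocardial radius: 25 - 5 = 20 mm
  basal <- sp$endo$vertices[sp$endo$basal_ring, ]
  r_eq <- sqrt(rowSums(basal[, 1:2]^2))
  expect_equal(mean(r_eq), 20, tolerance = 0.2)
  # half_thickness 0: all three surfaces coincide
  sp0 <- derive_surfaces(m, 0)
  expect_equal(sp0$endo$vertices, sp0$epi$vertices)
  expect_equal(sp0$endo$vertices, sp0$mid_mesh$vertices)
})

test_that("enclosed_volume matches the closed form and its invariances", {
  m <- hemi_model(25, 30, na = 16L, nc = 32L)
  v <- enclosed_volume(surface_mesh(m))
  expect_lt(abs(v - 39.26991) / 39.26991, 0.01)
  # refinement decreases the error
  coarse <- hemi_model(25, 30, na = 5L, nc = 8L)
  vc <- enclosed_volume(surface_mesh(coarse))
  expect_lt(abs(v - 39.26991), abs(vc - 39.26991))
  # translation invariance
  mt <- hemi_model(25, 30, na = 16L, nc = 32L, base = c(40, -13, 7))
  expect_equal(enclosed_volume(surface_mesh(mt)), v, tolerance = 1e-9)
  expect_error(enclosed_volume(list(vertices = diag(3))), "closed")
})

test_that("frames propagate independently from the first-frame fit", {
  x <- recon_sa_fixture()
  frames <- lapply(1:8, function(f) {
    v <- x$sa
    v$frame_index <- f
    v
  })
  series <- gated_series(frames, rr_ms = 1000)
  first <- fit_mid_surface(x$sa)
  fits <- propagate_to_frames(series, first)
  expect_false(any(attr(fits, "failed")))
  vols <- vapply(fits, function(m) enclosed_volume(surface_mesh(m)), 1)
  expect_lt(diff(range(vols)) / mean(vols), 0.02)
})
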