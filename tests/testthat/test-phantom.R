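test_that("half prolate spheroid volume matches the closed form", {
  expect_equal(half_prolate_spheroid_volume(25, 30), 39.26991, tolerance = 1e-6)
  expect_equal(round(half_prolate_spheroid_volume(25, 30)), 39)
  # both semi-axes 2 mm shorter: 31 mL, a 21 % underestimation
  expect_equal(half_prolate_spheroid_volume(23, 28), 31.02218, tolerance = 1e-6)
  expect_equal(round(100 * (1 - half_prolate_spheroid_volume(23, 28) /
                              half_prolate_spheroid_volume(25, 30))), 21)
  expect_equal(half_prolate_spheroid_volume(0, 30), 0)
  expect_error(half_prolate_spheroid_volume(-1, 30), "non-negative")
})

test_that("solve_spheroid_axes inverts the volume formula", {
  ax <- solve_spheroid_axes(39.26991, 1.2)
  expect_equal(unname(ax), c(25, 30), tolerance = 1e-6)
  ax2 <- solve_spheroid_axes(31.02218, 28 / 23)
  expect_equal(unname(ax2), c(23, 28), tolerance = 1e-6)
  for (v in c(5, 14, 40, 80, 120)) {
    for (r in c(0.8, 1, 1.2, 1.5)) {
      ax <- solve_spheroid_axes(v, r)
      expect_equal(unname(half_prolate_spheroid_volume(ax[1], ax[2])), v,
                   tolerance = 1e-6)
      expect_equal(unname(ax[2] / ax[1]), r, tolerance = 1e-9)
    }
  }
  expect_error(solve_spheroid_axes(-1, 1.2), "> 0")
  expect_error(solve_spheroid_axes(40, 0), "> 0")
})

test_that("cardiac volume curve hits the true extrema and EF exactly", {
  vc <- cardiac_volume_curve(40, 0.65, 8, 0.375)
  expect_equal(vc[1], 40)
  expect_equal(min(vc), 14)
  expect_equal(which.min(vc), 4L)
  expect_equal(min(cardiac_volume_curve(80, 0.45, 8, 0.375)), 44)
  # recomputed EF equals true EF to machine precision on a parameter grid
  for (edv in c(30, 60, 80)) {
    for (ef in c(0.2, 0.45, 0.65)) {
      for (nf in c(8L, 16L)) {
        vc <- cardiac_volume_curve(edv, ef, nf)
        expect_equal((max(vc) - min(vc)) / max(vc), ef, tolerance = 1e-12)
        expect_true(all(vc >= edv * (1 - ef) - 1e-12 & vc <= edv + 1e-12))
      }
    }
  }
  # near-zero ejection gives a near-constant curve
  vc0 <- cardiac_volume_curve(50, 1e-9, 8)
  expect_equal(vc0, rep(50, 8), tolerance = 1e-6)
  expect_error(cardiac_volume_curve(40, 1.2, 8), "true_ef")
})

test_that("voxelized cavity matches the analytic volume and converges", {
  spec <- phantom_spec(true_edv = 40, true_ef = 0.65, matrix_size = 64L,
                       n_slices = 48L)
  fr <- build_frame_activity(spec, 1)
  vox_ml <- prod(fr$voxel_size) / 1000
  v_vox <- sum(attr(fr, "cavity_fraction")) * vox_ml
  expect_lt(abs(v_vox - attr(fr, "true_cavity_ml")) /
              attr(fr, "true_cavity_ml"), 0.02)
  # finer grid: error shrinks below 0.2 %
  spec1 <- phantom_spec(true_edv = 40, true_ef = 0.65, matrix_size = 110L,
                        n_slices = 110L, pixel_size = 1)
  fr1 <- build_frame_activity(spec1, 1)
  v1 <- sum(attr(fr1, "cavity_fraction")) * prod(fr1$voxel_size) / 1000
  expect_lt(abs(v1 - 40) / 40, 0.002)
})

test_that("frame activity respects background and is reproducible", {
  spec0 <- phantom_spec(true_edv = 30, true_ef = 0.65, matrix_size = 48L,
                        n_slices = 40L, myocardium_to_background_ratio = Inf)
  fr0 <- build_frame_activity(spec0, 4)
  myo <- attr(fr0, "cavity_fraction")
  expect_true(all(fr0$grid[fr0$grid > 0] <= 1))
  # no background: activity only inside the epicardial hull
  geo <- attr(fr0, "geometry")
  expect_gt(sum(fr0$grid), 0)
  expect_equal(sum(fr0$grid > 0 & myo >= 1), 0) # cavity interior is cold
  fr0b <- build_frame_activity(spec0, 4)
  expect_identical(fr0$grid, fr0b$grid)
  expect_warning(build_frame_activity(
    phantom_spec(true_edv = 30, true_ef = 0.65, wall_thickness = 3,
                 matrix_size = 48L, n_slices = 40L), 1), "thinner")
})

test_that("breathing merge conserves activity and the centroid", {
  # compact activity (no torso cylinder touching the axial boundary)
  spec <- phantom_spec(true_edv = 40, true_ef = 0.65, matrix_size = 48L,
                       n_slices = 40L, myocardium_to_background_ratio = Inf)
  fr <- build_frame_activity(spec, 1)
  expect_identical(apply_breathing(fr, 0, 5)$grid, fr$grid)
  mg <- apply_breathing(fr, 10, 5)
  expect_lt(abs(sum(mg$grid) - sum(fr$grid)) / sum(fr$grid), 0.001)
  zc <- function(g) {
    z <- slice.index(g, 3)
    sum(g * z) / sum(g)
  }
  # positions sampled uniformly over one sinusoid have zero mean shift
  dz_mm <- 10 / 2 * sin(2 * pi * (0:4) / 5)
  expect_equal(mean(dz_mm), 0, tolerance = 1e-12)
  expect_equal(zc(mg$grid), zc(fr$grid), tolerance = 0.02)
})

test_that("phantom spec validates its invariants", {
  expect_error(phantom_spec(true_edv = -1), "true_edv")
  expect_error(phantom_spec(true_ef = 1.2), "true_ef")
  expect_error(phantom_spec(n_frames = 7), "8 or 16")
  expect_error(phantom_spec(breathing_positions = 0), "breathing_positions")
  s <- phantom_spec(n_frames = 16L)
  expect_s3_class(s, "phantom_spec")
  series <- simulate_gated_phantom(
    phantom_spec(true_edv = 30, true_ef = 0.45, matrix_size = 32L,
                 n_slices = 32L, breathing_positions = 2L))
  expect_s3_class(series, "gated_series")
  expect_length(series$frames, 8L)
  expect_equal(series$rr_ms, 1000)
})
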