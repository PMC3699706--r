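# acquisition and reconstruction chain on small grids

compact_phantom <- function() {
  spec <- phantom_spec(true_edv = 40, true_ef = 0.65, matrix_size = 48L,
                       n_slices = 40L, myocardium_to_background_ratio = Inf)
  build_frame_activity(spec, 1)
}

test_that("forward projection conserves counts and projects geometry", {
  fr <- compact_phantom()
  ps <- forward_project(fr, default_angles())
  expect_equal(dim(ps$projections)[3], 32L)
  sums <- apply(ps$projections, 3, sum)
  expect_true(all(abs(sums - sum(fr$grid)) / sum(fr$grid) < 0.005))
  # zero activity projects to zero
  z <- activity_volume(array(0, c(16, 16, 8)), 4.8)
  expect_true(all(forward_project(z, c(0, 45))$projections == 0))
  # single hot voxel lands at the predicted detector coordinate
  g <- array(0, c(33, 33, 9))
  g[25, 12, 5] <- 1
  hot <- activity_volume(g, 1)
  for (th in c(0, 30, 77)) {
    p <- forward_project(hot, th)$projections[, , 1]
    cx <- (33 - 1) / 2
    u_pred <- cx + (25 - 1 - cx) * cos(th * pi / 180) +
      (12 - 1 - cx) * sin(th * pi / 180)
    u_meas <- sum(p * (seq_len(33) - 1)) / sum(p)
    expect_lt(abs(u_meas - u_pred), 0.51)
  }
  expect_error(forward_project(fr, numeric(0)), "non-empty")
})

test_that("Poisson noise is scaled, reproducible and Poisson-distributed", {
  fr <- compact_phantom()
  ps <- forward_project(fr, default_angles(8))
  n1 <- add_poisson_noise(ps, 2e5, seed = 42)
  n2 <- add_poisson_noise(ps, 2e5, seed = 42)
  expect_identical(n1$projections, n2$projections)
  expect_true(all(n1$projections == round(n1$projections)))
  expect_lt(abs(sum(n1$projections) - 2e5), 3 * sqrt(2e5))
  # variance/mean ~ 1 on a uniform projection over 100 replicates
  u <- projection_set(array(100, c(10, 10, 1)), 0, 4.8)
  reps <- vapply(1:100, function(s)
    add_poisson_noise(u, 1e4, seed = s)$projections[1:50], numeric(50))
  expect_lt(abs(var(as.vector(reps)) / mean(reps) - 1), 0.05)
  expect_error(add_poisson_noise(ps, 0, 1), "> 0")
})

test_that("OSEM conserves counts and reduces the projection residual", {
  fr <- compact_phantom()
  ps <- forward_project(fr, default_angles())
  resid <- function(est) {
    fp <- forward_project(est, default_angles())
    sqrt(mean((fp$projections - ps$projections)^2))
  }
  prev <- Inf
  for (it in c(1L, 2L, 4L)) {
    rec <- osem_reconstruct(ps, recon_settings(iterations = it, subsets = 8))
    expect_true(all(rec$grid >= 0))
    r <- resid(rec)
    expect_lt(r, prev)
    prev <- r
  }
  rec4 <- osem_reconstruct(ps, recon_settings(4, 8))
  expect_lt(abs(sum(rec4$grid) - sum(ps$projections) / 32) /
              (sum(ps$projections) / 32), 0.01)
  # all-zero input
  z <- projection_set(array(0, c(16, 16, 8)),
                      default_angles(8), 4.8)
  expect_warning(rz <- osem_reconstruct(z, recon_settings(1, 8)),
                 "zero-count")
  expect_true(all(rz$grid == 0))
  expect_error(osem_reconstruct(ps, recon_settings(4, 7)), "divide")
})

test_that("Gaussian post-filter has the requested FWHM and conserves counts", {
  g <- array(0, c(41, 41, 41))
  g[21, 21, 21] <- 1000
  src <- activity_volume(g, 2)
  expect_identical(gaussian_postfilter(src, 0)$grid, src$grid)
  f <- gaussian_postfilter(src, 10)
  expect_lt(abs(sum(f$grid) - 1000) / 1000, 0.001)
  prof <- f$grid[, 21, 21]
  half <- max(prof) / 2
  xs <- (seq_len(41) - 21) * 2
  # linear interpolation refinement of the half-maximum crossings, on the
  # strictly monotone flanks
  ok_l <- which(prof[1:21] > 1e-9 * max(prof))
  ok_r <- 20 + which(prof[21:41] > 1e-9 * max(prof))
  lo <- approx(prof[ok_l], xs[ok_l], xout = half)$y
  hi <- approx(prof[ok_r], xs[ok_r], xout = half)$y
  expect_lt(abs((hi - lo) - 10), 1) # within half a voxel
})

test_that("short-axis reorientation aligns the long axis", {
  fr <- compact_phantom()
  d <- dim(fr$grid)
  centre <- (d - 1) / 2 * fr$voxel_size
  same <- reorient_short_axis(fr, c(0, 0, 1), centre)
  keep <- fr$grid > 0.5
  expect_lt(sqrt(mean((same$grid[keep] - fr$grid[keep])^2)), 0.02)
  # a tilted phantom becomes circular in reoriented slices
  spec <- phantom_spec(true_edv = 60, true_ef = 0.65, matrix_size = 64L,
                       n_slices = 48L, tilt_deg = 40,
                       myocardium_to_background_ratio = Inf)
  tilted <- build_frame_activity(spec, 1)
  loc <- locate_lv(gaussian_postfilter(tilted, 8))
  sa <- reorient_short_axis(tilted, loc$long_axis,
                            (loc$apex_point + loc$base_point) / 2)
  k <- which.max(apply(sa$grid, 3, sum))
  sl <- sa$grid[, , k]
  m <- sl > 0.5 * max(sl)
  ij <- which(m, arr.ind = TRUE)
  cv <- cov(ij)
  ev <- eigen(cv, symmetric = TRUE)$values
  ecc <- sqrt(1 - ev[2] / ev[1])
  expect_lt(ecc, 0.3)
  # round trip with the exact axis and centre on a smooth volume; the
  # residual is double-trilinear interpolation loss at 4.8 mm voxels
  smooth <- gaussian_postfilter(tilted, 15)
  d2 <- dim(smooth$grid)
  gc_mm <- (d2 - 1) / 2 * smooth$voxel_size
  axis_true <- c(-sin(40 * pi / 180), 0, cos(40 * pi / 180))
  fwd <- reorient_short_axis(smooth, axis_true, gc_mm)
  R <- attr(fwd, "rotation")
  back <- reorient_short_axis(fwd, drop(R %*% c(0, 0, 1)), gc_mm)
  core <- smooth$grid > 0.1 * max(smooth$grid)
  rms <- sqrt(mean((back$grid[core] - smooth$grid[core])^2)) /
    sqrt(mean(smooth$grid[core]^2))
  expect_lt(rms, 0.05)
  expect_error(reorient_short_axis(fr, c(0, 0, 0), centre), "non-zero")
})
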