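#' @title Mid-myocardial surface model
#' @description
#' Parametric closed LV surface: a radii field on `n_axial` axial levels times
#' `n_circ` circumferential angles (radius measured from the long axis), plus
#' an apical cap of `n_cap` sectors and an apical pole (radii measured from
#' the apex centre, the axis point of the first wall level). Level
#' `n_axial` is the basal (valve-plane) ring at the basal end of the axis
#' segment; level 1 is the apex-most wall ring.
#'
#' @param base_centre basal valve-plane centre on the long axis, mm.
#' @param axis unit vector along the long axis pointing from apex to base.
#' @param length apex-to-base extent of the modelled segment, mm.
#' @param wall_radii `n_axial x n_circ` matrix of radii, mm.
#' @param cap_radii radii of the apical cap sectors, mm.
#' @param pole_radius apical pole radius, mm.
#' @return An object of class `mid_surface_model`.
#' @export
mid_surface_model <- function(base_centre, axis, length, wall_radii,
                              cap_radii, pole_radius) {
  axis <- axis / sqrt(sum(axis^2))
  stopifnot(is.matrix(wall_radii), length > 0)
  if (any(!is.finite(wall_radii)) || any(wall_radii <= 0) ||
      any(!is.finite(cap_radii)) || any(cap_radii <= 0) ||
      !is.finite(pole_radius) || pole_radius <= 0)
    stop("all surface radii must be positive and finite", call. = FALSE)
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  structure(list(base_centre = as.numeric(base_centre), axis = axis,
                 length = length, wall_radii = wall_radii,
                 cap_radii = as.numeric(cap_radii),
                 pole_radius = pole_radius,
                 n_axial = nrow(wall_radii), n_circ = ncol(wall_radii),
                 n_cap = length(cap_radii), basal_level = nrow(wall_radii),
                 e1 = e1, e2 = e2),
            class = "mid_surface_model")
}

#' @export
print.mid_surface_model <- function(x, ...) {
  cat(sprintf(
    "<mid_surface_model> %d levels x %d angles + %d cap sectors, length %.1f mm\n",
    x$n_axial, x$n_circ, x$n_cap, x$length))
  invisible(x)
}

# axial distance of wall level l from the base; wall levels span the basal
# 75 % of the modelled extent, the apical cap sectors and pole the rest
wall_fraction <- 0.75
level_dist <- function(model, l) wall_fraction * model$length *
  (model$n_axial - l) / (model$n_axial - 1)

# node positions and outward sampling directions for all free nodes:
# wall (n_axial * n_circ, level-major), then cap sectors, then pole.
model_nodes <- function(model) {
  na <- model$n_axial; nc <- model$n_circ; ncap <- model$n_cap
  th <- 2 * pi * (seq_len(nc) - 1) / nc
  radial <- outer(cos(th), model$e1) + outer(sin(th), model$e2)
  pos <- matrix(0, na * nc + ncap + 1, 3)
  dir <- matrix(0, na * nc + ncap + 1, 3)
  for (l in seq_len(na)) {
    centre_l <- model$base_centre - level_dist(model, l) * model$axis
    idx <- (l - 1) * nc + seq_len(nc)
    pos[idx, ] <- matrix(centre_l, nc, 3, byrow = TRUE) +
      model$wall_radii[l, ] * radial
    dir[idx, ] <- radial
  }
  cap_centre <- model$base_centre - level_dist(model, 1) * model$axis
  ths <- 2 * pi * (seq_len(ncap) - 1) / ncap
  sect <- (outer(cos(ths), model$e1) + outer(sin(ths), model$e2)) *
    sin(pi / 4) - outer(rep(cos(pi / 4), ncap), model$axis)
  ci <- na * nc + seq_len(ncap)
  pos[ci, ] <- matrix(cap_centre, ncap, 3, byrow = TRUE) +
    model$cap_radii * sect
  dir[ci, ] <- sect
  pi_ <- na * nc + ncap + 1
  pos[pi_, ] <- cap_centre - model$pole_radius * model$axis
  dir[pi_, ] <- -model$axis
  list(pos = pos, dir = dir, n_wall = na * nc, n_cap = ncap,
       cap_centre = cap_centre)
}

wquantile <- function(x, w, p) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][vapply(p, function(pp) which(cw >= pp)[1], 1L)]
}

# threshold the myocardial shell: 50 % of the 99th-percentile count computed
# in a 120 mm box around the hottest voxel (so a large low-activity
# background cannot drag the percentile down), then the largest-total-count
# 6-connected component (ties towards the grid centre)
shell_voxels <- function(volume, box_half_mm = 60) {
  cnt <- volume$grid
  d <- dim(cnt)
  hot <- arrayInd(which.max(cnt), d)
  h <- pmax(1, ceiling(box_half_mm / volume$voxel_size))
  sub <- cnt[max(1, hot[1] - h[1]):min(d[1], hot[1] + h[1]),
             max(1, hot[2] - h[2]):min(d[2], hot[2] + h[2]),
             max(1, hot[3] - h[3]):min(d[3], hot[3] + h[3])]
  thr <- 0.5 * quantile(sub, 0.99, names = FALSE)
  mask <- cnt > thr & cnt > 0
  if (!any(mask))
    stop("LV localization failure: no voxels above threshold", call. = FALSE)
  lab <- cpp_label_cc(mask, dim(cnt))
  tot <- tapply(cnt[mask], lab[mask], sum)
  best <- as.integer(names(tot)[tot >= max(tot) * (1 - 1e-9)])
  if (length(best) > 1) {     # tie: component centroid nearest grid centre
    gc <- (dim(cnt) - 1) / 2 * volume$voxel_size
    d2 <- vapply(best, function(b) {
      ijk <- which(lab == b, arr.ind = TRUE)
      sum((colMeans(ijk - 1) * volume$voxel_size - gc)^2)
    }, 1)
    best <- best[which.min(d2)]
  } else best <- best[1]
  sel <- which(lab == best, arr.ind = TRUE)
  list(pts = (sel - 1) %*% diag(volume$voxel_size), w = cnt[lab == best])
}

#' Locate the left ventricle
#'
#' Thresholds the volume at 50 % of its 99th-percentile count, keeps the
#' connected component with the largest total count (ties broken towards the
#' grid centre), and derives the LV centre (count-weighted centroid), the long
#' axis (the principal direction of the shell's count-weighted covariance
#' whose eigenvalue is most distinct from the other two — correct for both
#' elongated and cup-shaped shells), and a starting radius (mean radial
#' distance of shell voxels from the axis).
#'
#' The axis is oriented from apex to base: the basal (open) end of the shell
#' shows a larger mean ring radius than the apical cap.
#'
#' @param volume an [activity_volume()].
#' @return List with `centre` (mm), `long_axis` (unit, apex to base),
#'   `initial_radius` (mm), plus `base_point`, `apex_point` and the shell
#'   voxel cloud used (for fit initialization).
#' @export
locate_lv <- function(volume) {
  stopifnot(inherits(volume, "activity_volume"))
  sh <- shell_voxels(volume)
  w <- sh$w / sum(sh$w)
  centre <- colSums(sh$pts * w)
  d <- sweep(sh$pts, 2, centre)
  cv <- crossprod(d * sqrt(w))
  eg <- eigen(cv, symmetric = TRUE)
  lam <- eg$values
  distinct <- vapply(1:3, function(i) abs(lam[i] - mean(lam[-i])), 1)
  u <- eg$vectors[, which.max(distinct)]
  t <- drop(d %*% u)
  rho <- sqrt(pmax(rowSums(d^2) - t^2, 0))
  qs <- wquantile(t, w, c(0.01, 0.3, 0.7, 0.99))
  mean_rho <- function(sel) sum(rho[sel] * w[sel]) / sum(w[sel])
  if (mean_rho(t >= qs[3]) < mean_rho(t <= qs[2])) {
    u <- -u
    t <- -t
    qs <- rev(-qs)
  }
  list(centre = centre, long_axis = u,
       initial_radius = sum(rho * w),
       base_point = centre + qs[4] * u, apex_point = centre + qs[1] * u,
       t = t, rho = rho, w = w)
}

# initial surface model from the located shell: per-level slab mean radii
init_mid_surface <- function(volume, loc, n_axial = 12L, n_circ = 24L,
                             n_cap = 6L) {
  L <- drop((loc$base_point - loc$apex_point) %*% loc$long_axis)
  t_base <- drop((loc$base_point - loc$centre) %*% loc$long_axis)
  r_lev <- vapply(seq_len(n_axial), function(l) {
    d_l <- wall_fraction * L * (n_axial - l) / (n_axial - 1)
    sel <- abs((t_base - loc$t) - d_l) <= 0.75 * L / n_axial
    if (!any(sel)) NA_real_ else sum(loc$rho[sel] * loc$w[sel]) /
      sum(loc$w[sel])
  }, 1)
  if (anyNA(r_lev)) {
    ok <- which(!is.na(r_lev))
    r_lev <- stats::approx(ok, r_lev[ok], xout = seq_len(n_axial),
                           rule = 2)$y
  }
  r_lev <- pmax(r_lev, 2)
  mid_surface_model(loc$base_point, loc$long_axis, L,
                    wall_radii = matrix(r_lev, n_axial, n_circ),
                    cap_radii = rep(max(0.7 * r_lev[1], 3), n_cap),
                    pole_radius = max((1 - wall_fraction) * L, 3))
}

#' Sample count profiles across the myocardial wall
#'
#' One profile per surface node, centred on the current surface and oriented
#' along the node's outward sampling direction (radial for wall levels,
#' sector direction for the cap, the long axis for the pole), sampled by
#' trilinear interpolation. Samples falling outside the grid read as zero and
#' flag the profile.
#'
#' @param volume an [activity_volume()].
#' @param model a [mid_surface_model()].
#' @param half_length profile half-length, mm.
#' @param spacing sample spacing along the profile, mm.
#' @return List of class `count_profiles`: `samples` (nodes x samples
#'   matrix), `offsets` (mm, signed arc positions), `out_of_grid` (logical
#'   per node), and the node geometry.
#' @export
sample_profiles <- function(volume, model, half_length = 15, spacing = 1) {
  stopifnot(inherits(volume, "activity_volume"),
            inherits(model, "mid_surface_model"))
  if (spacing <= 0 || half_length < spacing)
    stop("need spacing > 0 and half_length >= spacing", call. = FALSE)
  nodes <- model_nodes(model)
  off <- seq(-half_length, half_length, by = spacing)
  n <- nrow(nodes$pos)
  pts <- matrix(0, n * length(off), 3)
  for (i in seq_along(off))
    pts[(i - 1) * n + seq_len(n), ] <- nodes$pos + off[i] * nodes$dir
  pts_vox <- sweep(pts, 2, volume$voxel_size, "/")
  sm <- cpp_trilinear_sample(volume$grid, pts_vox)
  samples <- matrix(sm$values, n, length(off))
  inside <- matrix(sm$inside, n, length(off))
  structure(list(samples = samples, offsets = off,
                 out_of_grid = !apply(inside, 1, all), nodes = nodes,
                 spacing = spacing),
            class = "count_profiles")
}

#' Peak position along a count profile
#'
#' Arc position of the count maximum, refined by three-point parabolic
#' interpolation. Ties are broken towards zero offset; a flat profile (range
#' below 1 % of its maximum) returns zero offset flagged low-confidence, as
#' does a maximum at the profile boundary.
#'
#' @param samples numeric vector of counts at regular arc positions (>= 3).
#' @param spacing arc spacing, mm.
#' @param offsets optional arc positions (defaults to a grid centred at 0).
#' @return List `offset` (mm) and `confident` (logical).
#' @export
profile_peak <- function(samples, spacing = 1, offsets = NULL) {
  n <- length(samples)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  if (is.null(offsets)) offsets <- (seq_len(n) - (n + 1) / 2) * spacing
  mx <- max(samples)
  if (mx <= 0 || (mx - min(samples)) < 0.01 * mx)
    return(list(offset = 0, confident = FALSE))
  k_cand <- which(samples >= mx * (1 - 1e-12))
  k <- k_cand[which.min(abs(offsets[k_cand]))]
  if (k == 1 || k == n)
    return(list(offset = offsets[k], confident = FALSE))
  den <- samples[k - 1] - 2 * samples[k] + samples[k + 1]
  delta <- if (den < 0) 0.5 * (samples[k - 1] - samples[k + 1]) / den else 0
  delta <- max(-0.5, min(0.5, delta))
  list(offset = offsets[k] + delta * spacing, confident = TRUE)
}

# vectorized peaks for a count_profiles object
peak_offsets <- function(prof) {
  res <- apply(prof$samples, 1, function(s)
    profile_peak(s, spacing = prof$spacing, offsets = prof$offsets))
  offset <- vapply(res, `[[`, 1, "offset")
  confident <- vapply(res, `[[`, TRUE, "confident") & !prof$out_of_grid
  list(offset = offset, confident = confident)
}

# one Laplacian smoothing pass of the radii fields; low-confidence nodes are
# replaced by their neighbourhood mean outright
smooth_radii <- function(model, weight, replace = NULL) {
  wr <- model$wall_radii
  na <- model$n_axial; nc <- model$n_circ
  up <- wr[c(1, seq_len(na - 1)), , drop = FALSE]
  dn <- wr[c(seq_len(na - 1) + 1, na), , drop = FALSE]
  lf <- wr[, c(nc, seq_len(nc - 1)), drop = FALSE]
  rt <- wr[, c(seq_len(nc - 1) + 1, 1), drop = FALSE]
  nm <- (up + dn + lf + rt) / 4
  new_wall <- (1 - weight) * wr + weight * nm
  cr <- model$cap_radii
  ncap <- model$n_cap
  cap_nm <- (cr[c(ncap, seq_len(ncap - 1))] + cr[c(seq_len(ncap - 1) + 1, 1)] +
               model$pole_radius + mean(wr[1, ])) / 4
  new_cap <- (1 - weight) * cr + weight * cap_nm
  new_pole <- (1 - weight) * model$pole_radius + weight * mean(cr)
  if (!is.null(replace)) {
    wall_rep <- matrix(replace[seq_len(na * nc)], na, nc, byrow = TRUE)
    new_wall[wall_rep] <- nm[wall_rep]
    cap_rep <- replace[na * nc + seq_len(ncap)]
    new_cap[cap_rep] <- cap_nm[cap_rep]
    if (replace[na * nc + ncap + 1]) new_pole <- mean(cr)
  }
  model$wall_radii <- pmax(new_wall, 2)
  model$cap_radii <- pmax(new_cap, 2)
  model$pole_radius <- max(new_pole, 2)
  model
}

# re-estimate centre/axis from the wall ring centroids (damped update)
refit_frame <- function(model, damp = 0.5) {
  na <- model$n_axial
  cents <- t(vapply(seq_len(na), function(l) {
    th <- 2 * pi * (seq_len(model$n_circ) - 1) / model$n_circ
    radial <- outer(cos(th), model$e1) + outer(sin(th), model$e2)
    model$base_centre - level_dist(model, l) * model$axis +
      colMeans(model$wall_radii[l, ] * radial)
  }, numeric(3)))
  m <- colMeans(cents)
  dv <- sweep(cents, 2, m)
  v <- eigen(crossprod(dv), symmetric = TRUE)$vectors[, 1]
  if (sum(v * model$axis) < 0) v <- -v
  new_axis <- model$axis + damp * (v - model$axis)
  new_axis <- new_axis / sqrt(sum(new_axis^2))
  new_base <- m + drop((model$base_centre - m) %*% v) * v
  mid_surface_model(model$base_centre + damp * (new_base -
                                                  model$base_centre),
                    new_axis, model$length, model$wall_radii,
                    model$cap_radii, model$pole_radius)
}

#' Fit the mid-myocardial surface to a count volume
#'
#' Iterates: sample profiles perpendicular to the current surface, find the
#' maximal-count position on each ([profile_peak()]), move every node a
#' damped step towards its peak, apply Laplacian smoothing of the radii field
#' (low-confidence nodes take their smoothed neighbourhood value), and
#' re-estimate the centre and axis from the wall ring centroids. Converged
#' when the largest node displacement falls below `tol` or after `max_iter`
#' iterations.
#'
#' @param volume an [activity_volume()] (short-axis count volume).
#' @param init initial [mid_surface_model()]; if missing, one is built from
#'   [locate_lv()].
#' @param max_iter maximum iterations.
#' @param tol convergence threshold on the maximum node displacement, mm.
#' @param damp damping factor on the step towards the profile peak.
#' @param smooth_weight Laplacian smoothing weight.
#' @param half_length,spacing profile geometry, mm (see [sample_profiles()]).
#' @return The fitted `mid_surface_model`; attributes `iterations`,
#'   `converged`, `max_step`.
#' @export
fit_mid_surface <- function(volume, init = NULL, max_iter = 30L, tol = 0.1,
                            damp = 0.5, smooth_weight = 0.3,
                            half_length = 15, spacing = 1) {
  stopifnot(inherits(volume, "activity_volume"))
  if (is.null(init)) init <- init_mid_surface(volume, locate_lv(volume))
  model <- init
  extent <- max(dim(volume$grid) * volume$voxel_size)
  max_step <- Inf
  it <- 0L
  while (it < max_iter && max_step >= tol) {
    it <- it + 1L
    prev <- c(model$wall_radii, model$cap_radii, model$pole_radius,
              model$base_centre)
    prof <- sample_profiles(volume, model, half_length, spacing)
    pk <- peak_offsets(prof)
    step <- damp * pk$offset
    step[!pk$confident] <- 0
    na <- model$n_axial; nc <- model$n_circ; ncap <- model$n_cap
    model$wall_radii <- pmax(model$wall_radii +
                               matrix(step[seq_len(na * nc)], na, nc,
                                      byrow = TRUE), 2)
    model$cap_radii <- pmax(model$cap_radii +
                              step[na * nc + seq_len(ncap)], 2)
    model$pole_radius <- max(model$pole_radius + step[na * nc + ncap + 1], 2)
    model <- smooth_radii(model, smooth_weight, replace = !pk$confident)
    # centre/axis re-estimation runs over the early iterations only, so the
    # radii can settle in a fixed frame afterwards
    if (it <= max(5L, max_iter %/% 3)) model <- refit_frame(model)
    # net displacement this iteration: the damped data pull and the
    # smoothing/re-centring largely cancel once the fit reaches its
    # regularized equilibrium
    max_step <- max(abs(c(model$wall_radii, model$cap_radii,
                          model$pole_radius, model$base_centre) - prev))
    if (max(model$wall_radii) > extent)
      stop("surface fit diverged beyond the grid extent", call. = FALSE)
  }
  attr(model, "iterations") <- it
  attr(model, "converged") <- max_step < tol
  attr(model, "max_step") <- max_step
  model
}

# axial extent of the thresholded shell projected on a fixed axis
shell_extent_on_axis <- function(volume, axis) {
  sh <- shell_voxels(volume)
  w <- sh$w / sum(sh$w)
  centre <- colSums(sh$pts * w)
  t <- drop(sweep(sh$pts, 2, centre) %*% axis)
  qs <- wquantile(t, w, c(0.01, 0.99))
  list(base_point = centre + qs[2] * axis, length = qs[2] - qs[1])
}

#' Fit all frames of a gated series
#'
#' Each frame is fitted independently (no inter-frame basal constraint),
#' initialized from the first-frame solution with the axial extent
#' re-estimated from that frame's thresholded shell. A frame whose fit fails
#' is returned as `NULL` and flagged; downstream volume analysis interpolates
#' it from its neighbours.
#'
#' @param series a [gated_series()].
#' @param first_fit converged first-frame [mid_surface_model()].
#' @param ... fitting parameters passed to [fit_mid_surface()].
#' @return List of per-frame models; attribute `failed` flags failed frames.
#' @export
propagate_to_frames <- function(series, first_fit, ...) {
  stopifnot(inherits(series, "gated_series"),
            inherits(first_fit, "mid_surface_model"))
  failed <- logical(length(series$frames))
  fits <- vector("list", length(series$frames))
  for (f in seq_along(series$frames)) {
    fits[[f]] <- tryCatch({
      ext <- shell_extent_on_axis(series$frames[[f]], first_fit$axis)
      init <- mid_surface_model(ext$base_point, first_fit$axis, ext$length,
                                first_fit$wall_radii, first_fit$cap_radii,
                                first_fit$pole_radius)
      fit_mid_surface(series$frames[[f]], init, ...)
    }, error = function(e) {
      failed[f] <<- TRUE
      NULL
    })
  }
  attr(fits, "failed") <- failed
  fits
}
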