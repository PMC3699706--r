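#' Closed triangle mesh of a mid-surface model
#'
#' Tessellates the parametric surface into a closed triangle mesh: an apical
#' pole vertex, interpolated apical-cap rings (the cap-sector radii are
#' interpolated to the circumferential resolution and, together with the pole
#' and the first wall ring, linearly in polar angle onto intermediate rings,
#' so the cap is not a single coarse fan), the wall rings, and a flat basal
#' cap (fan to the basal-ring centroid). Faces are wound so that normals
#' point outward.
#'
#' Ring cross-sections are inscribed `n_circ`-gons; the exact
#' polygon-to-circle area factor `(2 pi / n) / sin(2 pi / n)` is carried as
#' attribute `az_correction` and applied by [enclosed_volume()], so circular
#' cross-sections integrate without the chord deficit.
#'
#' @param model a [mid_surface_model()].
#' @return An object of class `lv_mesh`: `vertices` (n x 3, mm), `faces`
#'   (m x 3 vertex indices), `normals` (outward unit vertex normals computed
#'   from the wall/cap faces only, so basal-ring normals stay in the valve
#'   plane; the basal-centre vertex has a zero normal), `basal_ring` (vertex
#'   indices of the valve-plane ring).
#' @export
surface_mesh <- function(model) {
  stopifnot(inherits(model, "mid_surface_model"))
  na <- model$n_axial; nc <- model$n_circ; ncap <- model$n_cap
  th <- 2 * pi * (seq_len(nc) - 1) / nc
  radial <- outer(cos(th), model$e1) + outer(sin(th), model$e2)
  cap_centre <- model$base_centre - level_dist(model, 1) * model$axis
  # cap radii interpolated periodically from the sector grid to nc azimuths
  ths <- 2 * pi * (seq_len(ncap) - 1) / ncap
  r_cap <- stats::approx(c(ths, 2 * pi), c(model$cap_radii,
                                           model$cap_radii[1]),
                         xout = th, rule = 2)$y
  # apical radii (distance from the cap centre) as a function of polar angle
  # alpha: 0 at the pole, pi/4 at the cap sectors, pi/2 at the first wall
  # ring; quadratic interpolation through the three anchors onto m
  # intermediate rings (exact for a sphere, ~0.4 % cap-volume error for
  # realistic ellipsoidal apices, against ~15 % for a single coarse fan)
  m <- max(4L, as.integer(ceiling(na / 2)))
  alpha <- pi / 2 * seq_len(m - 1) / m
  qcoef <- solve(rbind(c(1, 0, 0), c(1, pi / 4, (pi / 4)^2),
                       c(1, pi / 2, (pi / 2)^2)))
  r_apex <- function(al, j) {
    cf <- qcoef %*% c(model$pole_radius, r_cap[j], model$wall_radii[1, j])
    max(cf[1] + cf[2] * al + cf[3] * al^2, 0.5)
  }
  n_rings <- (m - 1L) + na
  n_vert <- 1L + nc * n_rings + 1L
  v <- matrix(0, n_vert, 3)
  v[1, ] <- cap_centre - model$pole_radius * model$axis
  for (i in seq_len(m - 1)) {
    r_al <- vapply(seq_len(nc), function(j) r_apex(alpha[i], j), 1)
    v[1 + (i - 1) * nc + seq_len(nc), ] <-
      matrix(cap_centre, nc, 3, byrow = TRUE) +
      (r_al * sin(alpha[i])) * radial -
      (r_al * cos(alpha[i])) %o% model$axis
  }
  for (l in seq_len(na)) {
    centre_l <- model$base_centre - level_dist(model, l) * model$axis
    v[1 + (m - 1 + l - 1) * nc + seq_len(nc), ] <-
      matrix(centre_l, nc, 3, byrow = TRUE) + model$wall_radii[l, ] * radial
  }
  basal_ring <- 1 + (n_rings - 1) * nc + seq_len(nc)
  v[n_vert, ] <- colMeans(v[basal_ring, , drop = FALSE])
  nxt <- c(seq_len(nc - 1) + 1, 1)
  ring_idx <- function(r) 1 + (r - 1) * nc + seq_len(nc) # r = 1..n_rings
  r1 <- ring_idx(1)
  faces <- cbind(1L, r1, r1[nxt])
  for (r in seq_len(n_rings - 1)) {
    a <- ring_idx(r); b <- ring_idx(r + 1)
    faces <- rbind(faces, cbind(a, b, b[nxt]), cbind(a, b[nxt], a[nxt]))
  }
  n_wall_faces <- nrow(faces)
  faces <- rbind(faces, cbind(n_vert, basal_ring[nxt], basal_ring))
  mesh <- list(vertices = v, faces = faces, basal_ring = basal_ring)
  if (signed_volume(mesh) < 0) {
    mesh$faces <- mesh$faces[, c(1, 3, 2)]
  }
  # outward vertex normals from wall/cap faces only
  fw <- mesh$faces[seq_len(n_wall_faces), , drop = FALSE]
  e1 <- v[fw[, 2], ] - v[fw[, 1], ]
  e2 <- v[fw[, 3], ] - v[fw[, 1], ]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- matrix(0, n_vert, 3)
  for (cidx in 1:3) {
    acc <- rowsum(fn, fw[, cidx], reorder = FALSE)
    nrm[as.integer(rownames(acc)), ] <- nrm[as.integer(rownames(acc)), ] + acc
  }
  len <- sqrt(rowSums(nrm^2))
  pos <- len > 0
  nrm[pos, ] <- nrm[pos, ] / len[pos]
  mesh$normals <- nrm
  attr(mesh, "az_correction") <- (2 * pi / nc) / sin(2 * pi / nc)
  class(mesh) <- "lv_mesh"
  mesh
}

signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
        a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
        a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Volume enclosed by a closed surface mesh
#'
#' Divergence-theorem (signed tetrahedron) volume of a closed triangle mesh,
#' optionally after clipping at a valve plane: vertices on the basal side of
#' the plane are projected onto it before integration.
#'
#' @param surface an `lv_mesh` (see [surface_mesh()]).
#' @param valve_plane optional list `point`, `normal` (normal towards the
#'   base); vertices beyond it are projected onto the plane.
#' @return Enclosed volume, mL.
#' @export
enclosed_volume <- function(surface, valve_plane = NULL) {
  if (!inherits(surface, "lv_mesh") || is.null(surface$faces))
    stop("enclosed_volume needs a closed lv_mesh", call. = FALSE)
  if (!is.null(valve_plane)) {
    nrm <- valve_plane$normal / sqrt(sum(valve_plane$normal^2))
    d <- drop(sweep(surface$vertices, 2, valve_plane$point) %*% nrm)
    out <- d > 0
    surface$vertices[out, ] <- surface$vertices[out, , drop = FALSE] -
      d[out] %o% nrm
  }
  az <- attr(surface, "az_correction")
  if (is.null(az)) az <- 1
  abs(signed_volume(surface)) * az / 1000
}

#' Symmetric endocardial/epicardial surfaces about the mid surface
#'
#' Offsets every mesh vertex by `half_thickness` along its outward vertex
#' normal, inward for the endocardium and outward for the epicardium, so the
#' two surfaces sit symmetrically about the maximal-count mid-myocardial
#' surface. An endocardial vertex that would collapse across the long axis is
#' clamped at 20 % of its mid radius and flagged. The valve plane is the
#' least-squares (here: exact) plane of the basal ring, normal towards the
#' base.
#'
#' @param mid fitted [mid_surface_model()].
#' @param half_thickness half wall thickness, mm.
#' @return An object of class `surface_pair`: meshes `endo`, `epi`,
#'   `mid_mesh`, the `mid` model, shared `normals`, `valve_plane`,
#'   `half_thickness`, and `n_clamped`.
#' @export
derive_surfaces <- function(mid, half_thickness = 5) {
  stopifnot(inherits(mid, "mid_surface_model"))
  if (half_thickness < 0) stop("half_thickness must be >= 0", call. = FALSE)
  mesh <- surface_mesh(mid)
  v <- mesh$vertices
  nrm <- mesh$normals
  endo_v <- v - half_thickness * nrm
  epi_v <- v + half_thickness * nrm
  # clamp: endocardial vertices may not come closer to the axis line (or to
  # the cap centre, for apical vertices) than 20 % of their mid distance
  cap_centre <- mid$base_centre - level_dist(mid, 1) * mid$axis
  t_mid <- drop(sweep(v, 2, mid$base_centre) %*% mid$axis)
  apical <- t_mid < -level_dist(mid, 1)  # beyond the first wall level
  ref <- function(pts) {
    t <- drop(sweep(pts, 2, mid$base_centre) %*% mid$axis)
    foot <- matrix(mid$base_centre, nrow(pts), 3, byrow = TRUE) +
      t %o% mid$axis
    d_ax <- sqrt(rowSums((pts - foot)^2))
    d_cap <- sqrt(rowSums(sweep(pts, 2, cap_centre)^2))
    ifelse(apical, d_cap, d_ax)
  }
  d_mid <- ref(v)
  d_endo <- ref(endo_v)
  bad <- which(d_endo < 0.2 * d_mid & d_mid > 1)
  if (length(bad)) {
    pull <- half_thickness * (d_mid[bad] - 0.2 * d_mid[bad]) /
      pmax(d_mid[bad] - d_endo[bad], 1e-9)
    endo_v[bad, ] <- v[bad, , drop = FALSE] -
      pmin(pull, half_thickness) * nrm[bad, , drop = FALSE]
  }
  endo <- mesh; endo$vertices <- endo_v
  epi <- mesh; epi$vertices <- epi_v
  valve_plane <- list(point = colMeans(v[mesh$basal_ring, , drop = FALSE]),
                      normal = mid$axis)
  structure(list(endo = endo, epi = epi, mid = mid, mid_mesh = mesh,
                 normals = nrm, valve_plane = valve_plane,
                 half_thickness = half_thickness,
                 n_clamped = length(bad)),
            class = "surface_pair")
}

#' @export
print.surface_pair <- function(x, ...) {
  cat(sprintf(
    "<surface_pair> half thickness %.1f mm, endo %.1f mL, epi %.1f mL\n",
    x$half_thickness, enclosed_volume(x$endo), enclosed_volume(x$epi)))
  invisible(x)
}

#' Write a mesh to Wavefront OBJ
#'
#' @param mesh an `lv_mesh`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.4f %.4f %.4f", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}
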