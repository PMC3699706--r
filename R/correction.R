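#' Edge-shift parameters
#'
#' Parameters of the volume-dependent epicardial edge-shift: `s0` is the
#' shift at a mid-ventricular volume of 0 mL and `v0` the volume at and above
#' which no adjustment is made. Defaults 3.5 mm and 85 mL.
#'
#' @param s0 shift at zero volume, mm (>= 0).
#' @param v0 volume above which no adjustment occurs, mL (> 0).
#' @return An object of class `shift_params`.
#' @export
shift_params <- function(s0 = 3.5, v0 = 85) {
  if (s0 < 0 || v0 <= 0)
    stop("need s0 >= 0 and v0 > 0", call. = FALSE)
  structure(list(s0 = s0, v0 = v0), class = "shift_params")
}

#' Volume-dependent epicardial edge shift
#'
#' The second-degree polynomial `s(v) = s0 * (1 - v/v0)^2` for `v <= v0`, and
#' 0 above — the unique quadratic through `s(0) = s0` and `s(v0) = 0` whose
#' first derivative also vanishes at `v0`, giving a smooth (C1) transition to
#' the uncorrected regime. In small hearts the partial-volume effect and the
#' short distance to the opposite wall pull the apparent surfaces inward;
#' both the endocardial and epicardial surfaces are therefore shifted
#' outward by `s(v_mid)` before volumes are computed.
#'
#' @param v_mid mid-ventricular (mid-myocardial surface) volume, mL (>= 0).
#'   Vectorized.
#' @param params a [shift_params()].
#' @return Shift in mm, non-increasing and convex in `v_mid`.
#' @export
edge_shift <- function(v_mid, params = shift_params()) {
  stopifnot(inherits(params, "shift_params"))
  if (any(v_mid < 0))
    stop("mid-ventricular volume must be >= 0", call. = FALSE)
  ifelse(v_mid >= params$v0, 0, params$s0 * (1 - v_mid / params$v0)^2)
}

#' Mid-ventricular volume
#'
#' Volume enclosed by the (pre-shift) mid-myocardial surface capped at the
#' valve plane — the quantity that drives [edge_shift()]. Evaluated per frame
#' before any shift is applied.
#'
#' @param mid a [mid_surface_model()].
#' @param valve_plane optional plane (`point`, `normal`); by default the
#'   surface's own basal closure is used.
#' @return Volume in mL.
#' @export
mid_ventricular_volume <- function(mid, valve_plane = NULL) {
  stopifnot(inherits(mid, "mid_surface_model"))
  enclosed_volume(surface_mesh(mid), valve_plane)
}

#' Shift both surfaces in the epicardial direction
#'
#' Moves every endocardial and epicardial vertex `shift` mm along its outward
#' normal. The mid surface and valve plane are unchanged; the endocardium
#' remains inside the epicardium (both move by the same amount).
#'
#' @param surfaces a [derive_surfaces()] pair.
#' @param shift outward shift, mm (>= 0).
#' @return The shifted `surface_pair`; attribute `shift_mm` records the
#'   applied shift.
#' @export
apply_shift <- function(surfaces, shift) {
  stopifnot(inherits(surfaces, "surface_pair"))
  if (shift < 0) stop("shift must be >= 0", call. = FALSE)
  if (shift > 0) {
    surfaces$endo$vertices <- surfaces$endo$vertices +
      shift * surfaces$normals
    surfaces$epi$vertices <- surfaces$epi$vertices + shift * surfaces$normals
  }
  attr(surfaces, "shift_mm") <- shift
  surfaces
}
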