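#' 3-D activity/count volume
#'
#' Lightweight container for a voxelized scalar field: a 3-D array with voxel
#' size in mm. The world position of voxel `(i, j, k)` (1-based) is
#' `((i-1)*dx, (j-1)*dy, (k-1)*dz)` mm, i.e. voxel centres sit on a regular
#' grid starting at the origin.
#'
#' @param grid numeric 3-D array, all values finite and `>= 0`.
#' @param voxel_size voxel edge lengths in mm (length 1 or 3).
#' @param frame_index cardiac frame this volume belongs to (1-based), or `NA`.
#' @param origin world position of voxel (1,1,1) in mm (carried as metadata).
#' @return An object of class `activity_volume`.
#' @export
activity_volume <- function(grid, voxel_size, frame_index = NA_integer_,
                            origin = c(0, 0, 0)) {
  stopifnot(is.array(grid), length(dim(grid)) == 3)
  if (any(!is.finite(grid)) || any(grid < 0))
    stop("activity values must be finite and non-negative", call. = FALSE)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("voxel_size must be positive", call. = FALSE)
  structure(list(grid = grid, voxel_size = voxel_size,
                 origin = as.numeric(origin),
                 frame_index = as.integer(frame_index)),
            class = "activity_volume")
}

#' @export
print.activity_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<activity_volume> %d x %d x %d voxels, %.2f x %.2f x %.2f mm",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3]))
  if (!is.na(x$frame_index)) cat(sprintf(", frame %d", x$frame_index))
  cat(sprintf(", total %.4g\n", sum(x$grid)))
  invisible(x)
}

#' @export
dim.activity_volume <- function(x) dim(x$grid)

# voxel volume in mL
voxel_ml <- function(vol) prod(vol$voxel_size) / 1000

#' Gated volume series
#'
#' An ordered list of per-frame [activity_volume()] objects sharing one grid
#' geometry, together with the R-R interval in milliseconds.
#'
#' @param frames list of `activity_volume` objects (8 or 16, ordered by
#'   cardiac phase starting at end-diastole).
#' @param rr_ms R-R interval in milliseconds.
#' @param meta optional named list of acquisition metadata.
#' @param check require 8 or 16 frames (set `FALSE` for intermediate objects).
#' @return An object of class `gated_series`.
#' @export
gated_series <- function(frames, rr_ms, meta = list(), check = TRUE) {
  stopifnot(is.list(frames), length(frames) >= 1)
  if (check && !length(frames) %in% c(8L, 16L))
    stop("a gated series must have 8 or 16 frames, got ", length(frames),
         call. = FALSE)
  d1 <- dim(frames[[1]]$grid)
  v1 <- frames[[1]]$voxel_size
  for (f in frames) {
    if (!identical(dim(f$grid), d1) || any(abs(f$voxel_size - v1) > 1e-9))
      stop("all frames must share the same grid geometry", call. = FALSE)
  }
  if (!is.numeric(rr_ms) || rr_ms <= 0)
    stop("rr_ms must be a positive R-R interval in milliseconds",
         call. = FALSE)
  structure(list(frames = frames, rr_ms = as.numeric(rr_ms), meta = meta),
            class = "gated_series")
}

#' @export
print.gated_series <- function(x, ...) {
  d <- dim(x$frames[[1]]$grid)
  cat(sprintf("<gated_series> %d frames, %d x %d x %d voxels, RR %.0f ms\n",
              length(x$frames), d[1], d[2], d[3], x$rr_ms))
  invisible(x)
}
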