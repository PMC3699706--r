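#' Write a gated volume series
#'
#' NIfTI: one 4-D file (4th axis = cardiac frame) with the R-R interval in a
#' JSON sidecar (`<path without extension>.json`), since NIfTI has no
#' standard slot for it. Interfile 3.3: a text header (`.hv`) and a raw
#' little-endian float32 data file (`.v`), frames concatenated.
#'
#' @param series a [gated_series()].
#' @param path output path; extension `.nii`/`.nii.gz` selects NIfTI, `.hv`
#'   Interfile.
#' @param format `"nifti"`, `"interfile"` or `"auto"` (from the extension).
#' @return `path`, invisibly.
#' @export
write_gated_volume <- function(series, path, format = c("auto", "nifti",
                                                        "interfile")) {
  stopifnot(inherits(series, "gated_series"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.hv$", path)) "interfile" else "nifti"
  d <- dim(series$frames[[1]]$grid)
  vox <- series$frames[[1]]$voxel_size
  arr <- array(0, c(d, length(series$frames)))
  for (f in seq_along(series$frames)) arr[, , , f] <- series$frames[[f]]$grid
  if (format == "nifti") {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(vox, series$rr_ms / length(series$frames))
    RNifti::writeNifti(img, path)
    side <- sub("\\.nii(\\.gz)?$", "", path)
    jsonlite::write_json(list(rr_ms = series$rr_ms,
                              n_frames = length(series$frames)),
                         paste0(side, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    datafile <- sub("\\.hv$", ".v", path)
    hdr <- c(
      "!INTERFILE :=",
      "!imaging modality := nucmed",
      "!version of keys := 3.3",
      paste0("!name of data file := ", basename(datafile)),
      "!number format := short float",
      "!number of bytes per pixel := 4",
      "imagedata byte order := LITTLEENDIAN",
      "number of dimensions := 4",
      paste0("!matrix size [1] := ", d[1]),
      paste0("!matrix size [2] := ", d[2]),
      paste0("!matrix size [3] := ", d[3]),
      paste0("number of time frames := ", length(series$frames)),
      paste0("scaling factor (mm/pixel) [1] := ", vox[1]),
      paste0("scaling factor (mm/pixel) [2] := ", vox[2]),
      paste0("scaling factor (mm/pixel) [3] := ", vox[3]),
      paste0("R-R interval (ms) := ", series$rr_ms),
      "!END OF INTERFILE :=")
    writeLines(hdr, path)
    con <- file(datafile, "wb")
    writeBin(as.numeric(arr), con, size = 4L, endian = "little")
    close(con)
  }
  invisible(path)
}

interfile_keys <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl(":=", lines, fixed = TRUE)]
  kv <- regmatches(lines, regexpr(":=", lines), invert = TRUE)
  keys <- tolower(trimws(sub("^!", "", vapply(kv, `[`, "", 1))))
  vals <- trimws(vapply(kv, function(x) if (length(x) > 1) x[2] else "", ""))
  stats::setNames(vals, keys)
}

#' Read a gated volume series
#'
#' @param path NIfTI (`.nii`/`.nii.gz`) or Interfile header (`.hv`) path.
#' @param format `"auto"`, `"nifti"` or `"interfile"`.
#' @param rr_ms R-R interval override, ms; required if neither the sidecar
#'   (NIfTI) nor the header (Interfile) carries it.
#' @return A [gated_series()]; errors on a malformed header, a frame count
#'   other than 8 or 16, non-uniform in-plane voxel size, or a missing R-R
#'   interval.
#' @export
read_gated_volume <- function(path, format = c("auto", "nifti",
                                               "interfile"), rr_ms = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.hv$", path)) "interfile" else "nifti"
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) != 4)
      stop("expected 4-D gated data, got ", length(dim(arr)), "-D",
           call. = FALSE)
    vox <- RNifti::pixdim(img)[1:3]
    side <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
    if (is.null(rr_ms) && file.exists(side))
      rr_ms <- jsonlite::read_json(side)$rr_ms
  } else {
    kv <- interfile_keys(path)
    need <- c("matrix size [1]", "matrix size [2]", "matrix size [3]",
              "number of time frames", "name of data file")
    if (!all(need %in% names(kv)))
      stop("malformed Interfile header: missing ",
           paste(setdiff(need, names(kv)), collapse = ", "), call. = FALSE)
    d <- as.integer(kv[c("matrix size [1]", "matrix size [2]",
                         "matrix size [3]")])
    nf <- as.integer(kv["number of time frames"])
    vox <- as.numeric(kv[c("scaling factor (mm/pixel) [1]",
                           "scaling factor (mm/pixel) [2]",
                           "scaling factor (mm/pixel) [3]")])
    datafile <- file.path(dirname(path), kv["name of data file"])
    con <- file(datafile, "rb")
    raw <- readBin(con, "numeric", n = prod(d) * nf, size = 4L,
                   endian = "little")
    close(con)
    if (length(raw) != prod(d) * nf)
      stop("Interfile data size does not match the header", call. = FALSE)
    arr <- array(raw, c(d, nf))
    if (is.null(rr_ms) && "r-r interval (ms)" %in% names(kv))
      rr_ms <- as.numeric(kv["r-r interval (ms)"])
  }
  if (!dim(arr)[4] %in% c(8L, 16L))
    stop("gated data must have 8 or 16 frames, found ", dim(arr)[4],
         call. = FALSE)
  if (any(!is.finite(vox)) || any(vox <= 0) ||
      abs(vox[1] - vox[2]) > 1e-6 * vox[1])
    stop("non-uniform or invalid voxel size in header", call. = FALSE)
  if (is.null(rr_ms))
    stop("R-R interval not found; supply rr_ms", call. = FALSE)
  frames <- lapply(seq_len(dim(arr)[4]), function(f)
    activity_volume(pmax(arr[, , , f], 0), vox, frame_index = f))
  gated_series(frames, rr_ms = rr_ms)
}

#' Default end-to-end pipeline configuration
#'
#' All tunable parameters of the simulate / acquire / reconstruct / segment /
#' correct / quantify chain, with their defaults. Serializes losslessly to
#' YAML via [write_pipeline_config()].
#'
#' @param ... named overrides of individual entries, e.g.
#'   `correction = list(s0_mm = 3)` (merged recursively).
#' @return Nested named list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(...) {
  cfg <- list(
    phantom = list(wall_thickness = 10, axis_ratio = 1.2, n_frames = 8L,
                   heart_rate = 60, breathing_amplitude = 15,
                   breathing_positions = 5L, matrix_size = 128L,
                   n_slices = 48L, pixel_size = 4.8,
                   myocardium_to_background_ratio = 10,
                   total_heart_counts = 4e6, systole_fraction = 0.375,
                   tilt_deg = 40),
    acquisition = list(n_views = 32L, arc_deg = 180, start_deg = -45,
                       collimator_fwhm = 15, poisson_noise = TRUE),
    recon = list(iterations = 4L, subsets = 8L, postfilter_fwhm = 10),
    segmentation = list(half_thickness = 5, n_axial = 12L, n_circ = 24L,
                        max_iter = 30L, tol = 0.1),
    correction = list(s0_mm = 3.5, v0_ml = 85, per_frame = TRUE),
    seed = 1L)
  ov <- list(...)
  for (nm in names(ov))
    cfg[[nm]] <- if (is.list(cfg[[nm]])) modifyList(cfg[[nm]], ov[[nm]])
      else ov[[nm]]
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration
#'
#' @param path YAML file path.
#' @return For the reader, a `pipeline_config` (unknown keys are an error);
#'   the writer returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(default_pipeline_config())
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config sections: ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg <- do.call(default_pipeline_config, raw[setdiff(names(raw), "seed")])
  if (!is.null(raw$seed)) cfg$seed <- raw$seed
  cfg
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
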