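#' Per-frame LV volume curve
#'
#' @param volumes endocardial volume per cardiac frame, mL (all > 0).
#' @param rr_ms R-R interval, milliseconds.
#' @param check require 8 or 16 frames.
#' @return An object of class `volume_curve`.
#' @export
volume_curve <- function(volumes, rr_ms, check = TRUE) {
  if (any(!is.finite(volumes)) || any(volumes <= 0))
    stop("all frame volumes must be positive", call. = FALSE)
  if (check && !length(volumes) %in% c(8L, 16L))
    stop("a gated volume curve has 8 or 16 frames", call. = FALSE)
  if (rr_ms <= 0) stop("rr_ms must be > 0", call. = FALSE)
  structure(list(volumes = as.numeric(volumes), rr_ms = as.numeric(rr_ms),
                 n_frames = length(volumes)),
            class = "volume_curve")
}

#' Global volumes and ejection fraction from raw frame volumes
#'
#' EDV and ESV are the maximum and minimum frame volumes (taken before any
#' Fourier smoothing); EF = (EDV - ESV) / EDV.
#'
#' @param curve a [volume_curve()].
#' @return Named vector `c(edv, esv, ef)` (mL, mL, fraction).
#' @export
edv_esv_ef <- function(curve) {
  stopifnot(inherits(curve, "volume_curve"))
  edv <- max(curve$volumes)
  esv <- min(curve$volumes)
  if (edv <= 0) stop("invalid curve: EDV is zero", call. = FALSE)
  c(edv = edv, esv = esv, ef = (edv - esv) / edv)
}

#' Truncated Fourier fit of the volume curve
#'
#' Least-squares trigonometric fit
#' `V(t) = a0 + sum_k a_k cos(2 pi k t / RR) + b_k sin(2 pi k t / RR)` up to
#' `n_harmonics` (default: fundamental to third harmonic), periodic with the
#' R-R interval. Frame `j` is placed at `t = (j-1) RR / n`; for equispaced
#' frames the fit equals the truncated discrete Fourier series, so `a0` is
#' the frame mean and band-limited inputs are reproduced exactly.
#'
#' @param curve a [volume_curve()].
#' @param n_harmonics number of harmonics; needs `n_frames > 2 * n_harmonics`.
#' @return An object of class `fourier_curve` with coefficients `a0`, `a`,
#'   `b` and the R-R interval.
#' @export
fourier_fit <- function(curve, n_harmonics = 3L) {
  stopifnot(inherits(curve, "volume_curve"))
  n <- curve$n_frames
  if (n <= 2 * n_harmonics)
    stop("too few frames for ", n_harmonics, " harmonics", call. = FALSE)
  t <- (seq_len(n) - 1) / n                       # phase in cycles
  X <- cbind(1, do.call(cbind, lapply(seq_len(n_harmonics), function(k)
    cbind(cos(2 * pi * k * t), sin(2 * pi * k * t)))))
  beta <- qr.coef(qr(X), curve$volumes)
  structure(list(a0 = beta[1],
                 a = beta[seq_len(n_harmonics) * 2],
                 b = beta[seq_len(n_harmonics) * 2 + 1],
                 rr_ms = curve$rr_ms, n_harmonics = n_harmonics),
            class = "fourier_curve")
}

#' Build a Fourier volume curve from explicit coefficients
#'
#' Convenience constructor for analytic test curves.
#'
#' @param a0 mean volume, mL.
#' @param a,b cosine and sine coefficients per harmonic, mL.
#' @param rr_ms R-R interval, ms.
#' @return A `fourier_curve`.
#' @export
fourier_curve <- function(a0, a, b, rr_ms) {
  stopifnot(length(a) == length(b))
  structure(list(a0 = a0, a = as.numeric(a), b = as.numeric(b),
                 rr_ms = rr_ms, n_harmonics = length(a)),
            class = "fourier_curve")
}

#' Evaluate a fitted volume curve
#'
#' @param fitted a `fourier_curve`.
#' @param t_ms time in milliseconds (vectorized; periodic in RR).
#' @return Volume in mL.
#' @export
eval_curve <- function(fitted, t_ms) {
  stopifnot(inherits(fitted, "fourier_curve"))
  w <- 2 * pi * t_ms / fitted$rr_ms
  v <- rep(fitted$a0, length(t_ms))
  for (k in seq_along(fitted$a))
    v <- v + fitted$a[k] * cos(k * w) + fitted$b[k] * sin(k * w)
  v
}

#' Analytic dV/dt of a fitted volume curve
#'
#' Term-wise derivative of the trigonometric series, in mL per second (RR
#' converted to seconds).
#'
#' @param fitted a `fourier_curve` (see [fourier_fit()]).
#' @return An object of class `dvdt_curve`; evaluate with [eval_dvdt()].
#' @export
dvdt <- function(fitted) {
  stopifnot(inherits(fitted, "fourier_curve"))
  structure(list(fit = fitted), class = "dvdt_curve")
}

#' Evaluate a dV/dt curve
#'
#' @param deriv a [dvdt()] object.
#' @param t_ms time in milliseconds (vectorized).
#' @return dV/dt in mL/s.
#' @export
eval_dvdt <- function(deriv, t_ms) {
  stopifnot(inherits(deriv, "dvdt_curve"))
  f <- deriv$fit
  w <- 2 * pi * t_ms / f$rr_ms
  rr_s <- f$rr_ms / 1000
  v <- numeric(length(t_ms))
  for (k in seq_along(f$a))
    v <- v + (2 * pi * k / rr_s) * (-f$a[k] * sin(k * w) +
                                      f$b[k] * cos(k * w))
  v
}

# filling-phase boundaries on a 1 ms grid: end-systole is the earliest time
# of the fitted minimum in [0, RR); end of filling is the earliest time of
# the fitted maximum in the following cycle
filling_phase <- function(fitted, grid_ms = 1) {
  t <- seq(0, fitted$rr_ms - grid_ms, by = grid_ms)
  v <- eval_curve(fitted, t)
  t_es <- t[which.min(v)]
  t2 <- seq(t_es + grid_ms, t_es + fitted$rr_ms, by = grid_ms)
  v2 <- eval_curve(fitted, t2)
  t_ed <- t2[which.max(v2)]
  list(t_es = t_es, t_ed = t_ed, grid_ms = grid_ms)
}

#' Peak filling rate
#'
#' Maximum dV/dt over the filling phase (end-systole to the next
#' end-diastole, both from the fitted curve on a 1 ms grid), divided by EDV.
#'
#' @param dvdt_curve a [dvdt()] object.
#' @param edv end-diastolic volume used for normalization, mL (> 0).
#' @param whole_cycle take the maximum over the whole cycle instead of the
#'   filling phase only.
#' @return List `pfr` (1/s), `pfr_ml_s` (mL/s), `t_peak_ms`, `t_es_ms`,
#'   `t_ed_ms`, `flagged` (TRUE when no positive dV/dt exists, in which case
#'   the rate is 0).
#' @export
pfr <- function(dvdt_curve, edv, whole_cycle = FALSE) {
  stopifnot(inherits(dvdt_curve, "dvdt_curve"))
  if (edv <= 0) stop("edv must be > 0", call. = FALSE)
  f <- dvdt_curve$fit
  ph <- filling_phase(f)
  tt <- if (whole_cycle) seq(0, f$rr_ms, by = ph$grid_ms) else
    seq(ph$t_es, ph$t_ed, by = ph$grid_ms)
  dv <- eval_dvdt(dvdt_curve, tt)
  i <- which.max(dv)
  if (dv[i] <= 0)
    return(list(pfr = 0, pfr_ml_s = 0, t_peak_ms = NA_real_,
                t_es_ms = ph$t_es, t_ed_ms = ph$t_ed, flagged = TRUE))
  list(pfr = dv[i] / edv, pfr_ml_s = dv[i], t_peak_ms = tt[i],
       t_es_ms = ph$t_es, t_ed_ms = ph$t_ed, flagged = FALSE)
}

#' One-third mean filling rate
#'
#' Average dV/dt over the first third of the filling time, divided by EDV.
#' Computed exactly via the mean-value identity
#' `(V(t_es + D/3) - V(t_es)) * 3 / D` with `D` the filling time.
#'
#' @inheritParams pfr
#' @return List `one_third_mfr` (1/s), `one_third_mfr_ml_s` (mL/s),
#'   `flagged`.
#' @export
one_third_mfr <- function(dvdt_curve, edv) {
  stopifnot(inherits(dvdt_curve, "dvdt_curve"))
  if (edv <= 0) stop("edv must be > 0", call. = FALSE)
  f <- dvdt_curve$fit
  ph <- filling_phase(f)
  D <- ph$t_ed - ph$t_es
  if (D <= 0)
    return(list(one_third_mfr = 0, one_third_mfr_ml_s = 0, flagged = TRUE))
  dv_ml <- eval_curve(f, ph$t_es + D / 3) - eval_curve(f, ph$t_es)
  rate <- dv_ml / (D / 3 / 1000)                  # mL/s
  list(one_third_mfr = rate / edv, one_third_mfr_ml_s = rate,
       flagged = rate <= 0)
}

#' Time to peak filling rate
#'
#' Time from end-systole to the peak filling rate, in milliseconds, and its
#' ratio to the R-R interval.
#'
#' @param dvdt_curve a [dvdt()] object.
#' @return List `tpfr_ms`, `tpfr_rr`, `flagged`.
#' @export
tpfr <- function(dvdt_curve) {
  stopifnot(inherits(dvdt_curve, "dvdt_curve"))
  p <- pfr(dvdt_curve, edv = 1)
  if (p$flagged)
    return(list(tpfr_ms = NA_real_, tpfr_rr = NA_real_, flagged = TRUE))
  t_ms <- p$t_peak_ms - p$t_es_ms
  list(tpfr_ms = t_ms, tpfr_rr = t_ms / dvdt_curve$fit$rr_ms,
       flagged = FALSE)
}

#' Heart-size class from end-systolic volume
#'
#' `NH` (normal-sized) for ESV > 20 mL, `SH20` for 10 < ESV <= 20 mL and
#' `SH10` for ESV <= 10 mL.
#'
#' @param esv end-systolic volume, mL (>= 0). Vectorized.
#' @return Character vector of classes.
#' @export
classify_heart_size <- function(esv) {
  if (any(esv < 0)) stop("esv must be >= 0", call. = FALSE)
  ifelse(esv > 20, "NH", ifelse(esv > 10, "SH20", "SH10"))
}

#' Full functional report from a volume curve
#'
#' EDV/ESV/EF from the raw frame extrema, then the truncated Fourier fit
#' (fundamental to third harmonic), its analytic dV/dt, and the diastolic
#' indices PFR, 1/3MFR, TPFR and TPFR/RR, plus the heart-size class.
#'
#' @param curve a [volume_curve()].
#' @param n_harmonics harmonics used for the fit.
#' @return An object of class `function_report`.
#' @export
quantify_function <- function(curve, n_harmonics = 3L) {
  stopifnot(inherits(curve, "volume_curve"))
  g <- edv_esv_ef(curve)
  fit <- fourier_fit(curve, n_harmonics)
  dv <- dvdt(fit)
  p <- pfr(dv, g[["edv"]])
  m <- one_third_mfr(dv, g[["edv"]])
  tp <- tpfr(dv)
  structure(list(edv = g[["edv"]], esv = g[["esv"]], ef = g[["ef"]],
                 pfr = p$pfr, one_third_mfr = m$one_third_mfr,
                 tpfr_ms = tp$tpfr_ms, tpfr_rr = tp$tpfr_rr,
                 heart_class = classify_heart_size(g[["esv"]]),
                 fitted_curve = fit, dvdt_curve = dv,
                 volumes = curve$volumes, rr_ms = curve$rr_ms,
                 flagged = p$flagged || m$flagged || tp$flagged),
            class = "function_report")
}

#' @export
print.function_report <- function(x, ...) {
  cat(sprintf(
    paste0("<function_report> EDV %.1f mL, ESV %.1f mL, EF %.1f %%, ",
           "class %s\n  PFR %.2f /s, 1/3MFR %.2f /s, TPFR %.0f ms ",
           "(TPFR/RR %.3f)\n"),
    x$edv, x$esv, 100 * x$ef, x$heart_class, x$pfr, x$one_third_mfr,
    x$tpfr_ms, x$tpfr_rr))
  invisible(x)
}
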