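test_that("EDV, ESV and EF come from the raw frame extrema", {
  vc <- volume_curve(cardiac_volume_curve(40, 0.65, 8), 1000)
  g <- edv_esv_ef(vc)
  expect_equal(unname(g), c(40, 14, 0.65))
  vc2 <- volume_curve(cardiac_volume_curve(80, 0.65, 8), 1000)
  expect_equal(edv_esv_ef(vc2)[["esv"]], 28)
  expect_equal(edv_esv_ef(vc2)[["ef"]], 0.65)
  const <- volume_curve(rep(50, 8), 800)
  expect_equal(edv_esv_ef(const)[["ef"]], 0)
  expect_error(volume_curve(c(rep(50, 7), 0), 800), "positive")
  expect_error(volume_curve(rep(50, 7), 800), "8 or 16")
})

test_that("the Fourier fit is exact on band-limited curves", {
  rr <- 1000
  t <- (0:7) / 8
  v <- 70 + 10 * cos(2 * pi * t) - 20 * sin(2 * pi * t) +
    4 * cos(2 * pi * 2 * t) + 2 * sin(2 * pi * 3 * t)
  fit <- fourier_fit(volume_curve(v, rr), 3)
  expect_equal(eval_curve(fit, t * rr), v, tolerance = 1e-9)
  expect_equal(unname(fit$a0), mean(v))
  # a Nyquist (4th-harmonic) component is annihilated, not aliased
  v4 <- v + 5 * cos(2 * pi * 4 * t)
  fit4 <- fourier_fit(volume_curve(v4, rr), 3)
  tt <- seq(0, rr, length.out = 257)[-257]
  spec <- Mod(fft(eval_curve(fit4, tt)))[1:9] / 256
  expect_lt(max(spec[6:9]), 1e-9)           # harmonics 5..8 empty
  expect_equal(eval_curve(fit4, tt), eval_curve(fit, tt), tolerance = 1e-9)
  expect_error(fourier_fit(volume_curve(rep(60, 8), 1000), 4), "too few")
})

test_that("dV/dt is the analytic derivative in mL per second", {
  rr <- 1000
  flat <- fourier_curve(60, 0, 0, rr)
  expect_equal(eval_dvdt(dvdt(flat), seq(0, rr, 50)), rep(0, 21))
  a <- 12
  sine <- fourier_curve(70, 0, a, rr)   # V = 70 + a sin(2 pi t / RR)
  dv <- dvdt(sine)
  tt <- seq(0, rr - 1, by = 1)
  expect_equal(max(eval_dvdt(dv, tt)), 2 * pi * a / (rr / 1000), tolerance = 1e-4)
  # central differences match the analytic derivative
  h <- 0.01
  num <- (eval_curve(sine, tt + h) - eval_curve(sine, tt - h)) / (2 * h) *
    1000
  expect_equal(eval_dvdt(dv, tt), num, tolerance = 1e-6)
})

test_that("PFR matches closed forms and is EDV-normalized", {
  rr <- 1000
  # pure fundamental: V = 75 - 25 cos -> EDV 100, ESV 50, filling over rr/2
  cur <- fourier_curve(75, -25, 0, rr)
  p <- pfr(dvdt(cur), edv = 100)
  expect_equal(p$pfr, pi / 2, tolerance = 1e-3)   # 2 pi A / (RR * EDV)
  expect_false(p$flagged)
  # scaling the curve leaves the normalized rate unchanged
  p3 <- pfr(dvdt(fourier_curve(3 * 75, 3 * -25, 0, rr)), edv = 300)
  expect_equal(p3$pfr, p$pfr, tolerance = 1e-9)
  # a flat curve has no positive filling slope and is flagged
  p0 <- pfr(dvdt(fourier_curve(60, 0, 0, rr)), edv = 60)
  expect_true(p0$flagged)
  expect_equal(p0$pfr, 0)
  expect_error(pfr(dvdt(cur), edv = 0), "> 0")
})

test_that("one-third mean filling rate matches its integral identity", {
  rr <- 1000
  cur <- fourier_curve(75, -25, 0, rr)
  m <- one_third_mfr(dvdt(cur), edv = 100)
  # first third of filling gains SV/4 -> 0.75 * SV / (D * EDV)
  expect_equal(m$one_third_mfr, 0.75 * 50 / 0.5 / 100, tolerance = 1e-3)
  # identity against numerical averaging of dV/dt
  cur2 <- fourier_curve(80, c(-18, 3, 0), c(4, -2, 1), rr)
  ph <- smallheart:::filling_phase(cur2)
  D <- ph$t_ed - ph$t_es
  tt <- seq(ph$t_es, ph$t_es + D / 3, by = 0.25)
  num <- mean(eval_dvdt(dvdt(cur2), tt))
  m2 <- one_third_mfr(dvdt(cur2), edv = 98)
  expect_equal(m2$one_third_mfr, num / 98, tolerance = 1e-2)
})

test_that("TPFR is the end-systole to peak-filling delay", {
  rr <- 1000
  cur <- fourier_curve(75, -25, 0, rr)
  tp <- tpfr(dvdt(cur))
  expect_equal(tp$tpfr_ms, 250, tolerance = 1.5)  # quarter period
  expect_equal(tp$tpfr_rr, 0.25, tolerance = 2e-3)
  # bounded by the cycle for assorted smooth curves
  for (s in 1:5) {
    cur2 <- fourier_curve(90, c(-15, 2 * sin(s), 1), c(5, -s, 0.5), rr)
    tp2 <- tpfr(dvdt(cur2))
    expect_gte(tp2$tpfr_rr, 0)
    expect_lte(tp2$tpfr_rr, 1)
  }
})

test_that("diastolic indices are invariant to scaling and phase", {
  rr <- 900
  v <- cardiac_volume_curve(70, 0.55, 8)
  base <- quantify_function(volume_curve(v, rr))
  scaled <- quantify_function(volume_curve(2.5 * v, rr))
  expect_equal(scaled$pfr, base$pfr, tolerance = 1e-9)
  expect_equal(scaled$one_third_mfr, base$one_third_mfr, tolerance = 1e-9)
  expect_equal(scaled$tpfr_ms, base$tpfr_ms, tolerance = 1e-9)
  expect_equal(scaled$ef, base$ef, tolerance = 1e-12)
  # phase rotation: indices agree up to the 1 ms grid on which end-systole
  # is located (a shifted curve can snap to the neighbouring grid point)
  for (k in c(2, 5)) {
    rot <- quantify_function(volume_curve(c(v[-(1:k)], v[1:k]), rr))
    expect_equal(rot$pfr, base$pfr, tolerance = 1e-3)
    expect_equal(rot$one_third_mfr, base$one_third_mfr, tolerance = 0.01)
    expect_lt(abs(rot$tpfr_ms - base$tpfr_ms), 2)
  }
})

test_that("EF from the fitted curve tracks the raw-frame EF", {
  for (ef in c(0.45, 0.65)) {
    v <- cardiac_volume_curve(60, ef, 8)
    rep_ <- quantify_function(volume_curve(v, 1000))
    fit_v <- eval_curve(rep_$fitted_curve, seq(0, 999))
    ef_fit <- (max(fit_v) - min(fit_v)) / max(fit_v)
    expect_lt(abs(ef_fit - rep_$ef), 0.03)
  }
})

test_that("heart size classes follow the ESV thresholds", {
  expect_equal(classify_heart_size(15), "SH20")
  expect_equal(classify_heart_size(10), "SH10")
  expect_equal(classify_heart_size(20.5), "NH")
  expect_equal(classify_heart_size(c(0, 10.0001, 20, 21)),
               c("SH10", "SH20", "SH20", "NH"))
  expect_error(classify_heart_size(-2), ">= 0")
  rep_ <- quantify_function(volume_curve(cardiac_volume_curve(40, 0.65, 8),
                                         1000))
  expect_equal(rep_$heart_class, classify_heart_size(rep_$esv))
  expect_true(rep_$esv <= rep_$edv && rep_$ef >= 0 && rep_$ef <= 1)
})
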