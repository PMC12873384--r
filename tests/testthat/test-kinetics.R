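test_that("noiseless logistic traces are recovered essentially exactly", {
  tr <- logistic_trace(seq(1, 400, by = 1), baseline = 0, A = 1,
                       t_m = 128, tau = 20)
  f <- fit_sigmoid(tr)
  expect_true(f$ok)
  expect_lt(abs(f$A - 1), 1e-6)
  expect_lt(abs(f$t_m - 128) / 128, 1e-6)
  expect_lt(abs(f$tau - 20) / 20, 1e-6)
  # value at the fitted midpoint is baseline + A/2 by construction
  expect_equal(predict_sigmoid(f, f$t_m), f$baseline + f$A / 2)
})

test_that("seeded noisy sigmoid fits land near truth", {
  set.seed(41)
  t <- seq(1, 400, by = 1)
  y <- 0.05 + 1 / (1 + exp(-(t - 128) / 20.5)) + rnorm(length(t), 0, 0.03)
  f <- fit_sigmoid(kinetic_trace(t, y, "tht"))
  expect_lt(abs(f$t_m - 128), 2)
  expect_lt(abs(f$tau - 20.5) / 20.5, 0.10)
})

test_that("fit equivariance: shifting time shifts t_m, leaves A and tau", {
  t <- seq(1, 400, by = 2)
  f0 <- fit_sigmoid(logistic_trace(t, 0.1, 2, 150, 25))
  f1 <- fit_sigmoid(logistic_trace(t + 37, 0.1, 2, 187, 25))
  expect_equal(f1$t_m - f0$t_m, 37, tolerance = 1e-4)
  expect_equal(f1$A, f0$A, tolerance = 1e-6)
  expect_equal(f1$tau, f0$tau, tolerance = 1e-6)
})

test_that("non-sigmoidal traces are flagged as failures", {
  set.seed(8)
  t <- seq(1, 120)
  f <- fit_sigmoid(kinetic_trace(t, sin(t / 3) + rnorm(120, 0, 0.5), "tht"))
  expect_false(f$ok)
})

test_that("landmarks satisfy the onset identity and the plateau rules", {
  tr <- logistic_trace(seq(1, 400, by = 1), 0.05, 1, 128, 20.5)
  f <- fit_sigmoid(tr)
  lm <- landmarks(f, tr)
  # t_m = 128, tau = 20.5 -> onset at 87 min
  expect_equal(lm$tht_on, 87, tolerance = 1e-4)
  expect_lt(lm$tht_on, lm$tht_m)
  # normalised fitted value at the onset is 1/(1 + e^2) by identity
  frac <- (predict_sigmoid(f, lm$tht_on) - f$baseline) / f$A
  expect_equal(frac, 1 / (1 + exp(2)), tolerance = 1e-12)
  expect_true(lm$tht_on < lm$tht_m && lm$tht_m < lm$tht_p)
  # fit-based plateau rule
  expect_equal(landmarks(f, tr, rule = "fit")$tht_p, f$t_m + 2 * f$tau)
  # trace reaching 98% of A at t ~ 208: default rule finds it within a step
  t98 <- 128 + 20.5 * log(0.98 / 0.02)
  expect_lt(abs(landmarks(f, tr)$tht_p - t98), 2)
  # plateau never reached inside a truncated trace
  short <- logistic_trace(seq(1, 140, by = 1), 0.05, 1, 128, 20.5)
  fs <- fit_sigmoid(short)
  expect_warning(lms <- landmarks(fs, short), "plateau")
  expect_true(is.na(lms$tht_p))
})

test_that("485/450 nm channels are extracted from emission spectra", {
  ax <- seq(400, 600, by = 1)
  tm <- c(5, 10, 15)
  sp <- matrix(0, length(ax), 3)
  sp[ax == 485, ] <- c(1, 2, 3)
  sp[ax == 450, ] <- c(5, 5, 5)
  ser <- spectrum_series(ax, sp, tm)
  th <- tht_trace(ser)
  tu <- turbidity_trace(ser)
  expect_equal(th$kind, "tht")
  expect_equal(tu$kind, "turbidity")
  # +/- 2 nm averaging: 5 grid points, one carrying the signal
  expect_equal(th$value, c(1, 2, 3) / 5)
  expect_equal(tu$value, rep(1, 3))
  # constant spectra -> constant trace
  cst <- spectrum_series(ax, matrix(2, length(ax), 3), tm)
  expect_equal(tht_trace(cst)$value, rep(2, 3))
  # axis not covering the channel
  red <- spectrum_series(seq(500, 600, 1), matrix(1, 101, 3), tm)
  expect_error(turbidity_trace(red), "450")
  expect_error(tht_trace(spectrum_series(seq(490, 600, 1), matrix(1, 111, 3), tm)),
               "485")
  # simulated emission: extracted ThT matches the injected waveform
  em <- simulate_emission_series(seq(5, 400, by = 5), noise = 0.002, seed = 3)
  th2 <- tht_trace(em)
  truth <- 0.05 + 1 / (1 + exp(-(th2$time_min - 128) / 20.5))
  expect_gt(cor(th2$value, truth), 0.999)
})

test_that("amide-I preprocessing anchors the baseline and normalises area", {
  ax <- seq(1500, 1800, by = 2)
  base <- 0.001 * (ax - 1500) + 0.2          # linear ramp
  bandv <- exp(-(ax - 1640)^2 / (2 * 15^2))
  buf <- rep(0.2, length(ax))
  out <- ftir_preprocess(bandv + base, buf + base - 0.2, ax)
  expect_true(out$ok)
  # window endpoints anchored at zero before normalisation, area exactly 1
  expect_lt(abs(out$intensity[1]), 1e-12)
  expect_lt(abs(out$intensity[length(out$intensity)]), 1e-12)
  expect_equal(pracma::trapz(out$axis, out$intensity), 1, tolerance = 1e-9)
  # ramp removed: shape matches the pure band normalised the same way
  idx <- ax >= 1590 & ax <= 1720
  pure <- bandv[idx] - (bandv[idx][1] + (bandv[idx][sum(idx)] - bandv[idx][1]) *
                          (ax[idx] - 1590) / (1720 - 1590))
  pure <- pure / pracma::trapz(ax[idx], pure)
  expect_equal(out$intensity, pure, tolerance = 1e-9)
  # spectrum equal to buffer: flagged, zero area
  expect_warning(z <- ftir_preprocess(buf, buf, ax), "area")
  expect_false(z$ok)
})

test_that("band kinetics recover injected waveforms and preserve ordering", {
  f <- simulate_ftir_series(noise = 0.002, seed = 4)
  pp <- ftir_preprocess_series(f$series, f$buffer)
  bk <- ftir_band_kinetics(pp)
  expect_gt(cor(bk$band_1620$value, f$truth_1620$value), 0.99)
  expect_gt(cor(bk$band_1695$value, f$truth_1695$value), 0.99)
  # antiparallel contacts (1695) rise before crystalline sheets (1620)
  expect_lt(half_rise_time(bk$band_1695), half_rise_time(bk$band_1620))
  expect_true(all(bk$band_1620$value >= 0 & bk$band_1620$value <= 1))
  # constant band: degenerate normalisation, zeros with warning
  ax <- seq(1590, 1720, 2)
  cstser <- spectrum_series(ax, matrix(1, length(ax), 4), c(1, 2, 3, 4), "ftir")
  expect_warning(bc <- ftir_band_kinetics(cstser, bands = 1620), "constant")
  expect_equal(bc$band_1620$value, rep(0, 4))
  expect_error(ftir_band_kinetics(pp, bands = 2000), "axis")
})
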