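test_that("sub-ROI grid matches brute-force window enumeration", {
  roi <- matrix(TRUE, 208, 40)
  g0 <- make_subroi_grid(roi, fix_acq, window_mm = c(2, 2), overlap = 0)
  # 2 mm is 104 samples axially and 20 lines laterally: exactly 2 x 2 windows
  expect_equal(g0$win_samples, 104L)
  expect_equal(g0$win_lines, 20L)
  expect_equal(g0$shape, c(2L, 2L))
  expect_true(all(g0$in_roi))

  g94 <- make_subroi_grid(roi, fix_acq, window_mm = c(2, 2), overlap = 0.94)
  expect_equal(g94$stride[1], floor(104 * 0.06))   # ~0.12 mm axial stride
  # brute-force enumeration of valid origins
  expect_equal(length(g94$origin_ax), length(seq(1, 208 - 104 + 1, by = 6)))
  expect_equal(length(g94$origin_lat), length(seq(1, 40 - 20 + 1, by = 1)))

  # windows overlapping the ROI complement are excluded
  roi2 <- roi; roi2[, 21:40] <- FALSE
  g2 <- make_subroi_grid(roi2, fix_acq, window_mm = c(2, 2), overlap = 0)
  expect_equal(unname(colSums(g2$in_roi)), c(2, 0))

  expect_error(make_subroi_grid(matrix(FALSE, 208, 40), fix_acq),
               "ROI smaller|no window")
  expect_error(make_subroi_grid(matrix(TRUE, 50, 10), fix_acq), "2.0 x 2.0 mm")
})

test_that("periodogram locates tones and halving the window halves resolution", {
  fs <- fix_acq$sampling_rate
  t <- (0:511) / fs
  win <- matrix(sin(2 * pi * 6e6 * t), 512, 4)
  ps <- estimate_power_spectrum(win, fix_acq)
  expect_equal(ps$frequencies[which.max(ps$values_db)], 6e6,
               tolerance = fs / 512 / 6e6)
  ps2 <- estimate_power_spectrum(win[1:256, ], fix_acq)
  expect_equal(diff(ps2$frequencies[1:2]), 2 * diff(ps$frequencies[1:2]))
  expect_error(estimate_power_spectrum(matrix(0, 64, 4), fix_acq), "zero")
  expect_error(estimate_power_spectrum(matrix(1, 64, 1), fix_acq), "2 scan lines")
})

test_that("white-noise periodogram averaging shrinks per-bin spread", {
  set.seed(1)
  one_line_sd <- apply(sapply(1:40, function(i) {
    ps <- estimate_power_spectrum(matrix(stats::rnorm(256 * 2), 256, 2), fix_acq)
    10^(ps$values_db / 10)
  }), 1, stats::sd)
  many_line_sd <- apply(sapply(1:40, function(i) {
    ps <- estimate_power_spectrum(matrix(stats::rnorm(256 * 64), 256, 64), fix_acq)
    10^(ps$values_db / 10)
  }), 1, stats::sd)
  # 64-line average vs 2-line average: sd ratio ~ sqrt(32)
  expect_equal(mean(many_line_sd / one_line_sd), 1 / sqrt(32), tolerance = 0.35)
})

test_that("normalization subtracts in dB and enforces matching grids", {
  f <- seq(4e6, 9e6, by = 1e5)
  mk <- function(v) structure(list(frequencies = f, values_db = v,
                                   n_lines_averaged = 1),
                              class = "power_spectrum")
  a <- mk(stats::runif(length(f), -5, 5))
  expect_equal(normalize_spectrum(a, a)$values_db, rep(0, length(f)))
  b <- mk(a$values_db + 6)
  expect_equal(normalize_spectrum(b, a)$values_db, rep(6, length(f)))
  short <- structure(list(frequencies = f[-1], values_db = a$values_db[-1],
                          n_lines_averaged = 1), class = "power_spectrum")
  expect_error(normalize_spectrum(a, short), "different frequency grids")
})

test_that("attenuation estimation and correction are mutually inverse", {
  f <- seq(4e6, 9e6, by = 2.5e5)
  depths <- c(1, 2, 3, 4)
  alpha <- 0.8
  spectra <- t(sapply(depths, function(z) -4 * alpha * z * f / 1e6))
  est <- estimate_ace(spectra, depths, f)
  expect_equal(est$ace, alpha, tolerance = 1e-10)

  # depth-independent spectra: zero attenuation
  flat <- matrix(3, length(depths), length(f))
  expect_equal(estimate_ace(flat, depths, f)$ace, 0)
  # increasing-with-depth spectra clamp at zero rather than go negative
  up <- t(sapply(depths, function(z) 2 * z * f / 1e6))
  expect_equal(estimate_ace(up, depths, f)$ace, 0)
  expect_error(estimate_ace(spectra[1, , drop = FALSE], depths[1], f),
               "2 distinct depths")

  sp <- structure(list(frequencies = f, values_db = spectra[3, ],
                       n_lines_averaged = 1), class = "power_spectrum")
  corr <- attenuation_correct(sp, est$ace, depths[3])
  expect_equal(corr$values_db, rep(0, length(f)), tolerance = 1e-9)
  expect_equal(attenuation_correct(sp, 0, 2)$values_db, sp$values_db)
  # correcting every depth then re-estimating gives ~0
  corrected <- t(sapply(seq_along(depths), function(i) {
    attenuation_correct(structure(list(frequencies = f,
                                       values_db = spectra[i, ],
                                       n_lines_averaged = 1),
                                  class = "power_spectrum"),
                        est$ace, depths[i])$values_db
  }))
  expect_equal(estimate_ace(corrected, depths, f)$ace, 0, tolerance = 1e-9)
})

test_that("attenuation recovery from simulated frames is unbiased", {
  roi <- matrix(TRUE, nrow(fix_refs[[1]]$samples), ncol(fix_refs[[1]]$samples))
  rec <- vapply(1:3, function(s) {
    tis <- diffuse_field(c(0.018, 0.0096), 1.2e8, seed = 100L + s)
    fr <- simulate_rf_frame(tis, fix_pulse, fix_acq, attenuation = 1,
                            seed = 100L + s)
    build_parametric_maps(fr, roi, fix_refs, fix_cfg)$ace
  }, numeric(1))
  expect_equal(mean(rec), 1, tolerance = 0.15)
})

test_that("spectral line fit is exact on lines and matches lm on noise", {
  f <- seq(4e6, 9e6, by = 1e5)
  mk <- function(v) structure(list(frequencies = f, values_db = v,
                                   n_lines_averaged = 1),
                              class = "power_spectrum")
  fit <- fit_spectral_line(mk(2 * f / 1e6 - 5), c(4e6, 9e6))
  expect_equal(fit$ss, 2, tolerance = 1e-12)
  expect_equal(fit$si, -5, tolerance = 1e-12)
  expect_equal(fit$mbf, 2 * 6.5 - 5, tolerance = 1e-12)
  expect_equal(fit$mbf, fit$ss * fit$f_c_mhz + fit$si)  # consistency identity

  flat <- fit_spectral_line(mk(rep(0, length(f))), c(4e6, 9e6))
  expect_equal(unlist(flat[c("mbf", "ss", "si")]),
               c(mbf = 0, ss = 0, si = 0))

  shifted <- fit_spectral_line(mk(2 * f / 1e6 - 5 + 3), c(4e6, 9e6))
  expect_equal(shifted$ss, fit$ss)
  expect_equal(shifted$si, fit$si + 3)
  expect_equal(shifted$mbf, fit$mbf + 3)

  set.seed(2)
  for (i in 1:20) {
    y <- stats::rnorm(length(f), 0, 3)
    ours <- fit_spectral_line(mk(y), c(4e6, 9e6))
    ref <- stats::lm(y ~ I(f / 1e6))
    expect_equal(ours$si, unname(stats::coef(ref)[1]), tolerance = 1e-9)
    expect_equal(ours$ss, unname(stats::coef(ref)[2]), tolerance = 1e-9)
  }
  expect_error(fit_spectral_line(mk(f * 0), c(4e6, 4.15e6)), "3 bins")
})

test_that("slope estimator bias under 1 dB noise is below 0.05 dB/MHz", {
  f <- seq(4e6, 9e6, length.out = 50)
  set.seed(3)
  err <- vapply(1:200, function(i) {
    y <- 1.7 * f / 1e6 + 4 + stats::rnorm(50, 0, 1)
    sp <- structure(list(frequencies = f, values_db = y,
                         n_lines_averaged = 1), class = "power_spectrum")
    fit_spectral_line(sp, c(4e6, 9e6))$ss - 1.7
  }, numeric(1))
  expect_lt(abs(mean(err)), 0.05)
})

test_that("spacing estimator finds exact periodicity and rejects noise", {
  f <- seq(4e6, 9e6, by = 5e4)
  delta <- 1.54e6
  sp <- structure(list(frequencies = f,
                       values_db = 10 * log10(1 + 0.9 * cos(2 * pi * f / delta)),
                       n_lines_averaged = 1), class = "power_spectrum")
  s <- estimate_sas(sp, fix_acq)
  expect_true(s$valid)
  expect_equal(s$delta_f, delta, tolerance = 0.02)
  expect_equal(s$sas, fix_acq$sound_speed / (2 * delta), tolerance = 0.02)

  # diffuse speckle: flagged invalid in the large majority of windows
  fracs <- vapply(1:3, function(s_) {
    tis <- diffuse_field(c(0.018, 0.0096), 1.2e8, seed = 700L + s_)
    fr <- simulate_rf_frame(tis, fix_pulse, fix_acq, seed = 700L + s_)
    roi <- matrix(TRUE, nrow(fr$samples), ncol(fr$samples))
    m <- build_parametric_maps(fr, roi, fix_refs, fix_cfg)$maps$SAS
    mean(m$valid_mask)
  }, numeric(1))
  expect_lt(mean(fracs), 0.2)
})

test_that("recovered spacing is monotone in the true spacing", {
  spacings <- c(0.3, 0.37, 0.45, 0.6, 0.8)
  rec <- vapply(seq_along(spacings), function(i) {
    fld <- regular_field(c(0.018, 0.0096), spacings[i] * 1e-3, fix_acq,
                         seed = 50L + i, jitter_sd = 0.02, amplitude = 2,
                         diffuse_density = 1e8, diffuse_sd = 0.3)
    fr <- simulate_rf_frame(fld, fix_pulse, fix_acq, seed = 50L + i)
    estimate_sas(fix_norm_spectrum(fr), fix_acq)$sas
  }, numeric(1))
  expect_true(all(is.finite(rec)))
  expect_true(all(diff(rec) > 0))
})

test_that("form-factor fit recovers diameter and separates amplitude", {
  f <- seq(4e6, 9e6, by = 1e5)
  model_db <- function(a_m, A) {
    k <- 2 * pi * f / fix_acq$sound_speed
    40 * log10(f / 1e6) - 10 * 0.827 * (k * a_m / 2)^2 / log(10) + A
  }
  mk <- function(v) structure(list(frequencies = f, values_db = v,
                                   n_lines_averaged = 1),
                              class = "power_spectrum")
  fit <- fit_form_factor(mk(model_db(90e-6, 12)), fix_acq)
  expect_true(fit$valid)
  expect_equal(fit$asd, 90e-6, tolerance = 0.02)
  expect_equal(fit$aac, 12, tolerance = 0.1)

  fit10 <- fit_form_factor(mk(model_db(90e-6, 22)), fix_acq)
  expect_equal(fit10$aac - fit$aac, 10, tolerance = 1e-6)
  expect_equal(fit10$asd, fit$asd)

  # pure f^4 spectrum (a -> 0 limit): pinned at the lower bound and flagged
  fit0 <- fit_form_factor(mk(40 * log10(f / 1e6) + 3), fix_acq)
  expect_false(fit0$valid)
  expect_equal(fit0$asd, 1e-6, tolerance = 0.05)
  expect_error(fit_form_factor(mk(rep(NA_real_, length(f))), fix_acq),
               "non-finite")
})

test_that("parametric maps have the grid shape and react to density contrast", {
  tis <- diffuse_field(c(0.018, 0.0096), 1.2e8, seed = 61L,
                       effective_diameter = 60e-6)
  fr <- simulate_rf_frame(tis, fix_pulse, fix_acq, attenuation = 0.6, seed = 61L)
  roi <- matrix(TRUE, nrow(fr$samples), ncol(fr$samples))
  bm <- build_parametric_maps(fr, roi, fix_refs, fix_cfg)
  expect_named(bm$maps, c("MBF", "SS", "SI", "SAS", "ASD", "AAC"))
  for (m in bm$maps) expect_equal(dim(m$values), bm$grid$shape)
  expect_equal(mean(bm$maps$ASD$values, na.rm = TRUE), 60e-6, tolerance = 0.25)

  # two-region medium: 4x density in the deep half -> ~6 dB AAC contrast
  half <- 0.009
  env4 <- function(z, x) ifelse(z > half, 2, 1)   # amplitude x2 = power x4
  diffs <- vapply(1:3, function(s) {
    tis2 <- diffuse_field(c(0.018, 0.0096), 1.2e8, seed = 70L + s,
                          amplitude_envelope = env4)
    fr2 <- simulate_rf_frame(tis2, fix_pulse, fix_acq, seed = 70L + s)
    bm2 <- build_parametric_maps(fr2, roi, fix_refs, fix_cfg)
    a <- bm2$maps$AAC
    depth_m <- (bm2$grid$origin_ax + (bm2$grid$win_samples - 1) / 2) *
      axial_sample_m(fix_acq)
    deep <- depth_m > half
    mean(a$values[deep, ], na.rm = TRUE) - mean(a$values[!deep, ], na.rm = TRUE)
  }, numeric(1))
  expect_equal(mean(diffs), 6, tolerance = 2)
})

test_that("map construction is deterministic given frame and config", {
  tis <- diffuse_field(c(0.012, 0.0064), 1.2e8, seed = 81L)
  fr <- simulate_rf_frame(tis, fix_pulse, fix_acq, seed = 81L)
  roi <- matrix(TRUE, nrow(fr$samples), ncol(fr$samples))
  b1 <- build_parametric_maps(fr, roi, fix_refs, fix_cfg)
  b2 <- build_parametric_maps(fr, roi, fix_refs, fix_cfg)
  for (p in names(b1$maps)) {
    expect_identical(b1$maps[[p]]$values, b2$maps[[p]]$values)
  }
  expect_identical(b1$ace, b2$ace)
})
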