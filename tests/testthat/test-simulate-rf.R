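test_that("a single scatterer echoes at the pulse-echo delay 2z/c", {
  fld <- scatterer_field(matrix(c(0.008, 0.0005), 1), 1,
                         extent = c(0.016, 0.001))
  fr <- simulate_rf_frame(fld, fix_pulse, fix_acq, n_lines = 1L)
  peak <- which.max(abs(fr$samples[, 1]))
  expected <- round(2 * 0.008 / fix_acq$sound_speed * fix_acq$sampling_rate) + 1
  expect_lte(abs(peak - expected), 1)
})

test_that("simulator validates its inputs", {
  expect_error(scatterer_field(matrix(numeric(0), 0, 2), numeric(0),
                               extent = c(0.01, 0.01)), "empty")
  fld <- scatterer_field(matrix(c(0.005, 5e-4), 1), 1, extent = c(0.01, 0.001))
  expect_error(simulate_rf_frame(fld, fix_pulse, fix_acq, attenuation = -1),
               ">= 0")
  expect_error(pulse_model(fractional_bandwidth = 2.5))
  expect_error(acquisition_spec(analysis_band = c(8e6, 9e6)))
  expect_error(acquisition_spec(sampling_rate = 1e7))
})

test_that("regular axial spacing produces a spectral comb at c/(2d)", {
  # oracle: an impulse train of period d has power-spectral peaks separated
  # by delta_f = c/(2d); for d = 0.5 mm this is 1.54 MHz
  d <- 0.5e-3
  fld <- regular_field(c(0.018, 0.0096), d, fix_acq, seed = 2L,
                       jitter_sd = 0.02, amplitude = 2,
                       diffuse_density = 1e8, diffuse_sd = 0.3)
  fr <- simulate_rf_frame(fld, fix_pulse, fix_acq, seed = 2L)
  spn <- fix_norm_spectrum(fr)
  s <- estimate_sas(spn, fix_acq)
  expect_true(s$valid)
  expect_equal(s$delta_f, fix_acq$sound_speed / (2 * d), tolerance = 0.1)
})

test_that("doubling diffuse scatterer density raises band power by ~3 dB", {
  band_db <- function(dens, seed) {
    fld <- diffuse_field(c(0.018, 0.0096), dens, seed = seed)
    fr <- simulate_rf_frame(fld, fix_pulse, fix_acq, seed = seed)
    mean(fix_norm_spectrum(fr)$values_db)
  }
  diffs <- vapply(1:8, function(s) {
    band_db(2.4e8, 5000 + s) - band_db(1.2e8, 6000 + s)
  }, numeric(1))
  expect_equal(mean(diffs), 10 * log10(2), tolerance = 0.5)
})

test_that("band power is linear in scatterer density", {
  dens <- c(0.6e8, 1.2e8, 2.4e8, 4.8e8)
  pow <- vapply(seq_along(dens), function(i) {
    fld <- diffuse_field(c(0.018, 0.0096), dens[i], seed = 40L + i)
    fr <- simulate_rf_frame(fld, fix_pulse, fix_acq, seed = 40L + i)
    mean(10^(fix_norm_spectrum(fr)$values_db / 10))
  }, numeric(1))
  r2 <- summary(stats::lm(pow ~ dens))$r.squared
  expect_gt(r2, 0.95)
})

test_that("reference frames are deterministic and self-normalize to 0 dB", {
  r1 <- make_reference_frames(fix_acq, fix_pulse, seed = 3L, n_frames = 2L)
  r2 <- make_reference_frames(fix_acq, fix_pulse, seed = 3L, n_frames = 2L)
  expect_identical(r1[[1]]$samples, r2[[1]]$samples)
  # a phantom window normalized by the phantom's own averaged spectrum
  ps <- estimate_power_spectrum(fix_refs[[1]]$samples[151:450, ], fix_acq)
  ref <- qusrad:::.reference_spectrum(fix_refs, 151L, 300L, fix_acq)
  spn <- normalize_spectrum(ps, ref, band = c(4e6, 9e6))
  expect_lt(mean(abs(spn$values_db)), 1.5)
  expect_lt(abs(mean(spn$values_db)), 1.0)
})

test_that("averaging periodograms across frames shrinks their variance", {
  refs <- make_reference_frames(fix_acq, fix_pulse, seed = 9L, n_frames = 20L,
                                extent = c(0.012, 0.0032))
  one <- function(fr) {
    ps <- estimate_power_spectrum(fr$samples[101:300, ], fix_acq)
    keep <- ps$frequencies >= 4e6 & ps$frequencies <= 9e6
    10^(ps$values_db[keep] / 10)
  }
  per_frame <- sapply(refs, one)
  avg_all <- rowMeans(per_frame)
  # variability across bins around the pulse envelope, single frame vs average
  env <- apply(per_frame, 1, mean)
  v_single <- mean(apply(per_frame / env, 2, stats::var))
  v_avg <- stats::var(avg_all / env)
  expect_lt(v_avg, v_single / 4)
})

test_that("quantization to bit depth round-trips within half a step", {
  fld <- diffuse_field(c(0.012, 0.0032), 1.2e8, seed = 5L)
  fr <- simulate_rf_frame(fld, fix_pulse, fix_acq, seed = 5L)
  q <- quantize_frame(fr)
  expect_true(is.integer(q$samples))
  expect_lte(max(abs(q$samples)), 2^15 - 1)
  expect_lt(max(abs(q$samples * q$scale - fr$samples)), q$scale / 2 + 1e-12)
})

test_that("cohort generator reproduces the study's class structure", {
  spec <- cohort_spec(n_recurrence = 28L, n_non_recurrence = 55L,
                      frames_range = c(3L, 3L), extent = c(0.004, 0.001),
                      seed = 2L)
  co <- make_cohort(spec, simulate_frames = FALSE)
  expect_equal(nrow(co$outcomes), 83L)
  expect_equal(sum(co$outcomes$label == "R"), 28L)
  expect_equal(sum(co$outcomes$label == "NR"), 55L)
  expect_error(cohort_spec(n_recurrence = 1L), "at least 2")
})

test_that("cohort generation is reproducible and censoring behaves", {
  sp <- cohort_spec(n_recurrence = 3L, n_non_recurrence = 3L,
                    frames_range = c(2L, 2L), extent = c(0.008, 0.004),
                    seed = 21L)
  c1 <- make_cohort(sp)
  c2 <- make_cohort(sp)
  expect_identical(c1$outcomes, c2$outcomes)
  expect_identical(c1$patients[[1]]$scans[[1]]$frame$samples,
                   c2$patients[[1]]$scans[[1]]$frame$samples)
  # degenerate censoring: everything censored at time zero
  sp0 <- cohort_spec(n_recurrence = 3L, n_non_recurrence = 3L,
                     censor_time = 0, seed = 4L)
  co0 <- make_cohort(sp0, simulate_frames = FALSE)
  expect_true(all(co0$outcomes$time_rfs_months == 0))
  expect_true(all(co0$outcomes$event_rfs == 0))
})

test_that("equal hazards give uniform log-rank p-values across seeds", {
  ps <- vapply(1:200, function(s) {
    sp <- cohort_spec(n_recurrence = 20L, n_non_recurrence = 20L,
                      hazard_rfs = c(R = 0.01, NR = 0.01),
                      censor_time = 120, seed = 3000L + s)
    oc <- make_cohort(sp, simulate_frames = FALSE)$outcomes
    r <- oc$label == "R"
    logrank(oc$time_rfs_months[r], oc$event_rfs[r],
            oc$time_rfs_months[!r], oc$event_rfs[!r])$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("scan containers round-trip through the text format", {
  co <- fix_mini_cohort(2L, 2L, seed = 31L)
  dir <- withr::local_tempdir()
  write_scan_container(co$patients[[1]], dir)
  back <- read_scan_container(file.path(dir, co$patients[[1]]$patient_id))
  expect_equal(back$label, co$patients[[1]]$label)
  expect_equal(length(back$scans), length(co$patients[[1]]$scans))
  orig <- co$patients[[1]]$scans[[1]]$frame$samples
  # quantization to 16 bits bounds the round-trip error
  expect_lt(max(abs(back$scans[[1]]$frame$samples - orig)),
            max(abs(orig)) / 2^15)
  expect_identical(back$scans[[1]]$roi, co$patients[[1]]$scans[[1]]$roi)
})
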