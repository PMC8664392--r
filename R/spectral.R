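#' Sliding sub-ROI window grid
#'
#' Lays a sliding-window grid over an ROI mask. Window size is given in mm
#' and converted to samples/lines via the acquisition geometry (axial:
#' c / (2 fs) per sample; lateral: line pitch). The stride is
#' window extent x (1 - overlap), floored to at least one sample. Windows
#' whose footprint leaves the ROI are kept in the grid shape but flagged out.
#'
#' @param roi_mask Logical matrix (axial sample x scan line), TRUE in tumour.
#' @param acq An `acquisition_spec`.
#' @param window_mm Length-2 numeric, window (axial mm, lateral mm).
#' @param overlap Overlap fraction in [0, 1), e.g. 0.94.
#' @return An object of class `subroi_grid` with elements `origin_ax`,
#'   `origin_lat` (1-based window origins), `win_samples`, `win_lines`,
#'   `shape`, and logical matrix `in_roi` of shape `shape`.
#' @export
make_subroi_grid <- function(roi_mask, acq, window_mm = c(2, 2), overlap = 0.94) {
  stopifnot(is.matrix(roi_mask), overlap >= 0, overlap < 1)
  if (length(window_mm) == 1L) window_mm <- rep(window_mm, 2)
  wa <- max(2L, round(window_mm[1] * 1e-3 / axial_sample_m(acq)))
  wl <- max(2L, round(window_mm[2] * 1e-3 / acq$line_pitch))
  if (nrow(roi_mask) < wa || ncol(roi_mask) < wl || !any(roi_mask)) {
    stop(sprintf(
      "ROI smaller than one analysis window: need at least %d samples x %d lines (%.1f x %.1f mm)",
      wa, wl, window_mm[1], window_mm[2]))
  }
  sa <- max(1L, floor(wa * (1 - overlap)))
  sl <- max(1L, floor(wl * (1 - overlap)))
  origin_ax <- seq(1L, nrow(roi_mask) - wa + 1L, by = sa)
  origin_lat <- seq(1L, ncol(roi_mask) - wl + 1L, by = sl)
  # cumulative-sum table for O(1) "window fully inside ROI" queries
  cs <- rbind(0, apply(roi_mask, 2, cumsum))
  cs <- cbind(0, t(apply(cs, 1, cumsum)))
  in_roi <- matrix(FALSE, length(origin_ax), length(origin_lat))
  for (i in seq_along(origin_ax)) {
    a <- origin_ax[i]
    tot <- cs[a + wa, origin_lat + wl] - cs[a, origin_lat + wl] -
      cs[a + wa, origin_lat] + cs[a, origin_lat]
    in_roi[i, ] <- tot == wa * wl
  }
  if (!any(in_roi)) {
    stop(sprintf(
      "no window of %d samples x %d lines fits inside the ROI mask", wa, wl))
  }
  structure(
    list(origin_ax = origin_ax, origin_lat = origin_lat,
         win_samples = wa, win_lines = wl,
         stride = c(sa, sl), shape = dim(in_roi), in_roi = in_roi),
    class = "subroi_grid"
  )
}

#' Averaged periodogram power spectrum of an RF window
#'
#' Each scan line is Hann-tapered and Fourier transformed; per-line
#' periodograms are averaged across lines and returned one-sided in dB.
#' Frequency resolution is fs / window length (no zero padding), so halving
#' the window halves the resolution.
#'
#' @param rf_window Numeric matrix, axial sample x scan line.
#' @param acq An `acquisition_spec`.
#' @return An object of class `power_spectrum`: `frequencies` (Hz),
#'   `values_db`, `n_lines_averaged`.
#' @export
estimate_power_spectrum <- function(rf_window, acq) {
  rf_window <- as.matrix(rf_window)
  if (ncol(rf_window) < 2L) stop("window must span at least 2 scan lines")
  if (all(rf_window == 0)) stop("window is identically zero: power spectrum undefined")
  n <- nrow(rf_window)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))   # Hann
  X <- stats::mvfft(rf_window * w)
  p <- rowMeans(abs(X)^2) / sum(w^2)
  nb <- floor(n / 2) + 1L
  structure(
    list(frequencies = acq$sampling_rate * (0:(nb - 1)) / n,
         values_db = 10 * log10(pmax(p[seq_len(nb)], .Machine$double.xmin)),
         n_lines_averaged = ncol(rf_window)),
    class = "power_spectrum"
  )
}

#' Reference-phantom normalization of a power spectrum
#'
#' Divides the sample spectrum by the phantom spectrum (a dB subtraction),
#' cancelling the system and pulse response; optionally restricted to the
#' analysis band.
#'
#' @param sample,reference `power_spectrum` objects on identical grids.
#' @param band Optional length-2 numeric band (Hz) to restrict to.
#' @return A `power_spectrum` of the dB ratio.
#' @export
normalize_spectrum <- function(sample, reference, band = NULL) {
  if (length(sample$frequencies) != length(reference$frequencies) ||
      any(abs(sample$frequencies - reference$frequencies) > 1e-6)) {
    stop("sample and reference spectra are on different frequency grids")
  }
  f <- sample$frequencies
  v <- sample$values_db - reference$values_db
  if (!is.null(band)) {
    keep <- f >= band[1] & f <= band[2]
    if (sum(keep) < 2L) stop("analysis band contains fewer than 2 frequency bins")
    f <- f[keep]; v <- v[keep]
  }
  structure(list(frequencies = f, values_db = v,
                 n_lines_averaged = sample$n_lines_averaged),
            class = "power_spectrum")
}

#' Attenuation coefficient estimate by spectral difference
#'
#' Regresses the normalized dB spectrum against depth at each frequency. Over
#' a pulse-echo path the excess attenuation relative to the reference is
#' 4 z_cm f_MHz alpha dB, so alpha = -slope / (4 f), averaged over the band
#' and clamped at zero.
#'
#' @param spectra Numeric matrix of normalized dB spectra, one row per depth
#'   group, columns on `frequencies`.
#' @param depths_cm Depth (cm) of each row's window centre.
#' @param frequencies Frequency grid in Hz.
#' @return List with `ace` (dB/cm/MHz) and the per-frequency slopes.
#' @export
estimate_ace <- function(spectra, depths_cm, frequencies) {
  spectra <- as.matrix(spectra)
  if (length(unique(depths_cm)) < 2L) {
    stop("attenuation estimation needs spectra from at least 2 distinct depths")
  }
  zc <- depths_cm - mean(depths_cm)
  slopes <- as.numeric(crossprod(zc, spectra)) / sum(zc^2)  # dB per cm, per f
  ace <- mean(-slopes / (4 * frequencies / 1e6))
  list(ace = max(0, ace), slopes_db_per_cm = slopes)
}

#' Apply attenuation correction to a normalized spectrum
#'
#' Adds back the pulse-echo attenuation loss 4 alpha z_cm f_MHz dB.
#'
#' @param spectrum A `power_spectrum`.
#' @param ace Attenuation coefficient in dB/cm/MHz.
#' @param depth_cm Window centre depth in cm (>= 0).
#' @return Corrected `power_spectrum`.
#' @export
attenuation_correct <- function(spectrum, ace, depth_cm) {
  if (depth_cm < 0) stop("depth must be >= 0")
  spectrum$values_db <- spectrum$values_db +
    4 * ace * depth_cm * spectrum$frequencies / 1e6
  spectrum
}

#' Linear spectral fit: mid-band fit, slope and intercept
#'
#' Ordinary least squares of the corrected dB spectrum against frequency in
#' MHz over the analysis band. SS is the slope (dB/MHz), SI the intercept at
#' 0 MHz (dB), and MBF the fitted value at the band centre, so
#' MBF = SS f_c + SI holds by construction.
#'
#' @param spectrum A `power_spectrum` (already band-restricted or not).
#' @param band Length-2 numeric analysis band in Hz.
#' @return List with `mbf`, `ss`, `si`, `f_c_mhz`.
#' @export
fit_spectral_line <- function(spectrum, band) {
  keep <- spectrum$frequencies >= band[1] & spectrum$frequencies <= band[2]
  f <- spectrum$frequencies[keep] / 1e6
  y <- spectrum$values_db[keep]
  if (length(f) < 3L) stop("spectral line fit needs at least 3 bins in band")
  fm <- mean(f)
  ss <- sum((f - fm) * (y - mean(y))) / sum((f - fm)^2)
  si <- mean(y) - ss * fm
  f_c <- mean(band) / 1e6
  list(mbf = ss * f_c + si, ss = ss, si = si, f_c_mhz = f_c)
}

#' Scatterer spacing estimate from spectral periodicity
#'
#' Regularly spaced scatterers imprint a comb of period delta_f = c / (2 d)
#' on the power spectrum. The dB band spectrum is detrended by its own
#' linear fit (removing pulse and residual attenuation tilt) and its
#' periodicity is measured with a normalized harmonic periodogram on a
#' continuous grid of candidate spacings,
#' r(d) = sum_h 2 |sum_j x_j exp(-2 pi i h f_j / delta_f(d))|^2 /
#' (n sum_j x_j^2), pooling `harmonics` comb harmonics -- a band-limited
#' cepstral peak detector (r = 1 at the true period for an exactly
#' sinusoidal log-spectrum such as cos(2 pi f / delta_f)). Since a comb of
#' period delta_f also phase-aligns at spacings 2d, 3d, ..., the fundamental
#' is taken as the smallest spacing among strong local maxima that is an
#' integer submultiple of the best-scoring one. A window is valid only if
#' the score reaches `peak_min` and remains above `jk_min` when any third of
#' the band is jackknifed out (a genuine comb spans the whole band, a
#' speckle lump does not); fully diffuse media are flagged invalid in the
#' large majority of windows. Candidates need at least 1.5 comb periods in
#' the band and a period above two frequency bins.
#'
#' @param spectrum Band-restricted normalized `power_spectrum`.
#' @param acq An `acquisition_spec`.
#' @param spacing_range_mm Length-2 search range in mm.
#' @param peak_min Minimum periodicity score of the peak.
#' @param n_candidates Number of candidate spacings searched.
#' @param harmonics Number of comb harmonics pooled into the score.
#' @param jk_min Minimum score after leaving out any third of the band.
#' @return List with `sas` (m), `valid`, `delta_f` (Hz), `peak`.
#' @export
estimate_sas <- function(spectrum, acq, spacing_range_mm = c(0.1, 2),
                         peak_min = 0.45, n_candidates = 160L,
                         harmonics = 2L, jk_min = 0.4) {
  invalid <- list(sas = NA_real_, valid = FALSE, delta_f = NA_real_,
                  peak = NA_real_)
  f <- spectrum$frequencies
  n <- length(f)
  if (n < 5L) return(invalid)
  detrend <- function(ff, y) {
    fm <- mean(ff); ym <- mean(y)
    b <- sum((ff - fm) * (y - ym)) / sum((ff - fm)^2)
    y - ym - b * (ff - fm)
  }
  x <- detrend(f, spectrum$values_db)
  if (sum(x^2) == 0) return(invalid)
  score <- function(ff, xx, period, n_harm = harmonics) {
    s <- 0
    for (h in seq_len(n_harm)) {
      z <- sum(xx * exp(-2i * pi * h * ff / period))
      s <- s + 2 * Mod(z)^2 / (length(xx) * sum(xx^2))
    }
    s
  }
  df <- f[2] - f[1]
  bw <- f[n] - f[1]
  d_cand <- seq(spacing_range_mm[1], spacing_range_mm[2],
                length.out = n_candidates) * 1e-3
  period <- acq$sound_speed / (2 * d_cand)
  ok <- (bw / period) >= 1.5 & period >= 2 * df
  if (!any(ok)) return(invalid)
  # peak location on the single-harmonic curve (pooling harmonics would tie
  # the true spacing with its half); validity on the pooled score below
  r <- rep(NA_real_, n_candidates)
  for (i in which(ok)) r[i] <- score(f, x, period[i], 1L)
  kmax <- which.max(r)
  if (!is.finite(r[kmax])) {
    return(invalid)
  }
  # fundamental selection among the harmonic family of the best candidate
  loc <- which(ok & r >= 0.6 * r[kmax])
  is_lmax <- vapply(loc, function(i) {
    lo <- if (i > 1 && is.finite(r[i - 1])) r[i - 1] else -Inf
    hi <- if (i < n_candidates && is.finite(r[i + 1])) r[i + 1] else -Inf
    r[i] >= lo && r[i] >= hi
  }, logical(1))
  loc <- loc[is_lmax]
  rat <- d_cand[kmax] / d_cand[loc]
  loc <- loc[abs(rat - round(rat)) <= 0.08 * round(rat)]
  k <- if (length(loc)) loc[which.min(d_cand[loc])] else kmax
  rp <- score(f, x, period[k])
  # jackknife: the periodicity must persist with any third of the band out
  thirds <- split(seq_len(n), cut(seq_len(n), 3))
  jk <- vapply(thirds, function(ii) {
    ff <- f[-ii]
    score(ff, detrend(ff, spectrum$values_db[-ii]), period[k])
  }, numeric(1))
  if (rp < peak_min || min(jk) < jk_min) {
    return(list(sas = NA_real_, valid = FALSE, delta_f = NA_real_,
                peak = rp))
  }
  delta_f <- .refine_comb_period(f, spectrum$values_db, period[k])
  list(sas = acq$sound_speed / (2 * delta_f), valid = TRUE,
       delta_f = delta_f, peak = r[k])
}

# Sub-bin refinement of the comb period: the separation of the actual
# spectral teeth (parabolically interpolated local maxima within 8 dB of the
# strongest), median over consecutive separations close to the periodogram
# period. Falls back to the periodogram period when no clean tooth pair
# exists.
.refine_comb_period <- function(f, y, T0) {
  n <- length(y)
  df <- f[2] - f[1]
  pk <- c(); ph <- c()
  for (i in 2:(n - 1)) {
    if (y[i] > y[i - 1] && y[i] >= y[i + 1]) {
      den <- y[i - 1] - 2 * y[i] + y[i + 1]
      delta <- if (den < 0) 0.5 * (y[i - 1] - y[i + 1]) / den else 0
      pk <- c(pk, f[i] + delta * df)
      ph <- c(ph, y[i])
    }
  }
  pk <- pk[ph >= max(ph) - 8]
  if (length(pk) >= 2L) {
    dd <- diff(pk)
    dd <- dd[abs(dd - T0) < 0.25 * T0]
    if (length(dd)) return(stats::median(dd))
  }
  T0
}

#' Effective scatterer diameter and acoustic concentration
#'
#' Fits the spherical-Gaussian backscatter model
#' dB(f) = 10 log10(f_MHz^4 exp(-0.827 (k a / 2)^2)) + A, k = 2 pi f / c,
#' by log-spaced grid search over the effective diameter a with one local
#' refinement, choosing the amplitude A in closed form (mean dB residual) at
#' each a. ASD is the minimizing a; AAC is the fitted amplitude in dB
#' (nominally dB/cm^3). When the input is a phantom-normalized ratio the
#' reference's Rayleigh f^4 dB shape is first restored
#' (`phantom_rayleigh = TRUE`), which is how parametric-map extraction calls
#' it; direct spectra synthesized from the model are fitted as-is.
#'
#' @param spectrum Band-restricted corrected `power_spectrum`.
#' @param acq An `acquisition_spec`.
#' @param diam_range_um Length-2 diameter search range in micrometres.
#' @param n_grid Points in the first (log-spaced) grid.
#' @param phantom_rayleigh Add 40 log10(f_MHz) before fitting (reference
#'   phantom of sub-resolution Rayleigh scatterers).
#' @return List with `asd` (m), `aac` (dB), `valid` (FALSE when pinned at the
#'   search boundary), `mse`.
#' @export
fit_form_factor <- function(spectrum, acq, diam_range_um = c(1, 300),
                            n_grid = 64L, phantom_rayleigh = FALSE) {
  f <- spectrum$frequencies
  y <- spectrum$values_db
  if (!all(is.finite(y))) stop("spectrum contains non-finite values")
  if (phantom_rayleigh) y <- y + 40 * log10(f / 1e6)
  k <- 2 * pi * f / acq$sound_speed
  base_db <- 40 * log10(f / 1e6)
  eval_a <- function(a_m) {
    shape <- base_db - 10 * 0.827 * (k * a_m / 2)^2 / log(10)
    A <- mean(y - shape)
    c(mse = mean((y - shape - A)^2), A = A)
  }
  search <- function(grid) {
    res <- vapply(grid, eval_a, numeric(2))
    i <- which.min(res["mse", ])
    list(a = grid[i], i = i, A = res["A", i], mse = res["mse", i])
  }
  grid1 <- exp(seq(log(diam_range_um[1] * 1e-6), log(diam_range_um[2] * 1e-6),
                   length.out = n_grid))
  s1 <- search(grid1)
  lo <- grid1[max(1L, s1$i - 1L)]
  hi <- grid1[min(n_grid, s1$i + 1L)]
  s2 <- search(seq(lo, hi, length.out = 33L))
  pinned <- s1$i == 1L || s1$i == n_grid
  list(asd = unname(s2$a), aac = unname(s2$A), valid = !pinned,
       mse = unname(s2$mse))
}
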