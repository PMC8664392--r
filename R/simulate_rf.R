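#' Scatterer field for RF simulation
#'
#' A 2D field of sub-resolution point scatterers with positions in metres
#' (axial depth, lateral offset), per-scatterer amplitudes, and optional
#' structural descriptors used as ground truth when testing the spectral
#' estimators: `mean_spacing` (dominant axial periodicity), `number_density`
#' (scatterers per m^2) and `effective_diameter` (Gaussian form-factor size
#' applied to the whole field).
#'
#' @param positions Two-column matrix, (axial m, lateral m) per scatterer.
#' @param amplitudes Numeric vector of scattering amplitudes.
#' @param extent Length-2 numeric, field size (axial m, lateral m).
#' @param mean_spacing Dominant axial spacing in m, or NA for diffuse fields.
#' @param number_density Scatterers per m^2.
#' @param effective_diameter Effective scatterer diameter in m (0 = point).
#' @return An object of class `scatterer_field`.
#' @export
scatterer_field <- function(positions, amplitudes, extent,
                            mean_spacing = NA_real_,
                            number_density = nrow(positions) / prod(extent),
                            effective_diameter = 0) {
  positions <- as.matrix(positions)
  if (nrow(positions) == 0L) stop("scatterer field is empty")
  stopifnot(ncol(positions) == 2L, length(amplitudes) == nrow(positions))
  if (!all(is.finite(amplitudes))) stop("amplitudes must be finite")
  if (any(positions[, 1] < 0 | positions[, 1] > extent[1]) ||
      any(positions[, 2] < 0 | positions[, 2] > extent[2])) {
    stop("scatterer positions outside stated extent")
  }
  if (number_density <= 0) stop("number_density must be positive")
  structure(
    list(positions = positions, amplitudes = amplitudes, extent = extent,
         mean_spacing = mean_spacing, number_density = number_density,
         effective_diameter = effective_diameter),
    class = "scatterer_field"
  )
}

#' Diffuse random scatterer field
#'
#' Uniform random positions with zero-mean Gaussian amplitudes: many
#' scatterers per resolution cell produce fully developed speckle, the
#' incoherent regime in which band power is proportional to number density.
#'
#' @param extent Field extent (axial m, lateral m).
#' @param density Scatterers per m^2.
#' @param seed Integer seed.
#' @param amplitude_sd Amplitude standard deviation.
#' @param effective_diameter Effective scatterer diameter in m.
#' @param amplitude_envelope Optional function (axial m, lateral m) ->
#'   multiplicative amplitude factor, used to inject spatial heterogeneity.
#' @return A `scatterer_field`.
#' @export
diffuse_field <- function(extent, density = 3e8, seed = 1L,
                          amplitude_sd = 1, effective_diameter = 0,
                          amplitude_envelope = NULL) {
  set.seed(seed)
  n <- max(1L, stats::rpois(1, density * prod(extent)))
  pos <- cbind(stats::runif(n, 0, extent[1]), stats::runif(n, 0, extent[2]))
  amp <- stats::rnorm(n, 0, amplitude_sd)
  if (!is.null(amplitude_envelope)) amp <- amp * amplitude_envelope(pos[, 1], pos[, 2])
  scatterer_field(pos, amp, extent, number_density = density,
                  effective_diameter = effective_diameter)
}

#' Regularly spaced scatterer field
#'
#' Axial lattice of scatterers with spacing `spacing` (optionally jittered),
#' repeated on every scan line, optionally superimposed on a diffuse
#' background. The regular component makes the averaged power spectrum a
#' frequency comb with period c / (2 spacing), the signature the scatterer
#' spacing estimator recovers.
#'
#' @param extent Field extent (axial m, lateral m).
#' @param spacing Axial spacing in m.
#' @param acq An `acquisition_spec` (for line placement).
#' @param seed Integer seed.
#' @param jitter_sd Axial position jitter sd, as a fraction of spacing.
#' @param amplitude Amplitude of the regular scatterers.
#' @param diffuse_density Density of an added diffuse background (0 = none).
#' @param diffuse_sd Amplitude sd of the diffuse background.
#' @return A `scatterer_field` with `mean_spacing` set.
#' @export
regular_field <- function(extent, spacing, acq, seed = 1L, jitter_sd = 0,
                          amplitude = 1, diffuse_density = 0, diffuse_sd = 1) {
  set.seed(seed)
  n_lines <- max(1L, floor(extent[2] / acq$line_pitch))
  z0 <- stats::runif(1, 0, spacing)
  z <- seq(z0, extent[1], by = spacing)
  pos <- NULL
  amp <- NULL
  for (j in seq_len(n_lines)) {
    zj <- z + if (jitter_sd > 0) stats::rnorm(length(z), 0, jitter_sd * spacing) else 0
    zj <- zj[zj >= 0 & zj <= extent[1]]
    pos <- rbind(pos, cbind(zj, rep((j - 0.5) * acq$line_pitch, length(zj))))
    amp <- c(amp, amplitude * stats::runif(length(zj), 0.8, 1.2))
  }
  if (diffuse_density > 0) {
    bg <- diffuse_field(extent, diffuse_density, seed = seed + 1L,
                        amplitude_sd = diffuse_sd)
    pos <- rbind(pos, bg$positions)
    amp <- c(amp, bg$amplitudes)
  }
  scatterer_field(pos, amp, extent, mean_spacing = spacing,
                  number_density = nrow(pos) / prod(extent))
}

#' One beamformed RF echo frame
#'
#' @param samples Numeric matrix, axial sample x scan line.
#' @param acq The `acquisition_spec` the frame was recorded with.
#' @param frame_id Identifier string.
#' @param attenuation True attenuation used in simulation, dB/cm/MHz.
#' @return An object of class `rf_frame`.
#' @export
rf_frame <- function(samples, acq, frame_id = "frame", attenuation = 0) {
  samples <- as.matrix(samples)
  if (!all(is.finite(samples))) stop("RF samples must be finite")
  structure(
    list(samples = samples, acquisition = acq, frame_id = frame_id,
         attenuation = attenuation),
    class = "rf_frame"
  )
}

# Hermitian frequency response combining linear-in-frequency attenuation
# (dB/cm/MHz over a pulse-echo path 2 z) and a Gaussian form factor of
# effective diameter a: amplitude sqrt(F), F = exp(-0.827 (k a / 2)^2).
.depth_filter <- function(n, acq, attenuation, depth_m, diameter_m) {
  f <- acq$sampling_rate * (0:(n - 1)) / n
  f <- pmin(f, acq$sampling_rate - f)      # symmetric -> real impulse response
  h <- rep(1, n)
  if (attenuation > 0) {
    db <- attenuation * (f / 1e6) * (4 * depth_m * 100)   # power dB, round trip
    h <- h * 10^(-db / 20)
  }
  if (diameter_m > 0) {
    k <- 2 * pi * f / acq$sound_speed
    h <- h * exp(-0.827 * (k * diameter_m / 2)^2 / 2)
  }
  h
}

#' Simulate one RF frame from a scatterer field
#'
#' Per scan line, the scatterer impulse train (linearly interpolated onto the
#' sample grid at pulse-echo delay 2 z / c) is convolved with the emission
#' pulse. Frequency-dependent attenuation and the field's Gaussian
#' form-factor size filter are applied cumulatively with depth, in blocks of
#' `block_samples` axial samples so the filter is evaluated at each block's
#' centre depth. Optional white electronic noise is added last.
#'
#' @param field A `scatterer_field`.
#' @param pulse A `pulse_model`.
#' @param acq An `acquisition_spec`.
#' @param attenuation Attenuation coefficient in dB/cm/MHz (>= 0).
#' @param seed Integer seed (controls additive noise only).
#' @param noise_sd Additive white-noise sd, in units of RF amplitude.
#' @param n_lines Number of scan lines; default spans the field laterally.
#' @param block_samples Axial block length for depth-dependent filtering.
#' @param frame_id Identifier string.
#' @return An `rf_frame`.
#' @export
simulate_rf_frame <- function(field, pulse, acq, attenuation = 0, seed = 1L,
                              noise_sd = 0, n_lines = NULL,
                              block_samples = 128L, frame_id = "frame") {
  if (!inherits(field, "scatterer_field")) stop("field must be a scatterer_field")
  if (attenuation < 0) stop("attenuation must be >= 0")
  set.seed(seed)
  dz <- axial_sample_m(acq)
  n_samp <- ceiling(field$extent[1] / dz) + 1L
  if (is.null(n_lines)) n_lines <- max(1L, floor(field$extent[2] / acq$line_pitch))

  # impulse train, linear split between the two straddling samples
  line <- pmin(pmax(floor(field$positions[, 2] / acq$line_pitch) + 1L, 1L), n_lines)
  s <- field$positions[, 1] / dz + 1
  s0 <- floor(s)
  frac <- s - s0
  train <- matrix(0, n_samp + 1L, n_lines)
  # rowsum() accumulates scatterers that land on the same (sample, line) cell
  ii <- c(s0, s0 + 1L) + (rep(line, 2L) - 1L) * (n_samp + 1L)
  vv <- c(field$amplitudes * (1 - frac), field$amplitudes * frac)
  agg <- rowsum(vv, ii)
  train[as.integer(rownames(agg))] <- agg
  train <- train[seq_len(n_samp), , drop = FALSE]

  pw <- sample_pulse(pulse, acq)
  nfft <- stats::nextn(n_samp + length(pw$waveform), 2)
  P <- stats::fft(c(pw$waveform, rep(0, nfft - length(pw$waveform))))

  pad <- function(m) rbind(m, matrix(0, nfft - nrow(m), ncol(m)))
  depth_dependent <- attenuation > 0 || field$effective_diameter > 0
  if (!depth_dependent) {
    Y <- stats::mvfft(pad(train)) * P
    rf_full <- Re(stats::mvfft(Y, inverse = TRUE)) / nfft
  } else {
    rf_full <- matrix(0, nfft, n_lines)
    starts <- seq(1L, n_samp, by = block_samples)
    for (b in starts) {
      rows <- b:min(b + block_samples - 1L, n_samp)
      blk <- matrix(0, n_samp, n_lines)
      blk[rows, ] <- train[rows, , drop = FALSE]
      if (all(blk == 0)) next
      z_mid <- (mean(rows) - 1) * dz
      H <- .depth_filter(nfft, acq, attenuation, z_mid, field$effective_diameter)
      Y <- stats::mvfft(pad(blk)) * (P * H)
      rf_full <- rf_full + Re(stats::mvfft(Y, inverse = TRUE)) / nfft
    }
  }
  # align so a scatterer at depth z peaks at sample 2 z / c * fs
  rf <- rf_full[(pw$center):(pw$center + n_samp - 1L), , drop = FALSE]
  if (noise_sd > 0) rf <- rf + matrix(stats::rnorm(length(rf), 0, noise_sd), nrow(rf))
  rf_frame(rf, acq, frame_id = frame_id, attenuation = attenuation)
}

#' Reference phantom frames for spectral normalization
#'
#' Simulates a tissue-mimicking phantom: a dense diffuse field of point
#' scatterers with known (default zero) attenuation, scanned repeatedly so
#' window spectra can be averaged across frames. Normalizing a sample
#' spectrum by the matched-depth phantom spectrum removes the system and
#' pulse response.
#'
#' @param acq An `acquisition_spec`.
#' @param pulse A `pulse_model`.
#' @param seed Integer seed.
#' @param n_frames Number of phantom frames (>= 5 recommended).
#' @param extent Phantom extent (axial m, lateral m).
#' @param density Scatterer density per m^2.
#' @param attenuation Phantom attenuation in dB/cm/MHz.
#' @return List of `rf_frame` objects.
#' @export
make_reference_frames <- function(acq, pulse, seed = 1L, n_frames = 5L,
                                  extent = c(0.018, 0.0096), density = 3e8,
                                  attenuation = 0) {
  set.seed(seed)
  frame_seeds <- sample.int(2^30, n_frames)
  lapply(seq_len(n_frames), function(i) {
    f <- diffuse_field(extent, density, seed = frame_seeds[i])
    simulate_rf_frame(f, pulse, acq, attenuation = attenuation,
                      seed = frame_seeds[i],
                      frame_id = sprintf("phantom-%02d", i))
  })
}

#' Quantize an RF frame to its digitizer bit depth
#'
#' Scales the frame to the signed integer range of the acquisition's bit
#' depth and rounds, returning the integer samples and the scale needed to
#' invert. Used when frames are written to a scan container.
#'
#' @param frame An `rf_frame`.
#' @return List with `samples` (integer matrix) and `scale`.
#' @export
quantize_frame <- function(frame) {
  half <- 2^(frame$acquisition$bit_depth - 1) - 1
  m <- max(abs(frame$samples))
  scale <- if (m > 0) m / half else 1
  list(samples = matrix(as.integer(round(frame$samples / scale)),
                        nrow(frame$samples)),
       scale = scale)
}
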