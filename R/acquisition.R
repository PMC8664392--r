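#' Acquisition metadata for an RF scan
#'
#' Bundles the transducer and digitizer settings every downstream estimator
#' needs: sampling rate, pulse centre frequency, usable analysis band, assumed
#' speed of sound, digitizer bit depth and lateral line pitch. Defaults mirror
#' a clinical linear-array acquisition: 7 MHz centre frequency with a 4-9 MHz
#' band, sampled at 40 MHz with 16-bit resolution.
#'
#' @param sampling_rate Digitizer sampling rate in Hz.
#' @param center_frequency Transducer centre frequency in Hz.
#' @param analysis_band Length-2 numeric, analysis band (low, high) in Hz.
#' @param sound_speed Assumed speed of sound in m/s (soft-tissue convention).
#' @param bit_depth Digitizer resolution, 8 or 16 bits.
#' @param line_pitch Lateral spacing between scan lines in m.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(sampling_rate = 40e6,
                             center_frequency = 7e6,
                             analysis_band = c(4e6, 9e6),
                             sound_speed = 1540,
                             bit_depth = 16L,
                             line_pitch = 1e-4) {
  stopifnot(length(analysis_band) == 2L)
  analysis_band <- as.numeric(analysis_band)
  if (!(analysis_band[1] < center_frequency &&
        center_frequency < analysis_band[2])) {
    stop("analysis_band must bracket center_frequency")
  }
  if (sampling_rate <= 2 * analysis_band[2]) {
    stop("sampling_rate must exceed twice the upper band edge")
  }
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (line_pitch <= 0) stop("line_pitch must be positive")
  structure(
    list(sampling_rate = sampling_rate,
         center_frequency = center_frequency,
         analysis_band = analysis_band,
         sound_speed = sound_speed,
         bit_depth = as.integer(bit_depth),
         line_pitch = line_pitch),
    class = "acquisition_spec"
  )
}

#' Axial extent of one RF sample
#'
#' Pulse-echo depth step per sample, c / (2 fs), in metres.
#' @param acq An `acquisition_spec`.
#' @return Metres per axial sample.
#' @export
axial_sample_m <- function(acq) acq$sound_speed / (2 * acq$sampling_rate)

#' Gaussian-enveloped emission pulse model
#'
#' The pulse is a Gaussian-windowed sinusoid; `fractional_bandwidth` is the
#' -6 dB (amplitude) fractional bandwidth of its spectrum. The default 0.71
#' places the -6 dB points of a 7 MHz pulse roughly at 4.5 and 9.5 MHz so the
#' 4-9 MHz analysis band carries usable energy.
#'
#' @param center_frequency Pulse centre frequency in Hz.
#' @param fractional_bandwidth -6 dB fractional bandwidth, in (0, 2).
#' @return An object of class `pulse_model`.
#' @export
pulse_model <- function(center_frequency = 7e6, fractional_bandwidth = 0.71) {
  if (fractional_bandwidth <= 0 || fractional_bandwidth >= 2) {
    stop("fractional_bandwidth must be in (0, 2)")
  }
  structure(
    list(center_frequency = center_frequency,
         fractional_bandwidth = fractional_bandwidth),
    class = "pulse_model"
  )
}

#' Sample a pulse waveform at the acquisition rate
#'
#' Returns the time-domain pulse and the index of its centre sample. The
#' Gaussian envelope sd in time is chosen so the amplitude spectrum has the
#' requested -6 dB fractional bandwidth: sigma_f = B f0 / (2 sqrt(2 ln 2))
#' with the -6 dB width 2 sqrt(2 ln(10^0.3)) sigma_f.
#'
#' @param pulse A `pulse_model`.
#' @param acq An `acquisition_spec`.
#' @return List with `waveform` (numeric vector) and `center` (1-based index).
#' @export
sample_pulse <- function(pulse, acq) {
  f0 <- pulse$center_frequency
  bw_hz <- pulse$fractional_bandwidth * f0
  # -6 dB amplitude full width of a Gaussian |P(f)| = exp(-(f-f0)^2/(2 s^2))
  sigma_f <- bw_hz / (2 * sqrt(2 * log(10^(6 / 20))))
  sigma_t <- 1 / (2 * pi * sigma_f)
  half <- ceiling(4 * sigma_t * acq$sampling_rate)
  t <- (-half:half) / acq$sampling_rate
  w <- exp(-t^2 / (2 * sigma_t^2)) * cos(2 * pi * f0 * t)
  list(waveform = w, center = half + 1L)
}
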