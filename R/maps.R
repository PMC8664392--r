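#' Parametric map of one QUS parameter on a sub-ROI grid
#'
#' @param parameter_name One of MBF, SS, SI, SAS, ASD, AAC.
#' @param values Numeric matrix on the grid shape.
#' @param valid_mask Logical matrix, TRUE where the value is usable.
#' @return An object of class `parametric_map`.
#' @export
parametric_map <- function(parameter_name, values, valid_mask) {
  stopifnot(is.matrix(values), identical(dim(values), dim(valid_mask)))
  if (any(!is.finite(values[valid_mask]))) {
    stop("parametric map has non-finite values flagged valid")
  }
  structure(list(parameter_name = parameter_name, values = values,
                 valid_mask = valid_mask),
            class = "parametric_map")
}

#' Default spectral/texture analysis configuration
#'
#' Bundles the tunable analysis settings: 2 mm x 2 mm windows at 94% overlap
#' over a 4-9 MHz band (the clinical protocol), scatterer-spacing search in
#' 0.1-2 mm, diameter search 1-300 um, 16 gray levels, displacement 1, the
#' four GLCM angles, and a 5 x 5-cell local window for regenerated texture
#' maps. Any element can be overridden via `...`.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of settings.
#' @export
qus_config <- function(...) {
  cfg <- list(
    window_mm = c(2, 2),
    overlap = 0.94,
    band = c(4e6, 9e6),
    sas_range_mm = c(0.1, 2),
    sas_peak_min = 0.45,
    sas_neighborhood = 1L,
    sas_gate_factor = 3L,
    asd_range_um = c(1, 300),
    n_levels = 16L,
    displacement = 1L,
    angles = c(0, 45, 90, 135),
    neighborhood = 5L,
    knn_k = 3L,
    svm_cost = 1,
    max_features = 3L,
    n_subsets = NULL
  )
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

# Average phantom window spectrum at one axial origin: per-line periodograms
# pooled over all lateral positions and frames.
.reference_spectrum <- function(reference_frames, origin_ax, win_samples, acq) {
  acc <- NULL
  n <- 0L
  for (fr in reference_frames) {
    win <- fr$samples[origin_ax:(origin_ax + win_samples - 1L), , drop = FALSE]
    ps <- estimate_power_spectrum(win, acq)
    p <- 10^(ps$values_db / 10) * ps$n_lines_averaged
    acc <- if (is.null(acc)) p else acc + p
    n <- n + ps$n_lines_averaged
    freqs <- ps$frequencies
  }
  structure(list(frequencies = freqs, values_db = 10 * log10(acc / n),
                 n_lines_averaged = n),
            class = "power_spectrum")
}

#' Build the six QUS parametric maps and the frame attenuation estimate
#'
#' Runs the sliding-window spectral pipeline over one frame: per-window
#' averaged periodograms, reference-phantom normalization at matched depth,
#' one frame-level attenuation estimate from depth-grouped spectra, per-window
#' attenuation correction, then the linear fit (MBF/SS/SI), scatterer-spacing
#' and form-factor (ASD/AAC) estimators. Estimator failures become invalid
#' map cells rather than errors.
#'
#' @param frame An `rf_frame`.
#' @param roi Logical ROI mask matching the frame.
#' @param reference_frames List of phantom `rf_frame`s.
#' @param config A `qus_config()` list.
#' @return List with `maps` (named list of 6 `parametric_map`s), `ace`
#'   (dB/cm/MHz), and the `grid`.
#' @export
build_parametric_maps <- function(frame, roi, reference_frames, config = qus_config()) {
  acq <- frame$acquisition
  grid <- make_subroi_grid(roi, acq, config$window_mm, config$overlap)
  wa <- grid$win_samples; wl <- grid$win_lines
  band <- config$band

  ref_cache <- new.env(parent = emptyenv())
  ref_at <- function(a) {
    key <- as.character(a)
    if (is.null(ref_cache[[key]])) {
      ref_cache[[key]] <- .reference_spectrum(reference_frames, a, wa, acq)
    }
    ref_cache[[key]]
  }

  shape <- grid$shape
  idx <- which(grid$in_roi, arr.ind = TRUE)
  depths_cm <- numeric(nrow(idx))
  norm_db <- NULL                       # windows x frequency bins
  for (w in seq_len(nrow(idx))) {
    a <- grid$origin_ax[idx[w, 1]]
    l <- grid$origin_lat[idx[w, 2]]
    win <- frame$samples[a:(a + wa - 1L), l:(l + wl - 1L), drop = FALSE]
    sp <- estimate_power_spectrum(win, acq)
    ns <- normalize_spectrum(sp, ref_at(a), band = band)
    if (is.null(norm_db)) {
      freqs <- ns$frequencies
      norm_db <- matrix(NA_real_, nrow(idx), length(freqs))
    }
    norm_db[w, ] <- ns$values_db
    depths_cm[w] <- (a + (wa - 1) / 2) * axial_sample_m(acq) * 100
  }

  # frame-level ACE from depth-grouped normalized spectra
  ace <- 0
  dgroups <- split(seq_len(nrow(idx)), depths_cm)
  if (length(dgroups) >= 2L) {
    gmat <- t(vapply(dgroups, function(ii) {
      colMeans(norm_db[ii, , drop = FALSE])
    }, numeric(length(freqs))))
    ace <- estimate_ace(gmat, as.numeric(names(dgroups)), freqs)$ace
  }

  # Dedicated spectra for the scatterer-spacing stage: a longer axial gate
  # (finer frequency resolution, as spacing estimators require) centred on
  # each window, normalized at matched depth, stored on the grid in linear
  # power for neighbourhood averaging.
  gate_mult <- config$sas_gate_factor %||% 3L
  wa_s <- min(gate_mult * wa, nrow(frame$samples))
  ref_s_cache <- new.env(parent = emptyenv())
  sas_freqs <- NULL
  lin <- NULL
  for (w in seq_len(nrow(idx))) {
    a <- grid$origin_ax[idx[w, 1]]
    l <- grid$origin_lat[idx[w, 2]]
    a0 <- min(max(1L, a - (wa_s - wa) %/% 2L), nrow(frame$samples) - wa_s + 1L)
    win <- frame$samples[a0:(a0 + wa_s - 1L), l:(l + wl - 1L), drop = FALSE]
    sp <- estimate_power_spectrum(win, acq)
    key <- as.character(a0)
    if (is.null(ref_s_cache[[key]])) {
      ref_s_cache[[key]] <- .reference_spectrum(reference_frames, a0, wa_s, acq)
    }
    ns <- normalize_spectrum(sp, ref_s_cache[[key]], band = band)
    if (is.null(lin)) {
      sas_freqs <- ns$frequencies
      lin <- array(NA_real_, c(shape[1], shape[2], length(sas_freqs)))
    }
    lin[idx[w, 1], idx[w, 2], ] <- 10^(ns$values_db / 10)
  }

  new_layer <- function() matrix(NA_real_, shape[1], shape[2])
  vals <- list(MBF = new_layer(), SS = new_layer(), SI = new_layer(),
               SAS = new_layer(), ASD = new_layer(), AAC = new_layer())
  ok <- lapply(vals, function(x) matrix(FALSE, shape[1], shape[2]))

  navg <- config$sas_neighborhood %||% 1L
  for (w in seq_len(nrow(idx))) {
    i <- idx[w, 1]; j <- idx[w, 2]
    sp <- structure(list(frequencies = freqs, values_db = norm_db[w, ],
                         n_lines_averaged = wl),
                    class = "power_spectrum")
    sp <- attenuation_correct(sp, ace, depths_cm[w])
    res <- try({
      fit <- fit_spectral_line(sp, band)
      vals$MBF[i, j] <- fit$mbf; ok$MBF[i, j] <- TRUE
      vals$SS[i, j] <- fit$ss;   ok$SS[i, j] <- TRUE
      vals$SI[i, j] <- fit$si;   ok$SI[i, j] <- TRUE
      # SAS on the neighbourhood-averaged spectrum: the heavy window overlap
      # makes adjacent sub-ROIs near-replicates, and averaging stabilizes the
      # comb against speckle
      ii <- max(1L, i - navg):min(shape[1], i + navg)
      jj <- max(1L, j - navg):min(shape[2], j + navg)
      pavg <- apply(lin[ii, jj, , drop = FALSE], 3, mean, na.rm = TRUE)
      sps <- structure(list(frequencies = sas_freqs,
                            values_db = 10 * log10(pavg),
                            n_lines_averaged = wl),
                       class = "power_spectrum")
      sas <- estimate_sas(sps, acq, config$sas_range_mm, config$sas_peak_min)
      if (sas$valid) { vals$SAS[i, j] <- sas$sas; ok$SAS[i, j] <- TRUE }
      ff <- fit_form_factor(sp, acq, config$asd_range_um, phantom_rayleigh = TRUE)
      if (ff$valid) {
        vals$ASD[i, j] <- ff$asd; ok$ASD[i, j] <- TRUE
        vals$AAC[i, j] <- ff$aac; ok$AAC[i, j] <- TRUE
      }
    }, silent = TRUE)
    if (inherits(res, "try-error")) next
  }

  maps <- lapply(names(vals), function(nm) {
    v <- vals[[nm]]; m <- ok[[nm]]
    v[!m] <- NA_real_
    parametric_map(nm, v, m)
  })
  names(maps) <- names(vals)
  if (all(!ok$MBF)) stop("all sub-ROI windows failed spectral estimation")
  list(maps = maps, ace = ace, grid = grid)
}
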