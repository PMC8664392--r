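#' Specification of a synthetic patient cohort
#'
#' Defines the study conditions the generator emulates: class sizes
#' (default 28 recurrence / 55 non-recurrence), per-class tumour-map
#' heterogeneity, per-class exponential hazards for recurrence-free and
#' overall survival, and a single administrative censoring time. Default
#' hazards are set so the classes' 5-year survivals are about 54%/83% (RFS)
#' and 74%/85% (OS). Acoustic ground truth per patient: a diffuse scatterer
#' field with a quasi-regular axial component (spacing drawn from
#' `spacing_range_mm`), an effective scatterer diameter, an attenuation
#' coefficient, and a log-normal spatial amplitude envelope whose strength
#' (`het_r` vs `het_nr`) is the class-separating property -- recurrence
#' tumours are patchy, non-recurrence tumours near-uniform.
#'
#' @param n_recurrence,n_non_recurrence Patients per class (>= 2 each).
#' @param frames_range Min/max frames (tumour slices) per patient.
#' @param het_r,het_nr Heterogeneity (log-amplitude sd of the spatial
#'   envelope) for the recurrence / non-recurrence class.
#' @param hazard_rfs,hazard_os Named per-class hazards (1/month),
#'   `c(R = ..., NR = ...)`.
#' @param censor_time Administrative censoring time in months.
#' @param extent Frame extent (axial m, lateral m).
#' @param base_density Diffuse scatterer density per m^2.
#' @param diameter_um Effective scatterer diameter in micrometres.
#' @param spacing_range_mm Per-patient dominant scatterer spacing range, mm.
#'   The default 0.3-0.5 mm keeps at least four lattice scatterers and two
#'   comb periods inside one 2 mm analysis window, the regime in which the
#'   spacing estimator can resolve the periodicity.
#' @param lattice_amplitude Amplitude of the quasi-regular scatterer
#'   component relative to the diffuse background sd.
#' @param lattice_jitter Axial jitter of the lattice, fraction of spacing.
#' @param attenuation_range Per-patient attenuation range, dB/cm/MHz.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_recurrence = 28L, n_non_recurrence = 55L,
                        frames_range = c(3L, 7L),
                        het_r = 0.6, het_nr = 0.15,
                        hazard_rfs = c(R = 0.0103, NR = 0.0031),
                        hazard_os = c(R = 0.0050, NR = 0.0027),
                        censor_time = 84,
                        extent = c(0.018, 0.0096),
                        base_density = 1.2e8,
                        diameter_um = 60,
                        spacing_range_mm = c(0.3, 0.5),
                        lattice_amplitude = 5,
                        lattice_jitter = 0.03,
                        attenuation_range = c(0.5, 0.9),
                        seed = 1L) {
  if (n_recurrence < 2L || n_non_recurrence < 2L) {
    stop("each class needs at least 2 patients")
  }
  if (any(hazard_rfs <= 0) || any(hazard_os <= 0)) stop("hazards must be > 0")
  structure(as.list(environment()), class = "cohort_spec")
}

# Smooth log-normal amplitude envelope: coarse Gaussian grid, bilinearly
# interpolated over the field, exponentiated with strength `het`.
.make_envelope <- function(extent, het, grid_n = 6L) {
  g <- matrix(stats::rnorm(grid_n * grid_n), grid_n, grid_n)
  function(z, x) {
    if (het <= 0) return(rep(1, length(z)))
    gi <- pmin(pmax(z / extent[1], 0), 1) * (grid_n - 1) + 1
    gj <- pmin(pmax(x / extent[2], 0), 1) * (grid_n - 1) + 1
    i0 <- pmin(floor(gi), grid_n - 1); fi <- gi - i0
    j0 <- pmin(floor(gj), grid_n - 1); fj <- gj - j0
    v <- g[cbind(i0, j0)] * (1 - fi) * (1 - fj) +
      g[cbind(i0 + 1, j0)] * fi * (1 - fj) +
      g[cbind(i0, j0 + 1)] * (1 - fi) * fj +
      g[cbind(i0 + 1, j0 + 1)] * fi * fj
    exp(het * v)
  }
}

#' Generate a synthetic outcome-labelled cohort of RF scans
#'
#' For each patient: class-dependent acoustic parameters, 3-7 simulated RF
#' frames (tumour slices) with a central rectangular ROI mask, and
#' exponential survival times truncated by administrative censoring. Shared
#' reference-phantom frames are attached for normalization. Deterministic
#' given the spec's seed.
#'
#' @param spec A `cohort_spec`.
#' @param acq An `acquisition_spec`.
#' @param pulse A `pulse_model`.
#' @param simulate_frames Set FALSE to generate outcomes and ground truth
#'   only (no RF simulation), for survival-side experiments.
#' @return An object of class `qus_cohort`: `patients` (list with
#'   `patient_id`, `label`, `truth`, `scans`), `outcomes` (data.frame),
#'   `reference_frames`, `spec`.
#' @export
make_cohort <- function(spec = cohort_spec(), acq = acquisition_spec(),
                        pulse = pulse_model(), simulate_frames = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_recurrence + spec$n_non_recurrence
  labels <- rep(c("R", "NR"), c(spec$n_recurrence, spec$n_non_recurrence))
  patient_seeds <- sample.int(2^30, n)
  reference_frames <- if (simulate_frames) {
    make_reference_frames(acq, pulse, seed = sample.int(2^30, 1),
                          extent = spec$extent, density = spec$base_density)
  } else list()

  dz <- axial_sample_m(acq)
  n_samp <- ceiling(spec$extent[1] / dz) + 1L
  n_lines <- max(1L, floor(spec$extent[2] / acq$line_pitch))
  roi <- matrix(FALSE, n_samp, n_lines)
  a0 <- round(n_samp * 0.15); a1 <- round(n_samp * 0.9)
  l0 <- max(1L, round(n_lines * 0.08)); l1 <- round(n_lines * 0.92)
  roi[a0:a1, l0:l1] <- TRUE

  patients <- vector("list", n)
  out <- vector("list", n)
  for (p in seq_len(n)) {
    set.seed(patient_seeds[p])
    lab <- labels[p]
    het <- if (lab == "R") spec$het_r else spec$het_nr
    spacing <- stats::runif(1, spec$spacing_range_mm[1],
                            spec$spacing_range_mm[2]) * 1e-3
    alpha <- stats::runif(1, spec$attenuation_range[1],
                          spec$attenuation_range[2])
    fr_choices <- seq(spec$frames_range[1], spec$frames_range[2])
    n_frames <- if (length(fr_choices) == 1L) fr_choices else sample(fr_choices, 1)
    frame_seeds <- sample.int(2^30, n_frames)
    pid <- sprintf("P%03d", p)

    scans <- if (!simulate_frames) list() else lapply(seq_len(n_frames), function(k) {
      set.seed(frame_seeds[k])
      env <- .make_envelope(spec$extent, het)
      fld <- regular_field(spec$extent, spacing, acq, seed = frame_seeds[k],
                           jitter_sd = spec$lattice_jitter,
                           amplitude = spec$lattice_amplitude,
                           diffuse_density = spec$base_density, diffuse_sd = 1)
      amp <- fld$amplitudes * env(fld$positions[, 1], fld$positions[, 2])
      fld <- scatterer_field(fld$positions, amp, fld$extent,
                             mean_spacing = spacing,
                             number_density = fld$number_density,
                             effective_diameter = spec$diameter_um * 1e-6)
      fr <- simulate_rf_frame(fld, pulse, acq, attenuation = alpha,
                              seed = frame_seeds[k],
                              frame_id = sprintf("%s-f%02d", pid, k))
      list(frame = fr, roi = roi)
    })

    set.seed(patient_seeds[p] + 7L)
    t_rfs <- stats::rexp(1, spec$hazard_rfs[[lab]])
    t_os <- stats::rexp(1, spec$hazard_os[[lab]])
    out[[p]] <- data.frame(
      patient_id = pid, label = lab,
      time_rfs_months = min(t_rfs, spec$censor_time),
      event_rfs = as.integer(t_rfs <= spec$censor_time),
      time_os_months = min(t_os, spec$censor_time),
      event_os = as.integer(t_os <= spec$censor_time),
      stringsAsFactors = FALSE)

    patients[[p]] <- list(
      patient_id = pid, label = lab,
      truth = list(heterogeneity = het, spacing_m = spacing,
                   attenuation = alpha,
                   diameter_m = spec$diameter_um * 1e-6,
                   density = spec$base_density),
      scans = scans)
  }
  structure(
    list(patients = patients, outcomes = do.call(rbind, out),
         reference_frames = reference_frames, spec = spec),
    class = "qus_cohort")
}

#' Simulate a feature-level cohort with a planted class effect
#'
#' Draws the 95-column feature matrix directly (independent standard normal
#' features) and shifts the chosen features by `effect_size` standard
#' deviations in the recurrence class. Used for classifier-harness
#' experiments where the question is whether the selection/evaluation
#' protocol finds a signal placed in a known tier (e.g. only in a
#' texture-derivative feature), without the cost of RF simulation.
#'
#' @param n_recurrence,n_non_recurrence Class sizes.
#' @param effect_features Character vector of catalog feature names carrying
#'   the effect (default a texture-derivative feature).
#' @param effect_size Shift in SD units added for the recurrence class.
#' @param seed Integer seed.
#' @return List with `features` (data.frame: patient_id + 95 columns) and
#'   `labels` (character vector "R"/"NR").
#' @export
simulate_feature_cohort <- function(n_recurrence = 28L, n_non_recurrence = 55L,
                                    effect_features = "SI-COR-CON",
                                    effect_size = 1.5, seed = 1L) {
  catalog <- feature_catalog()
  stopifnot(all(effect_features %in% catalog))
  set.seed(seed)
  n <- n_recurrence + n_non_recurrence
  labels <- rep(c("R", "NR"), c(n_recurrence, n_non_recurrence))
  m <- matrix(stats::rnorm(n * length(catalog)), n,
              dimnames = list(NULL, catalog))
  m[labels == "R", effect_features] <- m[labels == "R", effect_features] +
    effect_size
  df <- data.frame(patient_id = sprintf("P%03d", seq_len(n)), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  list(features = df, labels = labels)
}

#' Write / read cohort outcomes as CSV
#'
#' Columns: patient_id, label, time_rfs_months, event_rfs, time_os_months,
#' event_os.
#' @param outcomes Outcomes data.frame.
#' @param path File path.
#' @export
write_outcomes <- function(outcomes, path) {
  utils::write.csv(outcomes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_outcomes
#' @export
read_outcomes <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
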