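#' The 95-feature radiomics catalog
#'
#' Ordered feature names in three tiers: 7 spectral parameters (MBF, SS, SI,
#' SAS, ASD, AAC, ACE), 24 first-pass texture features (6 parametric maps --
#' no map for ACE -- x CON/COR/ENE/HOM), and 64 texture-derivative features
#' (texture maps of MBF, SI, ASD, AAC only x 4 x 4). 7 + 24 + 64 = 95.
#'
#' @return Character vector of 95 names with a `tier` attribute
#'   (`"spectral"`, `"tex1"`, `"tex2"`).
#' @export
feature_catalog <- function() {
  spectral <- c("MBF", "SS", "SI", "SAS", "ASD", "AAC", "ACE")
  map_params <- c("MBF", "SS", "SI", "SAS", "ASD", "AAC")
  feats <- c("CON", "COR", "ENE", "HOM")
  tex1 <- as.vector(t(outer(map_params, feats, paste, sep = "-")))
  deriv_params <- c("MBF", "SI", "ASD", "AAC")
  tex2 <- character(0)
  for (p in deriv_params) for (t1 in feats) {
    tex2 <- c(tex2, paste(p, t1, feats, sep = "-"))
  }
  nm <- c(spectral, tex1, tex2)
  attr(nm, "tier") <- rep(c("spectral", "tex1", "tex2"),
                          c(length(spectral), length(tex1), length(tex2)))
  nm
}

#' Extract the 95 features from one frame
#'
#' Builds the parametric maps, takes the mean over valid cells of each map
#' (first-order features) plus the frame attenuation estimate, the
#' angle-averaged GLCM features of each of the 6 maps (24 first-pass texture
#' features), and the second-pass GLCM features of the 16 regenerated
#' texture maps (64 texture derivatives). Features an estimator could not
#' produce are NA and get averaged out at the patient level.
#'
#' @param frame An `rf_frame`.
#' @param roi Logical ROI mask.
#' @param reference_frames Phantom frames for normalization.
#' @param config A `qus_config()` list.
#' @return Named numeric vector over [feature_catalog()].
#' @export
extract_frame_features <- function(frame, roi, reference_frames,
                                   config = qus_config()) {
  catalog <- feature_catalog()
  out <- stats::setNames(rep(NA_real_, length(catalog)), catalog)
  bm <- build_parametric_maps(frame, roi, reference_frames, config)

  for (p in names(bm$maps)) {
    m <- bm$maps[[p]]
    if (any(m$valid_mask)) out[[p]] <- mean(m$values[m$valid_mask])
  }
  out[["ACE"]] <- bm$ace

  feats <- c("CON", "COR", "ENE", "HOM")
  for (p in names(bm$maps)) {
    tx <- tryCatch(
      suppressWarnings(texture_of_map(bm$maps[[p]], config$n_levels,
                                      config$displacement, config$angles)),
      error = function(e) NULL)
    if (!is.null(tx)) out[paste(p, feats, sep = "-")] <- as.numeric(tx)
  }

  tmaps <- list()
  for (p in c("MBF", "SI", "ASD", "AAC")) {
    # assign via [<- with list(): a NULL from tryCatch must keep its slot
    tmaps[p] <- list(tryCatch(
      texture_map_of(bm$maps[[p]], config$n_levels, config$displacement,
                     config$neighborhood, config$angles),
      error = function(e) NULL))
  }
  if (!any(vapply(tmaps, is.null, logical(1)))) {
    d <- texture_derivative(tmaps, config$n_levels, config$displacement,
                            config$angles)
    out[names(d)] <- d
  }
  out
}

#' Patient-level feature vector: mean over tumour slices
#'
#' Extracts the frame-level features for every scan of one patient and
#' averages each feature over the frames where it is valid. A feature
#' invalid in every frame is an error naming the feature and patient.
#'
#' @param scans List of per-frame lists with elements `frame` (`rf_frame`)
#'   and `roi` (logical mask).
#' @param reference_frames Phantom frames.
#' @param config A `qus_config()` list.
#' @param patient_id Identifier used in error messages.
#' @return Named numeric vector over the catalog with attribute
#'   `n_frames_averaged`.
#' @export
extract_patient_features <- function(scans, reference_frames,
                                     config = qus_config(),
                                     patient_id = "patient") {
  if (length(scans) < 1L) stop("patient has no frames")
  recs <- vapply(scans, function(s) {
    extract_frame_features(s$frame, s$roi, reference_frames, config)
  }, numeric(length(feature_catalog())))
  recs <- matrix(recs, nrow = length(feature_catalog()),
                 dimnames = list(feature_catalog(), NULL))
  v <- rowMeans(recs, na.rm = TRUE)
  bad <- names(v)[!is.finite(v)]
  if (length(bad) > 0L) {
    stop(sprintf("feature(s) %s invalid in every frame of %s",
                 paste(bad, collapse = ", "), patient_id))
  }
  attr(v, "n_frames_averaged") <- length(scans)
  v
}

#' Cohort feature matrix
#'
#' Runs [extract_patient_features()] for every patient of a simulated cohort
#' and assembles the patient x 95 feature table, columns in catalog order.
#'
#' @param cohort A cohort from [make_cohort()].
#' @param config A `qus_config()` list.
#' @param progress Print one line per patient.
#' @return `data.frame` with `patient_id` then the 95 catalog columns.
#' @export
extract_cohort_features <- function(cohort, config = qus_config(),
                                    progress = FALSE) {
  rows <- lapply(cohort$patients, function(p) {
    if (progress) message("extracting ", p$patient_id)
    extract_patient_features(p$scans, cohort$reference_frames, config,
                             patient_id = p$patient_id)
  })
  m <- do.call(rbind, rows)
  df <- data.frame(patient_id = vapply(cohort$patients, `[[`, "", "patient_id"),
                   m, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Write / read a feature matrix as CSV
#'
#' First column `patient_id`, then the 95 catalog-named columns.
#' @param features Feature `data.frame`.
#' @param path File path.
#' @export
write_feature_matrix <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
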