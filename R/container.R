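#' Write a patient's scans to a plain-text container
#'
#' One directory per patient mirroring a hierarchical scan container:
#' `acquisition.json` (file-level attributes), `ground_truth.json` (sidecar
#' with the simulation ground truth), and `frames/<id>/` holding `rf.txt`
#' (integer samples, quantized to the acquisition bit depth, with the scale
#' in `meta.json`) and `roi.txt` (0/1 mask).
#'
#' @param patient One element of a `qus_cohort`'s `patients` list.
#' @param dir Output directory (created).
#' @return The patient directory path, invisibly.
#' @export
write_scan_container <- function(patient, dir) {
  pdir <- file.path(dir, patient$patient_id)
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  acq <- patient$scans[[1]]$frame$acquisition
  jsonlite::write_json(unclass(acq), file.path(pdir, "acquisition.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(c(patient$truth, list(label = patient$label)),
                       file.path(pdir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  for (s in patient$scans) {
    fdir <- file.path(pdir, "frames", s$frame$frame_id)
    dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
    q <- quantize_frame(s$frame)
    utils::write.table(q$samples, file.path(fdir, "rf.txt"),
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(s$roi * 1L, file.path(fdir, "roi.txt"),
                       row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(
      list(scale = q$scale, frame_id = s$frame$frame_id,
           attenuation = s$frame$attenuation),
      file.path(fdir, "meta.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(pdir)
}

#' @rdname write_scan_container
#' @param pdir A patient directory written by [write_scan_container()].
#' @return `read_scan_container`: a patient list (`patient_id`, `label`,
#'   `truth`, `scans`).
#' @export
read_scan_container <- function(pdir) {
  acq_l <- jsonlite::read_json(file.path(pdir, "acquisition.json"),
                               simplifyVector = TRUE)
  acq <- acquisition_spec(acq_l$sampling_rate, acq_l$center_frequency,
                          acq_l$analysis_band, acq_l$sound_speed,
                          acq_l$bit_depth, acq_l$line_pitch)
  truth <- jsonlite::read_json(file.path(pdir, "ground_truth.json"),
                               simplifyVector = TRUE)
  fdirs <- list.dirs(file.path(pdir, "frames"), recursive = FALSE)
  scans <- lapply(fdirs, function(fd) {
    meta <- jsonlite::read_json(file.path(fd, "meta.json"),
                                simplifyVector = TRUE)
    rf <- as.matrix(utils::read.table(file.path(fd, "rf.txt"))) * meta$scale
    dimnames(rf) <- NULL
    roi <- as.matrix(utils::read.table(file.path(fd, "roi.txt"))) == 1
    dimnames(roi) <- NULL
    list(frame = rf_frame(rf, acq, frame_id = meta$frame_id,
                          attenuation = meta$attenuation),
         roi = roi)
  })
  list(patient_id = basename(pdir), label = truth$label,
       truth = truth[setdiff(names(truth), "label")], scans = scans)
}
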