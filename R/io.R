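#' Write a simulated dataset to disk
#'
#' Writes the ASL timeseries and calibration images as NIfTI, the
#' acquisition sidecar and ground-truth scalars as JSON, the motion trace as
#' TSV, and the ground-truth maps as NIfTI.
#'
#' @param ds An `asl_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(ds$series$data, file.path(dir, "asl.nii.gz"))
  for (k in seq_along(ds$calib))
    RNifti::writeNifti(ds$calib[[k]],
                       file.path(dir, sprintf("calib%d.nii.gz", k - 1)))
  jsonlite::write_json(ds$sidecar, file.path(dir, "asl.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(ds$series$motion, file.path(dir, "motion.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  tr <- ds$truth
  for (nm in c("pv_gm", "pv_wm", "pv_csf", "abv", "t1_tissue", "m0_tissue",
               "bias_field"))
    RNifti::writeNifti(tr[[nm]], file.path(dir, paste0(nm, ".nii.gz")))
  RNifti::writeNifti(array(as.numeric(tr$csf_mask), tr$shape),
                     file.path(dir, "csf_mask.nii.gz"))
  RNifti::writeNifti(array(as.numeric(tr$parcels), tr$shape),
                     file.path(dir, "parcels.nii.gz"))
  scalars <- tr[c("f_gm", "f_wm", "att_gm", "att_wm", "att_arterial",
                  "abv_value", "t1_gm", "t1_wm", "t1_csf", "m0_gm", "m0_wm",
                  "m0_blood", "bias_amp", "empirical_gradient", "noise_sd",
                  "motion_sd", "lam_csf", "t2_csf", "t2_blood", "seed")]
  jsonlite::write_json(scalars, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing the files.
#' @return An `asl_dataset`.
#' @export
read_dataset <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "asl.json"), simplifyVector = TRUE)
  protocol <- asl_protocol(
    label_dur = side$LabelingDuration, plds = side$PostLabelingDelays,
    repeats = side$Repeats, mb_factor = side$MultibandAccelerationFactor,
    slice_dt = side$SliceReadoutTime, te = side$EchoTime,
    volume_order = side$VolumeOrder,
    n_slices = dim(RNifti::readNifti(file.path(dir, "asl.nii.gz")))[3])
  arr <- function(f) {
    a <- RNifti::readNifti(file.path(dir, f))
    array(as.numeric(a), dim(a))
  }
  data <- arr("asl.nii.gz")
  motion <- as.matrix(utils::read.table(file.path(dir, "motion.tsv"),
                                        sep = "\t"))
  dimnames(motion) <- NULL
  scalars <- jsonlite::read_json(file.path(dir, "truth.json"),
                                 simplifyVector = TRUE)
  d <- dim(data)[1:3]
  truth <- c(list(
    shape = d, protocol = protocol,
    pv_gm = arr("pv_gm.nii.gz"), pv_wm = arr("pv_wm.nii.gz"),
    pv_csf = arr("pv_csf.nii.gz"), abv = arr("abv.nii.gz"),
    t1_tissue = arr("t1_tissue.nii.gz"), m0_tissue = arr("m0_tissue.nii.gz"),
    bias_field = arr("bias_field.nii.gz"),
    csf_mask = arr("csf_mask.nii.gz") > 0.5,
    parcels = array(as.integer(round(arr("parcels.nii.gz"))), d),
    motion_trace = motion
  ), scalars)
  truth$brain_mask <- (truth$pv_gm + truth$pv_wm + truth$pv_csf) > 0.5
  class(truth) <- "asl_phantom"
  series <- structure(list(
    data = data, protocol = protocol,
    annotations = volume_annotations(protocol),
    motion = motion, corrections = character(0)
  ), class = "asl_series")
  calib <- lapply(0:1, function(k) arr(sprintf("calib%d.nii.gz", k)))
  structure(list(series = series, calib = calib, sidecar = as.list(side),
                 truth = truth), class = "asl_dataset")
}

# Write pipeline parameter maps, QC and IDPs under a directory.
write_pipeline_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wn <- function(a, f) if (!is.null(a)) RNifti::writeNifti(a, file.path(dir, f))
  if (!is.null(run$fit)) {
    wn(run$fit$cbf, "cbf.nii.gz"); wn(run$fit$f, "f_au.nii.gz")
    wn(run$fit$att, "att.nii.gz"); wn(run$fit$abv, "abv.nii.gz")
  }
  if (!is.null(run$pvec)) {
    wn(run$pvec$cbf_gm, "pvec_cbf_gm.nii.gz")
    wn(run$pvec$cbf_wm, "pvec_cbf_wm.nii.gz")
    wn(run$pvec$att_gm, "pvec_att_gm.nii.gz")
    wn(run$pvec$att_wm, "pvec_att_wm.nii.gz")
  }
  qc <- run$qc
  qc$provenance <- run$provenance
  jsonlite::write_json(qc, file.path(dir, "qc.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  if (!is.null(run$idps))
    utils::write.table(run$idps, file.path(dir, "idps.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(dir)
}
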