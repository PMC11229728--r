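# Disk interfaces: NIfTI volumes with correct affines, CSV tables,
# JSON/YAML sidecars for configs, transforms and fitted models.

#' Write a case's volumes as NIfTI-1
#'
#' @param case an [MpMriCase-class]
#' @param dir output directory (created if needed)
#' @return invisibly, the written file paths
#' @export
writeCaseNifti <- function(case, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- case@voxelSpacing
  paths <- character()
  for (nm in names(case@volumes)) {
    img <- RNifti::asNifti(case@volumes[[nm]])
    RNifti::pixdim(img) <- sp
    p <- file.path(dir, paste0(case@caseId, "_", nm, ".nii.gz"))
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  maskP <- file.path(dir, paste0(case@caseId, "_prostate.nii.gz"))
  maskImg <- RNifti::asNifti(array(as.integer(case@prostateMask),
                                   dim(case@prostateMask)))
  RNifti::pixdim(maskImg) <- sp
  RNifti::writeNifti(maskImg, maskP)
  sidecar <- list(case_id = case@caseId, voxel_spacing_mm = sp,
                  pe_ave_case = case@peAveCase,
                  muscle_roi_sizes = lengths(case@muscleRois))
  jsonlite::write_json(sidecar, file.path(dir, paste0(case@caseId,
                                                      "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(paths, maskP))
}

#' Read one NIfTI volume as a plain array
#' @param path NIfTI file
#' @return list: `data` array and `spacing` (mm)
#' @export
readNiftiVolume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim(img)),
       spacing = RNifti::pixdim(img)[seq_len(min(3, length(dim(img))))])
}

#' Serialize a rigid transform to JSON
#'
#' Records translation (mm), rotation (deg), centre (mm) and the rotation
#' convention (intrinsic, slice axis applied last).
#'
#' @param tf a [RigidTransform-class]
#' @param path output file
#' @export
writeTransformJson <- function(tf, path) {
  jsonlite::write_json(list(translation_mm = tf@translation,
                            rotation_deg = tf@rotation,
                            center_mm = tf@center,
                            convention = "intrinsic-xyz-slice-last"),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeTransformJson
#' @export
readTransformJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigidTransform(translation = x$translation_mm,
                 rotation = x$rotation_deg, center = x$center_mm)
}

#' Serialize a fitted tissue model to JSON
#'
#' The JSON coefficient file (type, zone, term names, intercept A, linear
#' B and quadratic C coefficients, fit metadata) is the artifact's
#' portable model representation.
#'
#' @param model a [LogisticTissueModel-class]
#' @param path output file
#' @export
writeModelJson <- function(model, path) {
  meta <- model@fitMetadata
  meta$trace <- NULL  # keep the sidecar small and stable
  jsonlite::write_json(
    list(model_type = model@modelType, zone = model@zone,
         intercept = model@intercept,
         linear = as.list(model@linCoef),
         quadratic = as.list(model@quadCoef),
         included_terms = model@includedTerms,
         metadata = meta),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeModelJson
#' @export
readModelJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lin <- unlist(x$linear)
  quad <- unlist(x$quadratic)
  new("LogisticTissueModel", modelType = x$model_type, zone = x$zone,
      intercept = x$intercept,
      linCoef = if (length(lin)) lin else
        stats::setNames(numeric(0), character(0)),
      quadCoef = if (length(quad)) quad else
        stats::setNames(numeric(0), character(0)),
      includedTerms = if (length(x$included_terms)) x$included_terms else
        character(0),
      fitMetadata = as.list(x$metadata))
}

#' Write / read an ROI table as CSV
#' @param table ROI data.frame
#' @param path CSV file
#' @export
writeRoiCsv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRoiCsv
#' @export
readRoiCsv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize a phantom configuration to YAML
#'
#' Tissue means/covariances, lesion specs and scalar settings are written
#' as plain YAML; the misalignment transform as its parameter triple.
#'
#' @param config a [PhantomConfig-class]
#' @param path YAML file
#' @export
writePhantomYaml <- function(config, path) {
  tp <- lapply(config@tissueParams, function(p)
    list(mean = as.list(p$mean), cov_diag = as.list(diag(as.matrix(p$cov)))))
  yaml::write_yaml(list(
    grid_shape = config@gridShape,
    voxel_spacing_mm = config@voxelSpacing,
    tissue_params = tp,
    lesion_specs = lapply(seq_len(nrow(config@lesionSpecs)), function(i)
      as.list(config@lesionSpecs[i, ])),
    coil_bias = list(amplitude = config@coilBias[1],
                     decay_mm = config@coilBias[2]),
    patient_pe_scale = config@patientPeScale,
    misalignment = list(translation_mm = config@misalignment@translation,
                        rotation_deg = config@misalignment@rotation),
    dwi_distortion_mm = config@dwiDistortion,
    size_scale = config@sizeScale,
    rng_seed = config@rngSeed), path)
  invisible(path)
}
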