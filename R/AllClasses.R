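#' @import methods
NULL

MRI_PARAMS <- c("t2w", "adc", "fa", "pe", "es", "wo")
TISSUE_CLASSES <- c("benign_PZ", "benign_TZ", "AFMS", "PCa_low", "PCa_high")
MODEL_TYPES <- c("afms_vs_cancer", "cancer_vs_benign", "high_vs_low")
ZONES <- c("PZ", "TZ")

isPsd <- function(S, tol = 1e-8) {
  S <- as.matrix(S)
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-6))) return(FALSE)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  all(ev > -tol * max(1, abs(ev[1])))
}

#' Rigid spatial transform
#'
#' A 6-parameter rigid-body transform: a point \eqn{p} (mm) maps to
#' \eqn{R (p - c) + c + t} where \eqn{R} is built from intrinsic rotations
#' applied in the order x, then y, then z (the slice axis last), `c` is the
#' rotation centre and `t` the translation.
#'
#' @slot translation numeric(3), mm per axis
#' @slot rotation numeric(3), degrees per axis
#' @slot center numeric(3), rotation centre in mm
#' @export
setClass("RigidTransform", representation(
  translation = "numeric", rotation = "numeric", center = "numeric"))

setValidity("RigidTransform", function(object) {
  if (length(object@translation) != 3 || length(object@rotation) != 3 ||
      length(object@center) != 3) return("translation, rotation and center must have length 3")
  if (any(!is.finite(c(object@translation, object@rotation, object@center))))
    return("non-finite transform parameters")
  TRUE
})

#' Construct a rigid transform
#'
#' @param translation mm per axis (length 3)
#' @param rotation degrees per axis (length 3)
#' @param center rotation centre in mm (length 3)
#' @return a [RigidTransform-class] object
#' @export
rigidTransform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                           center = c(0, 0, 0)) {
  new("RigidTransform", translation = as.numeric(translation),
      rotation = as.numeric(rotation), center = as.numeric(center))
}

#' Phantom configuration
#'
#' Describes one synthetic mpMRI case: grid geometry, tissue-class parameter
#' distributions over the six MRI parameters (t2w, adc, fa, pe, es, wo),
#' lesions, endorectal-coil bias on T2W, per-case DCE amplitude scale, and
#' optional rigid misalignment / diffusion distortion.
#'
#' @slot gridShape integer(3) voxels per axis
#' @slot voxelSpacing numeric(3) mm per axis
#' @slot tissueParams named list over exactly the classes benign_PZ,
#'   benign_TZ, AFMS, PCa_low, PCa_high; each element a list with `mean`
#'   (named numeric over the six parameters) and `cov` (6 x 6 PSD matrix)
#' @slot backgroundParams like `tissueParams` but for the non-prostate
#'   classes body, muscle and air
#' @slot lesionSpecs data.frame with columns zone ("PZ"/"TZ"), grade
#'   ("low"/"high"), volume_cc, and optional seed coordinates sx, sy, sz (mm)
#' @slot coilBias numeric(2): multiplicative T2W bias amplitude and decay
#'   length (mm) of the endorectal-coil reception profile
#' @slot patientPeScale positive scalar multiplying PE, ES and WO
#' @slot misalignment a [RigidTransform-class] applied to all non-T2W
#'   volumes, or identity
#' @slot dwiDistortion maximum local displacement (mm) of a smooth random
#'   warp applied to ADC and FA
#' @slot sizeScale scalar scaling of the prostate semi-axes
#' @slot caseJitter between-case tissue heterogeneity: each prostate
#'   tissue class's mean vector is offset once per case by a normal draw
#'   with SD equal to this fraction of the class SD
#' @slot spatialFrac fraction (0..1) of each prostate class's within-case
#'   SD carried by a smooth spatial field rather than iid voxel noise;
#'   total within-class variance is unchanged
#' @slot spatialScaleMm correlation length (mm) of the spatial field
#' @slot rngSeed integer seed making the case reproducible
#' @export
setClass("PhantomConfig", representation(
  gridShape = "integer", voxelSpacing = "numeric", tissueParams = "list",
  backgroundParams = "list", lesionSpecs = "data.frame", coilBias = "numeric",
  patientPeScale = "numeric", misalignment = "RigidTransform",
  dwiDistortion = "numeric", sizeScale = "numeric", caseJitter = "numeric",
  spatialFrac = "numeric", spatialScaleMm = "numeric",
  rngSeed = "integer"))

setValidity("PhantomConfig", function(object) {
  if (any(object@voxelSpacing <= 0)) return("voxelSpacing must be strictly positive")
  if (!identical(sort(names(object@tissueParams)), sort(TISSUE_CLASSES)))
    return(paste("tissueParams classes must be exactly:",
                 paste(TISSUE_CLASSES, collapse = ", ")))
  for (cl in names(object@tissueParams)) {
    p <- object@tissueParams[[cl]]
    if (!all(MRI_PARAMS %in% names(p$mean)))
      return(sprintf("tissueParams$%s$mean must name all of %s", cl,
                     paste(MRI_PARAMS, collapse = ", ")))
    if (!isPsd(p$cov)) return(sprintf("covariance for %s is not positive semi-definite", cl))
  }
  if (nrow(object@lesionSpecs) &&
      any(object@lesionSpecs$volume_cc < 0.01))
    return("lesion volumes must be >= 0.01 cc")
  if (object@patientPeScale <= 0) return("patientPeScale must be positive")
  if (object@dwiDistortion < 0) return("dwiDistortion must be non-negative")
  if (object@caseJitter < 0) return("caseJitter must be non-negative")
  if (object@spatialFrac < 0 || object@spatialFrac > 1)
    return("spatialFrac must lie in [0, 1]")
  if (object@spatialScaleMm <= 0) return("spatialScaleMm must be positive")
  TRUE
})

#' Ground truth of a phantom case
#'
#' @slot zoneLabels integer array: 0 background, 1 PZ, 2 TZ, 3 AFMS
#' @slot lesionLabels integer array of lesion ids (0 = none)
#' @slot lesionTable data.frame: id, grade ("low"/"high"), zone, volume_cc,
#'   centroid (cx, cy, cz in mm)
#' @slot appliedTransform the rigid misalignment actually applied to the
#'   non-T2W volumes (recovery target is its inverse)
#' @slot coilBiasField the multiplicative T2W bias field actually applied
#' @export
setClass("GroundTruth", representation(
  zoneLabels = "array", lesionLabels = "array", lesionTable = "data.frame",
  appliedTransform = "RigidTransform", coilBiasField = "array"))

setValidity("GroundTruth", function(object) {
  if (!identical(dim(object@zoneLabels), dim(object@lesionLabels)))
    return("zoneLabels and lesionLabels must share dimensions")
  inProstate <- object@zoneLabels %in% c(1L, 2L)
  if (any(object@lesionLabels > 0L & !inProstate))
    return("lesion voxels must lie inside PZ or TZ")
  TRUE
})

#' One multiparametric MRI case
#'
#' Holds the six parameter volumes on a common grid together with the
#' geometry and the per-case quantities used by the normalizations: the two
#' obturator-muscle reference ROIs for T2W scaling and the case-mean peak
#' enhancement over the prostate for DCE scaling.
#'
#' @slot volumes named list of 3D arrays; names include t2w, adc, fa, pe,
#'   es, wo
#' @slot voxelSpacing numeric(3) mm
#' @slot caseId character identifier
#' @slot muscleRois list of two voxel index vectors in obturator muscle
#' @slot peAveCase case-mean PE over the prostate (NA until computed)
#' @slot prostateMask logical array
#' @slot bodyMask logical array (body vs air), used for coil-bias correction
#' @export
setClass("MpMriCase", representation(
  volumes = "list", voxelSpacing = "numeric", caseId = "character",
  muscleRois = "list", peAveCase = "numeric", prostateMask = "array",
  bodyMask = "array"))

setValidity("MpMriCase", function(object) {
  dims <- lapply(object@volumes, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) > 1)
    return("all volumes must share one grid")
  if (length(object@muscleRois) == 2) {
    pro <- which(object@prostateMask)
    if (any(unlist(object@muscleRois) %in% pro))
      return("muscle ROIs must be disjoint from the prostate mask")
    if (any(lengths(object@muscleRois) == 0))
      return("muscle ROIs must be nonempty")
  }
  if (!is.na(object@peAveCase) && object@peAveCase <= 0)
    return("peAveCase must be positive once computed")
  TRUE
})

#' Cohort-level normalization statistics
#'
#' @slot peAveCohort mean of the per-case prostate-mean peak enhancement
#'   over all cases; the fixed reference of the DCE normalization
#' @export
setClass("CohortStats", representation(peAveCohort = "numeric"))

setValidity("CohortStats", function(object) {
  if (length(object@peAveCohort) != 1 || object@peAveCohort <= 0)
    return("peAveCohort must be a positive scalar")
  TRUE
})

#' Zone-specific logistic tissue model
#'
#' Log-odds \eqn{t = A + \sum_i B_i x_i + \sum_j C_j x_j^2} over the
#' included MRI parameters; probability \eqn{1/(1+e^{-t})}.
#'
#' @slot modelType one of afms_vs_cancer, cancer_vs_benign, high_vs_low
#' @slot zone "PZ" or "TZ"
#' @slot intercept A
#' @slot linCoef named numeric of B_i over included linear terms
#' @slot quadCoef named numeric of C_j over included quadratic terms (names
#'   are the underlying parameter names)
#' @slot includedTerms character vector of term labels
#' @slot fitMetadata list: n, class counts, positive class, selection trace,
#'   separation flag, cross-validation info
#' @export
setClass("LogisticTissueModel", representation(
  modelType = "character", zone = "character", intercept = "numeric",
  linCoef = "numeric", quadCoef = "numeric", includedTerms = "character",
  fitMetadata = "list"))

setValidity("LogisticTissueModel", function(object) {
  if (!object@modelType %in% MODEL_TYPES) return("unknown modelType")
  if (!object@zone %in% ZONES) return("zone must be PZ or TZ")
  terms <- c(names(object@linCoef),
             if (length(object@quadCoef))
               paste0(names(object@quadCoef), "_sq"))
  if (!setequal(terms, object@includedTerms))
    return("includedTerms must match coefficient names exactly")
  TRUE
})

#' ROC curve with operating point
#'
#' @slot thresholds score cutpoints (score >= threshold is called positive)
#' @slot sensitivity,specificity per-threshold values
#' @slot auc trapezoidal area under the curve
#' @slot operatingPoint named numeric (threshold, sensitivity, specificity)
#'   at the maximum Youden index, tie-broken toward equal sensitivity and
#'   specificity
#' @export
setClass("RocResult", representation(
  thresholds = "numeric", sensitivity = "numeric", specificity = "numeric",
  auc = "numeric", operatingPoint = "numeric"))

setValidity("RocResult", function(object) {
  if (object@auc < 0 || object@auc > 1) return("auc must lie in [0, 1]")
  TRUE
})

#' Voxel-wise risk maps and derived lesion masks for one case
#'
#' @slot pCancer,pHighgrade probability volumes (NA outside the effective
#'   mask)
#' @slot afmsMask voxels with AFMS-model probability >= 0.5, removed from
#'   the prostate before cancer mapping
#' @slot effectiveMask prostate minus AFMS mask (and minus voxels with
#'   missing parameters)
#' @slot prostateMask the original prostate segmentation
#' @slot pcamMask,hgMask binary lesion masks after thresholding (empty until
#'   [binarizeMaps()] is applied); hgMask is always a subset of pcamMask
#' @slot voxelSpacing mm
#' @slot cuts named numeric of the thresholds used (NA until binarized)
#' @slot nMissing number of prostate voxels excluded for missing parameters
#' @export
setClass("RiskMapSet", representation(
  pCancer = "array", pHighgrade = "array", afmsMask = "array",
  effectiveMask = "array", prostateMask = "array", pcamMask = "array",
  hgMask = "array", voxelSpacing = "numeric", cuts = "numeric",
  nMissing = "integer"))

setValidity("RiskMapSet", function(object) {
  p <- object@pCancer[object@effectiveMask]
  if (length(p) && (min(p, na.rm = TRUE) < 0 || max(p, na.rm = TRUE) > 1))
    return("probabilities must lie in [0, 1] inside the effective mask")
  if (any(object@hgMask & !object@pcamMask))
    return("hgMask must be a subset of pcamMask")
  if (any(object@afmsMask & object@pcamMask))
    return("afmsMask and pcamMask must be disjoint")
  TRUE
})

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform: t = (", paste(sprintf("%.2f", object@translation),
      collapse = ", "), ") mm; r = (",
      paste(sprintf("%.2f", object@rotation), collapse = ", "), ") deg\n")
})

setMethod("show", "MpMriCase", function(object) {
  d <- dim(object@volumes[[1]])
  cat("MpMriCase", object@caseId, ":", paste(d, collapse = " x "),
      "voxels @", paste(object@voxelSpacing, collapse = "x"), "mm;",
      length(object@volumes), "volumes (",
      paste(names(object@volumes), collapse = ", "), ")\n")
  cat("  prostate:", sum(object@prostateMask), "voxels; peAveCase:",
      signif(object@peAveCase, 4), "\n")
})

setMethod("show", "LogisticTissueModel", function(object) {
  cat("LogisticTissueModel", object@modelType, "/", object@zone, "\n")
  cat("  terms:", if (length(object@includedTerms))
    paste(object@includedTerms, collapse = ", ") else "(intercept only)", "\n")
  cat("  A =", signif(object@intercept, 4), "\n")
})

setMethod("show", "RocResult", function(object) {
  op <- object@operatingPoint
  cat(sprintf("RocResult: AUC = %.3f; operating point thr = %.3f (sens %.2f, spec %.2f)\n",
              object@auc, op["threshold"], op["sensitivity"], op["specificity"]))
})

setMethod("show", "RiskMapSet", function(object) {
  cat("RiskMapSet:", sum(object@effectiveMask), "effective voxels;",
      sum(object@afmsMask), "AFMS-masked;",
      sum(object@pcamMask), "cancer-mask voxels;",
      sum(object@hgMask), "high-grade voxels\n")
})

# ---- accessors ---------------------------------------------------------

#' Accessors for core objects
#'
#' @param x an object of the corresponding class
#' @param name volume name for `caseVolume`
#' @return the requested component
#' @name accessors
NULL

#' @rdname accessors
#' @export
caseVolume <- function(x, name) {
  stopifnot(is(x, "MpMriCase"))
  if (!name %in% names(x@volumes)) stop("no volume named ", name)
  x@volumes[[name]]
}

#' @rdname accessors
#' @export
prostateMask <- function(x) {
  if (is(x, "MpMriCase") || is(x, "RiskMapSet")) return(x@prostateMask)
  stop("no prostate mask for this class")
}

#' @rdname accessors
#' @export
lesionTable <- function(x) {
  stopifnot(is(x, "GroundTruth"))
  x@lesionTable
}

#' @rdname accessors
#' @export
zoneLabels <- function(x) {
  stopifnot(is(x, "GroundTruth"))
  x@zoneLabels
}

#' @rdname accessors
#' @export
pCancer <- function(x) {
  stopifnot(is(x, "RiskMapSet"))
  x@pCancer
}

#' @rdname accessors
#' @export
pHighgrade <- function(x) {
  stopifnot(is(x, "RiskMapSet"))
  x@pHighgrade
}

#' @rdname accessors
#' @export
cancerMask <- function(x) {
  stopifnot(is(x, "RiskMapSet"))
  x@pcamMask
}

#' @rdname accessors
#' @export
highgradeMask <- function(x) {
  stopifnot(is(x, "RiskMapSet"))
  x@hgMask
}

#' @rdname accessors
#' @export
modelTerms <- function(x) {
  stopifnot(is(x, "LogisticTissueModel"))
  x@includedTerms
}

#' @rdname accessors
#' @export
rocAuc <- function(x) {
  stopifnot(is(x, "RocResult"))
  x@auc
}
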