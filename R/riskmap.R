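# Voxel-wise application of the tissue models: AFMS exclusion, per-zone
# cancer and high-grade probability maps, volume-ratio threshold
# calibration, and binarization with the dual-threshold high-grade rule.

#' Build per-voxel cancer risk maps for one case
#'
#' The AFMS model is applied to every prostate voxel first; voxels with
#' AFMS probability >= 0.5 are removed from the prostate mask. Within the
#' remaining (effective) mask the cancer-vs-benign and high-vs-low models
#' of the voxel's zone are applied voxel-by-voxel. AFMS-labelled zone
#' voxels that survive the AFMS mask are scored with the TZ models (the
#' AFMS wedge abuts the transition zone). Voxels with any missing
#' parameter are excluded from the effective mask and counted.
#'
#' @param case a preprocessed [MpMriCase-class]
#' @param zones integer zone-label volume (1 PZ, 2 TZ, 3 AFMS)
#' @param models nested list `models[[zone]][[modelType]]` from
#'   [fitCohortModels()]
#' @param afmsCut AFMS exclusion threshold (default 0.5)
#' @return a [RiskMapSet-class] (not yet binarized)
#' @export
buildMaps <- function(case, zones, models, afmsCut = 0.5) {
  d <- dim(case@prostateMask)
  stopifnot(identical(dim(zones), d))
  for (z in ZONES)
    for (mt in MODEL_TYPES)
      if (is.null(models[[z]][[mt]]))
        stop("models must cover both zones and all three types")
  idx <- which(case@prostateMask)
  X <- data.frame(lapply(case@volumes[MRI_PARAMS], function(v) v[idx]))
  names(X) <- MRI_PARAMS
  ok <- rowSums(!is.finite(as.matrix(X))) == 0
  nMissing <- sum(!ok)

  zoneAt <- zones[idx]
  zoneAt[zoneAt == 3L] <- 2L  # AFMS wedge scored with the TZ models
  pAfms <- rep(NA_real_, length(idx))
  pCan <- rep(NA_real_, length(idx))
  pHg <- rep(NA_real_, length(idx))
  for (zi in 1:2) {
    zn <- ZONES[zi]
    sel <- ok & zoneAt == zi
    if (!any(sel)) next
    pAfms[sel] <- predict(models[[zn]]$afms_vs_cancer, X[sel, , drop = FALSE])
  }
  afms <- !is.na(pAfms) & pAfms >= afmsCut
  for (zi in 1:2) {
    zn <- ZONES[zi]
    sel <- ok & !afms & zoneAt == zi
    if (!any(sel)) next
    pCan[sel] <- predict(models[[zn]]$cancer_vs_benign, X[sel, , drop = FALSE])
    pHg[sel] <- predict(models[[zn]]$high_vs_low, X[sel, , drop = FALSE])
  }

  mk <- function(vals, default = NA_real_) {
    a <- array(default, d)
    a[idx] <- vals
    a
  }
  afmsMask <- array(FALSE, d)
  afmsMask[idx[afms]] <- TRUE
  effective <- array(FALSE, d)
  effective[idx[ok & !afms]] <- TRUE
  pc <- mk(ifelse(ok & !afms, pCan, NA_real_))
  ph <- mk(ifelse(ok & !afms, pHg, NA_real_))
  new("RiskMapSet", pCancer = pc, pHighgrade = ph, afmsMask = afmsMask,
      effectiveMask = effective, prostateMask = case@prostateMask,
      pcamMask = array(FALSE, d), hgMask = array(FALSE, d),
      voxelSpacing = case@voxelSpacing,
      cuts = c(afms = afmsCut, cancer = NA_real_, highgrade = NA_real_),
      nMissing = as.integer(nMissing))
}

#' Binarize risk maps into lesion masks
#'
#' The cancer mask collects effective-mask voxels with cancer probability
#' at or above the cancer cut. High-grade voxels must pass both models:
#' they are first confirmed cancer (in the cancer mask) and then confirmed
#' high grade, so the high-grade mask is always a subset of the cancer
#' mask.
#'
#' @param maps a [RiskMapSet-class] from [buildMaps()]
#' @param cancerCut,hgCut probability thresholds in (0, 1]
#' @return the maps with `pcamMask` and `hgMask` filled in
#' @export
binarizeMaps <- function(maps, cancerCut, hgCut) {
  if (cancerCut <= 0 || cancerCut > 1 || hgCut <= 0 || hgCut > 1)
    stop("cuts must lie in (0, 1]")
  pcam <- maps@effectiveMask & !is.na(maps@pCancer) &
    maps@pCancer >= cancerCut
  hg <- pcam & !is.na(maps@pHighgrade) & maps@pHighgrade >= hgCut
  maps@pcamMask <- pcam
  maps@hgMask <- hg
  maps@cuts["cancer"] <- cancerCut
  maps@cuts["highgrade"] <- hgCut
  validObject(maps)
  maps
}

#' MRI tumor burden
#'
#' Total cancer volume: the number of cancer-mask voxels times the voxel
#' volume.
#'
#' @param maps a binarized [RiskMapSet-class] (or a logical mask)
#' @param voxelVolumeCc voxel volume in cc; derived from the map spacing
#'   when omitted
#' @return volume in cc
#' @export
tumorBurden <- function(maps, voxelVolumeCc = NULL) {
  if (is(maps, "RiskMapSet")) {
    if (is.null(voxelVolumeCc))
      voxelVolumeCc <- prod(maps@voxelSpacing) / 1000
    return(sum(maps@pcamMask) * voxelVolumeCc)
  }
  stopifnot(!is.null(voxelVolumeCc))
  sum(maps) * voxelVolumeCc
}

# volume (cc) above each threshold for one probability map, restricted to
# a mask; vectorized over the threshold grid
volumeAboveThresholds <- function(p, mask, thresholds, voxelVolumeCc) {
  v <- p[mask]
  v <- v[is.finite(v)]
  vapply(thresholds, function(t) sum(v >= t) * voxelVolumeCc, numeric(1))
}

#' Calibrate a probability threshold by cohort volume ratio
#'
#' Sweeps a fixed threshold grid; at each threshold the per-case ratio of
#' MRI cancer volume to reference (histopathology) cancer volume is
#' computed and averaged over the cohort. The calibrated threshold is the
#' grid value whose cohort mean ratio is closest to one (smallest such
#' threshold on ties). For the high-grade model the cancer mask is fixed
#' first and the sweep runs over the high-grade probability within it.
#'
#' @param cohort list of per-case lists with elements `maps` (a
#'   [RiskMapSet-class]) and `refCc` (reference volume, cc, for the chosen
#'   compartment)
#' @param which `"cancer"` or `"highgrade"`
#' @param thresholds sweep grid (default 0.05 to 0.95 step 0.01)
#' @param cancerCut required for `which = "highgrade"`: the already
#'   calibrated cancer cut fixing the cancer mask
#' @return list: `threshold`, `perCaseRatios` (at the chosen threshold),
#'   `cohortMeanRatio`, and the full `sweep` data.frame
#' @export
calibrateThreshold <- function(cohort, which = c("cancer", "highgrade"),
                               thresholds = seq(0.05, 0.95, by = 0.01),
                               cancerCut = NULL) {
  which <- match.arg(which)
  refs <- vapply(cohort, function(x) x$refCc, numeric(1))
  use <- refs > 0
  if (sum(use) < 2) stop("need >= 2 cases with positive reference volume")
  if (which == "highgrade" && is.null(cancerCut))
    stop("highgrade calibration requires the calibrated cancerCut")
  ratios <- sapply(cohort[use], function(x) {
    maps <- x$maps
    voxCc <- prod(maps@voxelSpacing) / 1000
    if (which == "cancer") {
      p <- maps@pCancer
      mask <- maps@effectiveMask
    } else {
      p <- maps@pHighgrade
      mask <- maps@effectiveMask & !is.na(maps@pCancer) &
        maps@pCancer >= cancerCut
    }
    volumeAboveThresholds(p, mask, thresholds, voxCc) / x$refCc
  })
  ratios <- matrix(ratios, nrow = length(thresholds))
  meanRatio <- rowMeans(ratios)
  pick <- which.min(abs(meanRatio - 1))  # ties: which.min takes the first
  list(threshold = thresholds[pick],
       perCaseRatios = ratios[pick, ],
       cohortMeanRatio = meanRatio[pick],
       sweep = data.frame(threshold = thresholds, meanRatio = meanRatio))
}
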