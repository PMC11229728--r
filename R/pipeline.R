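# End-to-end phantom study: generate a cohort, normalize, tabulate tissue
# ROIs, fit the per-zone model sets, build and calibrate risk maps, and
# evaluate lesion detection, localization and volume quantification.

#' Run the full risk-map pipeline on a synthetic cohort
#'
#' Convenience orchestration used by the examples, the evaluation script
#' and the test-suite: cohort generation, per-case normalization with
#' cohort DCE statistics, ROI tabulation, model fitting with
#' cross-validation, map building, threshold calibration by cohort volume
#' ratio (cancer first, then high-grade within the fixed cancer mask),
#' binarization, lesion matching at the calibrated cuts, Bland-Altman
#' agreement and threshold-swept ROC curves.
#'
#' @param nCases cohort size
#' @param seed master seed (drives generation, ROI sampling and fold
#'   assignment)
#' @param baseConfig template [PhantomConfig-class]
#' @param roisPerClass ROIs tabulated per class per case
#' @param roiPlacementErrorMm histology-to-MRI ROI transfer error (mm SD)
#'   applied when tabulating training ROIs; emulates the landmark-based
#'   manual transfer of histology regions onto the T2W images
#' @param k cross-validation folds
#' @param lesionRocThresholds sweep grid for the per-lesion ROC curves;
#'   `NULL` (the default) centres each curve's sweep on its own calibrated
#'   operating threshold (from 0.2 below it, never under 0.05, up to
#'   0.95 in 0.05 steps) — below that range the binary masks flood and the
#'   per-lesion factor rules degenerate
#' @param ... passed to [generateCohort()]
#' @return list: `cohort`, `roiTable`, `models`, `cvResults`,
#'   `calibration` (cancer + highgrade), `cuts`, per-case `evaluation`,
#'   cohort `metrics` (all-cancer and high-grade), `blandAltman`, and
#'   `roc` (burden / lesion / highgrade)
#' @export
runPhantomStudy <- function(nCases = 40, seed = 1,
                            baseConfig = phantomConfig(),
                            roisPerClass = 8, roiPlacementErrorMm = 2,
                            k = 4,
                            lesionRocThresholds = NULL,
                            ...) {
  cohort <- generateCohort(nCases, baseConfig, seed = seed, ...)
  stats <- cohortPeStats(cohort)
  for (i in seq_along(cohort))
    cohort[[i]]$case <- preprocessCase(cohort[[i]]$case, stats)

  roiTable <- do.call(rbind, lapply(seq_along(cohort), function(i)
    suppressWarnings(extractRoiTable(cohort[[i]]$case, cohort[[i]]$truth,
                                     roisPerClass = roisPerClass,
                                     seed = seed + i,
                                     placementErrorMm = roiPlacementErrorMm))))
  models <- fitCohortModels(roiTable, k = k, seed = seed)

  sp <- baseConfig@voxelSpacing
  for (i in seq_along(cohort)) {
    cohort[[i]]$maps <- buildMaps(cohort[[i]]$case,
                                  cohort[[i]]$truth@zoneLabels, models)
    cohort[[i]]$refAll <- lesionsFromTruth(cohort[[i]]$truth, sp)
    cohort[[i]]$refHg <- lesionsFromTruth(cohort[[i]]$truth, sp,
                                          grades = "high")
  }

  calCancer <- calibrateThreshold(
    lapply(cohort, function(cs) list(maps = cs$maps,
                                     refCc = sum(cs$refAll$volume_cc))),
    which = "cancer")
  calHg <- calibrateThreshold(
    lapply(cohort, function(cs) list(maps = cs$maps,
                                     refCc = sum(cs$refHg$volume_cc))),
    which = "highgrade", cancerCut = calCancer$threshold)
  cuts <- c(cancer = calCancer$threshold, highgrade = calHg$threshold)

  aggAll <- c(tp = 0, fp = 0, tn = 0, fn = 0)
  aggHg <- c(tp = 0, fp = 0, tn = 0, fn = 0)
  hgAsCancer <- c(captured = 0, total = 0)
  mriAllCc <- refAllCc <- mriHgCc <- refHgCc <- numeric(length(cohort))
  evaluation <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    cs <- cohort[[i]]
    maps <- binarizeMaps(cs$maps, cuts["cancer"], cuts["highgrade"])
    cohort[[i]]$maps <- maps
    lesAll <- extractLesions(maps@pcamMask, sp)
    lesHg <- extractLesions(maps@hgMask, sp)
    mtAll <- matchLesions(lesAll, cs$refAll,
                          prostateMask = maps@prostateMask, spacing = sp)
    mtHg <- matchLesions(lesHg, cs$refHg,
                         prostateMask = maps@prostateMask, spacing = sp)
    aggAll <- aggAll + mtAll$counts[c("tp", "fp", "tn", "fn")]
    aggHg <- aggHg + mtHg$counts[c("tp", "fp", "tn", "fn")]
    # high-grade reference lesions captured by the all-cancer mask
    mtCapture <- matchLesions(lesAll, cs$refHg,
                              prostateMask = maps@prostateMask,
                              spacing = sp)
    big <- cs$refHg$volume_cc > 0.1
    hgAsCancer <- hgAsCancer +
      c(captured = sum(mtCapture$refTable$category[big] == "TP"),
        total = sum(big))
    mriAllCc[i] <- tumorBurden(maps)
    refAllCc[i] <- sum(cs$refAll$volume_cc)
    mriHgCc[i] <- sum(maps@hgMask) * prod(sp) / 1000
    refHgCc[i] <- sum(cs$refHg$volume_cc)
    evaluation[[i]] <- list(matchAll = mtAll, matchHg = mtHg,
                            burden = burdenConfusion(
                              min(mriAllCc[i], sum(maps@prostateMask) *
                                    prod(sp) / 1000),
                              min(refAllCc[i], sum(maps@prostateMask) *
                                    prod(sp) / 1000),
                              sum(maps@prostateMask) * prod(sp) / 1000))
  }

  metricsAll <- detectionMetrics(tp = aggAll["tp"], fp = aggAll["fp"],
                                 tn = aggAll["tn"], fn = aggAll["fn"])
  metricsHg <- detectionMetrics(tp = aggHg["tp"], fp = aggHg["fp"],
                                tn = aggHg["tn"], fn = aggHg["fn"])

  rocCases <- lapply(cohort, function(cs) list(maps = cs$maps,
                                               truth = cs$truth))
  rocBurden <- thresholdRoc(rocCases, "burden",
                            thresholds = seq(0.05, 0.95, by = 0.05))
  sweepAround <- function(cut) seq(max(0.05, cut - 0.2), 0.95, by = 0.05)
  lesThr <- if (is.null(lesionRocThresholds))
    sweepAround(cuts["cancer"]) else lesionRocThresholds
  hgThr <- if (is.null(lesionRocThresholds))
    sweepAround(cuts["highgrade"]) else lesionRocThresholds
  rocLesion <- thresholdRoc(rocCases, "lesion", thresholds = lesThr)
  rocHg <- thresholdRoc(rocCases, "highgrade", thresholds = hgThr,
                        cancerCut = cuts["cancer"])

  list(cohort = cohort, roiTable = roiTable, models = models,
       cvResults = attr(models, "cvResults"),
       calibration = list(cancer = calCancer, highgrade = calHg),
       cuts = cuts,
       evaluation = evaluation,
       metrics = list(all = metricsAll, highgrade = metricsHg,
                      hgCapturedAsCancer = hgAsCancer),
       volumes = data.frame(case = seq_along(cohort), mriAllCc = mriAllCc,
                            refAllCc = refAllCc, mriHgCc = mriHgCc,
                            refHgCc = refHgCc),
       blandAltman = blandAltman(mriAllCc, refAllCc),
       roc = list(burden = rocBurden, lesion = rocLesion,
                  highgrade = rocHg))
}
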