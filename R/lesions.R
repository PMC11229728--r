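# Lesion-level evaluation: connected-component lesion extraction, 27-sector
# localization, matching against reference lesions under volume-bound
# rules, tumor-burden and per-lesion confusion factors, Bland-Altman
# agreement, and threshold-swept ROC curves.

#' Extract lesions from a binary mask
#'
#' Lesions are 3D connected components (26-connectivity by default) of the
#' mask. Components at or below the minimum volume are dropped from the
#' lesion list but retained in a sub-threshold report.
#'
#' @param mask logical 3D array
#' @param spacing voxel spacing mm
#' @param minVolumeCc minimum lesion volume (default 0.1 cc; components
#'   with volume <= this are sub-threshold)
#' @param connectivity 26 or 6
#' @param source label recorded per lesion ("mri" or "reference")
#' @return data.frame (id, volume_cc, nvox, cx, cy, cz, grade, source) with
#'   attributes `voxels` (list of linear index vectors, one per row) and
#'   `subthreshold` (same columns for the dropped components)
#' @export
extractLesions <- function(mask, spacing, minVolumeCc = 0.1,
                           connectivity = 26, source = "mri") {
  d <- dim(mask)
  voxCc <- prod(spacing) / 1000
  lab <- labelComponents(mask, connectivity)
  n <- max(lab)
  empty <- data.frame(id = integer(), volume_cc = numeric(),
                      nvox = integer(), cx = numeric(), cy = numeric(),
                      cz = numeric(), grade = character(),
                      source = character())
  if (n == 0) {
    attr(empty, "voxels") <- list()
    attr(empty, "subthreshold") <- empty
    return(empty)
  }
  rows <- vector("list", n)
  voxList <- vector("list", n)
  for (i in seq_len(n)) {
    vox <- which(lab == i)
    ctr <- colMeans(voxelCoords(vox, d, spacing))
    rows[[i]] <- data.frame(id = i, volume_cc = length(vox) * voxCc,
                            nvox = length(vox), cx = ctr[1], cy = ctr[2],
                            cz = ctr[3], grade = "any", source = source)
    voxList[[i]] <- vox
  }
  tab <- do.call(rbind, rows)
  keep <- tab$volume_cc > minVolumeCc
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "voxels") <- voxList[keep]
  sub <- tab[!keep, , drop = FALSE]
  rownames(sub) <- NULL
  attr(out, "subthreshold") <- sub
  out
}

#' Reference lesions from phantom ground truth
#'
#' Builds the reference lesion table from the ground-truth lesion labels,
#' carrying grade and true volume. No minimum-volume filter is applied
#' here; the matching rules handle sub-threshold lesions.
#'
#' @param truth a [GroundTruth-class]
#' @param spacing voxel spacing mm
#' @param grades which grades to include (default both)
#' @return lesion data.frame in the [extractLesions()] format with the
#'   `voxels` attribute
#' @export
lesionsFromTruth <- function(truth, spacing, grades = c("low", "high")) {
  d <- dim(truth@lesionLabels)
  tab <- truth@lesionTable
  sel <- which(tab$grade %in% grades)
  rows <- vector("list", length(sel))
  voxList <- vector("list", length(sel))
  for (k in seq_along(sel)) {
    i <- tab$id[sel[k]]
    vox <- which(truth@lesionLabels == i)
    rows[[k]] <- data.frame(id = i, volume_cc = tab$volume_cc[sel[k]],
                            nvox = length(vox), cx = tab$cx[sel[k]],
                            cy = tab$cy[sel[k]], cz = tab$cz[sel[k]],
                            grade = tab$grade[sel[k]], source = "reference")
    voxList[[k]] <- vox
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(), volume_cc = numeric(), nvox = integer(),
               cx = numeric(), cy = numeric(), cz = numeric(),
               grade = character(), source = character())
  rownames(out) <- NULL
  attr(out, "voxels") <- voxList
  out
}

#' Localize a lesion centroid in the 27-sector prostate grid
#'
#' The prostate bounding box is split into equal thirds along each
#' anatomical axis; the centroid's third on each axis gives the sector
#' triple (left/mid/right, anterior/mid/posterior, apex/mid/base).
#' Centroids outside the box are clamped to the nearest sector and
#' flagged.
#'
#' @param centroid numeric(3) mm coordinates
#' @param prostateMask logical array
#' @param spacing voxel spacing mm
#' @return character(3) sector labels with attributes `cell` (1..27) and
#'   `clamped`
#' @export
localizeLesion <- function(centroid, prostateMask, spacing) {
  d <- dim(prostateMask)
  pts <- voxelCoords(which(prostateMask), d, spacing)
  lo <- apply(pts, 2, min)
  hi <- apply(pts, 2, max)
  clamped <- any(centroid < lo) || any(centroid > hi)
  third <- function(v, a, b) {
    f <- (v - a) / max(b - a, 1e-9)
    min(max(floor(f * 3) + 1, 1), 3)
  }
  ix <- third(centroid[1], lo[1], hi[1])
  iy <- third(centroid[2], lo[2], hi[2])
  iz <- third(centroid[3], lo[3], hi[3])
  labels <- c(c("left", "mid", "right")[ix],
              c("anterior", "mid", "posterior")[iy],
              c("apex", "mid", "base")[iz])
  attr(labels, "cell") <- (ix - 1L) + (iy - 1L) * 3L + (iz - 1L) * 9L + 1L
  attr(labels, "clamped") <- clamped
  labels
}

lesionVolumeBounds <- function(vRef, boundConvention = "symmetric") {
  upper <- (4 / 3) * vRef + 1
  lower <- if (boundConvention == "symmetric") 0.75 * (vRef - 1) else
    0.75 * vRef - 1
  c(lower = lower, upper = upper)
}

#' Match MRI lesions to reference lesions
#'
#' Co-location is automated: two lesions are co-located when either
#' centroid lies inside the other's component or the centroids are within
#' a configurable distance. Matched pairs are assigned greedily by voxel
#' overlap, tie-broken by volume similarity then centroid distance. Each
#' reference lesion above the minimum volume is a true positive when its
#' matched MRI lesion volume lies within the bounding lines
#' (lower 0.75 (v_ref - 1) cc by default, upper 4/3 v_ref + 1 cc) and a
#' false negative otherwise; an MRI lesion with no reference partner, or
#' one exceeding the upper bound, is a false positive; pairs where both
#' lesions are at or below the minimum volume are not applicable. True
#' negatives are counted as the 27 prostate sectors containing neither an
#' MRI nor a reference lesion centroid (an interpretation recorded in the
#' output metadata: the countable negative unit is not defined by the
#' per-lesion factor table itself).
#'
#' @param mri,ref lesion data.frames from [extractLesions()] /
#'   [lesionsFromTruth()]
#' @param prostateMask optional logical array enabling the sector-based
#'   true-negative count
#' @param spacing voxel spacing mm (required with `prostateMask`)
#' @param colocDistMm centroid-distance co-location tolerance (default 5)
#' @param boundConvention `"symmetric"` (0.75 (v_ref - 1)) or `"table"`
#'   (0.75 v_ref - 1)
#' @param minVolumeCc minimum countable lesion volume (default 0.1 cc)
#' @return list of class `MatchTable`: `refTable` and `mriTable` with
#'   `category` and `partner` columns, `counts` (tp, fp, fn, na, tn), and
#'   `meta`
#' @export
matchLesions <- function(mri, ref, prostateMask = NULL, spacing = NULL,
                         colocDistMm = 5, boundConvention = "symmetric",
                         minVolumeCc = 0.1) {
  mriVox <- attr(mri, "voxels")
  refVox <- attr(ref, "voxels")
  nM <- nrow(mri); nR <- nrow(ref)

  # candidate co-located pairs
  pairs <- list()
  if (nM && nR) {
    for (i in seq_len(nM)) {
      for (j in seq_len(nR)) {
        dist <- sqrt((mri$cx[i] - ref$cx[j])^2 + (mri$cy[i] - ref$cy[j])^2 +
                       (mri$cz[i] - ref$cz[j])^2)
        overlap <- if (!is.null(mriVox) && !is.null(refVox))
          length(intersect(mriVox[[i]], refVox[[j]])) else 0L
        centroidInside <- FALSE
        if (!is.null(spacing) && !is.null(refVox) && !is.null(mriVox)) {
          d3 <- if (!is.null(prostateMask)) dim(prostateMask) else NULL
          if (!is.null(d3)) {
            mc <- round(c(mri$cx[i], mri$cy[i], mri$cz[i]) / spacing) + 1
            rc <- round(c(ref$cx[j], ref$cy[j], ref$cz[j]) / spacing) + 1
            inBounds <- function(v) all(v >= 1) && all(v <= d3)
            lin <- function(v) v[1] + (v[2] - 1) * d3[1] +
              (v[3] - 1) * d3[1] * d3[2]
            centroidInside <-
              (inBounds(mc) && lin(mc) %in% refVox[[j]]) ||
              (inBounds(rc) && lin(rc) %in% mriVox[[i]])
          }
        }
        if (overlap > 0 || dist <= colocDistMm || centroidInside) {
          pairs[[length(pairs) + 1L]] <- data.frame(
            i = i, j = j, overlap = overlap, dist = dist,
            volSim = abs(log(mri$volume_cc[i] / ref$volume_cc[j])))
        }
      }
    }
  }
  mriPartner <- rep(NA_integer_, nM)
  refPartner <- rep(NA_integer_, nR)
  if (length(pairs)) {
    P <- do.call(rbind, pairs)
    P <- P[order(-P$overlap, P$volSim, P$dist), , drop = FALSE]
    for (r in seq_len(nrow(P))) {
      i <- P$i[r]; j <- P$j[r]
      if (is.na(mriPartner[i]) && is.na(refPartner[j])) {
        mriPartner[i] <- j
        refPartner[j] <- i
      }
    }
  }

  refCat <- character(nR)
  for (j in seq_len(nR)) {
    if (ref$volume_cc[j] <= minVolumeCc) {
      # countable only if a countable MRI lesion claims it; otherwise NA
      refCat[j] <- "NA"
      next
    }
    i <- refPartner[j]
    if (is.na(i) || mri$volume_cc[i] <= minVolumeCc) {
      refCat[j] <- "FN"
    } else {
      b <- lesionVolumeBounds(ref$volume_cc[j], boundConvention)
      refCat[j] <- if (mri$volume_cc[i] >= b["lower"] &&
                         mri$volume_cc[i] <= b["upper"]) "TP" else "FN"
    }
  }
  mriCat <- character(nM)
  for (i in seq_len(nM)) {
    if (mri$volume_cc[i] <= minVolumeCc) {
      mriCat[i] <- "NA"
      next
    }
    j <- mriPartner[i]
    if (is.na(j) || ref$volume_cc[j] <= minVolumeCc) {
      mriCat[i] <- "FP"
    } else {
      b <- lesionVolumeBounds(ref$volume_cc[j], boundConvention)
      mriCat[i] <- if (mri$volume_cc[i] > b["upper"]) "FP"
        else if (mri$volume_cc[i] < b["lower"]) "FN" else "TP"
    }
  }

  tn <- NA_integer_
  if (!is.null(prostateMask) && !is.null(spacing)) {
    occupied <- logical(27)
    markCell <- function(tab, cat) {
      for (r in seq_len(nrow(tab))) {
        if (tab$volume_cc[r] <= minVolumeCc) next
        s <- localizeLesion(c(tab$cx[r], tab$cy[r], tab$cz[r]),
                            prostateMask, spacing)
        occupied[attr(s, "cell")] <<- TRUE
      }
    }
    markCell(mri)
    markCell(ref)
    tn <- sum(!occupied)
  }

  refOut <- ref
  refOut$category <- refCat
  refOut$partner <- refPartner
  mriOut <- mri
  mriOut$category <- mriCat
  mriOut$partner <- mriPartner
  counts <- c(tp = sum(refCat == "TP"),
              fp = sum(mriCat == "FP"),
              fn = sum(refCat == "FN"),
              na = sum(refCat == "NA") + sum(mriCat == "NA"),
              tn = tn)
  structure(list(refTable = refOut, mriTable = mriOut, counts = counts,
                 meta = list(colocDistMm = colocDistMm,
                             boundConvention = boundConvention,
                             minVolumeCc = minVolumeCc,
                             tnConvention = "27-sector cells without lesion centroids (interpretation)")),
            class = "MatchTable")
}

#' Tumor-burden confusion volumes
#'
#' Volume-level confusion factors: TP = min(MRI, reference) volume,
#' FP = max(MRI - reference, 0), TN = prostate - max(MRI, reference),
#' FN = max(reference - MRI, 0). The four volumes always sum to the
#' prostate volume.
#'
#' @param mriCc,refCc,prostateCc volumes in cc (`mriCc`, `refCc` within
#'   the prostate)
#' @return list of class `BurdenConfusion`: tp_cc, fp_cc, tn_cc, fn_cc,
#'   prostate_cc
#' @export
burdenConfusion <- function(mriCc, refCc, prostateCc) {
  stopifnot(mriCc >= 0, refCc >= 0, mriCc <= prostateCc,
            refCc <= prostateCc)
  structure(list(tp_cc = min(mriCc, refCc),
                 fp_cc = max(mriCc - refCc, 0),
                 tn_cc = prostateCc - max(mriCc, refCc),
                 fn_cc = max(refCc - mriCc, 0),
                 prostate_cc = prostateCc),
            class = "BurdenConfusion")
}

#' Detection metrics from confusion counts
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP) and positive predictive
#' value TP/(TP+FP), reported both as raw fractions and as rounded
#' percentages. Zero denominators yield NA with a flag.
#'
#' @param x optional `MatchTable` (its counts are used)
#' @param tp,fp,tn,fn counts (or volumes), used when `x` is missing
#' @return list with sensitivity/specificity/ppv fractions, `*Pct`
#'   rounded percents, the counts, and `undefined` naming any metric with
#'   a zero denominator
#' @export
detectionMetrics <- function(x = NULL, tp = NULL, fp = NULL, tn = NULL,
                             fn = NULL) {
  if (!is.null(x) && inherits(x, "MatchTable")) {
    cts <- x$counts
    tp <- cts["tp"]; fp <- cts["fp"]; tn <- cts["tn"]; fn <- cts["fn"]
  }
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  ratio <- function(num, den) if (!is.na(den) && den > 0) num / den else
    NA_real_
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  ppv <- ratio(tp, tp + fp)
  undefined <- c("sensitivity", "specificity", "ppv")[is.na(c(sens, spec,
                                                              ppv))]
  list(sensitivity = sens, specificity = spec, ppv = ppv,
       sensitivityPct = round(100 * sens), specificityPct = round(100 * spec),
       ppvPct = round(100 * ppv),
       counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
       undefined = undefined)
}

#' Bland-Altman agreement of MRI and reference volumes
#'
#' Differences d = MRI - reference: mean, sample SD, limits of agreement
#' (mean +/- 1.96 SD), plus split summaries for pairs with reference
#' volume below and above 1 cc.
#'
#' @param mriVolumes,refVolumes paired numeric vectors (cc)
#' @return list: meanDiff, sdDiff, limits, n, and `bySize` split summaries
#' @export
blandAltman <- function(mriVolumes, refVolumes) {
  if (length(mriVolumes) != length(refVolumes)) stop("length mismatch")
  stopifnot(length(mriVolumes) >= 2)
  d <- mriVolumes - refVolumes
  summarize <- function(dd) {
    if (!length(dd)) return(list(n = 0L, meanDiff = NA_real_,
                                 sdDiff = NA_real_))
    list(n = length(dd), meanDiff = mean(dd),
         sdDiff = if (length(dd) > 1) stats::sd(dd) else 0)
  }
  m <- mean(d)
  s <- stats::sd(d)
  list(meanDiff = m, sdDiff = s, limits = m + c(-1.96, 1.96) * s,
       n = length(d),
       bySize = list(small = summarize(d[refVolumes < 1]),
                     large = summarize(d[refVolumes > 1])))
}

#' Threshold-swept ROC over a cohort of risk maps
#'
#' At each probability threshold the masks are recomputed and the
#' confusion factors evaluated: volume factors (tumor-burden ROC) or
#' per-lesion factors with the volume-bound matching rules (lesion ROC,
#' all-cancer or high-grade). Sensitivity / (1 - specificity) points are
#' accumulated over the cohort and the trapezoidal AUC computed with
#' (0,0) and (1,1) anchors.
#'
#' @param cases list of per-case lists with `maps` (a binarizable
#'   [RiskMapSet-class]) and `truth` (a [GroundTruth-class])
#' @param which `"burden"`, `"lesion"`, or `"highgrade"`
#' @param thresholds sweep grid (>= 2 values)
#' @param cancerCut fixed cancer cut for `which = "highgrade"`
#' @param connectivity lesion connectivity
#' @param boundConvention volume-bound convention for matching
#' @return a [RocResult-class]; the per-threshold confusion factors are in
#'   attribute `sweep`
#' @export
thresholdRoc <- function(cases, which = c("burden", "lesion", "highgrade"),
                         thresholds = seq(0.05, 0.95, by = 0.05),
                         cancerCut = 0.7, connectivity = 26,
                         boundConvention = "symmetric") {
  which <- match.arg(which)
  stopifnot(length(thresholds) >= 2)
  thresholds <- sort(thresholds)
  sens <- numeric(length(thresholds))
  spec <- numeric(length(thresholds))
  sweepRows <- vector("list", length(thresholds))

  # per-case fixed quantities
  prep <- lapply(cases, function(cs) {
    maps <- cs$maps
    sp <- maps@voxelSpacing
    voxCc <- prod(sp) / 1000
    refAll <- lesionsFromTruth(cs$truth, sp)
    refHg <- lesionsFromTruth(cs$truth, sp, grades = "high")
    list(maps = maps, truth = cs$truth, sp = sp, voxCc = voxCc,
         refAll = refAll, refHg = refHg,
         refAllCc = sum(refAll$volume_cc),
         refHgCc = sum(refHg$volume_cc),
         prostateCc = sum(maps@prostateMask) * voxCc)
  })

  for (k in seq_along(thresholds)) {
    t <- thresholds[k]
    if (which == "burden") {
      agg <- c(tp = 0, fp = 0, tn = 0, fn = 0)
      for (pc in prep) {
        mriCc <- volumeAboveThresholds(pc$maps@pCancer,
                                       pc$maps@effectiveMask, t, pc$voxCc)
        bc <- burdenConfusion(min(mriCc, pc$prostateCc),
                              min(pc$refAllCc, pc$prostateCc),
                              pc$prostateCc)
        agg <- agg + c(tp = bc$tp_cc, fp = bc$fp_cc, tn = bc$tn_cc,
                       fn = bc$fn_cc)
      }
    } else {
      agg <- c(tp = 0, fp = 0, tn = 0, fn = 0)
      for (pc in prep) {
        maps <- pc$maps
        if (which == "lesion") {
          mask <- maps@effectiveMask & !is.na(maps@pCancer) &
            maps@pCancer >= t
          refTab <- pc$refAll
        } else {
          mask <- maps@effectiveMask & !is.na(maps@pCancer) &
            maps@pCancer >= cancerCut & !is.na(maps@pHighgrade) &
            maps@pHighgrade >= t
          refTab <- pc$refHg
        }
        les <- extractLesions(mask, pc$sp, connectivity = connectivity)
        mt <- matchLesions(les, refTab, prostateMask = maps@prostateMask,
                           spacing = pc$sp,
                           boundConvention = boundConvention)
        cts <- mt$counts
        agg <- agg + c(tp = unname(cts["tp"]), fp = unname(cts["fp"]),
                       tn = unname(cts["tn"]), fn = unname(cts["fn"]))
      }
    }
    sens[k] <- if (agg["tp"] + agg["fn"] > 0)
      agg["tp"] / (agg["tp"] + agg["fn"]) else NA_real_
    spec[k] <- if (agg["tn"] + agg["fp"] > 0)
      agg["tn"] / (agg["tn"] + agg["fp"]) else NA_real_
    sweepRows[[k]] <- data.frame(threshold = t, tp = agg["tp"],
                                 fp = agg["fp"], tn = agg["tn"],
                                 fn = agg["fn"], sensitivity = sens[k],
                                 specificity = spec[k], row.names = NULL)
  }
  ok <- is.finite(sens) & is.finite(spec)
  fpr <- 1 - spec[ok]
  tpr <- sens[ok]
  ox <- c(1, fpr, 0); oy <- c(1, tpr, 0)
  ord <- order(ox, oy)
  auc <- sum(diff(ox[ord]) * (utils::head(oy[ord], -1) +
                                utils::tail(oy[ord], -1)) / 2)
  auc <- min(max(auc, 0), 1)
  youden <- tpr - fpr
  best <- which(youden == max(youden))
  pick <- best[which.min(abs(tpr[best] - (1 - fpr[best])))]
  res <- new("RocResult", thresholds = thresholds[ok], sensitivity = tpr,
             specificity = 1 - fpr, auc = auc,
             operatingPoint = c(threshold = thresholds[ok][pick],
                                sensitivity = tpr[pick],
                                specificity = (1 - fpr)[pick]))
  attr(res, "sweep") <- do.call(rbind, sweepRows)
  res
}
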