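# Synthetic mpMRI phantom: prostate with PZ/TZ zonal anatomy, an anterior
# fibromuscular stroma (AFMS) wedge, graded lesions of controlled volume,
# an endorectal-coil multiplicative bias on T2W, per-case DCE amplitude
# scaling, and optional rigid misalignment / diffusion distortion.

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Default tissue parameter distributions
#'
#' Mean vectors and (diagonal) covariances over the six MRI parameters for
#' the five prostate tissue classes. Units: t2w arbitrary (raw, before
#' normalization), adc in 1e-3 mm^2/s, fa dimensionless, pe/es/wo in
#' arbitrary DCE units (es, wo per second; wo positive = signal loss after
#' the peak). The means encode the qualitative contrasts of prostate
#' cancer on mpMRI (low T2W and ADC, high enhancement slope and washout)
#' and of AFMS (low T2W/ADC/DCE, high FA); the grade contrast is
#' deliberately weaker than the cancer-vs-benign contrast.
#'
#' @return named list over the tissue classes, each with `mean` and `cov`
#' @export
defaultTissueParams <- function() {
  sds <- c(t2w = 170, adc = 0.21, fa = 0.085, pe = 34, es = 4.3, wo = 0.77)
  mk <- function(...) {
    m <- c(...)
    names(m) <- MRI_PARAMS
    cv <- diag(sds^2)
    dimnames(cv) <- list(MRI_PARAMS, MRI_PARAMS)
    list(mean = m, cov = cv)
  }
  list(
    benign_PZ = mk(1350, 1.70, 0.15, 150, 6.0, 0.4),
    benign_TZ = mk(1200, 1.60, 0.22, 160, 6.0, 0.5),
    AFMS      = mk(650, 1.05, 0.55, 130, 12.0, 1.5),
    PCa_low   = mk(730, 0.95, 0.28, 170, 18.0, 2.6),
    PCa_high  = mk(705, 0.90, 0.295, 172, 19.5, 2.9)
  )
}

#' Default non-prostate tissue distributions (body, muscle, air)
#' @return named list with `mean` and `cov` per class
#' @export
defaultBackgroundParams <- function() {
  mk <- function(means, sds) {
    names(means) <- MRI_PARAMS
    cv <- diag(sds^2)
    dimnames(cv) <- list(MRI_PARAMS, MRI_PARAMS)
    list(mean = means, cov = cv)
  }
  list(
    body   = mk(c(400, 1.80, 0.20, 40, 2.0, 0.2), c(80, 0.30, 0.10, 15, 1.5, 0.3)),
    muscle = mk(c(500, 1.50, 0.30, 60, 3.0, 0.3), c(50, 0.20, 0.08, 15, 1.5, 0.3)),
    air    = mk(c(30, 0.30, 0.10, 5, 0.5, 0.05), c(15, 0.15, 0.06, 3, 0.5, 0.1))
  )
}

#' Build a phantom configuration
#'
#' @param gridShape voxels per axis (default 96 x 96 x 24)
#' @param voxelSpacing mm per axis (default 1 x 1 x 3; 3 mm slices)
#' @param tissueParams see [defaultTissueParams()]
#' @param backgroundParams see [defaultBackgroundParams()]
#' @param lesionSpecs data.frame with columns `zone`, `grade`, `volume_cc`
#'   and optional seed coordinates `sx`, `sy`, `sz` (mm)
#' @param coilBias c(amplitude, decay mm) of the multiplicative T2W field
#' @param patientPeScale per-case DCE amplitude multiplier
#' @param misalignment [RigidTransform-class] applied to non-T2W volumes
#' @param dwiDistortion max local displacement (mm) warped into ADC/FA
#' @param sizeScale prostate size multiplier
#' @param caseJitter between-case tissue heterogeneity as a fraction of
#'   the class SD (one mean offset per class per case)
#' @param spatialFrac fraction of the within-class SD carried by a smooth
#'   spatial heterogeneity field (regional tissue variation) instead of
#'   iid voxel noise; the total within-class variance is preserved
#' @param spatialScaleMm correlation length of that field (mm)
#' @param rngSeed integer seed
#' @return a validated [PhantomConfig-class]
#' @export
phantomConfig <- function(gridShape = c(96L, 96L, 24L),
                          voxelSpacing = c(1, 1, 3),
                          tissueParams = defaultTissueParams(),
                          backgroundParams = defaultBackgroundParams(),
                          lesionSpecs = data.frame(
                            zone = c("PZ", "TZ"), grade = c("high", "low"),
                            volume_cc = c(1.0, 0.5)),
                          coilBias = c(amplitude = 1.2, decay = 40),
                          patientPeScale = 1,
                          misalignment = rigidTransform(),
                          dwiDistortion = 0,
                          sizeScale = 1,
                          caseJitter = 0,
                          spatialFrac = 0.7,
                          spatialScaleMm = 12,
                          rngSeed = 1L) {
  new("PhantomConfig", gridShape = as.integer(gridShape),
      voxelSpacing = as.numeric(voxelSpacing), tissueParams = tissueParams,
      backgroundParams = backgroundParams, lesionSpecs = lesionSpecs,
      coilBias = as.numeric(coilBias), patientPeScale = patientPeScale,
      misalignment = misalignment, dwiDistortion = dwiDistortion,
      sizeScale = sizeScale, caseJitter = caseJitter,
      spatialFrac = spatialFrac, spatialScaleMm = spatialScaleMm,
      rngSeed = as.integer(rngSeed))
}

coordArrays <- function(d, sp) {
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  zs <- (seq_len(d[3]) - 1) * sp[3]
  list(
    X = array(rep(xs, times = d[2] * d[3]), d),
    Y = array(rep(rep(ys, each = d[1]), times = d[3]), d),
    Z = array(rep(zs, each = d[1] * d[2]), d)
  )
}

inEllipsoid <- function(co, center, semi) {
  ((co$X - center[1]) / semi[1])^2 + ((co$Y - center[2]) / semi[2])^2 +
    ((co$Z - center[3]) / semi[3])^2 <= 1
}

#' Generate one synthetic mpMRI case
#'
#' Voxel parameter vectors are drawn from their tissue-class multivariate
#' normal distribution on the T2W grid; the T2W volume is multiplied by the
#' endorectal-coil bias field, the DCE volumes (pe, es, wo) by the per-case
#' amplitude scale. Optionally the non-T2W volumes are rigidly misaligned
#' and the diffusion volumes locally distorted. Deterministic given
#' `config@rngSeed`.
#'
#' @param config a [PhantomConfig-class]
#' @return list with elements `case` ([MpMriCase-class]) and `truth`
#'   ([GroundTruth-class])
#' @export
generateCase <- function(config) {
  validObject(config)
  withSeed(config@rngSeed, {
    d <- config@gridShape
    sp <- config@voxelSpacing
    voxVolCc <- prod(sp) / 1000
    co <- coordArrays(d, sp)
    c0 <- (d - 1) * sp / 2
    scl <- config@sizeScale

    body <- inEllipsoid(co, c0, c(44, 44, 33))
    pc <- c0 + c(0, 6, 0)
    prostSemi <- c(22, 19, 16) * scl
    prostate <- inEllipsoid(co, pc, prostSemi)
    tz <- inEllipsoid(co, pc + c(0, -5 * scl, 1), c(14.5, 11, 10.5) * scl)
    afms <- prostate & (co$Y < pc[2] - 0.58 * prostSemi[2]) &
      (abs(co$X - pc[1]) < 9 * scl)

    zone <- array(0L, d)
    zone[prostate] <- 1L           # PZ
    zone[prostate & tz] <- 2L      # TZ
    zone[afms] <- 3L               # AFMS

    # obturator muscle: two lateral spheres; reference ROIs inside them
    muscCenters <- list(pc + c(-32, 4, 0), pc + c(32, 4, 0))
    muscle <- array(FALSE, d)
    for (mcc in muscCenters) muscle <- muscle | inEllipsoid(co, mcc, c(6, 6, 6))
    muscle <- muscle & !prostate
    muscleRois <- lapply(muscCenters, function(mcc)
      which(inEllipsoid(co, mcc, c(3, 3, 3))))

    # lesions: grown as spheroids by taking the target number of nearest
    # in-zone voxels around a seed
    lesion <- array(0L, d)
    specs <- config@lesionSpecs
    lesRows <- list()
    seedPts <- list()   # placed (seed, radius) pairs: keep foci distinct
    if (nrow(specs)) {
      for (li in seq_len(nrow(specs))) {
        zl <- if (specs$zone[li] == "PZ") 1L else 2L
        cand <- which(zone == zl & lesion == 0L)
        nTarget <- max(1L, round(specs$volume_cc[li] / voxVolCc))
        if (length(cand) < nTarget)
          stop(sprintf("lesion %d (%.2f cc) exceeds remaining %s capacity (%.2f cc)",
                       li, specs$volume_cc[li], specs$zone[li],
                       length(cand) * voxVolCc))
        candXYZ <- voxelCoords(cand, d, sp)
        rNew <- 6.2 * specs$volume_cc[li]^(1 / 3)   # equivalent-sphere mm
        if (all(c("sx", "sy", "sz") %in% names(specs)) &&
            is.finite(specs$sx[li])) {
          seedPt <- c(specs$sx[li], specs$sy[li], specs$sz[li])
        } else {
          # prefer seeds clear of already placed lesions (distinct foci)
          okSeed <- rep(TRUE, length(cand))
          for (buffer in c(4, 0)) {
            okSeed <- rep(TRUE, length(cand))
            for (sprev in seedPts) {
              dd <- sqrt((candXYZ[, 1] - sprev$pt[1])^2 +
                           (candXYZ[, 2] - sprev$pt[2])^2 +
                           (candXYZ[, 3] - sprev$pt[3])^2)
              okSeed <- okSeed & dd > (rNew + sprev$r + buffer)
            }
            if (any(okSeed)) break
          }
          pool <- if (any(okSeed)) which(okSeed) else seq_along(cand)
          seedPt <- candXYZ[pool[sample.int(length(pool), 1)], ]
        }
        seedPts[[length(seedPts) + 1L]] <- list(pt = seedPt, r = rNew)
        dist <- sqrt((candXYZ[, 1] - seedPt[1])^2 +
                       (candXYZ[, 2] - seedPt[2])^2 +
                       (candXYZ[, 3] - seedPt[3])^2)
        take <- cand[order(dist, cand)[seq_len(nTarget)]]
        lesion[take] <- li
        ctr <- colMeans(voxelCoords(take, d, sp))
        lesRows[[li]] <- data.frame(
          id = li, grade = specs$grade[li], zone = specs$zone[li],
          volume_cc = nTarget * voxVolCc,
          cx = ctr[1], cy = ctr[2], cz = ctr[3])
      }
    }
    lesTab <- if (length(lesRows)) do.call(rbind, lesRows) else
      data.frame(id = integer(), grade = character(), zone = character(),
                 volume_cc = numeric(), cx = numeric(), cy = numeric(),
                 cz = numeric())

    # voxel class map
    classId <- array(0L, d)                 # 0 = air
    classId[body] <- 6L                     # body
    classId[muscle] <- 7L
    classId[zone == 1L] <- 1L
    classId[zone == 2L] <- 2L
    classId[zone == 3L] <- 3L
    isLow <- lesion > 0L
    if (any(isLow)) {
      gr <- specs$grade[lesion[isLow]]
      classId[isLow] <- ifelse(gr == "high", 5L, 4L)
    }

    params <- c(config@tissueParams,
                list(body = config@backgroundParams$body,
                     muscle = config@backgroundParams$muscle,
                     air = config@backgroundParams$air))
    classKey <- c(air = 0L, benign_PZ = 1L, benign_TZ = 2L, AFMS = 3L,
                  PCa_low = 4L, PCa_high = 5L, body = 6L, muscle = 7L)

    # smooth regional heterogeneity fields (one per parameter, unit SD)
    h <- config@spatialFrac
    fields <- NULL
    if (h > 0) {
      fields <- lapply(MRI_PARAMS, function(p) {
        f <- gaussSmooth3d(array(stats::rnorm(prod(d)), d),
                           config@spatialScaleMm, sp)
        f / stats::sd(f)
      })
      names(fields) <- MRI_PARAMS
    }

    vols <- lapply(MRI_PARAMS, function(p) array(0, d))
    names(vols) <- MRI_PARAMS
    for (cl in names(classKey)) {
      idx <- which(classId == classKey[[cl]])
      if (!length(idx)) next
      pp <- params[[cl]]
      mu <- pp$mean[MRI_PARAMS]
      inProstate <- cl %in% TISSUE_CLASSES
      # between-case heterogeneity: one mean offset per prostate class
      if (config@caseJitter > 0 && inProstate) {
        sdv <- sqrt(diag(as.matrix(pp$cov)))
        mu <- mu + stats::rnorm(length(mu), 0, config@caseJitter * sdv)
      }
      covIid <- if (inProstate && h > 0) (1 - h^2) * pp$cov else pp$cov
      draws <- MASS::mvrnorm(length(idx), mu, covIid, tol = 1e-6)
      draws <- matrix(draws, nrow = length(idx))
      if (inProstate && h > 0) {
        sdv <- sqrt(diag(as.matrix(pp$cov)))
        for (k in seq_along(MRI_PARAMS))
          draws[, k] <- draws[, k] + h * sdv[k] * fields[[k]][idx]
      }
      for (k in seq_along(MRI_PARAMS)) vols[[k]][idx] <- draws[, k]
    }

    # endorectal coil reception profile (posterior to the prostate)
    coilPos <- pc + c(0, prostSemi[2] + 12, 0)
    distCoil <- sqrt((co$X - coilPos[1])^2 + (co$Y - coilPos[2])^2 +
                       (co$Z - coilPos[3])^2)
    bias <- 1 + config@coilBias[1] * exp(-distCoil / config@coilBias[2])
    vols$t2w <- pmax(vols$t2w * bias, 0)

    for (p in c("pe", "es", "wo")) vols[[p]] <- vols[[p]] * config@patientPeScale

    # local diffusion distortion: smooth random displacement capped in mm
    if (config@dwiDistortion > 0) {
      disp <- lapply(1:3, function(k)
        gaussSmooth3d(array(stats::rnorm(prod(d)), d), 12, sp))
      mag <- sqrt(disp[[1]]^2 + disp[[2]]^2 + disp[[3]]^2)
      scale <- config@dwiDistortion / max(mag)
      pts <- voxelCoords(seq_len(prod(d)), d, sp)
      warped <- cbind(pts[, 1] + as.vector(disp[[1]]) * scale,
                      pts[, 2] + as.vector(disp[[2]]) * scale,
                      pts[, 3] + as.vector(disp[[3]]) * scale)
      for (p in c("adc", "fa")) {
        w <- trilinearSample(vols[[p]], warped, sp, fill = NA_real_)
        w[!is.finite(w)] <- vols[[p]][!is.finite(w)]
        vols[[p]] <- array(w, d)
      }
    }

    if (!isIdentityTransform(config@misalignment)) {
      for (p in setdiff(MRI_PARAMS, "t2w"))
        vols[[p]] <- resampleVolume(vols[[p]], config@misalignment, sp)
    }

    case <- new("MpMriCase", volumes = vols, voxelSpacing = sp,
                caseId = paste0("phantom-", config@rngSeed),
                muscleRois = muscleRois, peAveCase = NA_real_,
                prostateMask = prostate, bodyMask = body)
    truth <- new("GroundTruth", zoneLabels = zone, lesionLabels = lesion,
                 lesionTable = lesTab,
                 appliedTransform = config@misalignment,
                 coilBiasField = bias)
    list(case = case, truth = truth)
  })
}

#' Generate a cohort of phantom cases
#'
#' Cases vary in prostate size, lesion number/size/grade/zone, and per-case
#' DCE amplitude. Lesion volumes follow a clamped log-normal whose mean/SD
#' default to the burden statistics of a prostatectomy cohort (mean 0.55 cc,
#' SD 0.98 cc); lesion count is Poisson (mean 3.7, at least one).
#' Reproducible given `seed`.
#'
#' @param nCases number of cases (>= 1)
#' @param baseConfig template [PhantomConfig-class]
#' @param seed integer cohort seed
#' @param lesionVolMeanlog,lesionVolSdlog log-normal parameters of lesion
#'   volume (cc)
#' @param lesionRate mean lesions per case
#' @param pHighGrade probability a lesion is high grade (GG >= 3)
#' @param pPZ probability a lesion sits in the peripheral zone
#' @param peScaleSdlog log-normal sd of the per-case DCE amplitude
#' @param minBurdenCc minimum total lesion volume per case (cc); volumes
#'   are redrawn until the total reaches it, emulating a biopsy-proven
#'   cancer cohort
#' @param sizeScaleRange uniform range of the prostate size multiplier
#' @param misalignMaxMm,misalignMaxDeg if positive, draw a uniform rigid
#'   misalignment within these bounds for the non-T2W volumes
#' @param dwiDistortion max diffusion-distortion displacement (mm)
#' @return list of per-case lists (`case`, `truth`, `config`)
#' @export
generateCohort <- function(nCases, baseConfig = phantomConfig(), seed = 1,
                           lesionVolMeanlog = -1.313, lesionVolSdlog = 1.196,
                           lesionRate = 3.7, pHighGrade = 0.4, pPZ = 0.7,
                           peScaleSdlog = 0.3,
                           minBurdenCc = 0.5,
                           sizeScaleRange = c(0.88, 1.12),
                           misalignMaxMm = 0, misalignMaxDeg = 0,
                           dwiDistortion = 0) {
  stopifnot(nCases >= 1)
  withSeed(seed, {
    out <- vector("list", nCases)
    for (i in seq_len(nCases)) {
      caseSeed <- sample.int(.Machine$integer.max %/% 2, 1)
      sizeScale <- stats::runif(1, sizeScaleRange[1], sizeScaleRange[2])
      peScale <- stats::rlnorm(1, 0, peScaleSdlog)
      nLes <- max(1L, stats::rpois(1, lesionRate))
      volsCc <- pmin(pmax(stats::rlnorm(nLes, lesionVolMeanlog,
                                        lesionVolSdlog), 0.02), 5)
      tries <- 0L
      while (sum(volsCc) < minBurdenCc && tries < 50L) {
        volsCc <- pmin(pmax(stats::rlnorm(nLes, lesionVolMeanlog,
                                          lesionVolSdlog), 0.02), 5)
        tries <- tries + 1L
      }
      zones <- ifelse(stats::runif(nLes) < pPZ, "PZ", "TZ")
      # keep the transition zone from being over-filled
      tzIdx <- which(zones == "TZ")
      if (length(tzIdx) && sum(volsCc[tzIdx]) > 3.5 * sizeScale^3) {
        zones[tzIdx[order(volsCc[tzIdx], decreasing = TRUE)][1]] <- "PZ"
      }
      grades <- ifelse(stats::runif(nLes) < pHighGrade, "high", "low")
      mis <- rigidTransform(center = (baseConfig@gridShape - 1) *
                              baseConfig@voxelSpacing / 2)
      if (misalignMaxMm > 0 || misalignMaxDeg > 0) {
        mis <- rigidTransform(
          translation = stats::runif(3, -misalignMaxMm, misalignMaxMm),
          rotation = stats::runif(3, -misalignMaxDeg, misalignMaxDeg),
          center = (baseConfig@gridShape - 1) * baseConfig@voxelSpacing / 2)
      }
      cfg <- baseConfig
      cfg@lesionSpecs <- data.frame(zone = zones, grade = grades,
                                    volume_cc = volsCc)
      cfg@patientPeScale <- peScale
      cfg@sizeScale <- sizeScale
      cfg@misalignment <- mis
      cfg@dwiDistortion <- dwiDistortion
      cfg@rngSeed <- caseSeed
      res <- generateCase(cfg)
      res$case@caseId <- sprintf("case-%03d", i)
      res$config <- cfg
      out[[i]] <- res
    }
    out
  })
}

#' Tabulate tissue ROI means from a phantom case
#'
#' Draws small spherical ROIs fully contained in a single tissue class and
#' records the mean of every MRI parameter, emulating the tabulation of
#' clear-cut tissue regions used to train the tissue models. Classes whose
#' geometry cannot host the requested number of spheres are reported short
#' with a warning.
#'
#' @param case an [MpMriCase-class] (typically after normalization)
#' @param truth the matching [GroundTruth-class]
#' @param roisPerClass ROIs requested per tissue class present
#' @param roiRadiusMm ROI sphere radius (mm)
#' @param seed sampling seed
#' @param placementErrorMm SD (mm) of a random offset applied to each ROI
#'   centre after it is chosen, emulating the error of transferring
#'   histology regions onto the MRI via anatomical landmarks; the offset
#'   sphere may straddle tissue classes while the row keeps its intended
#'   label. 0 (the default) samples spheres fully inside one class.
#' @return data.frame with case_id, zone, tissue_class and the six
#'   parameter means; attribute `shortfall` reports classes that came up
#'   short
#' @export
extractRoiTable <- function(case, truth, roisPerClass = 6,
                            roiRadiusMm = 2.5, seed = 1,
                            placementErrorMm = 0) {
  d <- dim(truth@zoneLabels)
  sp <- case@voxelSpacing
  if (roisPerClass == 0) {
    return(data.frame(case_id = character(), zone = character(),
                      tissue_class = character(), t2w = numeric(),
                      adc = numeric(), fa = numeric(), pe = numeric(),
                      es = numeric(), wo = numeric()))
  }
  classId <- array(0L, d)
  classId[truth@zoneLabels == 1L] <- 1L
  classId[truth@zoneLabels == 2L] <- 2L
  classId[truth@zoneLabels == 3L] <- 3L
  les <- truth@lesionLabels
  if (any(les > 0L)) {
    gr <- truth@lesionTable$grade[les[les > 0L]]
    classId[les > 0L] <- ifelse(gr == "high", 5L, 4L)
  }
  classNames <- c("benign", "benign", "AFMS", "PCa_low", "PCa_high")
  off <- sphereOffsets(roiRadiusMm, sp)
  nOff <- nrow(off)
  rows <- list()
  short <- character()
  withSeed(seed, {
    for (cid in 1:5) {
      vox <- which(classId == cid)
      if (!length(vox)) { short <- c(short, classNames[cid]); next }
      cand <- vox[sample.int(length(vox))]
      got <- 0L
      ci <- 1L
      while (got < roisPerClass && ci <= length(cand) &&
             ci <= 80L * roisPerClass) {
        ctr <- arrayInd(cand[ci], d)
        ci <- ci + 1L
        xs <- ctr[1] + off[, 1]; ys <- ctr[2] + off[, 2]; zs <- ctr[3] + off[, 3]
        if (any(xs < 1 | xs > d[1] | ys < 1 | ys > d[2] | zs < 1 | zs > d[3]))
          next
        lin <- cbind(xs, ys, zs)
        if (any(classId[lin] != cid)) next
        if (placementErrorMm > 0) {
          shift <- round(stats::rnorm(3, 0, placementErrorMm) / sp)
          xs2 <- xs + shift[1]; ys2 <- ys + shift[2]; zs2 <- zs + shift[3]
          okv <- xs2 >= 1 & xs2 <= d[1] & ys2 >= 1 & ys2 <= d[2] &
            zs2 >= 1 & zs2 <= d[3]
          if (sum(okv) < nOff / 2) next
          lin <- cbind(xs2[okv], ys2[okv], zs2[okv])
        }
        vals <- vapply(MRI_PARAMS, function(p) mean(case@volumes[[p]][lin]),
                       numeric(1))
        if (any(!is.finite(vals))) next
        got <- got + 1L
        zn <- truth@zoneLabels[ctr[1], ctr[2], ctr[3]]
        rows[[length(rows) + 1L]] <- data.frame(
          case_id = case@caseId,
          zone = c("PZ", "TZ", "TZ")[zn],
          tissue_class = classNames[cid],
          t2w = vals["t2w"], adc = vals["adc"], fa = vals["fa"],
          pe = vals["pe"], es = vals["es"], wo = vals["wo"],
          row.names = NULL)
      }
      if (got < roisPerClass)
        short <- c(short, sprintf("%s (%d/%d)", classNames[cid], got,
                                  roisPerClass))
    }
  })
  if (length(short))
    warning("ROI shortfall for class(es): ", paste(short, collapse = ", "))
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case_id = character(), zone = character(),
               tissue_class = character(), t2w = numeric(), adc = numeric(),
               fa = numeric(), pe = numeric(), es = numeric(), wo = numeric())
  attr(tab, "shortfall") <- short
  tab
}
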