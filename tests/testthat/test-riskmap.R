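# Map building, AFMS exclusion, binarization with the dual-threshold
# rule, burden arithmetic and threshold calibration.

mkMapModel <- function(A = 0, B = numeric(0), type = "cancer_vs_benign",
                       zone = "PZ") {
  new("LogisticTissueModel", modelType = type, zone = zone, intercept = A,
      linCoef = B, quadCoef = setNames(numeric(0), character(0)),
      includedTerms = names(B) %||% character(0), fitMetadata = list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a tiny case with handcrafted volumes on a 6x6x2 grid
tinyCase <- function() {
  d <- c(6L, 6L, 2L)
  vols <- lapply(seq_along(ProCaMap:::MRI_PARAMS), function(i) array(1, d))
  names(vols) <- ProCaMap:::MRI_PARAMS
  prostate <- array(FALSE, d)
  prostate[2:5, 2:5, ] <- TRUE
  new("MpMriCase", volumes = vols, voxelSpacing = c(1, 1, 3),
      caseId = "tiny", muscleRois = list(), peAveCase = NA_real_,
      prostateMask = prostate, bodyMask = array(TRUE, d))
}

tinyModels <- function(afmsA = -10, cancerB = 2, hgB = 1) {
  m <- list()
  for (z in c("PZ", "TZ")) {
    m[[z]] <- list(
      afms_vs_cancer = mkMapModel(A = afmsA, type = "afms_vs_cancer",
                                  zone = z),
      cancer_vs_benign = mkMapModel(A = 0, B = c(adc = cancerB),
                                    type = "cancer_vs_benign", zone = z),
      high_vs_low = mkMapModel(A = 0, B = c(wo = hgB),
                               type = "high_vs_low", zone = z))
  }
  m
}

test_that("map values equal model predictions and respect zone assignment", {
  case <- tinyCase()
  case@volumes$adc[3, 3, 1] <- 2     # cancer-like voxel
  zones <- array(0L, dim(case@prostateMask))
  zones[case@prostateMask] <- 1L
  zones[4:5, 2:5, ] <- 2L
  models <- tinyModels()
  # distinct TZ model to verify per-zone application
  models$TZ$cancer_vs_benign <- mkMapModel(A = 1, B = c(adc = -1),
                                           type = "cancer_vs_benign",
                                           zone = "TZ")
  maps <- buildMaps(case, zones, models)
  expect_equal(maps@pCancer[3, 3, 1], plogis(2 * 2), tolerance = 1e-12)
  expect_equal(maps@pCancer[2, 2, 1], plogis(2 * 1), tolerance = 1e-12)
  expect_equal(maps@pCancer[4, 2, 1], plogis(1 - 1), tolerance = 1e-12)
  # swapping the zone labels swaps the model assignment exactly
  zonesSw <- zones
  zonesSw[zones == 1L] <- 2L
  zonesSw[zones == 2L] <- 1L
  mapsSw <- buildMaps(case, zonesSw, models)
  expect_equal(mapsSw@pCancer[2, 2, 1], plogis(1 - 1), tolerance = 1e-12)
  expect_equal(mapsSw@pCancer[4, 2, 1], plogis(2 * 1), tolerance = 1e-12)
  # with no AFMS-like voxels the effective mask is the prostate mask
  expect_equal(maps@effectiveMask, case@prostateMask)
  expect_equal(sum(maps@afmsMask), 0)
})

test_that("AFMS-probable voxels are removed from the effective mask and
           missing-parameter voxels are excluded with a count", {
  case <- tinyCase()
  zones <- array(0L, dim(case@prostateMask))
  zones[case@prostateMask] <- 1L
  models <- tinyModels()
  # an AFMS model keyed on fa: fa >= 1 gives probability ~1
  models$PZ$afms_vs_cancer <- mkMapModel(A = -5, B = c(fa = 10),
                                         type = "afms_vs_cancer",
                                         zone = "PZ")
  case@volumes$fa[2, 2, 1] <- 1      # AFMS-like
  case@volumes$t2w[5, 5, 2] <- NA    # missing parameter
  maps <- buildMaps(case, zones, models)
  expect_true(maps@afmsMask[2, 2, 1])
  expect_false(maps@effectiveMask[2, 2, 1])
  expect_false(maps@effectiveMask[5, 5, 2])
  expect_equal(maps@nMissing, 1L)
  expect_true(is.na(maps@pCancer[2, 2, 1]))
})

test_that("binarization applies inclusive cuts and the dual-threshold
           high-grade rule", {
  case <- tinyCase()
  zones <- array(0L, dim(case@prostateMask))
  zones[case@prostateMask] <- 1L
  maps <- buildMaps(case, zones, tinyModels())
  # craft probabilities directly
  maps@pCancer[case@prostateMask] <- 0.6
  maps@pCancer[2, 2, 1] <- 0.8
  maps@pHighgrade[case@prostateMask] <- 0.99
  maps@pHighgrade[2, 2, 1] <- 0.9
  bm <- binarizeMaps(maps, 0.7, 0.5)
  # (p_cancer .8, p_hg .9) with cuts (.7, .5): in both masks
  expect_true(bm@pcamMask[2, 2, 1])
  expect_true(bm@hgMask[2, 2, 1])
  # (p_cancer .6, p_hg .99): in neither (must first be confirmed cancer)
  expect_false(bm@pcamMask[3, 3, 1])
  expect_false(bm@hgMask[3, 3, 1])
  expect_true(all(!bm@hgMask | bm@pcamMask))
  # boundary: cut exactly 1 keeps only p == 1
  maps2 <- maps
  maps2@pCancer[case@prostateMask] <- 0.999
  expect_equal(sum(binarizeMaps(maps2, 1, 0.5)@pcamMask), 0)
  expect_error(binarizeMaps(maps, 0, 0.5), "cuts")
  # property: hgMask is a subset of pcamMask for random maps
  withr::with_seed(5, {
    for (rep in 1:20) {
      maps@pCancer[case@prostateMask] <- runif(sum(case@prostateMask))
      maps@pHighgrade[case@prostateMask] <- runif(sum(case@prostateMask))
      bmr <- binarizeMaps(maps, runif(1, 0.2, 0.9), runif(1, 0.2, 0.9))
      expect_true(all(!bmr@hgMask | bmr@pcamMask))
    }
  })
})

test_that("tumor burden counts mask voxels times voxel volume and is
           non-increasing in the cut", {
  case <- tinyCase()
  zones <- array(0L, dim(case@prostateMask))
  zones[case@prostateMask] <- 1L
  maps <- buildMaps(case, zones, tinyModels())
  withr::with_seed(8, {
    maps@pCancer[case@prostateMask] <- runif(sum(case@prostateMask))
  })
  expect_equal(tumorBurden(binarizeMaps(maps, 0.99999, 0.5)), 0)
  bm <- binarizeMaps(maps, 0.5, 0.5)
  expect_equal(tumorBurden(bm), sum(bm@pcamMask) * 0.003, tolerance = 1e-12)
  burdens <- vapply(seq(0.1, 0.9, 0.1), function(ct)
    tumorBurden(binarizeMaps(maps, ct, 0.5)), numeric(1))
  expect_true(all(diff(burdens) <= 0))
  # 334 voxels at 0.003 cc = 1.002 cc
  expect_equal(tumorBurden(array(c(rep(TRUE, 334), rep(FALSE, 66)),
                                 c(100, 2, 2)), voxelVolumeCc = 0.003),
               1.002, tolerance = 1e-12)
})

test_that("threshold calibration: tie rule, arithmetic and monotone sweep", {
  case <- tinyCase()
  zones <- array(0L, dim(case@prostateMask))
  zones[case@prostateMask] <- 1L
  maps <- buildMaps(case, zones, tinyModels())
  n <- sum(case@prostateMask)
  voxCc <- 0.003
  # maps equal to a reference indicator: every threshold gives ratio 1,
  # the smallest grid value wins the tie
  ind <- maps
  ind@pCancer[case@prostateMask] <- rep(c(1, 0), length.out = n)
  refCc <- sum(ind@pCancer[case@prostateMask] == 1) * voxCc
  cal <- calibrateThreshold(list(list(maps = ind, refCc = refCc),
                                 list(maps = ind, refCc = refCc)),
                            which = "cancer")
  expect_equal(cal$threshold, 0.05)
  expect_equal(cal$cohortMeanRatio, 1, tolerance = 1e-12)
  # two cases with ratios 0.5 and 1.5 average to exactly 1
  half <- maps
  half@pCancer[case@prostateMask] <- rep(c(1, 0, 0, 0), length.out = n)
  oneHalf <- maps
  oneHalf@pCancer[case@prostateMask] <- rep(c(1, 1, 1, 0), length.out = n)
  ref2 <- sum(half@pCancer[case@prostateMask] == 1) * voxCc * 2
  cal2 <- calibrateThreshold(list(list(maps = half, refCc = ref2),
                                  list(maps = oneHalf, refCc = ref2)),
                             which = "cancer")
  expect_equal(cal2$cohortMeanRatio, 1, tolerance = 0.01)
  # property: the mean-ratio sweep is non-increasing in the threshold
  withr::with_seed(9, {
    rmaps <- maps
    rmaps@pCancer[case@prostateMask] <- runif(n)
    calR <- calibrateThreshold(list(list(maps = rmaps, refCc = 0.01),
                                    list(maps = ind, refCc = refCc)),
                               which = "cancer")
  })
  expect_true(all(diff(calR$sweep$meanRatio) <= 1e-12))
  expect_error(calibrateThreshold(list(list(maps = maps, refCc = 0)),
                                  which = "cancer"), ">= 2 cases")
})
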