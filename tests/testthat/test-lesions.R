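# Lesion extraction, sector localization, matching with volume bounds,
# confusion factors, Bland-Altman and threshold ROC mechanics.

test_that("connected components: counts, volumes and the 0.1 cc filter", {
  sp <- c(1, 1, 3)
  mask <- array(FALSE, c(30, 30, 10))
  mask[3:7, 3:6, 2:4] <- TRUE              # 60 voxels = 0.18 cc
  mask[20:24, 20:23, 6:8] <- TRUE          # 60 voxels = 0.18 cc
  mask[15, 15, 5] <- TRUE                  # single voxel, sub-threshold
  les <- extractLesions(mask, sp)
  expect_equal(nrow(les), 2)
  expect_equal(les$volume_cc, c(0.18, 0.18), tolerance = 1e-12)
  sub <- attr(les, "subthreshold")
  expect_equal(nrow(sub), 1)
  expect_equal(sub$volume_cc, 0.003, tolerance = 1e-12)
  # empty mask: empty list
  none <- extractLesions(array(FALSE, c(5, 5, 5)), sp)
  expect_equal(nrow(none), 0)
  # 6- vs 26-connectivity: a diagonal pair separates only under 6
  diagMask <- array(FALSE, c(10, 10, 4))
  diagMask[2, 2, 2] <- TRUE
  diagMask[3, 3, 3] <- TRUE
  expect_equal(max(labelComponents(diagMask, 26)), 1)
  expect_equal(max(labelComponents(diagMask, 6)), 2)
})

test_that("sector localization maps the 27 cells and flags clamping", {
  mask <- array(FALSE, c(30, 30, 15))
  mask[6:24, 6:24, 3:13] <- TRUE
  sp <- c(1, 1, 2)
  lo <- c(5, 5, 4); hi <- c(23, 23, 24)   # mm bounding box of the mask
  mid <- (lo + hi) / 2
  ctr <- localizeLesion(mid, mask, sp)
  expect_equal(as.character(ctr), c("mid", "mid", "mid"))
  # 27 synthetic centroids, one per cell third: all cells distinct
  third <- function(k, a, b) a + (b - a) * (c(1, 3, 5)[k] / 6)
  cells <- integer()
  for (ix in 1:3) for (iy in 1:3) for (iz in 1:3) {
    s <- localizeLesion(c(third(ix, lo[1], hi[1]), third(iy, lo[2], hi[2]),
                          third(iz, lo[3], hi[3])), mask, sp)
    cells <- c(cells, attr(s, "cell"))
  }
  expect_equal(sort(cells), 1:27)
  out <- localizeLesion(c(-10, 0, 0), mask, sp)
  expect_true(attr(out, "clamped"))
})

lesRow <- function(id, vol, x, y, z, grade = "any", source = "mri") {
  df <- data.frame(id = id, volume_cc = vol, nvox = round(vol / 0.003),
                   cx = x, cy = y, cz = z,
                   grade = rep_len(grade, length(id)),
                   source = rep_len(source, length(id)))
  attr(df, "voxels") <- replicate(nrow(df), integer(0), simplify = FALSE)
  df
}

test_that("volume-bound rules classify matched pairs per the factor table", {
  # co-located 3 cc reference: upper bound 4/3*3 + 1 = 5 cc,
  # lower bound 0.75*(3-1) = 1.5 cc
  ref <- lesRow(1, 3, 10, 10, 10, source = "reference")
  over <- lesRow(1, 5.1, 11, 10, 10)
  mt <- matchLesions(over, ref)
  expect_equal(unname(mt$counts["fp"]), 1)
  expect_equal(mt$refTable$category, "FN")
  ok <- lesRow(1, 2.0, 11, 10, 10)
  mt2 <- matchLesions(ok, ref)
  expect_equal(unname(mt2$counts["tp"]), 1)
  expect_equal(mt2$mriTable$category, "TP")
  under <- lesRow(1, 1.4, 11, 10, 10)
  mt3 <- matchLesions(under, ref)
  expect_equal(mt3$refTable$category, "FN")
  expect_equal(unname(mt3$counts["fp"]), 0)
  # reference lesion with no MRI partner anywhere: FN
  mt4 <- matchLesions(lesRow(integer(0), numeric(0), numeric(0),
                             numeric(0), numeric(0)),
                      lesRow(1, 0.5, 10, 10, 10, source = "reference"))
  expect_equal(unname(mt4$counts["fn"]), 1)
  # both sub-threshold: not applicable
  mt5 <- matchLesions(lesRow(1, 0.05, 10, 10, 10),
                      lesRow(1, 0.08, 11, 10, 10, source = "reference"))
  expect_equal(unname(mt5$counts["na"]), 2)
  expect_equal(unname(mt5$counts["tp"] + mt5$counts["fp"] +
                        mt5$counts["fn"]), 0)
  # the alternative printed lower-bound convention is selectable
  mt6 <- matchLesions(lesRow(1, 1.4, 11, 10, 10), ref,
                      boundConvention = "table")  # 0.75*3 - 1 = 1.25
  expect_equal(mt6$refTable$category, "TP")
})

test_that("burden confusion volumes follow the min/max factor table and
           sum to the prostate volume", {
  bc <- burdenConfusion(2, 2, 30)
  expect_equal(unlist(bc[c("tp_cc", "fp_cc", "tn_cc", "fn_cc")]),
               c(tp_cc = 2, fp_cc = 0, tn_cc = 28, fn_cc = 0))
  bc2 <- burdenConfusion(3, 2, 30)
  expect_equal(unlist(bc2[c("tp_cc", "fp_cc", "tn_cc", "fn_cc")]),
               c(tp_cc = 2, fp_cc = 1, tn_cc = 27, fn_cc = 0))
  bc3 <- burdenConfusion(0, 2, 30)
  expect_equal(unlist(bc3[c("tp_cc", "fp_cc", "tn_cc", "fn_cc")]),
               c(tp_cc = 0, fp_cc = 0, tn_cc = 28, fn_cc = 2))
  # fuzz: volumes are nonnegative and sum exactly to the prostate volume
  withr::with_seed(14, {
    for (i in 1:200) {
      pr <- runif(1, 10, 60)
      m <- runif(1, 0, pr); r <- runif(1, 0, pr)
      b <- burdenConfusion(m, r, pr)
      v <- unlist(b[c("tp_cc", "fp_cc", "tn_cc", "fn_cc")])
      expect_true(all(v >= 0))
      expect_equal(sum(v), pr, tolerance = 1e-9)
    }
  })
})

test_that("detection metrics reproduce printed-count arithmetic and flag
           undefined ratios", {
  m <- detectionMetrics(tp = 135, fp = 32, tn = 143, fn = 15)
  expect_equal(m$sensitivityPct, 90)
  expect_equal(m$ppvPct, 81)
  expect_equal(m$specificityPct, 82)
  expect_equal(m$sensitivity, 135 / 150, tolerance = 1e-12)
  z <- detectionMetrics(tp = 0, fp = 0, tn = 5, fn = 0)
  expect_true(all(c("sensitivity", "ppv") %in% z$undefined))
})

test_that("Bland-Altman: hand-computed moments, shift property and size
           split", {
  ba <- blandAltman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba$meanDiff, 0)
  expect_equal(ba$sdDiff, 0)
  ba2 <- blandAltman(c(2, 1), c(1, 2))   # differences +1, -1
  expect_equal(ba2$meanDiff, 0)
  expect_equal(ba2$sdDiff, sqrt(2), tolerance = 1e-12)
  expect_equal(ba2$limits, c(-1.96, 1.96) * sqrt(2), tolerance = 1e-12)
  # adding a constant to the MRI volumes shifts the mean, not the SD
  mri <- c(0.5, 1.2, 3.1, 0.9); ref <- c(0.6, 1.0, 2.5, 1.1)
  b0 <- blandAltman(mri, ref)
  b1 <- blandAltman(mri + 0.7, ref)
  expect_equal(b1$meanDiff, b0$meanDiff + 0.7, tolerance = 1e-12)
  expect_equal(b1$sdDiff, b0$sdDiff, tolerance = 1e-12)
  expect_equal(b0$bySize$small$n, 1)   # only ref 0.6 is below 1 cc
  expect_equal(b0$bySize$large$n, 2)
  expect_error(blandAltman(1:3, 1:4), "length")
})

test_that("matching agrees with a brute-force factor-table oracle on
           randomized configurations", {
  # unambiguous geometry (well-separated sites, one MRI lesion near at
  # most one reference), then check every lesion against an independent
  # re-statement of the factor rules
  withr::with_seed(99, {
    for (repi in 1:300) {
      sites <- expand.grid(x = c(10, 30, 50), y = c(10, 35, 60),
                           z = c(6, 20, 34))
      nR <- sample(0:4, 1)
      nM <- sample(0:4, 1)
      used <- sample(nrow(sites), nR + nM)   # distinct, >= 14 mm apart
      refSites <- sites[used[seq_len(nR)], , drop = FALSE]
      refVol <- round(runif(nR, 0.02, 6), 3)
      ref <- lesRow(seq_len(nR), refVol, refSites$x, refSites$y,
                    refSites$z, source = "reference")
      # each MRI lesion sits on at most one reference site (within 3 mm)
      # or on its own free site, keeping the pairing unambiguous
      mx <- my <- mz <- numeric(nM)
      hit <- integer(nM)
      unhit <- seq_len(nR)
      for (i in seq_len(nM)) {
        if (length(unhit) > 0 && runif(1) < 0.6) {
          j <- unhit[sample.int(length(unhit), 1)]
          unhit <- setdiff(unhit, j)
          hit[i] <- j
          mx[i] <- refSites$x[j] + runif(1, -2, 2)
          my[i] <- refSites$y[j] + runif(1, -2, 2)
          mz[i] <- refSites$z[j]
        } else {
          s <- sites[used[nR + i], ]
          mx[i] <- s$x; my[i] <- s$y; mz[i] <- s$z
        }
      }
      mriVol <- round(runif(nM, 0.02, 8), 3)
      mri <- lesRow(seq_len(nM), mriVol, mx, my, mz)
      mt <- matchLesions(mri, ref)

      # oracle: direct evaluation of the factor table per lesion
      for (j in seq_len(nR)) {
        i <- which(hit == j)
        vR <- refVol[j]
        if (vR <= 0.1) {
          expect_equal(mt$refTable$category[j], "NA")
          next
        }
        expCat <- if (length(i) == 1 && mriVol[i] > 0.1 &&
                        mriVol[i] >= 0.75 * (vR - 1) &&
                        mriVol[i] <= 4 / 3 * vR + 1) "TP" else "FN"
        expect_equal(mt$refTable$category[j], expCat)
      }
      for (i in seq_len(nM)) {
        vM <- mriVol[i]
        if (vM <= 0.1) {
          expect_equal(mt$mriTable$category[i], "NA")
          next
        }
        j <- hit[i]
        expCat <- if (j == 0 || refVol[j] <= 0.1) "FP"
          else if (vM > 4 / 3 * refVol[j] + 1) "FP"
          else if (vM < 0.75 * (refVol[j] - 1)) "FN" else "TP"
        expect_equal(mt$mriTable$category[i], expCat)
      }
    }
  })
})

test_that("category assignment is invariant to lesion ordering", {
  ref <- lesRow(1:2, c(0.5, 2), c(10, 40), c(10, 40), c(10, 30),
                source = "reference")
  mri <- lesRow(1:2, c(0.45, 2.2), c(11, 41), c(10, 40), c(10, 30))
  a <- matchLesions(mri, ref)$counts
  refR <- ref[2:1, ]; attr(refR, "voxels") <- attr(ref, "voxels")[2:1]
  mriR <- mri[2:1, ]; attr(mriR, "voxels") <- attr(mri, "voxels")[2:1]
  b <- matchLesions(mriR, refR)$counts
  expect_equal(a, b)
})

test_that("size-restricted sub-populations filter counted lesions without
           re-categorizing them", {
  ref <- lesRow(1:3, c(0.5, 2.5, 0.3), c(10, 30, 50), c(10, 30, 50),
                c(10, 20, 30), source = "reference")
  mri <- lesRow(1:3, c(0.55, 2.4, 5.0), c(10, 30, 50), c(11, 30, 50),
                c(10, 20, 30))
  mt <- matchLesions(mri, ref)
  full <- mt$refTable
  subPop <- full[full$volume_cc > 0.1 & full$volume_cc < 1, ]
  # the sub-1-cc rows keep the categories they had in the full analysis
  expect_equal(subPop$category,
               full$category[full$volume_cc > 0.1 & full$volume_cc < 1])
})
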