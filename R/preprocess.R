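# Per-case image preparation: endorectal coil bias correction, ADC from a
# two-b-value DWI pair, semi-quantitative DCE features, and the T2W / DCE
# normalizations that reduce patient-to-patient variance.

#' Correct endorectal-coil intensity bias
#'
#' Divides the T2W volume by a smooth positive field estimated by heavy
#' Gaussian low-pass filtering within the body mask (normalized
#' convolution), rescaled to unit mean over the mask. This is a generic
#' divide-by-smooth-field correction for the coil reception profile.
#'
#' @param t2w nonnegative 3D array
#' @param bodyMask logical array (field is estimated inside it)
#' @param spacing voxel spacing mm
#' @param sigmaMm smoothing scale; default one quarter of the in-plane FOV
#' @return list: `corrected` volume and the estimated `field`
#' @export
correctCoilBias <- function(t2w, bodyMask, spacing, sigmaMm = NULL) {
  if (!any(bodyMask)) stop("empty body mask")
  if (min(t2w, na.rm = TRUE) < 0) stop("t2w must be nonnegative")
  d <- dim(t2w)
  if (is.null(sigmaMm)) sigmaMm <- (d[1] - 1) * spacing[1] / 4
  m <- array(as.numeric(bodyMask), d)
  num <- gaussSmooth3d(t2w * m, sigmaMm, spacing)
  den <- gaussSmooth3d(m, sigmaMm, spacing)
  field <- array(1, d)
  ok <- den > 1e-8
  field[ok] <- num[ok] / den[ok]
  mu <- mean(field[bodyMask])
  if (mu <= 0) return(list(corrected = t2w, field = array(1, d)))
  field <- field / mu
  field[field <= 1e-6] <- 1  # flat (e.g. all-zero) input: leave unchanged
  list(corrected = t2w / field, field = field)
}

#' Apparent diffusion coefficient from a two-b-value pair
#'
#' ADC = ln(S0/Sb)/b per voxel. Voxels with non-positive signal in either
#' image are set to 0 and counted in the `nFlagged` attribute.
#'
#' @param s0 signal at b = 0
#' @param sb signal at b = `bValue`
#' @param bValue diffusion weighting in s/mm^2 (> 0)
#' @return ADC volume in mm^2/s with attribute `nFlagged`
#' @export
computeAdc <- function(s0, sb, bValue) {
  stopifnot(bValue > 0)
  if (!identical(dim(s0), dim(sb))) stop("s0 and sb must share dimensions")
  bad <- !(s0 > 0 & sb > 0)
  adc <- array(0, dim(s0))
  adc[!bad] <- log(s0[!bad] / sb[!bad]) / bValue
  attr(adc, "nFlagged") <- sum(bad)
  adc
}

#' Semi-quantitative DCE features: peak enhancement, slope, washout
#'
#' Per voxel: baseline is the mean of the pre-contrast frames (first
#' `nBaseline`); PE = max(signal) - baseline; ES = the largest forward
#' finite-difference slope up to the (first) peak; WO = the negated
#' least-squares slope from the peak to the end, so positive WO means
#' signal loss after the peak. Monotone non-decreasing curves give WO <= 0;
#' flat series give (0, 0, 0).
#'
#' @param dce 4D array (x, y, z, time)
#' @param times acquisition times in seconds, strictly increasing
#' @param nBaseline number of pre-contrast frames (default 2)
#' @return list of 3D volumes `pe`, `es`, `wo`
#' @export
computeDceFeatures <- function(dce, times, nBaseline = 2) {
  d <- dim(dce)
  stopifnot(length(d) == 4, length(times) == d[4], d[4] >= 4,
            all(diff(times) > 0), nBaseline >= 1, nBaseline < d[4])
  nvox <- prod(d[1:3])
  S <- matrix(dce, nrow = nvox, ncol = d[4])
  baseline <- rowMeans(S[, seq_len(nBaseline), drop = FALSE])
  peakIdx <- max.col(S, ties.method = "first")
  peakVal <- S[cbind(seq_len(nvox), peakIdx)]
  pe <- peakVal - baseline

  dt <- diff(times)
  slopes <- sweep(S[, -1, drop = FALSE] - S[, -d[4], drop = FALSE], 2, dt, `/`)
  # forward differences ending at or before the peak
  es <- numeric(nvox)
  before <- outer(rep(1, nvox), seq_len(d[4] - 1)) <= (peakIdx - 1)
  anyBefore <- peakIdx > 1
  masked <- ifelse(before, slopes, -Inf)
  es[anyBefore] <- apply(masked[anyBefore, , drop = FALSE], 1, max)

  # least-squares slope of the post-peak segment (peak included)
  wo <- numeric(nvox)
  for (p in sort(unique(peakIdx))) {
    if (p > d[4] - 1) next
    sel <- peakIdx == p
    tt <- times[p:d[4]]
    tc <- tt - mean(tt)
    denom <- sum(tc^2)
    seg <- S[sel, p:d[4], drop = FALSE]
    wo[sel] <- -(seg %*% tc) / denom
  }
  flat <- apply(S, 1, function(r) all(r == r[1]))
  pe[flat] <- 0; es[flat] <- 0; wo[flat] <- 0
  list(pe = array(pe, d[1:3]), es = array(es, d[1:3]), wo = array(wo, d[1:3]))
}

#' Muscle-referenced T2W normalization
#'
#' Divides every voxel by the mean T2W over the union of the two obturator
#' muscle reference ROIs, removing receiver-gain differences between
#' patients.
#'
#' @param case an [MpMriCase-class] with `muscleRois` set
#' @param t2w optional volume to normalize (defaults to the case's t2w)
#' @return list: normalized `t2w` and the scalar `muscleMean`
#' @export
normalizeT2w <- function(case, t2w = NULL) {
  if (length(case@muscleRois) != 2) stop("muscle ROIs not set")
  if (is.null(t2w)) t2w <- case@volumes$t2w
  mm <- mean(t2w[unlist(case@muscleRois)])
  if (!is.finite(mm) || mm <= 0) stop("muscle mean must be positive")
  list(t2w = t2w / mm, muscleMean = mm)
}

#' Case-mean peak enhancement over the prostate
#' @param case an [MpMriCase-class]
#' @return scalar PE averaged over the prostate mask
#' @export
casePeAve <- function(case) {
  v <- case@volumes$pe[case@prostateMask]
  mean(v[is.finite(v)])
}

#' Cohort DCE reference
#'
#' The cohort-level PE reference is the mean over cases of each case's
#' prostate-mean peak enhancement. It must be computed before any case is
#' DCE-normalized.
#'
#' @param cases list of [MpMriCase-class] objects (or of lists holding a
#'   `case` element)
#' @return a [CohortStats-class]
#' @export
cohortPeStats <- function(cases) {
  pe <- vapply(cases, function(x) {
    cs <- if (is(x, "MpMriCase")) x else x$case
    casePeAve(cs)
  }, numeric(1))
  new("CohortStats", peAveCohort = mean(pe))
}

#' DCE normalization of enhancement slope and washout
#'
#' Scales ES and WO by the ratio of the cohort PE reference to the case's
#' prostate-mean PE, removing per-patient contrast-amplitude differences
#' while preserving the per-voxel ES/WO ratio.
#'
#' @param case an [MpMriCase-class] with `peAveCase` computed
#' @param cohort a [CohortStats-class]
#' @return list of normalized `es` and `wo` volumes
#' @export
normalizeDce <- function(case, cohort) {
  peJ <- case@peAveCase
  if (is.na(peJ)) peJ <- casePeAve(case)
  if (!is.finite(peJ) || peJ <= 0) stop("case-mean PE must be positive")
  f <- cohort@peAveCohort / peJ
  list(es = case@volumes$es * f, wo = case@volumes$wo * f)
}

#' Full per-case preprocessing
#'
#' Applies coil-bias correction and muscle normalization to T2W and, when
#' cohort statistics are supplied, DCE normalization to ES and WO. Returns
#' the case with its volumes replaced by the prepared versions and
#' `peAveCase` filled in.
#'
#' @param case an [MpMriCase-class]
#' @param cohort optional [CohortStats-class]; if missing, only T2W is
#'   prepared
#' @return the updated [MpMriCase-class]
#' @export
preprocessCase <- function(case, cohort = NULL) {
  cb <- correctCoilBias(case@volumes$t2w, case@bodyMask, case@voxelSpacing)
  nt <- normalizeT2w(case, cb$corrected)
  case@volumes$t2w <- nt$t2w
  case@peAveCase <- casePeAve(case)
  if (!is.null(cohort)) {
    nd <- normalizeDce(case, cohort)
    case@volumes$es <- nd$es
    case@volumes$wo <- nd$wo
  }
  case
}
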