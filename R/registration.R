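# Two-step rigid alignment to the T2W grid: (a) 2D in-plane registration of
# the full FOV, then (b) 3D refinement localized to the (dilated) prostate,
# both maximizing normalized mutual information. QC against fixed error
# criteria: 2 mm in-plane (one third of the diameter of a 0.1 cc lesion)
# and 3 mm out-of-plane (the slice thickness).

QC_IN_PLANE_MM <- 2
QC_OUT_OF_PLANE_MM <- 3

#' Normalized mutual information of two volumes
#'
#' NMI = (H(A) + H(B)) / H(A, B) over the masked voxels, using equal-width
#' histogram bins per image. Symmetric in its arguments; >= 1, with 2
#' attained by a non-degenerate self-pair.
#'
#' @param a,b numeric arrays of equal dimension
#' @param bins number of histogram bins (>= 2)
#' @param mask optional logical array restricting the evaluation
#' @return the NMI score
#' @export
nmi <- function(a, b, bins = 32, mask = NULL) {
  stopifnot(identical(dim(a), dim(b)), bins >= 2)
  av <- as.vector(a); bv <- as.vector(b)
  if (!is.null(mask)) { av <- av[mask]; bv <- bv[mask] }
  ok <- is.finite(av) & is.finite(bv)
  av <- av[ok]; bv <- bv[ok]
  if (length(av) < bins^2)
    warning("fewer masked voxels than bins^2; NMI estimate is unstable")
  cutBin <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) return(rep(1L, length(x)))
    pmin(pmax(floor((x - r[1]) / (r[2] - r[1]) * bins) + 1L, 1L), bins)
  }
  ia <- cutBin(av); ib <- cutBin(bv)
  joint <- tabulate(ia + (ib - 1L) * bins, nbins = bins * bins)
  pj <- joint[joint > 0] / length(av)
  hj <- -sum(pj * log(pj))
  pa <- tabulate(ia, nbins = bins); pa <- pa[pa > 0] / length(av)
  pb <- tabulate(ib, nbins = bins); pb <- pb[pb > 0] / length(av)
  ha <- -sum(pa * log(pa)); hb <- -sum(pb * log(pb))
  if (hj == 0) return(2)  # degenerate: both constant
  (ha + hb) / hj
}

# NMI between fixed and moving under candidate parameters, evaluated at the
# fixed-grid points `pts` (mm) carrying fixed values `fixedVals`. The
# candidate transform maps moving -> fixed, so moving is sampled at T^-1(p).
nmiAt <- function(par6, pts, fixedVals, moving, spacing, center, bins) {
  tf <- rigidTransform(translation = par6[1:3], rotation = par6[4:6],
                       center = center)
  Minv <- solve(transformMatrix(tf))
  q <- sweep(pts %*% t(Minv[1:3, 1:3]), 2, Minv[1:3, 4], `+`)
  mv <- trilinearSample(moving, q, spacing, fill = NA_real_)
  ok <- is.finite(mv) & is.finite(fixedVals)
  if (sum(ok) < 100) return(1)
  suppressWarnings(nmi(array(fixedVals[ok]), array(mv[ok]), bins = bins))
}

#' Two-step rigid registration of a moving volume to the T2W grid
#'
#' Step (a) searches in-plane translation and axial rotation over the full
#' field of view (histograms pooled across slices) with a coarse grid
#' followed by Nelder-Mead refinement; step (b) refines all six rigid
#' parameters within the dilated prostate mask. Deterministic given the
#' fixed optimizer settings.
#'
#' @param moving volume to align (already interpolated to the T2W grid)
#' @param fixedT2w the reference T2W volume
#' @param prostateMask logical array used to localize step (b)
#' @param spacing voxel spacing mm
#' @param bins histogram bins for NMI (default 32)
#' @param searchMm,searchDeg half-width of the coarse in-plane search
#' @param step2 set `FALSE` to stop after the in-plane step
#' @param coarsen in-plane downsampling factor for step (a)
#' @return the estimated [RigidTransform-class] (moving-to-fixed), with
#'   attributes `nmi` and `converged`
#' @export
registerCase <- function(moving, fixedT2w, prostateMask, spacing,
                         bins = 32, searchMm = 6, searchDeg = 6,
                         step2 = TRUE, coarsen = 3L) {
  d <- dim(fixedT2w)
  center <- (d - 1) * spacing / 2

  # --- step (a): in-plane, full FOV, downsampled in-plane for speed
  ix <- seq(1L, d[1], by = coarsen)
  iy <- seq(1L, d[2], by = coarsen)
  sub <- as.matrix(expand.grid(x = ix, y = iy, z = seq_len(d[3])))
  pts <- cbind((sub[, 1] - 1) * spacing[1], (sub[, 2] - 1) * spacing[2],
               (sub[, 3] - 1) * spacing[3])
  fixedVals <- fixedT2w[sub]
  objA <- function(p3) -nmiAt(c(p3[1], p3[2], 0, 0, 0, p3[3]), pts,
                              fixedVals, moving, spacing, center, bins)
  grid <- expand.grid(tx = seq(-searchMm, searchMm, by = 3),
                      ty = seq(-searchMm, searchMm, by = 3),
                      rz = seq(-searchDeg, searchDeg, by = 3))
  vals <- apply(grid, 1, objA)
  p0 <- as.numeric(grid[which.min(vals), ])
  optA <- stats::optim(p0, objA, method = "Nelder-Mead",
                       control = list(maxit = 200, reltol = 1e-7))
  parA <- c(optA$par[1], optA$par[2], 0, 0, 0, optA$par[3])
  converged <- optA$convergence == 0

  par <- parA
  bestVal <- -optA$value
  if (step2) {
    roi <- dilateMask(prostateMask, 6, spacing)
    idx <- which(roi)
    if (length(idx) > 15000) {
      idx <- idx[seq(1, length(idx), length.out = 15000)]
    }
    ptsB <- voxelCoords(idx, d, spacing)
    fixedB <- fixedT2w[idx]
    objB <- function(p6) -nmiAt(p6, ptsB, fixedB, moving, spacing, center,
                                bins)
    # step (a) leaves the slice-axis translation at zero; scan it coarsely
    # so the 6-parameter refinement starts in the right slice basin
    zGrid <- seq(-5, 5, by = 1.25)
    zVals <- vapply(zGrid, function(tz) {
      p <- parA
      p[3] <- tz
      objB(p)
    }, numeric(1))
    parA[3] <- zGrid[which.min(zVals)]
    optB <- stats::optim(parA, objB, method = "Nelder-Mead",
                         control = list(maxit = 400, reltol = 1e-8))
    if (-optB$value >= -objB(parA)) {
      par <- optB$par
      bestVal <- -optB$value
      converged <- converged && optB$convergence == 0
    }
  }
  if (!converged)
    warning("registration optimizer did not fully converge; returning best so far")
  tf <- rigidTransform(translation = par[1:3], rotation = par[4:6],
                       center = center)
  attr(tf, "nmi") <- bestVal
  attr(tf, "converged") <- converged
  tf
}

#' Registration quality control against a reference transform
#'
#' The residual transform (estimated composed with the inverse reference)
#' is evaluated as the mean displacement of the prostate voxels, split into
#' the in-plane (x, y) and out-of-plane (slice axis) components, and
#' compared with the 2 mm / 3 mm criteria.
#'
#' @param estimated,reference [RigidTransform-class] objects about the same
#'   centre
#' @param prostateMask logical array
#' @param spacing voxel spacing mm
#' @return list: `inPlaneErrorMm`, `outOfPlaneErrorMm`, `passed`
#' @export
qcTransform <- function(estimated, reference, prostateMask, spacing) {
  resid <- composeTransforms(estimated, invertTransform(reference))
  pts <- voxelCoords(which(prostateMask), dim(prostateMask), spacing)
  mapped <- applyTransform(resid, pts)
  dxy <- sqrt(rowSums((mapped[, 1:2, drop = FALSE] -
                         pts[, 1:2, drop = FALSE])^2))
  dz <- abs(mapped[, 3] - pts[, 3])
  ip <- mean(dxy)
  op <- mean(dz)
  list(inPlaneErrorMm = ip, outOfPlaneErrorMm = op,
       passed = ip <= QC_IN_PLANE_MM && op <= QC_OUT_OF_PLANE_MM)
}

#' Resample a registered volume onto the T2W grid
#'
#' Applies the estimated moving-to-fixed transform with trilinear
#' interpolation (nearest-neighbour for label volumes); voxels mapped from
#' outside the source FOV are set to the fill value.
#'
#' @param vol the moving volume
#' @param tf the [RigidTransform-class] from [registerCase()]
#' @param spacing voxel spacing mm
#' @param fill out-of-FOV value (default NA)
#' @param nearest nearest-neighbour interpolation for labels
#' @return resampled volume on the T2W grid
#' @export
resampleToT2w <- function(vol, tf, spacing, fill = NA_real_,
                          nearest = FALSE) {
  resampleVolume(vol, tf, spacing, fill = fill, nearest = nearest)
}
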