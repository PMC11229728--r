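# Physical coordinate convention used throughout: voxel (i, j, k) (1-based)
# sits at ((i-1)*dx, (j-1)*dy, (k-1)*dz) mm. Axis 1 = left-right (x),
# axis 2 = anterior(low)-posterior(high) (y), axis 3 = apex(low)-base(high)
# (z, the slice axis).

#' Physical coordinates of voxels
#'
#' @param idx linear voxel indices into an array of dimension `dims`
#' @param dims integer length-3 array dimension
#' @param spacing numeric length-3 voxel spacing in mm
#' @return n x 3 matrix of mm coordinates
#' @keywords internal
voxelCoords <- function(idx, dims, spacing) {
  ai <- arrayInd(idx, dims)
  cbind((ai[, 1] - 1) * spacing[1],
        (ai[, 2] - 1) * spacing[2],
        (ai[, 3] - 1) * spacing[3])
}

#' Trilinear sampling of a 3D volume at arbitrary mm positions
#'
#' Positions outside the volume receive `fill`.
#'
#' @param vol 3D numeric array
#' @param pts n x 3 matrix of mm coordinates
#' @param spacing voxel spacing (mm)
#' @param fill value for points outside the field of view
#' @return numeric vector of sampled values
#' @keywords internal
trilinearSample <- function(vol, pts, spacing, fill = NA_real_) {
  d <- dim(vol)
  gx <- pts[, 1] / spacing[1] + 1
  gy <- pts[, 2] / spacing[2] + 1
  gz <- pts[, 3] / spacing[3] + 1
  inside <- gx >= 1 & gx <= d[1] & gy >= 1 & gy <= d[2] & gz >= 1 & gz <= d[3]
  out <- rep(fill, nrow(pts))
  if (!any(inside)) return(out)
  gx <- gx[inside]; gy <- gy[inside]; gz <- gz[inside]
  x0 <- pmin(pmax(floor(gx), 1), d[1] - 1)
  y0 <- pmin(pmax(floor(gy), 1), d[2] - 1)
  z0 <- pmin(pmax(floor(gz), 1), d[3] - 1)
  # degenerate single-slice axes
  if (d[1] == 1) x0 <- rep(1, length(gx))
  if (d[2] == 1) y0 <- rep(1, length(gy))
  if (d[3] == 1) z0 <- rep(1, length(gz))
  fx <- gx - x0; fy <- gy - y0; fz <- gz - z0
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  nx <- d[1]; nxy <- d[1] * d[2]
  lin <- function(ix, iy, iz) ix + (iy - 1) * nx + (iz - 1) * nxy
  v000 <- vol[lin(x0, y0, z0)]; v100 <- vol[lin(x1, y0, z0)]
  v010 <- vol[lin(x0, y1, z0)]; v110 <- vol[lin(x1, y1, z0)]
  v001 <- vol[lin(x0, y0, z1)]; v101 <- vol[lin(x1, y0, z1)]
  v011 <- vol[lin(x0, y1, z1)]; v111 <- vol[lin(x1, y1, z1)]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[inside] <- c0 * (1 - fz) + c1 * fz
  out
}

# 1D Gaussian convolution matrix with truncated (renormalized) edges
gaussConvMat <- function(n, sigmaVox) {
  if (sigmaVox <= 0 || n == 1) return(diag(n))
  hw <- max(1L, ceiling(3 * sigmaVox))
  off <- -hw:hw
  k <- exp(-0.5 * (off / sigmaVox)^2)
  K <- matrix(0, n, n)
  for (m in seq_along(off)) {
    i <- seq_len(n)
    j <- i + off[m]
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- k[m]
  }
  K / rowSums(K)
}

applyAxisConv <- function(vol, K, axis) {
  d <- dim(vol)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  v <- aperm(vol, perm)
  dp <- dim(v)
  m <- K %*% matrix(v, nrow = dp[1])
  v <- array(m, dp)
  aperm(v, order(perm))
}

#' Separable 3D Gaussian smoothing
#'
#' @param vol 3D numeric array
#' @param sigmaMm smoothing scale in mm (scalar or per-axis)
#' @param spacing voxel spacing in mm
#' @return smoothed array of the same dimension
#' @keywords internal
gaussSmooth3d <- function(vol, sigmaMm, spacing) {
  sigmaMm <- rep_len(sigmaMm, 3)
  d <- dim(vol)
  for (ax in 1:3) {
    s <- sigmaMm[ax] / spacing[ax]
    if (s > 0 && d[ax] > 1) vol <- applyAxisConv(vol, gaussConvMat(d[ax], s), ax)
  }
  vol
}

#' Voxel offsets within a sphere of given physical radius
#'
#' @return m x 3 integer matrix of (dx, dy, dz) voxel offsets whose physical
#'   length is at most `radiusMm`
#' @keywords internal
sphereOffsets <- function(radiusMm, spacing) {
  rx <- floor(radiusMm / spacing[1])
  ry <- floor(radiusMm / spacing[2])
  rz <- floor(radiusMm / spacing[3])
  g <- expand.grid(dx = -rx:rx, dy = -ry:ry, dz = -rz:rz)
  dist <- sqrt((g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 +
                 (g$dz * spacing[3])^2)
  as.matrix(g[dist <= radiusMm, , drop = FALSE])
}

#' Binary dilation with a spherical structuring element
#' @keywords internal
dilateMask <- function(mask, radiusMm, spacing) {
  d <- dim(mask)
  off <- sphereOffsets(radiusMm, spacing)
  ai <- arrayInd(which(mask), d)
  out <- array(FALSE, d)
  for (m in seq_len(nrow(off))) {
    x <- ai[, 1] + off[m, 1]; y <- ai[, 2] + off[m, 2]; z <- ai[, 3] + off[m, 3]
    ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
    out[cbind(x[ok], y[ok], z[ok])] <- TRUE
  }
  out
}

#' 3D connected-component labelling
#'
#' Labels connected foreground voxels of a binary volume. Components are
#' numbered in decreasing size order.
#'
#' @param mask 3D logical array
#' @param connectivity 26 (vertex/edge/face neighbours, the default) or 6
#'   (face neighbours only)
#' @return integer array of the same dimension; 0 = background
#' @export
labelComponents <- function(mask, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 26))
  d <- dim(mask)
  dp <- d + 2L
  pad <- array(FALSE, dp)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  nxp <- dp[1]; nxyp <- dp[1] * dp[2]
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  if (connectivity == 6) g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) == 1, ]
  offs <- g$dx + g$dy * nxp + g$dz * nxyp
  fg <- which(pad)
  lab <- integer(length(pad))
  cur <- 0L
  for (seed in fg) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    lab[seed] <- cur
    frontier <- seed
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, offs, `+`)))
      nb <- nb[pad[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      frontier <- nb
    }
  }
  out <- array(lab, dp)[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  # renumber by decreasing size for reproducible ordering
  if (cur > 1L) {
    sz <- tabulate(out[out > 0L], nbins = cur)
    ord <- order(sz, decreasing = TRUE)
    remap <- integer(cur)
    remap[ord] <- seq_len(cur)
    out[out > 0L] <- remap[out[out > 0L]]
  }
  out
}
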