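# Rigid-transform algebra. Points map as p' = R (p - c) + c + t with
# R = Rz %*% Ry %*% Rx (intrinsic rotations, slice axis applied last).

rotationMatrix <- function(rotationDeg) {
  r <- rotationDeg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' Homogeneous 4x4 matrix of a rigid transform
#' @param tf a [RigidTransform-class]
#' @return 4 x 4 matrix acting on homogeneous mm coordinates
#' @export
transformMatrix <- function(tf) {
  R <- rotationMatrix(tf@rotation)
  t <- tf@translation + tf@center - R %*% tf@center
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- t
  M
}

matrixToTransform <- function(M, center = c(0, 0, 0)) {
  R <- M[1:3, 1:3]
  # Euler angles for R = Rz(g) Ry(b) Rx(a)
  b <- asin(pmin(pmax(-R[3, 1], -1), 1))
  if (abs(cos(b)) > 1e-9) {
    a <- atan2(R[3, 2], R[3, 3])
    g <- atan2(R[2, 1], R[1, 1])
  } else {  # gimbal lock: fold everything into x rotation
    a <- atan2(-R[2, 3], R[2, 2])
    g <- 0
  }
  rot <- c(a, b, g) * 180 / pi
  t <- M[1:3, 4] - center + R %*% center
  rigidTransform(translation = as.numeric(t), rotation = rot, center = center)
}

#' Apply a rigid transform to points
#' @param tf a [RigidTransform-class]
#' @param pts n x 3 matrix of mm coordinates
#' @return n x 3 matrix of mapped coordinates
#' @export
applyTransform <- function(tf, pts) {
  M <- transformMatrix(tf)
  sweep(pts %*% t(M[1:3, 1:3]), 2, M[1:3, 4], `+`)
}

#' Compose rigid transforms (apply `second` after `first`)
#' @param first,second [RigidTransform-class] objects
#' @return the composed transform, expressed about `second`'s centre
#' @export
composeTransforms <- function(second, first) {
  matrixToTransform(transformMatrix(second) %*% transformMatrix(first),
                    center = second@center)
}

#' Invert a rigid transform
#' @param tf a [RigidTransform-class]
#' @return the inverse transform about the same centre
#' @export
invertTransform <- function(tf) {
  matrixToTransform(solve(transformMatrix(tf)), center = tf@center)
}

isIdentityTransform <- function(tf, tol = 1e-9) {
  all(abs(tf@translation) < tol) && all(abs(tf@rotation) < tol)
}

#' Resample a volume under a rigid transform
#'
#' Produces the transformed image on the same grid: the output value at
#' position `p` is the input sampled at `T^-1(p)` (trilinear), so the image
#' content moves with the transform. Positions mapping outside the input
#' field of view receive `fill`.
#'
#' @param vol 3D numeric array
#' @param tf a [RigidTransform-class]
#' @param spacing voxel spacing in mm
#' @param fill fill value for out-of-FOV voxels (default `NA`)
#' @param nearest use nearest-neighbour interpolation (for label volumes)
#' @return array of the same dimension
#' @export
resampleVolume <- function(vol, tf, spacing, fill = NA_real_, nearest = FALSE) {
  if (isIdentityTransform(tf)) return(vol)
  d <- dim(vol)
  idx <- seq_len(prod(d))
  pts <- voxelCoords(idx, d, spacing)
  Minv <- solve(transformMatrix(tf))
  q <- sweep(pts %*% t(Minv[1:3, 1:3]), 2, Minv[1:3, 4], `+`)
  if (nearest) {
    gi <- round(q[, 1] / spacing[1]) + 1
    gj <- round(q[, 2] / spacing[2]) + 1
    gk <- round(q[, 3] / spacing[3]) + 1
    ok <- gi >= 1 & gi <= d[1] & gj >= 1 & gj <= d[2] & gk >= 1 & gk <= d[3]
    out <- rep(fill, length(idx))
    out[ok] <- vol[cbind(gi[ok], gj[ok], gk[ok])]
  } else {
    out <- trilinearSample(vol, q, spacing, fill = fill)
  }
  array(out, d)
}
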