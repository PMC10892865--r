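## Pinhole camera mathematics: projection, backprojection, rigid motions and
## two-ray triangulation. Conventions: 0-based pixels, x right / y down, the
## camera looks down +z; 3D units are mm. The IR eye camera frame is the world
## frame for all eye-side geometry.

as_points3 <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  stopifnot(ncol(p) == 3L)
  p
}

as_points2 <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1L)
  stopifnot(ncol(q) == 2L)
  q
}

unit3 <- function(v) v / sqrt(sum(v^2))

#' Project 3D camera-frame points to pixels
#'
#' Standard pinhole projection (fx x/z + cx, fy y/z + cy); if the camera has
#' nonzero radial distortion coefficients they are applied to the normalized
#' coordinates before the focal scaling.
#'
#' @param K a [CameraIntrinsics-class].
#' @param p a length-3 vector or an N x 3 matrix of points (mm) with z > 0.
#' @return An N x 2 matrix of (u, v) pixel coordinates (a 1 x 2 matrix for a
#'   single point).
#' @export
projectPoints <- function(K, p) {
  p <- as_points3(p)
  if (any(p[, 3] <= 0))
    stop("projectPoints: point(s) behind the camera (z <= 0)")
  xn <- p[, 1] / p[, 3]
  yn <- p[, 2] / p[, 3]
  if (any(K@dist != 0)) {
    r2 <- xn^2 + yn^2
    f <- 1 + K@dist[1] * r2 + K@dist[2] * r2^2
    xn <- xn * f
    yn <- yn * f
  }
  cbind(u = K@fx * xn + K@cx, v = K@fy * yn + K@cy)
}

#' Backproject pixels to viewing rays
#'
#' Returns unit ray directions through the given pixels; every ray originates
#' at the camera centre (0, 0, 0) of that camera's frame. Radial distortion,
#' when present, is inverted by fixed-point iteration.
#'
#' @param K a [CameraIntrinsics-class].
#' @param q a length-2 vector or N x 2 matrix of (u, v) pixels.
#' @return An N x 3 matrix of unit direction vectors.
#' @export
backprojectPixels <- function(K, q) {
  q <- as_points2(q)
  xd <- (q[, 1] - K@cx) / K@fx
  yd <- (q[, 2] - K@cy) / K@fy
  if (any(K@dist != 0)) {
    # invert r_d = r * (1 + k1 r^2 + k2 r^4) by fixed point on the undistorted coords
    xu <- xd; yu <- yd
    for (i in 1:20) {
      r2 <- xu^2 + yu^2
      f <- 1 + K@dist[1] * r2 + K@dist[2] * r2^2
      xu <- xd / f
      yu <- yd / f
    }
    xd <- xu; yd <- yu
  }
  d <- cbind(xd, yd, 1)
  d / sqrt(rowSums(d^2))
}

#' Apply or invert a rigid transform
#'
#' `applyRigid` maps points x to R x + t; `invertRigid` returns the inverse
#' motion. Directions (rays) are rotated with `rotateOnly = TRUE`.
#'
#' @param rig a [RigidTransform-class].
#' @param p length-3 vector or N x 3 matrix.
#' @param rotateOnly if TRUE apply only the rotation (for direction vectors).
#' @return Transformed N x 3 matrix.
#' @export
applyRigid <- function(rig, p, rotateOnly = FALSE) {
  p <- as_points3(p)
  out <- p %*% t(rig@rotation)
  if (!rotateOnly) out <- sweep(out, 2L, rig@translation, "+")
  out
}

#' @rdname applyRigid
#' @export
invertRigid <- function(rig) {
  rigidTransform(t(rig@rotation), -as.numeric(t(rig@rotation) %*% rig@translation))
}

#' Camera centre of the transformed frame
#'
#' For extrinsics mapping world (IR-frame) points into a second camera's frame
#' (x_cam = R x + t), the second camera's centre expressed in the world frame
#' is -R't.
#'
#' @param rig a [RigidTransform-class] (world -> camera).
#' @return length-3 numeric, camera centre in the world frame (mm).
#' @export
cameraCenter <- function(rig) {
  as.numeric(-t(rig@rotation) %*% rig@translation)
}

#' Triangulate two viewing rays
#'
#' Intersects two (generally skew) 3D lines by the midpoint of their common
#' perpendicular segment; the segment length (`gap`) is returned as a quality
#' measure and is zero iff the rays intersect exactly. Ray directions need not
#' be normalized. Vectorized over rows.
#'
#' @param originA,originB ray origins, length-3 or N x 3 (mm).
#' @param dirA,dirB ray directions, length-3 or N x 3.
#' @return A list with `point` (N x 3 midpoints, mm) and `gap` (numeric N, mm).
#' @export
triangulateRays <- function(originA, dirA, originB, dirB) {
  oa <- as_points3(originA); da <- as_points3(dirA)
  ob <- as_points3(originB); db <- as_points3(dirB)
  n <- max(nrow(oa), nrow(da), nrow(ob), nrow(db))
  expand <- function(m) if (nrow(m) == n) m else m[rep(1L, n), , drop = FALSE]
  oa <- expand(oa); da <- expand(da); ob <- expand(ob); db <- expand(db)
  da <- da / sqrt(rowSums(da^2))
  db <- db / sqrt(rowSums(db^2))
  # closest points: solve [1 -b; b -1] [ta; tb] = [w.da; w.db], b = da.db, w = ob - oa
  b <- rowSums(da * db)
  if (any(abs(b) >= 1 - 1e-9))
    stop("triangulateRays: parallel rays (degenerate geometry)")
  w <- ob - oa
  wa <- rowSums(w * da)
  wb <- rowSums(w * db)
  den <- 1 - b^2
  ta <- (wa - b * wb) / den
  tb <- (b * wa - wb) / den
  pa <- oa + da * ta
  pb <- ob + db * tb
  list(point = (pa + pb) / 2, gap = sqrt(rowSums((pa - pb)^2)))
}
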