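## Per-user 3D eyeball model. Corresponding pupil-boundary points seen by the
## two eye cameras are triangulated into 3D surface points; the sphere centre
## (radius fixed at the anatomical 12 mm) is then estimated by Gauss-Newton on
## the radial residuals. The model provides the IR -> RGB point-to-point
## mapping (backproject, intersect the sphere, reproject) and the 3D gaze ray
## along the optical axis.

EYE_RADIUS_MM <- 12.0

#' Build the per-user eyeball model
#'
#' Each correspondence (one pupil-boundary point seen in both eye cameras) is
#' triangulated; pairs whose skew-ray gap exceeds `gapMax` are rejected as bad
#' matches. The sphere centre c minimizing sum_i (||p_i - c|| - 12)^2 is found
#' by Gauss-Newton with the analytic Jacobian, initialized at
#' mean(p) + 12 * (unit mean viewing direction); on non-convergence a
#' Nelder-Mead fallback is used.
#'
#' @param corr data.frame with columns uIr, vIr, uRgb, vRgb (pixels) and
#'   optionally frameId; see [makeCorrespondences()].
#' @param Kir,Krgb [CameraIntrinsics-class] of the two eye cameras.
#' @param rig [RigidTransform-class] mapping IR-frame points into the RGB
#'   camera frame.
#' @param gapMax maximum triangulation gap in mm for a pair to be used.
#' @param maxIter Gauss-Newton iteration cap.
#' @return An [EyeballModel-class].
#' @export
buildEyeModel <- function(corr, Kir, Krgb, rig, gapMax = 2, maxIter = 100L) {
  if (nrow(corr) < 4L)
    stop("buildEyeModel: insufficient data (need >= 4 correspondences)")
  dIr <- backprojectPixels(Kir, cbind(corr$uIr, corr$vIr))
  dRgbCam <- backprojectPixels(Krgb, cbind(corr$uRgb, corr$vRgb))
  # express the RGB rays in the IR (world) frame
  Rinv <- t(rig@rotation)
  dRgb <- dRgbCam %*% t(Rinv)
  oRgb <- cameraCenter(rig)
  tri <- triangulateRays(c(0, 0, 0), dIr, oRgb, dRgb)
  keep <- tri$gap < gapMax
  if (sum(keep) < 4L)
    stop("buildEyeModel: insufficient data (fewer than 4 pairs pass gapMax)")
  pts <- tri$point[keep, , drop = FALSE]
  meanDir <- unit3(colMeans(dIr[keep, , drop = FALSE]))
  c0 <- colMeans(pts) + EYE_RADIUS_MM * meanDir
  fit <- fitSphereCenter(pts, c0, maxIter = maxIter)
  new("EyeballModel", center = fit$center, radius = EYE_RADIUS_MM,
      nSupportPoints = as.integer(nrow(pts)), rmsResidual = fit$rms)
}

# Fixed-radius sphere fit: Gauss-Newton on r_i(c) = ||p_i - c|| - R,
# J_i = -(p_i - c)' / ||p_i - c||; Nelder-Mead fallback on non-convergence.
fitSphereCenter <- function(pts, c0, radius = EYE_RADIUS_MM, maxIter = 100L,
                            tol = 1e-12) {
  cc <- c0
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    d <- sweep(pts, 2L, cc)          # p_i - c
    nrm <- sqrt(rowSums(d^2))
    if (any(nrm < 1e-9)) break       # centre collapsed onto a point
    r <- nrm - radius
    J <- -d / nrm
    step <- tryCatch(solve(crossprod(J), -crossprod(J, r)),
                     error = function(e) NULL)
    if (is.null(step)) break
    cc <- cc + as.numeric(step)
    if (sqrt(sum(step^2)) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    obj <- function(c_) {
      d <- sweep(pts, 2L, c_)
      sum((sqrt(rowSums(d^2)) - radius)^2)
    }
    opt <- stats::optim(cc, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000L, reltol = 1e-14))
    cc <- opt$par
  }
  d <- sweep(pts, 2L, cc)
  res <- sqrt(rowSums(d^2)) - radius
  list(center = as.numeric(cc), rms = sqrt(mean(res^2)))
}

#' Intersect rays with the eyeball sphere
#'
#' Solves ||o + t d - c||^2 = r^2 and returns the root closer to the ray
#' origin: the camera-facing surface, where a visible pupil must lie (the far
#' root is anatomically impossible). Vectorized over rows.
#'
#' @param origin ray origin(s), length-3 or N x 3 (mm), outside the sphere.
#' @param dir unit ray direction(s), length-3 or N x 3.
#' @param model an [EyeballModel-class], or a length-3 centre.
#' @param radius sphere radius, defaults to the model's 12 mm.
#' @return N x 3 matrix of surface points (mm).
#' @section Errors: rays that miss the sphere (negative discriminant) raise an
#'   error of class `gazeNoIntersection`.
#' @export
raySphereIntersect <- function(origin, dir, model, radius = NULL) {
  ctr <- if (is(model, "EyeballModel")) model@center else as.numeric(model)
  r <- if (!is.null(radius)) radius
       else if (is(model, "EyeballModel")) model@radius else EYE_RADIUS_MM
  o <- as_points3(origin); d <- as_points3(dir)
  n <- max(nrow(o), nrow(d))
  if (nrow(o) != n) o <- o[rep(1L, n), , drop = FALSE]
  if (nrow(d) != n) d <- d[rep(1L, n), , drop = FALSE]
  oc <- sweep(o, 2L, ctr)
  b <- rowSums(oc * d)                  # t^2 + 2 b t + c0 = 0 for unit d
  c0 <- rowSums(oc^2) - r^2
  disc <- b^2 - c0
  if (any(disc < 0))
    stop(structure(class = c("gazeNoIntersection", "error", "condition"),
                   list(message = "raySphereIntersect: ray(s) miss the sphere",
                        call = sys.call())))
  t1 <- -b - sqrt(disc)                 # near root (origin outside, b < 0)
  o + d * t1
}

#' Map an IR eye-image point to the RGB eye image
#'
#' The point-to-point stereo mapping enabled by the eyeball model: backproject
#' the IR pixel, intersect the viewing ray with the eyeball sphere (near
#' root), move the 3D surface point into the RGB camera frame and project.
#' Vectorized over rows.
#'
#' @param q (u, v) pixel(s) in the IR image, length-2 or N x 2.
#' @param model an [EyeballModel-class].
#' @param Kir,Krgb intrinsics of the two eye cameras.
#' @param rig IR -> RGB [RigidTransform-class].
#' @return N x 2 matrix of RGB-image pixels.
#' @section Errors: propagates `gazeNoIntersection` when a ray misses the
#'   sphere (the frame is then skipped by callers).
#' @export
mapIrToRgb <- function(q, model, Kir, Krgb, rig) {
  d <- backprojectPixels(Kir, q)
  p3 <- raySphereIntersect(c(0, 0, 0), d, model)
  projectPoints(Krgb, applyRigid(rig, p3))
}

#' 3D gaze ray (optical axis)
#'
#' The gaze ray originates at the eyeball centre and passes through the 3D
#' pupil-centre surface point out into the world. Only the optical axis is
#' computed; the per-person kappa offset to the visual axis is not corrected.
#'
#' @param model an [EyeballModel-class].
#' @param pupilCenterIr (u, v) pupil centre in the IR image.
#' @param Kir IR camera intrinsics.
#' @return list(origin, direction): origin = eyeball centre (mm), direction a
#'   unit 3-vector pointing from the centre through the pupil.
#' @export
gazeRay <- function(model, pupilCenterIr, Kir) {
  d <- backprojectPixels(Kir, pupilCenterIr)
  p <- raySphereIntersect(c(0, 0, 0), d, model)
  g <- unit3(as.numeric(p) - model@center)
  list(origin = model@center, direction = g)
}
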