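#' @import methods
NULL

#' Pinhole camera intrinsics
#'
#' Holds the internal parameters of one pinhole camera: focal lengths and
#' principal point in pixels, the image size, and optional radial distortion
#' coefficients (2-coefficient model, default zero).
#'
#' Pixel coordinates are 0-based, x to the right, y down; the camera looks
#' down its +z axis and all 3D camera-frame coordinates are in millimetres.
#'
#' @slot fx,fy focal lengths in pixels (> 0).
#' @slot cx,cy principal point in pixels, inside the image.
#' @slot width,height image size in pixels.
#' @slot dist numeric(2), radial distortion coefficients (k1, k2).
#' @seealso [cameraIntrinsics()], [projectPoints()], [backprojectPixels()]
#' @export
setClass("CameraIntrinsics",
  representation(fx = "numeric", fy = "numeric", cx = "numeric",
                 cy = "numeric", width = "numeric", height = "numeric",
                 dist = "numeric"),
  prototype(dist = c(0, 0)))

setValidity("CameraIntrinsics", function(object) {
  msg <- character()
  if (length(object@fx) != 1L || object@fx <= 0) msg <- c(msg, "fx must be a single positive number")
  if (length(object@fy) != 1L || object@fy <= 0) msg <- c(msg, "fy must be a single positive number")
  if (object@cx < 0 || object@cx >= object@width) msg <- c(msg, "cx must lie in [0, width)")
  if (object@cy < 0 || object@cy >= object@height) msg <- c(msg, "cy must lie in [0, height)")
  if (length(object@dist) != 2L || any(!is.finite(object@dist))) msg <- c(msg, "dist must be two finite radial coefficients")
  if (length(msg)) msg else TRUE
})

#' Construct camera intrinsics
#'
#' @param fx,fy focal lengths in pixels.
#' @param cx,cy principal point in pixels.
#' @param width,height image size in pixels.
#' @param dist radial distortion coefficients (k1, k2); default none.
#' @return A [CameraIntrinsics-class] object.
#' @examples
#' K <- cameraIntrinsics(500, 500, 320, 240, 640, 480)
#' projectPoints(K, c(0, 0, 100))
#' @export
cameraIntrinsics <- function(fx, fy, cx, cy, width, height, dist = c(0, 0)) {
  new("CameraIntrinsics", fx = as.numeric(fx), fy = as.numeric(fy),
      cx = as.numeric(cx), cy = as.numeric(cy),
      width = as.numeric(width), height = as.numeric(height),
      dist = as.numeric(dist))
}

#' Rigid transform between camera frames
#'
#' A proper rigid motion x' = R x + t mapping points from one camera frame to
#' another (translation in mm). Used for the stereo extrinsics between the IR
#' and RGB eye cameras, which are consumed as calibration inputs.
#'
#' @slot rotation 3x3 orthonormal matrix with det +1.
#' @slot translation length-3 numeric, mm.
#' @seealso [rigidTransform()], [applyRigid()], [invertRigid()]
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  msg <- character()
  if (!all(dim(R) == c(3L, 3L))) msg <- c(msg, "rotation must be 3x3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-9) msg <- c(msg, "rotation must be orthonormal (R'R = I within 1e-9)")
    if (abs(det(R) - 1) > 1e-9) msg <- c(msg, "rotation must have determinant +1")
  }
  if (length(object@translation) != 3L || any(!is.finite(object@translation)))
    msg <- c(msg, "translation must be a finite 3-vector")
  if (length(msg)) msg else TRUE
})

#' Construct a rigid transform
#'
#' @param rotation 3x3 orthonormal rotation matrix.
#' @param translation length-3 translation in mm.
#' @return A [RigidTransform-class].
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation, translation = as.numeric(translation))
}

#' Pupil detection in one eye image
#'
#' Output contract of the pupil detector: sub-pixel pupil centre, axis-aligned
#' bounding box, fitted boundary ellipse and a confidence score. The same
#' contract a learned detector would honour, so detectors are interchangeable.
#'
#' @slot center numeric(2), pupil centre (u, v), 0-based pixels.
#' @slot bbox numeric(4): (u_min, v_min, width, height), clipped to the image.
#' @slot ellipse list with elements `center` (u, v), `a`, `b` (semi-axes, a >= b > 0)
#'   and `theta` (orientation of the major axis, radians).
#' @slot score detection confidence in [0, 1].
#' @seealso [detectPupil()], [sampleBoundaryPoints()]
#' @export
setClass("PupilDetection",
  representation(center = "numeric", bbox = "numeric", ellipse = "list",
                 score = "numeric"))

setValidity("PupilDetection", function(object) {
  msg <- character()
  if (length(object@center) != 2L || any(!is.finite(object@center)))
    msg <- c(msg, "center must be finite (u, v)")
  b <- object@bbox
  if (length(b) != 4L || b[3] <= 0 || b[4] <= 0)
    msg <- c(msg, "bbox must be (u_min, v_min, width, height) with positive size")
  else if (length(object@center) == 2L) {
    if (object@center[1] < b[1] || object@center[1] > b[1] + b[3] ||
        object@center[2] < b[2] || object@center[2] > b[2] + b[4])
      msg <- c(msg, "center must lie inside bbox")
  }
  e <- object@ellipse
  if (!all(c("center", "a", "b", "theta") %in% names(e)))
    msg <- c(msg, "ellipse must have center, a, b, theta")
  else if (!(e$a >= e$b && e$b > 0))
    msg <- c(msg, "ellipse semi-axes must satisfy a >= b > 0")
  if (length(object@score) != 1L || object@score < 0 || object@score > 1)
    msg <- c(msg, "score must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Per-user 3D eyeball model
#'
#' The eyeball is modelled as a sphere of fixed anatomical radius 12 mm; only
#' its centre is estimated per user, from 3D points triangulated off the pupil
#' boundary as seen by the two eye cameras. All coordinates are in the IR eye
#' camera frame (the world frame of the eye-side geometry).
#'
#' @slot center numeric(3), sphere centre in mm, IR-camera frame.
#' @slot radius fixed at 12 mm.
#' @slot nSupportPoints number of triangulated points used by the fit (>= 4).
#' @slot rmsResidual root-mean-square radial residual of the fit, mm.
#' @seealso [buildEyeModel()], [mapIrToRgb()], [gazeRay()]
#' @export
setClass("EyeballModel",
  representation(center = "numeric", radius = "numeric",
                 nSupportPoints = "integer", rmsResidual = "numeric"))

setValidity("EyeballModel", function(object) {
  msg <- character()
  if (length(object@center) != 3L || any(!is.finite(object@center)))
    msg <- c(msg, "center must be a finite 3-vector (mm)")
  if (!identical(object@radius, 12.0))
    msg <- c(msg, "radius is fixed at 12 mm")
  if (object@nSupportPoints < 4L)
    msg <- c(msg, "at least 4 support points are required")
  if (object@rmsResidual < 0)
    msg <- c(msg, "rmsResidual must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Corneal image patch
#'
#' The corneal reflection cropped from the RGB eye image around the pupil and
#' mirrored so its content matches world orientation (the cornea acts as a
#' mirror). The gaze point is the pupil centre expressed in crop-local
#' coordinates after the flip.
#'
#' @slot pixels numeric matrix (grayscale) or array (h, w, 3), values in [0, 1].
#' @slot bboxRgb numeric(4) (u_min, v_min, width, height) of the crop in full
#'   RGB-eye-image coordinates, clipped to image bounds.
#' @slot gazePoint numeric(2), pupil centre in crop-local (flipped) coordinates.
#' @slot flipped logical, always TRUE after extraction.
#' @seealso [extractCornealImage()], [gazeToScene()]
#' @export
setClass("CornealImage",
  representation(pixels = "ANY", bboxRgb = "numeric", gazePoint = "numeric",
                 flipped = "logical"))

setValidity("CornealImage", function(object) {
  msg <- character()
  if (length(object@bboxRgb) != 4L || object@bboxRgb[3] <= 0 || object@bboxRgb[4] <= 0)
    msg <- c(msg, "bboxRgb must be (u_min, v_min, width, height) with positive size")
  g <- object@gazePoint
  if (length(g) != 2L || any(!is.finite(g)))
    msg <- c(msg, "gazePoint must be finite (u, v)")
  else if (g[1] < -0.5 || g[1] > object@bboxRgb[3] - 0.5 ||
           g[2] < -0.5 || g[2] > object@bboxRgb[4] - 0.5)
    msg <- c(msg, "gazePoint must lie inside the crop")
  if (length(msg)) msg else TRUE
})

#' Corneal-to-scene homography model
#'
#' A 3x3 projective map H transferring points from corneal (eye-image) to
#' front-scene coordinates, estimated by RANSAC over pooled feature matches
#' and refit by least squares on the inliers; H is normalized to H[3,3] = 1.
#'
#' `frame` records the coordinate frame of the corneal side: `"rgb"` for the
#' pooled per-session model (full RGB-eye-image coordinates, stationary under
#' eye rotation) or `"crop"` for a per-frame model in crop-local coordinates.
#'
#' @slot H 3x3 matrix, H[3,3] = 1, invertible.
#' @slot nInliers,nTotal RANSAC inlier count and total match count.
#' @slot inlierThreshold reprojection threshold in pixels.
#' @slot perPairInliers named integer vector of inlier counts per source pair.
#' @slot frame "rgb" or "crop".
#' @slot lowConfidence TRUE when fewer than 10 inliers supported the fit.
#' @seealso [estimateHomography()], [applyHomography()], [gazeToScene()]
#' @export
setClass("HomographyModel",
  representation(H = "matrix", nInliers = "integer", nTotal = "integer",
                 inlierThreshold = "numeric", perPairInliers = "integer",
                 frame = "character", lowConfidence = "logical"))

setValidity("HomographyModel", function(object) {
  msg <- character()
  H <- object@H
  if (!all(dim(H) == c(3L, 3L))) msg <- c(msg, "H must be 3x3")
  else {
    if (abs(H[3, 3] - 1) > 1e-12) msg <- c(msg, "H must be normalized to H[3,3] = 1")
    if (abs(det(H)) <= 1e-12) msg <- c(msg, "H must be invertible")
  }
  if (object@nInliers > object@nTotal) msg <- c(msg, "nInliers cannot exceed nTotal")
  if (!object@frame %in% c("rgb", "crop")) msg <- c(msg, "frame must be 'rgb' or 'crop'")
  if (length(msg)) msg else TRUE
})

## show methods ---------------------------------------------------------------

setMethod("show", "CameraIntrinsics", function(object) {
  cat(sprintf("CameraIntrinsics %dx%d  fx=%.1f fy=%.1f  c=(%.1f, %.1f)",
              object@width, object@height, object@fx, object@fy,
              object@cx, object@cy))
  if (any(object@dist != 0)) cat(sprintf("  dist=(%g, %g)", object@dist[1], object@dist[2]))
  cat("\n")
})

setMethod("show", "RigidTransform", function(object) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("RigidTransform  rotation %.2f deg, translation (%.2f, %.2f, %.2f) mm\n",
              ang, object@translation[1], object@translation[2], object@translation[3]))
})

setMethod("show", "PupilDetection", function(object) {
  cat(sprintf("PupilDetection  center (%.2f, %.2f) px  bbox [%g, %g, %g, %g]  a=%.1f b=%.1f  score %.2f\n",
              object@center[1], object@center[2],
              object@bbox[1], object@bbox[2], object@bbox[3], object@bbox[4],
              object@ellipse$a, object@ellipse$b, object@score))
})

setMethod("show", "EyeballModel", function(object) {
  cat(sprintf("EyeballModel  center (%.3f, %.3f, %.3f) mm  r = 12 mm  %d points, rms %.4g mm\n",
              object@center[1], object@center[2], object@center[3],
              object@nSupportPoints, object@rmsResidual))
})

setMethod("show", "CornealImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("CornealImage  %d x %d crop at (%g, %g), gaze point (%.1f, %.1f), flipped=%s\n",
              d[2], d[1], object@bboxRgb[1], object@bboxRgb[2],
              object@gazePoint[1], object@gazePoint[2], object@flipped))
})

setMethod("show", "HomographyModel", function(object) {
  cat(sprintf("HomographyModel (%s frame)  %d/%d inliers @ %.1f px%s\n",
              object@frame, object@nInliers, object@nTotal,
              object@inlierThreshold,
              if (object@lowConfidence) "  [low confidence]" else ""))
})

## accessors ------------------------------------------------------------------

#' Accessors for CornealGaze model objects
#'
#' Small read-only accessors so user code never touches slots directly.
#'
#' @param object a CornealGaze S4 object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
eyeCenter <- function(object) object@center

#' @rdname accessors
#' @export
eyeRadius <- function(object) object@radius

#' @rdname accessors
#' @export
rmsResidual <- function(object) object@rmsResidual

#' @rdname accessors
#' @export
pupilCenter <- function(object) object@center

#' @rdname accessors
#' @export
pupilBbox <- function(object) object@bbox

#' @rdname accessors
#' @export
pupilEllipse <- function(object) object@ellipse

#' @rdname accessors
#' @export
homographyMatrix <- function(object) object@H

#' @rdname accessors
#' @export
nInliers <- function(object) object@nInliers

#' @rdname accessors
#' @export
gazePoint <- function(object) object@gazePoint

#' @rdname accessors
#' @export
cornealBbox <- function(object) object@bboxRgb

#' @rdname accessors
#' @export
cornealPixels <- function(object) object@pixels

#' @rdname accessors
#' @export
imageSize <- function(object) c(width = object@width, height = object@height)
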