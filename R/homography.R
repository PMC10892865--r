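## Corneal-to-scene mapping: pooled feature matches, RANSAC homography with a
## 4-point DLT minimal solver and Hartley normalization, and gaze transfer.
##
## Coordinate frames. Matches are produced in crop-local (flipped) corneal
## coordinates. A per-frame homography can be fitted there directly. The
## pooled per-session homography is instead estimated in full RGB-eye-image
## coordinates: the corneal reflection is quasi-stationary in that frame when
## the eye rotates (a spherical mirror surface does not move when it spins),
## whereas the crop origin tracks the moving pupil, so pooling crop-local
## coordinates across frames would mix inconsistent frames. Each match row
## carries its crop geometry so it can be lifted exactly.

#' Pool feature matches across image pairs
#'
#' Concatenates per-pair match sets, preserving each match's source pair id;
#' no deduplication is performed.
#'
#' @param pairs list of match data.frames as returned by [detectAndMatch()]
#'   (or [simulateSession()]).
#' @return One pooled match data.frame.
#' @export
accumulateMatches <- function(pairs) {
  pairs <- Filter(function(m) !is.null(m) && nrow(m) > 0, pairs)
  if (!length(pairs))
    stop("accumulateMatches: insufficient data (all match sets empty)")
  do.call(rbind, pairs)
}

# lift crop-local match coordinates into the full RGB eye image using the
# per-row crop geometry columns (cropU0, cropV0, cropW)
liftMatchesToRgb <- function(matches) {
  need <- c("cropU0", "cropV0", "cropW")
  if (!all(need %in% names(matches)))
    stop("liftMatchesToRgb: matches lack crop geometry columns")
  u <- matches$cropU0 + (matches$cropW - 1 - matches$uCrop)
  v <- matches$cropV0 + matches$vCrop
  cbind(u, v)
}

# Hartley-normalized direct linear transform from >= 4 point pairs
homographyDLT <- function(src, dst) {
  n <- nrow(src)
  norm <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2L, ctr)^2))
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
    T <- matrix(c(s, 0, 0, 0, s, 0, -s * ctr[1], -s * ctr[2], 1), 3, 3)
    list(T = T, p = cbind(s * (p[, 1] - ctr[1]), s * (p[, 2] - ctr[2])))
  }
  ns <- norm(src); nd <- norm(dst)
  x <- ns$p[, 1]; y <- ns$p[, 2]
  xp <- nd$p[, 1]; yp <- nd$p[, 2]
  A <- matrix(0, 2 * n, 9)
  A[seq(1, 2 * n, 2), ] <- cbind(-x, -y, -1, 0, 0, 0, x * xp, y * xp, xp)
  A[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, -x, -y, -1, x * yp, y * yp, yp)
  h <- eigen(crossprod(A), symmetric = TRUE)$vectors[, 9]
  Hn <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% Hn %*% ns$T
  if (abs(H[3, 3]) < 1e-12) return(NULL)
  H / H[3, 3]
}

homographyTransfer <- function(H, pts) {
  pts <- as_points2(pts)
  s <- H[3, 1] * pts[, 1] + H[3, 2] * pts[, 2] + H[3, 3]
  cbind((H[1, 1] * pts[, 1] + H[1, 2] * pts[, 2] + H[1, 3]) / s,
        (H[2, 1] * pts[, 1] + H[2, 2] * pts[, 2] + H[2, 3]) / s)
}

#' Estimate the corneal-to-scene homography by RANSAC
#'
#' Random 4-point samples are solved by normalized DLT; the consensus model
#' under the forward-transfer inlier threshold wins, with adaptive early exit
#' at the given confidence; the final model is a least-squares (DLT) refit on
#' all inliers, normalized to H[3,3] = 1. Fewer than 10 inliers flags the
#' model as low confidence.
#'
#' @param matches match data.frame (columns uCrop, vCrop, uScene, vScene,
#'   pairId and, for `frame = "rgb"`, the crop geometry columns).
#' @param frame `"crop"` fits in crop-local coordinates (per-frame model);
#'   `"rgb"` lifts the corneal points into full eye-image coordinates first
#'   (pooled per-session model).
#' @param inlierThreshold RANSAC reprojection threshold, pixels.
#' @param maxIter iteration cap.
#' @param confidence early-exit confidence.
#' @param seed optional integer; fixes the RANSAC sampling for
#'   reproducibility without disturbing the caller's RNG stream.
#' @return A [HomographyModel-class].
#' @export
estimateHomography <- function(matches, frame = c("rgb", "crop"),
                               inlierThreshold = 3, maxIter = 2000L,
                               confidence = 0.99, seed = NULL) {
  frame <- match.arg(frame)
  n <- nrow(matches)
  if (is.null(matches) || n < 4L)
    stop("estimateHomography: insufficient data (need >= 4 matches)")
  src <- if (frame == "rgb") liftMatchesToRgb(matches)
         else cbind(matches$uCrop, matches$vCrop)
  dst <- cbind(matches$uScene, matches$vScene)
  runRansac <- function() {
    bestInl <- rep(FALSE, n)
    bestCount <- -1L
    iter <- 0L
    needed <- maxIter
    while (iter < min(maxIter, needed)) {
      iter <- iter + 1L
      idx <- sample.int(n, 4L)
      H <- tryCatch(homographyDLT(src[idx, , drop = FALSE], dst[idx, , drop = FALSE]),
                    error = function(e) NULL)
      if (is.null(H)) next
      err <- sqrt(rowSums((homographyTransfer(H, src) - dst)^2))
      inl <- err < inlierThreshold
      cnt <- sum(inl)
      if (cnt > bestCount) {
        bestCount <- cnt
        bestInl <- inl
        w <- cnt / n
        needed <- if (w >= 1) 1L
                  else ceiling(log(1 - confidence) / log(1 - w^4 + 1e-300))
      }
    }
    bestInl
  }
  inl <- with_seed(seed, runRansac())
  if (sum(inl) < 4L)
    stop("estimateHomography: RANSAC found no 4-match consensus")
  # least-squares refit on inliers, then one re-classification + refit pass
  for (pass in 1:2) {
    H <- homographyDLT(src[inl, , drop = FALSE], dst[inl, , drop = FALSE])
    if (is.null(H)) stop("estimateHomography: degenerate inlier refit")
    err <- sqrt(rowSums((homographyTransfer(H, src) - dst)^2))
    inl <- err < inlierThreshold
  }
  pairIds <- if ("pairId" %in% names(matches)) matches$pairId else rep(1L, n)
  per <- vapply(split(inl, pairIds), sum, integer(1))
  new("HomographyModel", H = H, nInliers = as.integer(sum(inl)),
      nTotal = as.integer(n), inlierThreshold = inlierThreshold,
      perPairInliers = per, frame = frame,
      lowConfidence = sum(inl) < 10L)
}

#' Apply a homography to points
#'
#' Computes S (u', v', 1)' = H (u, v, 1)' and divides by the scale factor S.
#'
#' @param model a [HomographyModel-class] or a bare 3x3 matrix.
#' @param q (u, v) point(s), length-2 or N x 2.
#' @return N x 2 matrix of transferred points.
#' @section Errors: |S| < 1e-12 (a point mapped to the line at infinity)
#'   raises an error.
#' @export
applyHomography <- function(model, q) {
  H <- if (is(model, "HomographyModel")) model@H else model
  q <- as_points2(q)
  s <- H[3, 1] * q[, 1] + H[3, 2] * q[, 2] + H[3, 3]
  if (any(abs(s) < 1e-12))
    stop("applyHomography: point at infinity (scale factor ~ 0)")
  cbind((H[1, 1] * q[, 1] + H[1, 2] * q[, 2] + H[1, 3]) / s,
        (H[2, 1] * q[, 1] + H[2, 2] * q[, 2] + H[2, 3]) / s)
}

#' Transfer the corneal gaze point into the scene image
#'
#' Applies the homography to the corneal image's gaze point (the pupil
#' centre). For a pooled `"rgb"`-frame model the gaze point is first lifted
#' from crop-local to full eye-image coordinates through the crop's bbox and
#' mirror. Points landing outside the scene frame are flagged, not rejected.
#'
#' @param corneal a [CornealImage-class].
#' @param model a [HomographyModel-class].
#' @param sceneSize optional c(width, height) of the scene image, used to set
#'   the `clipped` flag.
#' @return list(point = numeric(2) scene pixel, clipped = logical).
#' @export
gazeToScene <- function(corneal, model, sceneSize = NULL) {
  q <- if (model@frame == "rgb")
    cropToRgb(corneal@gazePoint, corneal@bboxRgb)
  else matrix(corneal@gazePoint, 1L)
  p <- as.numeric(applyHomography(model, q))
  clipped <- if (is.null(sceneSize)) NA
             else p[1] < 0 || p[1] > sceneSize[1] - 1 ||
                  p[2] < 0 || p[2] > sceneSize[2] - 1
  list(point = p, clipped = clipped)
}
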