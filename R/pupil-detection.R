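## Classical pupil detector for IR eye images. It honours the same output
## contract as a learned detector (centre + bbox + ellipse + score), so the
## downstream 3D pipeline never knows which detector produced the detection.

#' Direct least-squares ellipse fit
#'
#' Fits an ellipse to 2D points by the direct conic least-squares method with
#' the ellipse-specific constraint 4AC - B^2 = 1, then converts the conic to
#' geometric parameters.
#'
#' @param pts N x 2 matrix of (u, v) points, N >= 5.
#' @return list(center, a, b, theta) with semi-axes a >= b and major-axis
#'   orientation theta in radians.
#' @export
fitEllipseLS <- function(pts) {
  pts <- as_points2(pts)
  if (nrow(pts) < 5L) stop("fitEllipseLS: need at least 5 points")
  x <- pts[, 1]; y <- pts[, 2]
  mx <- mean(x); my <- mean(y)
  s <- mean(c(stats::sd(x), stats::sd(y)))
  if (s == 0) stop("fitEllipseLS: degenerate point set")
  x <- (x - mx) / s; y <- (y - my) / s
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  # premultiply by inv(C1), C1 = [[0,0,2],[0,-1,0],[2,0,0]]
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  idx <- which(cond > 0)
  if (!length(idx)) stop("fitEllipseLS: no elliptical solution")
  a1 <- V[, idx[1]]
  coefN <- c(a1, as.numeric(Tm %*% a1))  # conic in normalized coords
  # undo normalization: substitute x = (u - mx)/s, y = (v - my)/s
  A <- coefN[1] / s^2
  B <- coefN[2] / s^2
  C <- coefN[3] / s^2
  D <- coefN[4] / s - 2 * A * mx - B * my
  E <- coefN[5] / s - 2 * C * my - B * mx
  F <- coefN[6] + A * mx^2 + B * mx * my + C * my^2 -
       coefN[4] * mx / s - coefN[5] * my / s
  conicToEllipse(c(A, B, C, D, E, F))
}

conicToEllipse <- function(coef) {
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; F <- coef[6]
  M <- matrix(c(2 * A, B, B, 2 * C), 2, 2)
  ctr <- solve(M, -c(D, E))
  F0 <- A * ctr[1]^2 + B * ctr[1] * ctr[2] + C * ctr[2]^2 + D * ctr[1] + E * ctr[2] + F
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eq <- eigen(Q, symmetric = TRUE)
  ax2 <- -F0 / eq$values
  if (any(ax2 <= 0)) stop("conicToEllipse: conic is not an ellipse")
  axes <- sqrt(ax2)
  major <- which.max(axes)
  vmaj <- eq$vectors[, major]
  list(center = as.numeric(ctr), a = max(axes), b = min(axes),
       theta = atan2(vmaj[2], vmaj[1]) %% pi)
}

#' Default pupil-detection configuration
#'
#' @param min_area_frac,max_area_frac admissible pupil area as a fraction of
#'   the image area.
#' @param n_boundary_points boundary points sampled per detection for the
#'   eyeball fit.
#' @return Named list of detector settings.
#' @export
pupilDetectionConfig <- function(min_area_frac = 0.001, max_area_frac = 0.05,
                                 n_boundary_points = 32L) {
  list(min_area_frac = min_area_frac, max_area_frac = max_area_frac,
       n_boundary_points = as.integer(n_boundary_points))
}

#' Detect the pupil in an IR eye image
#'
#' Segments the dark pupil by two-stage Otsu thresholding (dark structures
#' against the bright background, then pupil against iris within the dark
#' class, guarded against splitting a unimodal pupil blob), keeps the largest
#' connected component whose area lies within the configured fraction bounds,
#' and fits an ellipse to the component boundary by direct least squares. The
#' detection centre is the ellipse centre; the bounding box is the
#' axis-aligned box of the ellipse.
#'
#' @param image grayscale matrix in [0, 1], at least 64 x 64.
#' @param config see [pupilDetectionConfig()].
#' @return A [PupilDetection-class].
#' @section Errors: throws an error of class `gazeDetectionFailure` when no
#'   admissible pupil component exists; callers skip such frames.
#' @export
detectPupil <- function(image, config = pupilDetectionConfig()) {
  image <- toGray(image)
  h <- nrow(image); w <- ncol(image)
  if (h < 64L || w < 64L) stop("detectPupil: image must be at least 64x64")
  npx <- h * w
  failure <- function(msg) stop(structure(class = c("gazeDetectionFailure", "error", "condition"),
                                          list(message = msg, call = sys.call(-1))))
  # two-stage segmentation: Otsu separates dark structures (pupil + iris)
  # from the bright background, then a second Otsu restricted to the dark
  # class splits pupil from iris. The second split is only accepted when the
  # two dark sub-classes are genuinely separated (> 3 within-class sd),
  # otherwise the dark class is a single unimodal blob (the pupil itself)
  # and splitting it would halve the pupil.
  thr <- otsuThreshold(image)
  darkVals <- image[image <= thr]
  if (length(unique(darkVals)) >= 2L) {
    t2 <- otsuThreshold(darkVals)
    c1 <- darkVals[darkVals <= t2]
    c2 <- darkVals[darkVals > t2]
    if (length(c1) > 1L && length(c2) > 1L &&
        mean(c2) - mean(c1) > 3 * max(stats::sd(c1), stats::sd(c2), 1e-6))
      thr <- t2
  }
  mask <- image <= thr
  if (!any(mask)) failure("detectPupil: empty segmentation")
  lab <- t(EBImage::bwlabel(t(mask)))
  sizes <- tabulate(lab[lab > 0])
  admissible <- which(sizes >= config$min_area_frac * npx &
                      sizes <= config$max_area_frac * npx)
  if (!length(admissible)) failure("detectPupil: no component within area bounds")
  keep <- admissible[which.max(sizes[admissible])]
  comp <- lab == keep
  # boundary: component pixels with at least one 4-neighbour outside
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- comp
  inner <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
           pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  edge <- comp & !inner
  idx <- which(edge, arr.ind = TRUE)
  if (nrow(idx) < 5L) failure("detectPupil: component too small to fit")
  bpts <- cbind(idx[, 2] - 1, idx[, 1] - 1)  # (u, v), 0-based
  ell <- fitEllipseLS(bpts)
  eu <- sqrt((ell$a * cos(ell$theta))^2 + (ell$b * sin(ell$theta))^2)
  ev <- sqrt((ell$a * sin(ell$theta))^2 + (ell$b * cos(ell$theta))^2)
  bbox <- clipBbox(c(ell$center[1] - eu, ell$center[2] - ev, 2 * eu, 2 * ev), w, h)
  center <- c(clamp(ell$center[1], bbox[1], bbox[1] + bbox[3]),
              clamp(ell$center[2], bbox[2], bbox[2] + bbox[4]))
  # score: pupil/surround contrast, discounted by interior non-uniformity (a
  # real pupil is uniformly dark; pixel noise raises the interior sd) and by
  # the raggedness of the boundary against the fitted ellipse
  ring <- clipBbox(c(bbox[1] - 0.5 * bbox[3], bbox[2] - 0.5 * bbox[4],
                     2 * bbox[3], 2 * bbox[4]), w, h)
  sub <- image[(ring[2] + 1):(ring[2] + ring[4]), (ring[1] + 1):(ring[1] + ring[3])]
  subc <- comp[(ring[2] + 1):(ring[2] + ring[4]), (ring[1] + 1):(ring[1] + ring[3])]
  contrast <- mean(sub[!subc]) - mean(sub[subc])
  resid <- ellipseRadialResiduals(bpts, ell)
  interiorSd <- if (sum(inner) > 10) stats::sd(image[inner]) else stats::sd(image[comp])
  score <- clamp(contrast, 0, 1) * exp(-2 * interiorSd - 0.5 * stats::sd(resid))
  new("PupilDetection", center = center, bbox = bbox,
      ellipse = ell, score = clamp(score, 0, 1))
}

# relative radial residuals of points against an ellipse (0 = on the ellipse)
ellipseRadialResiduals <- function(pts, ell) {
  dx <- pts[, 1] - ell$center[1]
  dy <- pts[, 2] - ell$center[2]
  xe <- dx * cos(ell$theta) + dy * sin(ell$theta)
  ye <- -dx * sin(ell$theta) + dy * cos(ell$theta)
  rho <- sqrt(xe^2 + ye^2)
  phi <- atan2(ye, xe)
  re <- ell$a * ell$b / sqrt((ell$b * cos(phi))^2 + (ell$a * sin(phi))^2)
  rho / re - 1
}

#' Sample evenly spaced points on a detection's boundary ellipse
#'
#' Points are taken at n evenly spaced parameter angles t of the fitted
#' ellipse, p(t) = c + a cos(t) e_major + b sin(t) e_minor. Using the same
#' parameter angles in two cameras puts the two boundaries in correspondence.
#'
#' @param det a [PupilDetection-class] (or a bare ellipse list).
#' @param n number of points, >= 4.
#' @return n x 2 matrix of (u, v) points.
#' @export
sampleBoundaryPoints <- function(det, n) {
  if (n < 4L) stop("sampleBoundaryPoints: n must be >= 4")
  ell <- if (is(det, "PupilDetection")) det@ellipse else det
  t <- 2 * pi * (seq_len(n) - 1) / n
  ct <- cos(ell$theta); st <- sin(ell$theta)
  cbind(u = ell$center[1] + ell$a * cos(t) * ct - ell$b * sin(t) * st,
        v = ell$center[2] + ell$a * cos(t) * st + ell$b * sin(t) * ct)
}

#' Pair pupil-boundary points across the two eye cameras
#'
#' Builds a correspondence set by sampling both fitted ellipses at equal
#' parameter angles (an approximation: equal angles do not label physically
#' identical limbus points, but the triangulated points still lie on the
#' eyeball surface, which is all the sphere fit needs).
#'
#' @param detIr,detRgb [PupilDetection-class] objects from the timestamp-paired
#'   IR and RGB frames.
#' @param n points per frame.
#' @param frameId identifier recorded with each pair.
#' @return data.frame(uIr, vIr, uRgb, vRgb, frameId) — a correspondence set.
#' @export
makeCorrespondences <- function(detIr, detRgb, n = 32L, frameId = 1L) {
  a <- sampleBoundaryPoints(detIr, n)
  b <- sampleBoundaryPoints(detRgb, n)
  data.frame(uIr = a[, 1], vIr = a[, 2], uRgb = b[, 1], vRgb = b[, 2],
             frameId = frameId)
}
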