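## Synthetic data generator. Emulates the wearable rig (IR eye camera
## 800x600, RGB eye camera 1280x960, front scene camera 1280x960), a 12 mm
## sphere-eye with a circular pupil on its surface, pixel-level detection
## noise, and a corneal reflection that is a projectively warped, mirrored,
## blurred copy of a planar textured scene. Every quantity is emitted twice:
## as a noisy observation and as exact ground truth, so each pipeline stage
## can be scored in isolation. Fully deterministic given the scenario seed.

rotationAboutAxis <- function(axis, angle) {
  a <- unit3(axis)
  ca <- cos(angle); sa <- sin(angle)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) * ca + sa * K + (1 - ca) * (a %o% a)
}

smallRandomRotation <- function(maxDeg) {
  ax <- stats::rnorm(3)
  rotationAboutAxis(ax, stats::runif(1, 0, maxDeg * pi / 180))
}

# orthonormal basis perpendicular to a unit vector
perpBasis <- function(g) {
  ref <- if (abs(g[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit3(pracmaCross(ref, g))
  e2 <- pracmaCross(g, e1)
  list(e1 = e1, e2 = e2)
}

pracmaCross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build a synthetic three-camera rig
#'
#' Image sizes follow the wearable headset (IR eye 800x600, RGB eye 1280x960,
#' front scene 1280x960); focal lengths are drawn from plausible ranges for
#' eye cameras focused at a few centimetres and a wide front camera. The two
#' eye cameras are separated by a small randomized baseline (5-15 mm) with a
#' small relative rotation; the front camera faces the opposite direction.
#' Deterministic given the seed.
#'
#' @param seed integer RNG seed.
#' @return list with `Kir`, `Krgb`, `Kfront` ([CameraIntrinsics-class]),
#'   `rgbFromIr`, `frontFromIr` ([RigidTransform-class]) and `baselineMm`.
#' @export
makeRig <- function(seed = 1L) {
  with_seed(seed, {
    # eye-camera focal lengths chosen so the whole eyeball stays in frame at
    # the 28-45 mm working distance (the pupil then covers ~1-4% of the frame)
    Kir <- cameraIntrinsics(fx = stats::runif(1, 550, 750),
                            fy = stats::runif(1, 550, 750),
                            cx = 400 + stats::runif(1, -10, 10),
                            cy = 300 + stats::runif(1, -10, 10),
                            width = 800, height = 600)
    Krgb <- cameraIntrinsics(fx = stats::runif(1, 900, 1200),
                             fy = stats::runif(1, 900, 1200),
                             cx = 640 + stats::runif(1, -10, 10),
                             cy = 480 + stats::runif(1, -10, 10),
                             width = 1280, height = 960)
    Kfront <- cameraIntrinsics(fx = stats::runif(1, 900, 1200),
                               fy = stats::runif(1, 900, 1200),
                               cx = 640 + stats::runif(1, -10, 10),
                               cy = 480 + stats::runif(1, -10, 10),
                               width = 1280, height = 960)
    baseline <- stats::runif(1, 5, 15)
    bdir <- unit3(c(stats::rnorm(1, 1, 0.2), stats::rnorm(1, 0, 0.2),
                    stats::rnorm(1, 0, 0.1)))
    Crgb <- baseline * bdir                      # RGB camera centre, IR frame
    # the RGB camera is verged onto the nominal eye position (both eye
    # cameras must keep the pupil in frame at close range), with a small
    # random mounting rotation on top
    nominalEye <- c(0, -5, 35)
    zr <- unit3(nominalEye - Crgb)
    xr <- unit3(pracmaCross(c(0, 1, 0), zr))
    Rrel <- smallRandomRotation(2) %*% rbind(xr, pracmaCross(zr, xr), zr)
    rgbFromIr <- rigidTransform(Rrel, -as.numeric(Rrel %*% Crgb))
    # front camera sits near the eye cameras and faces the world (-z)
    Cfront <- c(stats::runif(1, -20, 20), stats::runif(1, -30, 0),
                stats::runif(1, -5, 5))
    Rfront <- rotationAboutAxis(c(0, 1, 0), pi) %*% smallRandomRotation(3)
    frontFromIr <- rigidTransform(Rfront, -as.numeric(Rfront %*% Cfront))
    list(Kir = Kir, Krgb = Krgb, Kfront = Kfront,
         rgbFromIr = rgbFromIr, frontFromIr = frontFromIr,
         baselineMm = baseline)
  })
}

#' Define a synthetic session scenario
#'
#' Bundles the rig, eye geometry, gaze distribution and noise levels that
#' define one simulated recording session. Defaults mirror the evaluated
#' study conditions: 100 eye-camera frame pairs for the eyeball model, 220
#' corneal/scene pairs pooled for the homography, a planar textured scene at
#' 0.5-1 m, a 2 mm pupil, and 20 fps eye streams paired at 1 fps.
#'
#' @param seed integer; drives every random draw in the session.
#' @param nCalibFrames paired eye-camera frames used for the eyeball model.
#' @param nCalibPairs corneal/scene image pairs pooled for the homography.
#' @param nEvents evaluation gaze events.
#' @param pixelNoiseSd Gaussian noise added to projected pupil centres and
#'   boundary points (pixels) — the pupil-detection noise.
#' @param matchNoiseSd Gaussian noise on the scene side of feature matches
#'   (pixels).
#' @param outlierFraction fraction of feature matches replaced by uniform
#'   random scene points.
#' @param nBoundaryPoints pupil-boundary points per frame.
#' @param nMatchesPerPair feature matches generated per corneal/scene pair.
#' @param pupilRadiusMm pupil radius on the eye sphere, mm.
#' @param maxGazeAngleDeg half-angle of the gaze cone around the base gaze.
#' @param sceneDistanceMm distance of the scene plane from the front camera;
#'   NULL draws it uniformly from 500-1000 mm.
#' @param cornealBlurSigma,cornealDownsample blur (pixels) and resolution-loss
#'   factor of the rendered corneal patch.
#' @param marginFrac crop margin around the transformed pupil bounding box.
#' @return A scenario list consumed by [simulateSession()].
#' @export
syntheticScenario <- function(seed = 1L,
                              nCalibFrames = 100L,
                              nCalibPairs = 220L,
                              nEvents = 100L,
                              pixelNoiseSd = 0,
                              matchNoiseSd = 0,
                              outlierFraction = 0,
                              nBoundaryPoints = 32L,
                              nMatchesPerPair = 70L,
                              pupilRadiusMm = 2,
                              maxGazeAngleDeg = 15,
                              sceneDistanceMm = NULL,
                              cornealBlurSigma = 1,
                              cornealDownsample = 2,
                              marginFrac = 0.1) {
  stopifnot(pixelNoiseSd >= 0, matchNoiseSd >= 0,
            outlierFraction >= 0, outlierFraction < 1)
  rig <- makeRig(seed)
  with_seed(seed + 7L, {
    # 30-45 mm working distance: close enough for the eye to fill the frame,
    # far enough that a 2 mm pupil stays within the detector's area prior
    eyeCenter <- c(stats::runif(1, -3, 3), stats::runif(1, -8, -2),
                   stats::runif(1, 30, 45))
    baseGaze <- unit3(c(stats::runif(1, -0.05, 0.05),
                        stats::runif(1, 0.25, 0.35), -1))
    D <- if (is.null(sceneDistanceMm)) stats::runif(1, 500, 1000)
         else sceneDistanceMm
  })
  stopifnot(eyeCenter[3] >= 25, eyeCenter[3] <= 60)
  list(seed = as.integer(seed), rig = rig, eyeCenter = eyeCenter,
       baseGaze = baseGaze, sceneDistanceMm = D,
       nCalibFrames = as.integer(nCalibFrames),
       nCalibPairs = as.integer(nCalibPairs),
       nEvents = as.integer(nEvents),
       pixelNoiseSd = pixelNoiseSd, matchNoiseSd = matchNoiseSd,
       outlierFraction = outlierFraction,
       nBoundaryPoints = as.integer(nBoundaryPoints),
       nMatchesPerPair = as.integer(nMatchesPerPair),
       pupilRadiusMm = pupilRadiusMm, maxGazeAngleDeg = maxGazeAngleDeg,
       cornealBlurSigma = cornealBlurSigma,
       cornealDownsample = cornealDownsample, marginFrac = marginFrac)
}

# gaze directions in a cone around the base gaze (area-uniform in angle^2)
sampleGazeDirections <- function(n, base, maxDeg) {
  pb <- perpBasis(base)
  theta <- sqrt(stats::runif(n)) * maxDeg * pi / 180
  phi <- stats::runif(n, 0, 2 * pi)
  t(vapply(seq_len(n), function(i) {
    unit3(cos(theta[i]) * base +
          sin(theta[i]) * (cos(phi[i]) * pb$e1 + sin(phi[i]) * pb$e2))
  }, numeric(3)))
}

# pupil boundary circle on the sphere for gaze g (radius rp on a 12 mm eye)
pupilBoundary3d <- function(center, g, rp, phi) {
  alpha <- asin(rp / EYE_RADIUS_MM)
  pb <- perpBasis(g)
  ring <- t(vapply(phi, function(p) {
    center + EYE_RADIUS_MM * (cos(alpha) * g +
      sin(alpha) * (cos(p) * pb$e1 + sin(p) * pb$e2))
  }, numeric(3)))
  ring
}

# geometry of one gaze event: 3D pupil centre/boundary and their projections.
# requireInFrame = FALSE is used for virtual anchor gazes that are never
# observed as frames (only their projective relation is needed).
eventGeometry <- function(scn, g, requireInFrame = TRUE) {
  rig <- scn$rig
  p3 <- scn$eyeCenter + EYE_RADIUS_MM * g
  # visibility: pupil must sit on the camera-facing hemisphere for both cameras
  visIr <- sum(unit3(p3) * g) < -0.15
  visRgb <- sum(unit3(p3 - cameraCenter(rig$rgbFromIr)) * g) < -0.15
  if (!(visIr && visRgb)) return(NULL)
  inFrame <- function(q, K)
    q[1] >= 0 && q[1] <= K@width - 1 && q[2] >= 0 && q[2] <= K@height - 1
  irC <- projectPoints(rig$Kir, p3)
  rgbC <- projectPoints(rig$Krgb, applyRigid(rig$rgbFromIr, p3))
  if (requireInFrame && (!inFrame(irC, rig$Kir) || !inFrame(rgbC, rig$Krgb)))
    return(NULL)
  phi <- 2 * pi * (seq_len(scn$nBoundaryPoints) - 1) / scn$nBoundaryPoints
  ring <- pupilBoundary3d(scn$eyeCenter, g, scn$pupilRadiusMm, phi)
  list(g = g, p3 = p3, irCenter = irC, rgbCenter = rgbC,
       irRing = projectPoints(rig$Kir, ring),
       rgbRing = projectPoints(rig$Krgb, applyRigid(rig$rgbFromIr, ring)))
}

# physical scene gaze: optical axis intersected with the scene plane,
# projected into the front camera
planeGazePixel <- function(scn, g) {
  rig <- scn$rig
  Cf <- cameraCenter(rig$frontFromIr)
  axis <- as.numeric(t(rig$frontFromIr@rotation) %*% c(0, 0, 1))
  P0 <- Cf + scn$sceneDistanceMm * axis
  t <- sum((P0 - scn$eyeCenter) * axis) / sum(g * axis)
  G <- scn$eyeCenter + t * g
  projectPoints(rig$Kfront, applyRigid(rig$frontFromIr, G))
}

# session-level reflection homography, full RGB eye image -> scene image,
# anchored exactly to the physical plane-gaze geometry at 4 reference gazes
sessionHomography <- function(scn) {
  pb <- perpBasis(scn$baseGaze)
  ang <- 0.9 * scn$maxGazeAngleDeg * pi / 180
  src <- matrix(0, 4, 2); dst <- matrix(0, 4, 2)
  for (i in 1:4) {
    az <- pi / 4 + (i - 1) * pi / 2
    g <- unit3(cos(ang) * scn$baseGaze +
               sin(ang) * (cos(az) * pb$e1 + sin(az) * pb$e2))
    ev <- eventGeometry(scn, g, requireInFrame = FALSE)
    if (is.null(ev)) stop("sessionHomography: reference gaze not visible")
    src[i, ] <- ev$rgbCenter
    dst[i, ] <- planeGazePixel(scn, g)
  }
  homographyDLT(src, dst)
}

# true crop bbox around the projected RGB pupil ring, with margin, clipped
trueCropBbox <- function(scn, rgbRing) {
  u0 <- min(rgbRing[, 1]); u1 <- max(rgbRing[, 1])
  v0 <- min(rgbRing[, 2]); v1 <- max(rgbRing[, 2])
  mw <- (u1 - u0) * scn$marginFrac; mh <- (v1 - v0) * scn$marginFrac
  b <- clipBbox(c(u0 - mw, v0 - mh, u1 - u0 + 2 * mw, v1 - v0 + 2 * mh),
                scn$rig$Krgb@width, scn$rig$Krgb@height)
  c(floor(b[1]), floor(b[2]), floor(b[3]), floor(b[4]))
}

# affine lift crop-local (flipped) -> full RGB image, as a 3x3 matrix
cropLiftMatrix <- function(bbox) {
  matrix(c(-1, 0, 0, 0, 1, 0, bbox[1] + bbox[3] - 1, bbox[2], 1), 3, 3)
}

# synthesize feature matches for one frame given its true crop->scene map
synthesizeMatches <- function(scn, Hframe, bbox, pairId) {
  n <- scn$nMatchesPerPair
  # corneal points uniform in the crop's inscribed ellipse (the pupil region)
  a <- (bbox[3] - 1) / 2; b <- (bbox[4] - 1) / 2
  r <- sqrt(stats::runif(n)); th <- stats::runif(n, 0, 2 * pi)
  uc <- a + a * r * cos(th)
  vc <- b + b * r * sin(th)
  sc <- homographyTransfer(Hframe, cbind(uc, vc))
  if (scn$matchNoiseSd > 0)
    sc <- sc + matrix(stats::rnorm(2 * n, 0, scn$matchNoiseSd), n, 2)
  nOut <- round(scn$outlierFraction * n)
  if (nOut > 0) {
    out <- sample.int(n, nOut)
    sc[out, 1] <- stats::runif(nOut, 0, scn$rig$Kfront@width - 1)
    sc[out, 2] <- stats::runif(nOut, 0, scn$rig$Kfront@height - 1)
  }
  data.frame(uCrop = uc, vCrop = vc, uScene = sc[, 1], vScene = sc[, 2],
             dist = stats::runif(n, 0.1, 0.6), pairId = pairId,
             cropU0 = bbox[1], cropV0 = bbox[2],
             cropW = bbox[3], cropH = bbox[4])
}

#' Simulate a full auto-calibration + tracking session
#'
#' Generates, under one seed: (i) `nCalibFrames` timestamp-paired eye-camera
#' frames with noisy pupil-boundary correspondences for the eyeball fit;
#' (ii) `nCalibPairs` corneal/scene pairs with synthetic feature matches
#' (noise and outliers as configured) for the homography; (iii) `nEvents`
#' evaluation gaze events with noisy IR detections and exact ground truth.
#' The ground-truth scene gaze is defined through the session reflection
#' homography (see the package vignette), so a noiseless run of the full
#' pipeline reproduces it to numerical tolerance.
#'
#' @param scn scenario from [syntheticScenario()].
#' @return list(observations, truth): `observations` holds what a real
#'   recording would provide (noisy detections, matches, timestamps);
#'   `truth` holds the eyeball centre, the session homography, per-event
#'   noiseless projections, per-frame crop->scene homographies, the true
#'   scene gaze, stream timestamps and a log of skipped events.
#' @export
simulateSession <- function(scn) {
  with_seed(scn$seed + 1000L, {
    Hfull <- sessionHomography(scn)
    noisy <- function(m) {
      if (scn$pixelNoiseSd > 0)
        m + matrix(stats::rnorm(length(m), 0, scn$pixelNoiseSd), nrow(m), ncol(m))
      else m
    }
    skipped <- character(0)

    ## (i) eyeball-model calibration frames
    gCal <- sampleGazeDirections(scn$nCalibFrames, scn$baseGaze,
                                 scn$maxGazeAngleDeg)
    corr <- vector("list", scn$nCalibFrames)
    for (i in seq_len(scn$nCalibFrames)) {
      ev <- eventGeometry(scn, gCal[i, ])
      if (is.null(ev)) { skipped <- c(skipped, paste0("calib_frame_", i, ":pupil_not_visible")); next }
      ir <- noisy(ev$irRing); rgb <- noisy(ev$rgbRing)
      corr[[i]] <- data.frame(uIr = ir[, 1], vIr = ir[, 2],
                              uRgb = rgb[, 1], vRgb = rgb[, 2], frameId = i)
    }
    calibCorr <- do.call(rbind, corr)

    ## (ii) homography calibration pairs
    gPair <- sampleGazeDirections(scn$nCalibPairs, scn$baseGaze,
                                  scn$maxGazeAngleDeg)
    calibMatches <- vector("list", scn$nCalibPairs)
    for (i in seq_len(scn$nCalibPairs)) {
      ev <- eventGeometry(scn, gPair[i, ])
      if (is.null(ev)) { skipped <- c(skipped, paste0("calib_pair_", i, ":pupil_not_visible")); next }
      bbox <- trueCropBbox(scn, ev$rgbRing)
      Hframe <- Hfull %*% cropLiftMatrix(bbox)
      calibMatches[[i]] <- synthesizeMatches(scn, Hframe, bbox, pairId = i)
    }

    ## (iii) evaluation events
    gEv <- sampleGazeDirections(scn$nEvents, scn$baseGaze, scn$maxGazeAngleDeg)
    evRows <- vector("list", scn$nEvents)
    truthRows <- vector("list", scn$nEvents)
    eventMatches <- vector("list", scn$nEvents)
    Hframes <- vector("list", scn$nEvents)
    for (i in seq_len(scn$nEvents)) {
      ev <- eventGeometry(scn, gEv[i, ])
      if (is.null(ev)) { skipped <- c(skipped, paste0("event_", i, ":pupil_not_visible")); next }
      bbox <- trueCropBbox(scn, ev$rgbRing)
      Hframe <- Hfull %*% cropLiftMatrix(bbox)
      sTrue <- homographyTransfer(Hfull, ev$rgbCenter)
      irC <- noisy(ev$irCenter)
      ringN <- noisy(ev$irRing)
      irBbox <- c(min(ringN[, 1]), min(ringN[, 2]),
                  max(ringN[, 1]) - min(ringN[, 1]),
                  max(ringN[, 2]) - min(ringN[, 2]))
      evRows[[i]] <- data.frame(eventId = i,
                                uIr = irC[1], vIr = irC[2],
                                bboxU = irBbox[1], bboxV = irBbox[2],
                                bboxW = irBbox[3], bboxH = irBbox[4])
      truthRows[[i]] <- data.frame(eventId = i,
                                   gx = ev$g[1], gy = ev$g[2], gz = ev$g[3],
                                   uIrTrue = ev$irCenter[1], vIrTrue = ev$irCenter[2],
                                   uRgbTrue = ev$rgbCenter[1], vRgbTrue = ev$rgbCenter[2],
                                   uSceneTrue = sTrue[1], vSceneTrue = sTrue[2],
                                   cropU0 = bbox[1], cropV0 = bbox[2],
                                   cropW = bbox[3], cropH = bbox[4])
      eventMatches[[i]] <- synthesizeMatches(scn, Hframe, bbox, pairId = i)
      Hframes[[i]] <- Hframe
    }

    ## eye-stream timestamps: 20 fps with jitter, paired at 1 fps
    dur <- max(scn$nCalibFrames, scn$nEvents)
    tIr <- seq(0, dur - 0.05, by = 0.05) + stats::runif(dur * 20, 0, 0.01)
    tRgb <- seq(0.02, dur - 0.03, by = 0.05) + stats::runif(dur * 20, 0, 0.01)

    list(observations = list(calibCorrespondences = calibCorr,
                             calibMatches = calibMatches,
                             events = do.call(rbind, evRows),
                             eventMatches = eventMatches,
                             irTimestamps = tIr, rgbTimestamps = tRgb),
         truth = list(eyeCenter = scn$eyeCenter,
                      sessionHomography = Hfull,
                      events = do.call(rbind, truthRows),
                      frameHomographies = Hframes,
                      skipped = skipped),
         scenario = scn)
  })
}

#' Pair the two eye streams by nearest timestamps
#'
#' Within every window of `period` seconds, selects the single IR/RGB frame
#' pair with the smallest absolute timestamp difference (at most one pair per
#' window; windows with an empty stream yield no pair). This reproduces the
#' 1 fps selection from two free-running 20 fps captures.
#'
#' @param tIr,tRgb sorted timestamp vectors (seconds) of the two streams.
#' @param period selection window length in seconds.
#' @return data.frame(window, irIndex, rgbIndex, tIr, tRgb, dt).
#' @export
pairNearestTimestamps <- function(tIr, tRgb, period = 1) {
  if (!length(tIr) || !length(tRgb))
    return(data.frame(window = integer(0), irIndex = integer(0),
                      rgbIndex = integer(0), tIr = numeric(0),
                      tRgb = numeric(0), dt = numeric(0)))
  wmax <- floor(max(max(tIr), max(tRgb)) / period)
  out <- vector("list", wmax + 1L)
  for (w in 0:wmax) {
    ia <- which(tIr >= w * period & tIr < (w + 1) * period)
    ib <- which(tRgb >= w * period & tRgb < (w + 1) * period)
    if (!length(ia) || !length(ib)) next
    d <- abs(outer(tIr[ia], tRgb[ib], "-"))
    k <- arrayInd(which.min(d), dim(d))
    out[[w + 1L]] <- data.frame(window = w, irIndex = ia[k[1]],
                                rgbIndex = ib[k[2]],
                                tIr = tIr[ia[k[1]]], tRgb = tRgb[ib[k[2]]],
                                dt = d[k])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(window = integer(0), irIndex = integer(0),
                      rgbIndex = integer(0), tIr = numeric(0),
                      tRgb = numeric(0), dt = numeric(0))
  res
}
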