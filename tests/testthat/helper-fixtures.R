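# Shared fixtures: tiny cameras, synthetic disk images for the detector,
# and match sets generated from a known homography.

simpleK <- function(fx = 500, fy = 500, cx = 320, cy = 240,
                    width = 640, height = 480, dist = c(0, 0)) {
  cameraIntrinsics(fx, fy, cx, cy, width, height, dist)
}

randomRotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3))) -> Q
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# bright image with a dark disk; optional iris-grey annulus and pixel noise
diskImage <- function(width = 640, height = 480, center = c(300, 200),
                      radius = 40, bg = 0.85, fg = 0.05, noiseSd = 0,
                      irisScale = 0) {
  u <- matrix(rep(0:(width - 1), each = height), height, width)
  v <- matrix(rep(0:(height - 1), times = width), height, width)
  r2 <- (u - center[1])^2 + (v - center[2])^2
  img <- matrix(bg, height, width)
  if (irisScale > 1) img[r2 <= (radius * irisScale)^2] <- 0.45
  img[r2 <= radius^2] <- fg
  if (noiseSd > 0)
    img <- pmin(pmax(img + matrix(rnorm(height * width, 0, noiseSd),
                                  height, width), 0), 1)
  img
}

# matches drawn from a known homography, with optional noise and outliers
hMatches <- function(H, n = 200, range = c(0, 300), noiseSd = 0,
                     outlierFrac = 0, pairId = 1L) {
  src <- cbind(runif(n, range[1], range[2]), runif(n, range[1], range[2]))
  dst <- applyHomography(H, src)
  inlier <- rep(TRUE, n)
  if (noiseSd > 0) dst <- dst + matrix(rnorm(2 * n, 0, noiseSd), n, 2)
  nOut <- round(outlierFrac * n)
  if (nOut > 0) {
    out <- sample.int(n, nOut)
    dst[out, ] <- cbind(runif(nOut, -500, 1500), runif(nOut, -500, 1500))
    inlier[out] <- FALSE
  }
  df <- data.frame(uCrop = src[, 1], vCrop = src[, 2],
                   uScene = dst[, 1], vScene = dst[, 2],
                   dist = runif(n), pairId = pairId)
  attr(df, "inlier") <- inlier
  df
}

# small noiseless scenario for geometry tests
tinyScenario <- function(seed, ...) {
  syntheticScenario(seed = seed, nCalibFrames = 12L, nCalibPairs = 4L,
                    nEvents = 4L, nBoundaryPoints = 16L,
                    nMatchesPerPair = 30L, ...)
}
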