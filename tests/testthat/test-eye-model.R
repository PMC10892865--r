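test_that("eyeball centre is recovered exactly from noiseless correspondences", {
  scn <- syntheticScenario(seed = 2, nCalibFrames = 25L, nBoundaryPoints = 8L,
                           nCalibPairs = 4L, nEvents = 4L)
  s <- simulateSession(scn)
  rig <- scn$rig
  model <- buildEyeModel(s$observations$calibCorrespondences,
                         rig$Kir, rig$Krgb, rig$rgbFromIr)
  expect_lt(sqrt(sum((eyeCenter(model) - s$truth$eyeCenter)^2)), 1e-3)
  expect_lt(rmsResidual(model), 1e-6)
  expect_identical(eyeRadius(model), 12.0)
  # reported residual is consistent with the points it summarizes: noiseless
  # support points all lie on the fitted sphere
  expect_gte(model@nSupportPoints, 4L)
})

test_that("too few correspondences raise an insufficient-data error", {
  scn <- tinyScenario(2)
  s <- simulateSession(scn)
  corr <- s$observations$calibCorrespondences[1:3, ]
  rig <- scn$rig
  expect_error(buildEyeModel(corr, rig$Kir, rig$Krgb, rig$rgbFromIr),
               "insufficient")
})

test_that("ray-sphere intersection returns the camera-facing root", {
  model <- new("EyeballModel", center = c(0, 0, 35), radius = 12,
               nSupportPoints = 4L, rmsResidual = 0)
  p <- raySphereIntersect(c(0, 0, 0), c(0, 0, 1), model)
  expect_equal(as.numeric(p), c(0, 0, 23))
  # tangent ray (offset exactly 12 mm): single root, on the sphere
  pt <- raySphereIntersect(c(12, 0, 0), c(0, 0, 1), model)
  expect_equal(as.numeric(pt), c(12, 0, 35), tolerance = 1e-6)
  expect_error(raySphereIntersect(c(30, 0, 0), c(0, 0, 1), model),
               class = "gazeNoIntersection")
})

test_that("ray-sphere roots agree with a bisection oracle", {
  set.seed(13)
  ctr <- c(1.5, -2, 40)
  model <- new("EyeballModel", center = ctr, radius = 12,
               nSupportPoints = 4L, rmsResidual = 0)
  hits <- 0
  for (i in 1:100) {
    d <- c(rnorm(2, 0, 0.15), 1)
    d <- d / sqrt(sum(d^2))
    f <- function(t) sum((t * d - ctr)^2) - 144
    tmid <- sum(d * ctr)           # closest approach along the ray
    if (f(tmid) > 0) next          # ray misses the sphere
    hits <- hits + 1
    p <- raySphereIntersect(c(0, 0, 0), d, model)
    expect_lt(abs(sqrt(sum((as.numeric(p) - ctr)^2)) - 12), 1e-9)
    # the near root is bracketed between the origin and closest approach
    tstar <- uniroot(f, c(0, tmid), tol = 1e-13)$root
    expect_lt(max(abs(as.numeric(p) - tstar * d)), 1e-9)
  }
  expect_gt(hits, 50)
})

test_that("IR-to-RGB mapping is the identity for a degenerate two-camera rig", {
  K <- simpleK()
  model <- new("EyeballModel", center = c(0, 0, 35), radius = 12,
               nSupportPoints = 4L, rmsResidual = 0)
  q <- cbind(runif(20, 200, 440), runif(20, 160, 320))
  out <- mapIrToRgb(q, model, K, K, rigidTransform())
  expect_lt(max(abs(out - q)), 1e-9)
})

test_that("noiseless mapping lands on the true RGB pupil centre", {
  for (seed in c(3, 4)) {
    scn <- syntheticScenario(seed = seed, nCalibFrames = 20L, nCalibPairs = 4L,
                             nEvents = 10L, nBoundaryPoints = 12L)
    s <- simulateSession(scn)
    rig <- scn$rig
    model <- buildEyeModel(s$observations$calibCorrespondences,
                           rig$Kir, rig$Krgb, rig$rgbFromIr)
    tr <- s$truth$events
    mapped <- mapIrToRgb(cbind(tr$uIrTrue, tr$vIrTrue), model,
                         rig$Kir, rig$Krgb, rig$rgbFromIr)
    err <- sqrt(rowSums((mapped - cbind(tr$uRgbTrue, tr$vRgbTrue))^2))
    expect_lt(max(err), 0.1)
  }
})

test_that("rays missing the eyeball raise a mapping-failure condition", {
  model <- new("EyeballModel", center = c(0, 0, 35), radius = 12,
               nSupportPoints = 4L, rmsResidual = 0)
  K <- simpleK()
  # a pixel far in the image corner backprojects past the sphere
  expect_error(mapIrToRgb(c(0, 0), model, K, K, rigidTransform()),
               class = "gazeNoIntersection")
})

test_that("gaze ray is the optical axis through the pupil", {
  K <- simpleK()
  model <- new("EyeballModel", center = c(0, 0, 35), radius = 12,
               nSupportPoints = 4L, rmsResidual = 0)
  # pupil at the camera-facing pole: gaze points straight at the camera
  g <- gazeRay(model, c(K@cx, K@cy), K)
  expect_equal(g$origin, c(0, 0, 35))
  expect_equal(g$direction, c(0, 0, -1), tolerance = 1e-12)
  # the ray passes through the surface point by construction
  p <- raySphereIntersect(c(0, 0, 0), c(0, 0, 1), model)
  expect_lt(max(abs(g$origin + 12 * g$direction - as.numeric(p))), 1e-6)
})

test_that("recovered gaze direction matches the synthetic truth within 0.2 deg", {
  scn <- syntheticScenario(seed = 6, nCalibFrames = 20L, nCalibPairs = 4L,
                           nEvents = 10L, nBoundaryPoints = 12L)
  s <- simulateSession(scn)
  rig <- scn$rig
  model <- buildEyeModel(s$observations$calibCorrespondences,
                         rig$Kir, rig$Krgb, rig$rgbFromIr)
  tr <- s$truth$events
  for (i in seq_len(nrow(tr))) {
    g <- gazeRay(model, c(tr$uIrTrue[i], tr$vIrTrue[i]), rig$Kir)
    ang <- acos(min(1, sum(g$direction * c(tr$gx[i], tr$gy[i], tr$gz[i]))))
    expect_lt(ang * 180 / pi, 0.2)
  }
})

test_that("centre error decreases monotonically as pixel noise decreases", {
  medianErr <- function(noise) {
    errs <- vapply(1:7, function(s) {
      scn <- syntheticScenario(seed = 300 + s, nCalibFrames = 25L,
                               nBoundaryPoints = 8L, nCalibPairs = 4L,
                               nEvents = 4L, pixelNoiseSd = noise)
      ses <- simulateSession(scn)
      rig <- scn$rig
      m <- buildEyeModel(ses$observations$calibCorrespondences,
                         rig$Kir, rig$Krgb, rig$rgbFromIr)
      sqrt(sum((eyeCenter(m) - ses$truth$eyeCenter)^2))
    }, numeric(1))
    median(errs)
  }
  errs <- vapply(c(2, 1, 0.5, 0), medianErr, numeric(1))
  expect_true(all(diff(errs) < 0))
})
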