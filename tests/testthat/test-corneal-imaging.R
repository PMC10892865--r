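test_that("horizontal flip is an involution and the gaze transform self-inverts", {
  set.seed(3)
  img <- matrix(runif(100 * 80), 80, 100)
  expect_identical(flipImage(flipImage(img)), img)
  # 100 px wide crop, pupil at crop-local u = 20 -> flipped u = 79
  crop <- extractCornealImage(img, c(0, 0, 100, 80), c(20, 30))
  expect_equal(gazePoint(crop), c(79, 30))
  # applying the same width-w flip again restores the original coordinate
  g <- gazePoint(crop)
  expect_equal(c(100 - 1 - g[1], g[2]), c(20, 30))
})

test_that("crop content equals the image restricted to the bbox, mirrored", {
  set.seed(4)
  img <- matrix(runif(60 * 90), 60, 90)
  crop <- extractCornealImage(img, c(10, 5, 40, 30), c(25, 15))
  expect_identical(cornealPixels(crop),
                   flipImage(img[6:35, 11:50]))
  expect_true(crop@flipped)
})

test_that("empty bounding boxes are rejected", {
  img <- matrix(0.5, 50, 50)
  expect_error(extractCornealImage(img, c(60, 60, 10, 10), c(0, 0)), "empty")
})

test_that("bbox transform is the identity (up to margin) for a degenerate rig", {
  K <- simpleK()
  model <- new("EyeballModel", center = c(0, 0, 35), radius = 12,
               nSupportPoints = 4L, rmsResidual = 0)
  det <- c(280, 200, 80, 60)
  out <- transformBbox(det, model, K, K, rigidTransform(), marginFrac = 0)
  expect_equal(out, det, tolerance = 1e-9)
  out2 <- transformBbox(det, model, K, K, rigidTransform(), marginFrac = 0.1)
  expect_equal(out2, c(272, 194, 96, 72), tolerance = 1e-9)
})

test_that("bbox at the image edge is clipped, not rejected", {
  # a small frame whose corner the eyeball silhouette still covers
  K <- cameraIntrinsics(500, 500, 320, 240, 400, 300)
  model <- new("EyeballModel", center = c(0, 0, 35), radius = 12,
               nSupportPoints = 4L, rmsResidual = 0)
  out <- transformBbox(c(340, 240, 55, 55), model, K, K, rigidTransform(),
                       marginFrac = 0.1)
  expect_lte(out[1] + out[3], K@width)
  expect_lte(out[2] + out[4], K@height)
  expect_lt(out[1] + out[3], 340 + 55 * 1.2)  # actually clipped
  expect_true(all(out[3:4] > 0))
})

test_that("transformed bbox contains the true RGB pupil ellipse", {
  for (seed in c(2, 5, 9)) {
    scn <- syntheticScenario(seed = seed, nCalibFrames = 20L, nCalibPairs = 4L,
                             nEvents = 8L, nBoundaryPoints = 12L)
    s <- simulateSession(scn)
    rig <- scn$rig
    model <- buildEyeModel(s$observations$calibCorrespondences,
                           rig$Kir, rig$Krgb, rig$rgbFromIr)
    tr <- s$truth$events
    for (i in seq_len(nrow(tr))) {
      ev <- CornealGaze:::eventGeometry(scn, c(tr$gx[i], tr$gy[i], tr$gz[i]))
      irBbox <- c(min(ev$irRing[, 1]), min(ev$irRing[, 2]),
                  diff(range(ev$irRing[, 1])), diff(range(ev$irRing[, 2])))
      bb <- transformBbox(irBbox, model, rig$Kir, rig$Krgb, rig$rgbFromIr)
      ring <- ev$rgbRing
      # clip the expectation to the frame, as the bbox itself is clipped
      ru <- pmin(pmax(ring[, 1], 0), rig$Krgb@width - 1)
      rv <- pmin(pmax(ring[, 2], 0), rig$Krgb@height - 1)
      expect_true(all(ru >= bb[1] - 1e-6 & ru <= bb[1] + bb[3] + 1e-6))
      expect_true(all(rv >= bb[2] - 1e-6 & rv <= bb[2] + bb[4] + 1e-6))
    }
  }
})

test_that("flipping the rendered corneal patch aligns it with the scene", {
  scn <- tinyScenario(5)
  s <- simulateSession(scn)
  id <- s$truth$events$eventId[1]
  tri <- renderTriad(s, id)
  tr <- s$truth$events[s$truth$events$eventId == id, ]
  bbox <- c(tr$cropU0, tr$cropV0, tr$cropW, tr$cropH)
  corneal <- extractCornealImage(tri$rgb, bbox, c(tr$uRgbTrue, tr$vRgbTrue))
  # scene content predicted by the true per-frame homography, crop-local
  Hi <- s$truth$frameHomographies[[id]]
  h <- nrow(cornealPixels(corneal)); w <- ncol(cornealPixels(corneal))
  uu <- rep(0:(w - 1), each = h); vv <- rep(0:(h - 1), times = w)
  sp <- applyHomography(Hi, cbind(uu, vv))
  pred <- matrix(CornealGaze:::bilinearSample(tri$scene, sp[, 1], sp[, 2],
                                              fill = 0.5), h, w)
  corFlipped <- cor(as.numeric(cornealPixels(corneal)), as.numeric(pred))
  corRaw <- cor(as.numeric(flipImage(cornealPixels(corneal))), as.numeric(pred))
  expect_gt(corFlipped, corRaw)
  expect_gt(corFlipped, 0.9)
})
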