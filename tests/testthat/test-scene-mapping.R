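test_that("applying a homography handles scaling and the division by S", {
  expect_equal(as.numeric(applyHomography(diag(3), c(50, 60))), c(50, 60))
  expect_equal(as.numeric(applyHomography(diag(c(2, 2, 1)), c(3, 4))), c(6, 8))
  expect_equal(as.numeric(applyHomography(diag(c(1, 1, 2)), c(10, 20))), c(5, 10))
  Hinf <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, -0.1, 1))
  expect_error(applyHomography(Hinf, c(0, 10)), "infinity")
})

test_that("homography composed with its inverse is the identity", {
  set.seed(12)
  H <- rbind(c(1.2, 0.1, 30), c(-0.05, 0.9, -12), c(1e-4, -2e-4, 1))
  q <- cbind(runif(200, 0, 500), runif(200, 0, 500))
  back <- applyHomography(solve(H) / solve(H)[3, 3], applyHomography(H, q))
  expect_lt(max(abs(back - q)), 1e-9)
})

test_that("pooling match sets preserves sizes and provenance", {
  set.seed(5)
  H <- diag(3)
  a <- hMatches(H, n = 30, pairId = 1L)
  b <- hMatches(H, n = 45, pairId = 2L)
  pooled <- accumulateMatches(list(a, b))
  expect_equal(nrow(pooled), 75)
  expect_equal(unname(table(pooled$pairId)), c(30L, 45L), ignore_attr = TRUE)
  expect_error(accumulateMatches(list(NULL, a[0, ])), "insufficient")
})

test_that("RANSAC recovers an exact homography from clean matches", {
  set.seed(7)
  H <- rbind(c(1.1, 0.08, 40), c(-0.03, 0.95, 25), c(2e-4, -1e-4, 1))
  m <- hMatches(H, n = 120)
  fit <- estimateHomography(m, frame = "crop", seed = 99)
  test <- cbind(runif(100, 0, 300), runif(100, 0, 300))
  err <- sqrt(rowSums((applyHomography(fit, test) - applyHomography(H, test))^2))
  expect_lt(max(err), 1e-6)
  expect_equal(nInliers(fit), 120L)
  expect_false(fit@lowConfidence)
  expect_error(estimateHomography(m[1:3, ], frame = "crop"), "insufficient")
})

test_that("RANSAC withstands 30% outliers and 1 px noise", {
  set.seed(17)
  errs <- vapply(1:8, function(s) {
    H <- rbind(c(1.05, 0.05, 20), c(-0.04, 1.1, 10), c(1e-4, 1e-4, 1))
    m <- hMatches(H, n = 200, noiseSd = 1, outlierFrac = 0.3)
    fit <- estimateHomography(m, frame = "crop", seed = 500 + s)
    held <- cbind(runif(100, 0, 300), runif(100, 0, 300))
    max(sqrt(rowSums((applyHomography(fit, held) -
                      applyHomography(H, held))^2)))
  }, numeric(1))
  expect_lt(median(errs), 2)
})

test_that("estimation is invariant to similarity re-normalization of inputs", {
  set.seed(23)
  H <- rbind(c(0.9, -0.1, 60), c(0.12, 1.05, -20), c(-1e-4, 2e-4, 1))
  m <- hMatches(H, n = 80)
  fit1 <- estimateHomography(m, frame = "crop", seed = 1)
  # similarity-transform both sides; the recovered map must conjugate exactly
  s <- 3.7; tx <- 150; ty <- -40
  m2 <- m
  m2$uCrop <- s * m$uCrop + tx;  m2$vCrop <- s * m$vCrop + ty
  m2$uScene <- s * m$uScene + tx; m2$vScene <- s * m$vScene + ty
  fit2 <- estimateHomography(m2, frame = "crop", seed = 1)
  test <- cbind(runif(50, 0, 300), runif(50, 0, 300))
  p1 <- applyHomography(fit1, test)
  p2 <- applyHomography(fit2, cbind(s * test[, 1] + tx, s * test[, 2] + ty))
  expect_lt(max(abs((p2[, 1] - tx) / s - p1[, 1])), 1e-6)
  expect_lt(max(abs((p2[, 2] - ty) / s - p1[, 2])), 1e-6)
})

test_that("inlier count is non-increasing as the threshold decreases", {
  set.seed(29)
  H <- diag(3)
  m <- hMatches(H, n = 150, noiseSd = 2)
  counts <- vapply(c(6, 3, 1.5, 0.75), function(thr) {
    nInliers(estimateHomography(m, frame = "crop", inlierThreshold = thr,
                                seed = 11))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("matching a scene against its own sub-crop is corner-consistent", {
  tex <- makeTexture(2, 400, 300)
  # crop pixels are world-oriented (as a corneal crop is after its mirror
  # flip), so the true crop-to-scene map is a pure translation
  crop <- new("CornealImage", pixels = tex[51:200, 101:300],
              bboxRgb = c(100, 50, 200, 150), gazePoint = c(100, 75),
              flipped = TRUE)
  m <- detectAndMatch(crop, tex, featureMatchConfig(scales = 1))
  expect_gte(nrow(m), 10)
  err <- sqrt(rowSums((cbind(m$uCrop + 100, m$vCrop + 50) -
                       cbind(m$uScene, m$vScene))^2))
  expect_gte(mean(err < 2), 0.9)
})

test_that("a featureless crop yields the too-few-matches state", {
  flat <- new("CornealImage", pixels = matrix(0.5, 64, 64),
              bboxRgb = c(0, 0, 64, 64), gazePoint = c(32, 32), flipped = TRUE)
  expect_warning(m <- detectAndMatch(flat, makeTexture(3, 300, 300)),
                 "too few")
  expect_equal(nrow(m), 0)
  tiny <- new("CornealImage", pixels = matrix(0.5, 16, 16),
              bboxRgb = c(0, 0, 16, 16), gazePoint = c(8, 8), flipped = TRUE)
  expect_error(detectAndMatch(tiny, makeTexture(3, 300, 300)), "32x32")
})

test_that("matches on a rendered corneal patch transfer within 3 px (median)", {
  scn <- tinyScenario(5)
  s <- simulateSession(scn)
  id <- s$truth$events$eventId[1]
  tri <- renderTriad(s, id)
  tr <- s$truth$events[s$truth$events$eventId == id, ]
  corneal <- extractCornealImage(tri$rgb, c(tr$cropU0, tr$cropV0, tr$cropW, tr$cropH),
                                 c(tr$uRgbTrue, tr$vRgbTrue))
  m <- detectAndMatch(corneal, tri$scene)
  expect_gte(nrow(m), 4)
  Hi <- s$truth$frameHomographies[[id]]
  err <- sqrt(rowSums((applyHomography(Hi, cbind(m$uCrop, m$vCrop)) -
                       cbind(m$uScene, m$vScene))^2))
  expect_lt(median(err), 3)
})

test_that("gaze transfer honours frames and flags out-of-frame points", {
  corneal <- new("CornealImage", pixels = matrix(0, 1, 1),
                 bboxRgb = c(0, 0, 120, 100), gazePoint = c(50, 60),
                 flipped = TRUE)
  idModel <- new("HomographyModel", H = diag(3), nInliers = 50L, nTotal = 50L,
                 inlierThreshold = 3, perPairInliers = c(`1` = 50L),
                 frame = "crop", lowConfidence = FALSE)
  out <- gazeToScene(corneal, idModel, sceneSize = c(640, 480))
  expect_equal(out$point, c(50, 60))
  expect_false(out$clipped)
  # a point mapping outside the scene is flagged clipped, not an error
  Hfar <- diag(3); Hfar[1, 3] <- 5000
  farModel <- new("HomographyModel", H = Hfar, nInliers = 50L, nTotal = 50L,
                  inlierThreshold = 3, perPairInliers = c(`1` = 50L),
                  frame = "crop", lowConfidence = FALSE)
  out2 <- gazeToScene(corneal, farModel, sceneSize = c(640, 480))
  expect_true(out2$clipped)
  # rgb-frame model: the gaze point is lifted through the crop geometry
  rgbModel <- new("HomographyModel", H = diag(3), nInliers = 50L, nTotal = 50L,
                  inlierThreshold = 3, perPairInliers = c(`1` = 50L),
                  frame = "rgb", lowConfidence = FALSE)
  out3 <- gazeToScene(corneal, rgbModel, sceneSize = c(640, 480))
  expect_equal(out3$point, c(120 - 1 - 50, 60))
})

test_that("per-session pooled homography transfers noiseless gaze within 5 px", {
  scn <- syntheticScenario(seed = 8, nCalibFrames = 20L, nCalibPairs = 30L,
                           nEvents = 10L, nBoundaryPoints = 12L)
  s <- simulateSession(scn)
  pooled <- estimateHomography(accumulateMatches(s$observations$calibMatches),
                               frame = "rgb", seed = 42)
  tr <- s$truth$events
  for (i in seq_len(nrow(tr))) {
    corneal <- CornealGaze:::cornealFromGeometry(
      c(tr$cropU0[i], tr$cropV0[i], tr$cropW[i], tr$cropH[i]),
      c(tr$uRgbTrue[i], tr$vRgbTrue[i]))
    out <- gazeToScene(corneal, pooled)
    expect_lt(sqrt(sum((out$point - c(tr$uSceneTrue[i], tr$vSceneTrue[i]))^2)), 5)
  }
})
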