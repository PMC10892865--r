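test_that("rig construction is deterministic and uses the headset geometry", {
  r1 <- makeRig(42)
  r2 <- makeRig(42)
  expect_identical(r1, r2)
  expect_equal(unname(imageSize(r1$Kir)), c(800, 600))
  expect_equal(unname(imageSize(r1$Krgb)), c(1280, 960))
  expect_equal(unname(imageSize(r1$Kfront)), c(1280, 960))
  baselines <- vapply(1:100, function(s) makeRig(s)$baselineMm, numeric(1))
  expect_true(all(baselines >= 5 & baselines <= 15))
})

test_that("session simulation is byte-identical under a fixed seed", {
  scn <- tinyScenario(9, pixelNoiseSd = 0.7, matchNoiseSd = 1,
                      outlierFraction = 0.1)
  s1 <- simulateSession(scn)
  s2 <- simulateSession(scn)
  expect_identical(s1, s2)
})

test_that("noiseless boundary projections are exact ellipses", {
  scn <- tinyScenario(3)
  s <- simulateSession(scn)
  tr <- s$truth$events
  for (i in seq_len(min(3, nrow(tr)))) {
    ev <- CornealGaze:::eventGeometry(scn, c(tr$gx[i], tr$gy[i], tr$gz[i]))
    for (ring in list(ev$irRing, ev$rgbRing)) {
      fit <- fitEllipseLS(ring)
      resid <- CornealGaze:::ellipseRadialResiduals(ring, fit)
      expect_lt(max(abs(resid)) * max(fit$a, fit$b), 1e-7)
    }
  }
})

test_that("injected pixel noise has the configured standard deviation", {
  scn <- syntheticScenario(seed = 10, nCalibFrames = 4L, nCalibPairs = 4L,
                           nEvents = 1000L, nBoundaryPoints = 8L,
                           nMatchesPerPair = 8L, pixelNoiseSd = 1)
  s <- simulateSession(scn)
  ev <- s$observations$events
  tr <- s$truth$events
  stopifnot(nrow(ev) == nrow(tr))
  dev <- c(ev$uIr - tr$uIrTrue, ev$vIr - tr$vIrTrue)
  expect_equal(sd(dev), 1, tolerance = 0.1)
})

test_that("timestamp pairing picks the nearest pair per one-second window", {
  # identical timestamps pair index-to-index
  t <- seq(0, 9.95, by = 0.5)
  p <- pairNearestTimestamps(t, t, period = 1)
  expect_equal(p$irIndex, p$rgbIndex)
  expect_true(all(p$dt == 0))
  expect_equal(nrow(p), 10)
  # offset streams: every selected pair is within half the stream offset
  tIr <- seq(0, 9.95, by = 0.05)
  tRgb <- seq(0.02, 9.97, by = 0.05)
  p2 <- pairNearestTimestamps(tIr, tRgb, period = 1)
  expect_equal(nrow(p2), 10)
  expect_true(all(p2$dt <= 0.025 + 1e-12))
  # brute-force oracle on jittered random streams
  set.seed(77)
  tA <- sort(runif(60, 0, 6)); tB <- sort(runif(45, 0, 6))
  got <- pairNearestTimestamps(tA, tB, period = 1)
  for (w in unique(got$window)) {
    ia <- which(tA >= w & tA < w + 1)
    ib <- which(tB >= w & tB < w + 1)
    best <- min(abs(outer(tA[ia], tB[ib], "-")))
    expect_equal(got$dt[got$window == w], best)
  }
  # an empty stream yields no pairs
  expect_equal(nrow(pairNearestTimestamps(numeric(0), tB)), 0)
})

test_that("rendered triads have the rig's image sizes", {
  scn <- tinyScenario(5)
  s <- simulateSession(scn)
  tri <- renderTriad(s, s$truth$events$eventId[1])
  expect_equal(dim(tri$ir), c(600, 800))
  expect_equal(dim(tri$rgb), c(960, 1280))
  expect_equal(dim(tri$scene), c(960, 1280))
  expect_error(renderTriad(s, s$truth$events$eventId[1],
                           texture = matrix(0.5, 100, 100)), "256x256")
})

test_that("undegraded corneal patch equals the warped scene bit-for-bit", {
  scn <- tinyScenario(6, cornealBlurSigma = 0, cornealDownsample = 1)
  s <- simulateSession(scn)
  id <- s$truth$events$eventId[1]
  tri <- renderTriad(s, id)
  tr <- s$truth$events[s$truth$events$eventId == id, ]
  us <- tr$cropU0:(tr$cropU0 + tr$cropW - 1)
  vs <- tr$cropV0:(tr$cropV0 + tr$cropH - 1)
  uu <- rep(us, each = length(vs)); vv <- rep(vs, times = length(us))
  sp <- applyHomography(s$truth$sessionHomography, cbind(uu, vv))
  expected <- matrix(CornealGaze:::bilinearSample(tri$scene, sp[, 1], sp[, 2],
                                                  fill = 0.5),
                     length(vs), length(us))
  expect_identical(tri$rgb[vs + 1, us + 1], expected)
})

test_that("the noiseless pipeline closes end-to-end below 0.05 degrees", {
  scn <- syntheticScenario(seed = 7, nCalibFrames = 60L, nCalibPairs = 25L,
                           nEvents = 20L)
  s <- simulateSession(scn)
  models <- runAutocalibrate(s)
  rec <- runTrack(s, models, mode = "pooled")
  expect_true(all(rec$valid))
  err <- angularError(cbind(rec$u_est, rec$v_est),
                      cbind(rec$u_true, rec$v_true), scn$rig$Kfront)
  expect_lt(max(err), 0.05)
})
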