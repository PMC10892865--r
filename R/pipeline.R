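## Pipeline drivers and serialization: auto-calibration (eyeball model +
## pooled homography), batch gaze tracking over a session, and JSON/CSV
## readers and writers for camera parameters, fitted models and sessions.
## Offline batch design: directories of observations rather than live
## capture; the algorithmic path is identical.

#' Auto-calibrate from a session
#'
#' Runs the two calibration stages on a session's observations: the eyeball
#' sphere fit on the pooled pupil-boundary correspondences, then RANSAC
#' homography estimation on the pooled corneal/scene feature matches (in the
#' stationary eye-image frame).
#'
#' @param session a session list as produced by [simulateSession()] or
#'   [readSession()].
#' @param minFrames minimum number of paired eye frames required.
#' @param minPairs minimum number of corneal/scene pairs with matches.
#' @param gapMax triangulation gap threshold passed to [buildEyeModel()], mm.
#' @param inlierThreshold RANSAC threshold, pixels.
#' @param seed RANSAC sampling seed; defaults to the scenario seed + 2000.
#' @return list(eye = [EyeballModel-class], homography =
#'   [HomographyModel-class]).
#' @export
runAutocalibrate <- function(session, minFrames = 50L, minPairs = 20L,
                             gapMax = 2, inlierThreshold = 3, seed = NULL) {
  corr <- session$observations$calibCorrespondences
  nFrames <- length(unique(corr$frameId))
  if (nFrames < minFrames)
    stop(sprintf("runAutocalibrate: %d paired eye frames < min_frames = %d",
                 nFrames, minFrames))
  matchSets <- Filter(function(m) !is.null(m) && nrow(m) > 0,
                      session$observations$calibMatches)
  if (length(matchSets) < minPairs)
    stop(sprintf("runAutocalibrate: %d corneal/scene pairs < min_pairs = %d",
                 length(matchSets), minPairs))
  rig <- session$scenario$rig
  eye <- buildEyeModel(corr, rig$Kir, rig$Krgb, rig$rgbFromIr, gapMax = gapMax)
  if (is.null(seed)) seed <- session$scenario$seed + 2000L
  hom <- estimateHomography(accumulateMatches(matchSets), frame = "rgb",
                            inlierThreshold = inlierThreshold, seed = seed)
  list(eye = eye, homography = hom)
}

# CornealImage carrying geometry only (image-free tracking path); replicates
# the integer flooring of extractCornealImage so both paths agree exactly.
cornealFromGeometry <- function(bboxRgb, pupilCenterRgb) {
  u0 <- floor(bboxRgb[1]); v0 <- floor(bboxRgb[2])
  cw <- floor(bboxRgb[3]); ch <- floor(bboxRgb[4])
  if (cw < 1 || ch < 1) stop("cornealFromGeometry: empty bounding box")
  local <- c(pupilCenterRgb[1] - u0, pupilCenterRgb[2] - v0)
  gp <- c(clamp(cw - 1 - local[1], -0.5, cw - 0.5),
          clamp(local[2], -0.5, ch - 0.5))
  new("CornealImage", pixels = matrix(0, 1, 1),
      bboxRgb = c(u0, v0, cw, ch), gazePoint = gp, flipped = TRUE)
}

#' Track gaze over a session's evaluation events
#'
#' For every event: map the (noisy) IR pupil detection into the RGB eye image
#' through the eyeball model, transform its bounding box, form the corneal
#' crop geometry, and transfer the gaze point into the scene image with the
#' homography (pooled session model, or re-estimated per frame from that
#' event's matches). Failures mark the record invalid and the run continues.
#'
#' @param session session list with observations and ground truth.
#' @param models list(eye, homography) from [runAutocalibrate()].
#' @param mode "pooled" uses the session homography; "per_frame" estimates a
#'   crop-local homography from each event's own matches.
#' @param participant,sessionLabel identifiers copied into the records.
#' @return data.frame of gaze records (participant, session, triad, u_est,
#'   v_est, u_true, v_true, valid) with a "log" attribute listing skipped
#'   frames as machine-parsable reason codes.
#' @export
runTrack <- function(session, models, mode = c("pooled", "per_frame"),
                     participant = 1L, sessionLabel = "synthetic") {
  mode <- match.arg(mode)
  scn <- session$scenario
  rig <- scn$rig
  events <- session$observations$events
  truth <- session$truth$events
  log <- character(0)
  rows <- vector("list", nrow(events))
  for (k in seq_len(nrow(events))) {
    e <- events[k, ]
    tr <- truth[truth$eventId == e$eventId, ]
    rec <- data.frame(participant = participant, session = sessionLabel,
                      triad = e$eventId, u_est = NA_real_, v_est = NA_real_,
                      u_true = tr$uSceneTrue, v_true = tr$vSceneTrue,
                      valid = FALSE)
    est <- tryCatch({
      pRgb <- mapIrToRgb(c(e$uIr, e$vIr), models$eye, rig$Kir, rig$Krgb,
                         rig$rgbFromIr)
      bboxRgb <- transformBbox(c(e$bboxU, e$bboxV, e$bboxW, e$bboxH),
                               models$eye, rig$Kir, rig$Krgb, rig$rgbFromIr,
                               marginFrac = scn$marginFrac)
      corneal <- cornealFromGeometry(bboxRgb, pRgb)
      sceneSize <- c(rig$Kfront@width, rig$Kfront@height)
      if (mode == "pooled") {
        gazeToScene(corneal, models$homography, sceneSize = sceneSize)
      } else {
        m <- session$observations$eventMatches[[e$eventId]]
        if (is.null(m) || nrow(m) < 4L) stop("per_frame: too few matches")
        hom <- estimateHomography(m, frame = "crop",
                                  seed = scn$seed + 3000L + e$eventId)
        # the per-frame model lives in the match set's own crop frame, which
        # may differ from the detection-derived crop; move the pupil centre
        # into that frame through the shared full-RGB frame
        qc <- rgbToCrop(pRgb, c(m$cropU0[1], m$cropV0[1], m$cropW[1], m$cropH[1]))
        p <- as.numeric(applyHomography(hom, qc))
        list(point = p,
             clipped = p[1] < 0 || p[1] > sceneSize[1] - 1 ||
                       p[2] < 0 || p[2] > sceneSize[2] - 1)
      }
    }, error = function(err) err)
    if (inherits(est, "error")) {
      log <- c(log, sprintf("event_%d:%s", e$eventId,
                            gsub("[^a-zA-Z0-9_]+", "_", conditionMessage(est))))
    } else {
      rec$u_est <- est$point[1]
      rec$v_est <- est$point[2]
      rec$valid <- TRUE
    }
    rows[[k]] <- rec
  }
  out <- do.call(rbind, rows)
  attr(out, "log") <- log
  out
}

## ---- model serialization ----------------------------------------------------

#' Save / load fitted models as JSON
#'
#' The eyeball model serializes as `{center_mm, radius_mm, n_support_points,
#' rms_residual_mm}`; the homography as its 9 entries row-major plus inlier
#' diagnostics. Load is the exact inverse of save.
#'
#' @param model the model object.
#' @param path file path.
#' @return `loadEyeModel` / `loadHomographyModel` return the reconstructed
#'   object; the savers return the path invisibly.
#' @name modelIO
NULL

#' @rdname modelIO
#' @export
saveEyeModel <- function(model, path) {
  jsonlite::write_json(list(center_mm = model@center, radius_mm = model@radius,
                            n_support_points = model@nSupportPoints,
                            rms_residual_mm = model@rmsResidual),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname modelIO
#' @export
loadEyeModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("EyeballModel", center = as.numeric(x$center_mm),
      radius = as.numeric(x$radius_mm),
      nSupportPoints = as.integer(x$n_support_points),
      rmsResidual = as.numeric(x$rms_residual_mm))
}

#' @rdname modelIO
#' @export
saveHomographyModel <- function(model, path) {
  jsonlite::write_json(list(H = as.numeric(t(model@H)),
                            n_inliers = model@nInliers,
                            n_total = model@nTotal,
                            inlier_threshold_px = model@inlierThreshold,
                            per_pair_inliers = as.list(model@perPairInliers),
                            frame = model@frame,
                            low_confidence = model@lowConfidence),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname modelIO
#' @export
loadHomographyModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  per <- unlist(x$per_pair_inliers)
  new("HomographyModel", H = matrix(as.numeric(x$H), 3, 3, byrow = TRUE),
      nInliers = as.integer(x$n_inliers), nTotal = as.integer(x$n_total),
      inlierThreshold = as.numeric(x$inlier_threshold_px),
      perPairInliers = structure(as.integer(per), names = names(per)),
      frame = x$frame, lowConfidence = as.logical(x$low_confidence))
}

## ---- camera parameter files -------------------------------------------------

intrinsicsToList <- function(K) {
  list(fx = K@fx, fy = K@fy, cx = K@cx, cy = K@cy,
       width = K@width, height = K@height, dist = K@dist)
}

intrinsicsFromList <- function(x) {
  cameraIntrinsics(x$fx, x$fy, x$cx, x$cy, x$width, x$height,
                   dist = if (is.null(x$dist) || !length(x$dist)) c(0, 0)
                          else as.numeric(unlist(x$dist)))
}

rigidToList <- function(rig) {
  list(R = as.numeric(t(rig@rotation)), t = rig@translation)
}

rigidFromList <- function(x) {
  rigidTransform(matrix(as.numeric(unlist(x$R)), 3, 3, byrow = TRUE),
                 as.numeric(unlist(x$t)))
}

#' Read / write camera parameter files
#'
#' JSON or YAML (by extension) with per-camera intrinsics blocks `ir`, `rgb`,
#' `front` of the form `{fx, fy, cx, cy, width, height, dist[]}` and rigid
#' pose blocks `rgb_from_ir` (and optionally `front_from_ir`) as `{R: 9
#' numbers row-major, t: 3 numbers mm}`. These are consumed as calibration
#' inputs; the chessboard calibration that produces them is out of scope.
#'
#' @param path file path ending in .json, .yaml or .yml.
#' @param rig a rig list (as from [makeRig()]).
#' @return `readCameraConfig` returns a rig list; `writeCameraConfig` the
#'   path, invisibly.
#' @export
readCameraConfig <- function(path) {
  if (!file.exists(path)) stop("readCameraConfig: no such file: ", path)
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  rig <- list(Kir = intrinsicsFromList(x$ir),
              Krgb = intrinsicsFromList(x$rgb),
              Kfront = intrinsicsFromList(x$front),
              rgbFromIr = rigidFromList(x$rgb_from_ir))
  if (!is.null(x$front_from_ir))
    rig$frontFromIr <- rigidFromList(x$front_from_ir)
  rig
}

#' @rdname readCameraConfig
#' @export
writeCameraConfig <- function(rig, path) {
  x <- list(ir = intrinsicsToList(rig$Kir),
            rgb = intrinsicsToList(rig$Krgb),
            front = intrinsicsToList(rig$Kfront),
            rgb_from_ir = rigidToList(rig$rgbFromIr))
  if (!is.null(rig$frontFromIr))
    x$front_from_ir <- rigidToList(rig$frontFromIr)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path, precision = 15L)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## ---- session directories ----------------------------------------------------

#' Write / read a session directory
#'
#' Serializes a session as plain text: `cameras.json`,
#' `calib_correspondences.csv`, `calib_matches.csv`, `events.csv`,
#' `event_matches.csv`, `truth_events.csv`, `truth.json` (eyeball centre,
#' session homography, skip log) and `timestamps.csv`. `readSession` is the
#' inverse, reconstructing the in-memory session object.
#'
#' @param session session list from [simulateSession()].
#' @param dir directory (created if missing).
#' @return `writeSession` returns `dir` invisibly; `readSession` the session.
#' @export
writeSession <- function(session, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  scn <- session$scenario
  writeCameraConfig(scn$rig, file.path(dir, "cameras.json"))
  wcsv <- function(df, name) utils::write.csv(df, file.path(dir, name),
                                              row.names = FALSE)
  wcsv(session$observations$calibCorrespondences, "calib_correspondences.csv")
  wcsv(accumulateMatches(session$observations$calibMatches), "calib_matches.csv")
  wcsv(session$observations$events, "events.csv")
  wcsv(accumulateMatches(session$observations$eventMatches), "event_matches.csv")
  wcsv(session$truth$events, "truth_events.csv")
  nts <- max(length(session$observations$irTimestamps),
             length(session$observations$rgbTimestamps))
  pad <- function(x) c(x, rep(NA_real_, nts - length(x)))
  wcsv(data.frame(tIr = pad(session$observations$irTimestamps),
                  tRgb = pad(session$observations$rgbTimestamps)),
       "timestamps.csv")
  scnOut <- scn[setdiff(names(scn), "rig")]
  jsonlite::write_json(list(eye_center_mm = session$truth$eyeCenter,
                            session_homography = as.numeric(t(session$truth$sessionHomography)),
                            skipped = session$truth$skipped,
                            scenario = scnOut),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeSession
#' @export
readSession <- function(dir) {
  rig <- readCameraConfig(file.path(dir, "cameras.json"))
  rcsv <- function(name) utils::read.csv(file.path(dir, name))
  tj <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  scn <- tj$scenario
  scn$rig <- rig
  scn$eyeCenter <- as.numeric(unlist(scn$eyeCenter))
  scn$baseGaze <- as.numeric(unlist(scn$baseGaze))
  calibMatches <- rcsv("calib_matches.csv")
  eventMatches <- rcsv("event_matches.csv")
  ts <- rcsv("timestamps.csv")
  evm <- split(eventMatches, eventMatches$pairId)
  eventMatchList <- list()
  for (id in names(evm)) eventMatchList[[as.integer(id)]] <- evm[[id]]
  list(observations = list(
         calibCorrespondences = rcsv("calib_correspondences.csv"),
         calibMatches = unname(split(calibMatches, calibMatches$pairId)),
         events = rcsv("events.csv"),
         eventMatches = eventMatchList,
         irTimestamps = ts$tIr[!is.na(ts$tIr)],
         rgbTimestamps = ts$tRgb[!is.na(ts$tRgb)]),
       truth = list(
         eyeCenter = as.numeric(tj$eye_center_mm),
         sessionHomography = matrix(as.numeric(tj$session_homography), 3, 3,
                                    byrow = TRUE),
         events = rcsv("truth_events.csv"),
         skipped = as.character(tj$skipped)),
       scenario = scn)
}
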