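## Angular gaze-error evaluation. Errors between estimated and ground-truth
## scene-image gaze points are measured as the angle between their viewing
## rays under the front-scene camera intrinsics, then aggregated per
## participant (mean, sample SD, median) and summarized across participants.

#' Angular error between two scene gaze points
#'
#' Backprojects both pixels to unit viewing rays in the front camera frame and
#' returns the angle between them, in degrees. The dot product is clamped to
#' [-1, 1] before acos, so identical points give exactly 0. Vectorized over
#' rows.
#'
#' @param pEst,pTrue (u, v) pixels, length-2 or N x 2.
#' @param Kfront [CameraIntrinsics-class] of the front-scene camera.
#' @return numeric vector of angles in degrees.
#' @export
angularError <- function(pEst, pTrue, Kfront) {
  a <- backprojectPixels(Kfront, pEst)
  b <- backprojectPixels(Kfront, pTrue)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) != n) a <- a[rep(1L, n), , drop = FALSE]
  if (nrow(b) != n) b <- b[rep(1L, n), , drop = FALSE]
  acos(clamp(rowSums(a * b), -1, 1)) * 180 / pi
}

#' Aggregate gaze records into per-participant error summaries
#'
#' Records are grouped by participant (and session label when present); the
#' angular error of each valid record with both gaze points present is
#' computed, and per-participant mean, sample (n-1) standard deviation and
#' median are reported. The median is the outlier-robust statistic: with at
#' least 3 records it is unaffected by a single arbitrarily wild error.
#' Overall summaries are the unweighted mean of the per-participant means and
#' of the per-participant medians, each also reported rounded to 2 decimals.
#'
#' @param records data.frame with columns participant, session, triad, u_est,
#'   v_est, u_true, v_true, valid (logical); alternatively an `error` column
#'   of precomputed angular errors in degrees.
#' @param Kfront front camera intrinsics (needed unless `error` is supplied).
#' @return list with `perParticipant` (data.frame participant, session, n,
#'   mean, sd, median) and `overall` (meanOfMeans, meanOfMedians, plus both
#'   rounded to 2 decimals).
#' @export
aggregateGazeErrors <- function(records, Kfront = NULL) {
  if (!"error" %in% names(records)) {
    ok <- records$valid &
      is.finite(records$u_est) & is.finite(records$v_est) &
      is.finite(records$u_true) & is.finite(records$v_true)
    records <- records[ok, , drop = FALSE]
    if (!nrow(records)) stop("aggregateGazeErrors: no valid records")
    if (is.null(Kfront))
      stop("aggregateGazeErrors: Kfront required to compute errors")
    records$error <- angularError(cbind(records$u_est, records$v_est),
                                  cbind(records$u_true, records$v_true),
                                  Kfront)
  } else if (!nrow(records)) stop("aggregateGazeErrors: no valid records")
  if (!"session" %in% names(records)) records$session <- "all"
  key <- interaction(records$participant, records$session, drop = TRUE)
  per <- do.call(rbind, lapply(split(records, key), function(g) {
    data.frame(participant = g$participant[1], session = g$session[1],
               n = nrow(g), mean = mean(g$error),
               sd = if (nrow(g) > 1) stats::sd(g$error) else NA_real_,
               median = stats::median(g$error))
  }))
  rownames(per) <- NULL
  overall <- list(meanOfMeans = mean(per$mean),
                  meanOfMedians = mean(per$median))
  overall$meanOfMeansRounded <- round(overall$meanOfMeans, 2)
  overall$meanOfMediansRounded <- round(overall$meanOfMedians, 2)
  list(perParticipant = per, overall = overall)
}

#' Published per-participant gaze-error summaries
#'
#' Loads the reference per-participant gaze-error tables (mean, SD and median
#' angular error in degrees for 12 participants) reported for the
#' corneal-imaging eye tracker's evaluation study: an indoor session (tracking
#' screen markers) and an outdoor session (looking at objects). These are the
#' inputs to the headline accuracy figures: the indoor average is the mean of
#' the per-participant means, the outdoor average the mean of the
#' per-participant medians.
#'
#' @param session "indoors" or "outdoors".
#' @return data.frame with columns participant, mean, sd, median (degrees).
#' @export
referenceGazeTables <- function(session = c("indoors", "outdoors")) {
  session <- match.arg(session)
  path <- system.file("extdata",
                      paste0(session, "_gaze_summary.csv"),
                      package = "CornealGaze", mustWork = TRUE)
  utils::read.csv(path)
}
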