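## Corneal image acquisition: the pupil bounding box detected in the IR image
## is transformed into the RGB eye image with the 3D mapping, the patch is
## cropped, and mirrored so its content matches world orientation.

#' Transform an IR pupil bounding box into the RGB eye image
#'
#' Maps the four corners of the detection's bounding box with [mapIrToRgb()],
#' takes their axis-aligned bounding box, enlarges it by `marginFrac` on every
#' side (so features just outside the pupil boundary survive the crop) and
#' clips it to the RGB image bounds.
#'
#' @param det a [PupilDetection-class] from the IR image (or a bare bbox
#'   numeric(4)).
#' @param model,Kir,Krgb,rig as in [mapIrToRgb()].
#' @param marginFrac fractional margin added around the transformed box.
#' @return numeric(4) bbox (u_min, v_min, width, height) in RGB coordinates.
#' @section Errors: if any corner ray misses the eyeball sphere the extraction
#'   fails with a `gazeNoIntersection` error.
#' @export
transformBbox <- function(det, model, Kir, Krgb, rig, marginFrac = 0.1) {
  b <- if (is(det, "PupilDetection")) det@bbox else det
  corners <- rbind(c(b[1], b[2]),
                   c(b[1] + b[3], b[2]),
                   c(b[1], b[2] + b[4]),
                   c(b[1] + b[3], b[2] + b[4]))
  q <- mapIrToRgb(corners, model, Kir, Krgb, rig)
  u0 <- min(q[, 1]); u1 <- max(q[, 1])
  v0 <- min(q[, 2]); v1 <- max(q[, 2])
  mw <- (u1 - u0) * marginFrac
  mh <- (v1 - v0) * marginFrac
  clipBbox(c(u0 - mw, v0 - mh, (u1 - u0) + 2 * mw, (v1 - v0) + 2 * mh),
           Krgb@width, Krgb@height)
}

#' Extract the corneal image
#'
#' Crops the RGB eye image to the (integer-aligned) bounding box and flips the
#' crop horizontally: the cornea acts as a convex mirror, so a horizontal
#' mirror restores world orientation for a roughly frontal scene. The pupil
#' centre is carried into crop-local coordinates through the same crop+flip,
#' becoming the corneal gaze point.
#'
#' @param rgbImage full RGB eye image (matrix or h x w x 3 array, values in
#'   [0, 1]).
#' @param bboxRgb bbox (u_min, v_min, width, height) from [transformBbox()].
#' @param pupilCenterRgb (u, v) pupil centre in full-image coordinates.
#' @param flip direction of the mirror flip; horizontal unless a particular
#'   camera mount requires vertical.
#' @return A [CornealImage-class].
#' @export
extractCornealImage <- function(rgbImage, bboxRgb, pupilCenterRgb,
                                flip = c("horizontal", "vertical")) {
  flip <- match.arg(flip)
  h <- dim(rgbImage)[1]; w <- dim(rgbImage)[2]
  b <- clipBbox(bboxRgb, w, h)
  u0 <- floor(b[1]); v0 <- floor(b[2])
  cw <- floor(b[3]); ch <- floor(b[4])
  if (cw < 1 || ch < 1) stop("extractCornealImage: empty bounding box")
  rows <- (v0 + 1):(v0 + ch)
  cols <- (u0 + 1):(u0 + cw)
  crop <- if (length(dim(rgbImage)) == 3L) rgbImage[rows, cols, , drop = FALSE]
          else rgbImage[rows, cols, drop = FALSE]
  crop <- flipImage(crop, flip)
  local <- c(pupilCenterRgb[1] - u0, pupilCenterRgb[2] - v0)
  gp <- if (flip == "horizontal") c(cw - 1 - local[1], local[2])
        else c(local[1], ch - 1 - local[2])
  gp <- c(clamp(gp[1], -0.5, cw - 0.5), clamp(gp[2], -0.5, ch - 0.5))
  new("CornealImage", pixels = crop, bboxRgb = c(u0, v0, cw, ch),
      gazePoint = gp, flipped = TRUE)
}

#' Mirror an image
#'
#' @param img matrix or h x w x c array.
#' @param direction "horizontal" mirrors about the vertical axis.
#' @return The mirrored image (an involution: flipping twice restores the
#'   original pixel-for-pixel).
#' @export
flipImage <- function(img, direction = c("horizontal", "vertical")) {
  direction <- match.arg(direction)
  if (length(dim(img)) == 3L) {
    out <- img
    for (k in seq_len(dim(img)[3])) out[, , k] <- flipImage(img[, , k], direction)
    return(out)
  }
  if (direction == "horizontal") img[, rev(seq_len(ncol(img))), drop = FALSE]
  else img[rev(seq_len(nrow(img))), , drop = FALSE]
}

# crop-local (flipped) -> full RGB image coordinates, and back; both are the
# same affine map composed with the mirror, so one function serves both ways.
cropToRgb <- function(pts, bbox, flip = "horizontal") {
  pts <- as_points2(pts)
  if (flip == "horizontal")
    cbind(bbox[1] + (bbox[3] - 1 - pts[, 1]), bbox[2] + pts[, 2])
  else
    cbind(bbox[1] + pts[, 1], bbox[2] + (bbox[4] - 1 - pts[, 2]))
}

rgbToCrop <- function(pts, bbox, flip = "horizontal") {
  pts <- as_points2(pts)
  if (flip == "horizontal")
    cbind((bbox[3] - 1) - (pts[, 1] - bbox[1]), pts[, 2] - bbox[2])
  else
    cbind(pts[, 1] - bbox[1], (bbox[4] - 1) - (pts[, 2] - bbox[2]))
}
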