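## Local-feature detection and matching between the corneal crop and the
## front-scene image: a classical corner/patch matcher. Harris corners are
## detected on both images, described by mean/variance-normalized intensity
## patches, and matched by nearest neighbour with Lowe's ratio test. Scale
## change between the low-resolution corneal reflection and the scene is
## handled by matching against a small image pyramid of the scene and keeping
## the best-supported level.

#' Harris corner detection
#'
#' @param img grayscale matrix in [0, 1].
#' @param maxCorners cap on the number of corners returned (strongest first).
#' @param sigma Gaussian integration scale for the structure tensor, pixels.
#' @param k Harris sensitivity constant.
#' @param qualityLevel minimum response as a fraction of the strongest corner.
#' @param border margin in pixels excluded at the image border (must cover the
#'   descriptor patch).
#' @return N x 2 matrix of (u, v) corner locations (0-based, integer pixels).
#' @export
harrisCorners <- function(img, maxCorners = 400L, sigma = 1.5, k = 0.04,
                          qualityLevel = 0.01, border = 8L) {
  h <- nrow(img); w <- ncol(img)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (img[, 3:w] - img[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (img[3:h, ] - img[1:(h - 2), ]) / 2
  Ixx <- gaussianBlur(gx * gx, sigma)
  Iyy <- gaussianBlur(gy * gy, sigma)
  Ixy <- gaussianBlur(gx * gy, sigma)
  R <- Ixx * Iyy - Ixy^2 - k * (Ixx + Iyy)^2
  # 3x3 non-maximum suppression
  shift <- function(m, dr, dc) {
    out <- matrix(-Inf, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  isMax <- R >= shift(R, -1, -1) & R >= shift(R, -1, 0) & R >= shift(R, -1, 1) &
           R >= shift(R, 0, -1)  & R >  shift(R, 0, 1)  &
           R >  shift(R, 1, -1)  & R >  shift(R, 1, 0)  & R >  shift(R, 1, 1)
  thr <- qualityLevel * max(R)
  cand <- isMax & R > thr
  cand[c(seq_len(border), (h - border + 1):h), ] <- FALSE
  cand[, c(seq_len(border), (w - border + 1):w)] <- FALSE
  idx <- which(cand, arr.ind = TRUE)
  if (!nrow(idx)) return(matrix(numeric(0), 0, 2))
  resp <- R[cand]
  ord <- order(resp, decreasing = TRUE)
  idx <- idx[ord[seq_len(min(maxCorners, length(ord)))], , drop = FALSE]
  cbind(u = idx[, 2] - 1, v = idx[, 1] - 1)
}

# normalized intensity-patch descriptors at integer corner locations
patchDescriptors <- function(img, corners, radius = 5L) {
  if (!nrow(corners)) return(matrix(numeric(0), 0, (2 * radius + 1)^2))
  offs <- expand.grid(dv = -radius:radius, du = -radius:radius)
  h <- nrow(img)
  base <- (corners[, 2] + 1) + h * corners[, 1]     # linear index of centre
  D <- vapply(seq_len(nrow(offs)), function(j) {
    img[base + offs$dv[j] + h * offs$du[j]]
  }, numeric(nrow(corners)))
  if (is.null(dim(D))) D <- matrix(D, nrow = 1L)
  mu <- rowMeans(D)
  D <- D - mu
  nrm <- sqrt(rowSums(D^2))
  nrm[nrm < 1e-9] <- 1
  D / nrm
}

# nearest-neighbour matching with Lowe's ratio test; returns index pairs
matchDescriptors <- function(descA, descB, ratio = 0.75) {
  if (!nrow(descA) || nrow(descB) < 2L)
    return(data.frame(a = integer(0), b = integer(0), dist = numeric(0)))
  # squared distance via inner products (descriptors are unit-norm)
  sim <- descA %*% t(descB)
  d2 <- pmax(2 - 2 * sim, 0)
  best <- max.col(-d2)
  d1 <- d2[cbind(seq_len(nrow(d2)), best)]
  d2m <- d2
  d2m[cbind(seq_len(nrow(d2)), best)] <- Inf
  second <- d2m[cbind(seq_len(nrow(d2)), max.col(-d2m))]
  keep <- sqrt(d1) < ratio * sqrt(second)
  data.frame(a = which(keep), b = best[keep], dist = sqrt(d1[keep]))
}

# bilinear resize by a scale factor (factor < 1 shrinks)
resizeImage <- function(img, factor) {
  h <- nrow(img); w <- ncol(img)
  nh <- max(2L, round(h * factor)); nw <- max(2L, round(w * factor))
  ui <- ((seq_len(nw) - 0.5) / factor) - 0.5
  vi <- ((seq_len(nh) - 0.5) / factor) - 0.5
  uu <- rep(clamp(ui, 0, w - 1), each = nh)
  vv <- rep(clamp(vi, 0, h - 1), times = nw)
  matrix(bilinearSample(img, uu, vv), nh, nw)
}

#' Feature matching configuration
#'
#' @param ratio Lowe nearest-neighbour ratio-test threshold.
#' @param maxCorners corner cap per image.
#' @param scales scene pyramid scale factors searched for the best match
#'   support (the corneal reflection is a minified copy of the scene).
#' @param preSmooth Gaussian pre-smoothing sigma applied to both images
#'   before detection/description, making descriptors tolerant of the
#'   corneal patch's blur and resolution loss.
#' @param patchRadius descriptor patch radius in pixels (patch side is
#'   2*radius + 1).
#' @return Named list of matcher settings.
#' @export
featureMatchConfig <- function(ratio = 0.75, maxCorners = 400L,
                               scales = c(1, 1.4, 2, 2.8, 4),
                               preSmooth = 1.5, patchRadius = 7L) {
  list(ratio = ratio, maxCorners = as.integer(maxCorners), scales = scales,
       preSmooth = preSmooth, patchRadius = as.integer(patchRadius))
}

#' Detect and match features between a corneal image and the scene
#'
#' Corners are detected on the flipped corneal crop and on each level of a
#' scene pyramid; descriptors are matched with the ratio test and the pyramid
#' level with the most surviving matches wins (its scene coordinates are
#' mapped back to full scene resolution). Corneal features outside the
#' inscribed elliptical pupil-region mask of the crop are discarded before
#' matching.
#'
#' @param corneal a [CornealImage-class] (crop at least 32 x 32).
#' @param scene scene image (grayscale matrix or color array).
#' @param config see [featureMatchConfig()].
#' @param pairId identifier recorded on every match for provenance.
#' @return A match data.frame with columns uCrop, vCrop (crop-local),
#'   uScene, vScene, dist, pairId, and the crop geometry columns cropU0,
#'   cropV0, cropW, cropH needed to lift matches into full eye-image
#'   coordinates. Zero rows (with a warning) when fewer than 4 matches
#'   survive: the pair then contributes nothing.
#' @export
detectAndMatch <- function(corneal, scene, config = featureMatchConfig(),
                           pairId = 1L) {
  crop <- toGray(corneal@pixels)
  if (nrow(crop) < 32L || ncol(crop) < 32L)
    stop("detectAndMatch: corneal crop must be at least 32x32")
  scene <- toGray(scene)
  rad <- config$patchRadius
  crop <- gaussianBlur(crop, config$preSmooth)
  cc <- harrisCorners(crop, maxCorners = config$maxCorners, border = rad + 3L)
  if (nrow(cc)) {
    # pupil-region mask: inscribed ellipse of the crop
    a <- (ncol(crop) - 1) / 2; b <- (nrow(crop) - 1) / 2
    inMask <- ((cc[, 1] - a) / a)^2 + ((cc[, 2] - b) / b)^2 <= 1
    cc <- cc[inMask, , drop = FALSE]
  }
  dc <- patchDescriptors(crop, cc, radius = rad)
  best <- NULL
  for (s in config$scales) {
    sc <- if (s == 1) scene else resizeImage(scene, 1 / s)
    if (nrow(sc) < 2L * rad + 8L || ncol(sc) < 2L * rad + 8L) next
    sc <- gaussianBlur(sc, config$preSmooth)
    cs <- harrisCorners(sc, maxCorners = config$maxCorners, border = rad + 3L)
    ds <- patchDescriptors(sc, cs, radius = rad)
    m <- matchDescriptors(dc, ds, ratio = config$ratio)
    if (is.null(best) || nrow(m) > nrow(best$m)) best <- list(m = m, s = s, cs = cs)
  }
  emptyMatches <- function() {
    data.frame(uCrop = numeric(0), vCrop = numeric(0), uScene = numeric(0),
               vScene = numeric(0), dist = numeric(0), pairId = integer(0),
               cropU0 = numeric(0), cropV0 = numeric(0), cropW = numeric(0),
               cropH = numeric(0))
  }
  if (is.null(best) || nrow(best$m) < 4L) {
    warning("detectAndMatch: too few matches; pair contributes nothing")
    return(emptyMatches())
  }
  m <- best$m; s <- best$s
  sceneU <- (best$cs[m$b, 1] + 0.5) * s - 0.5
  sceneV <- (best$cs[m$b, 2] + 0.5) * s - 0.5
  bb <- corneal@bboxRgb
  data.frame(uCrop = cc[m$a, 1], vCrop = cc[m$a, 2],
             uScene = sceneU, vScene = sceneV, dist = m$dist,
             pairId = pairId, cropU0 = bb[1], cropV0 = bb[2],
             cropW = bb[3], cropH = bb[4])
}
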