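## Image rendering for the synthetic sessions: a procedural textured planar
## scene, an IR eye image (bright sclera, darker iris, dark pupil ellipse at
## the true projection), and an RGB eye image whose corneal patch is the
## scene warped through the true reflection homography, mirrored by the
## crop/flip convention, blurred and resolution-degraded. Rendering is only
## needed to exercise the image-side operators (pupil detector, feature
## matcher); the geometric simulation works without it.

#' Generate a procedural scene texture
#'
#' A planar-scene stand-in (screen / bulletin-board analog): random
#' axis-aligned rectangles of varying intensity on a mid-grey background,
#' lightly blurred, with faint pixel noise. Rich in corners, so both the
#' corner detector and the homography have something to work with.
#'
#' @param seed RNG seed.
#' @param width,height texture size in pixels (defaults: front camera size).
#' @param nRect number of rectangles.
#' @return grayscale matrix in [0, 1].
#' @export
makeTexture <- function(seed = 1L, width = 1280L, height = 960L,
                        nRect = 150L) {
  with_seed(seed, {
    img <- matrix(0.5, height, width)
    for (i in seq_len(nRect)) {
      w <- round(stats::runif(1, 20, width / 5))
      h <- round(stats::runif(1, 20, height / 5))
      u0 <- round(stats::runif(1, 1, width - w))
      v0 <- round(stats::runif(1, 1, height - h))
      img[v0:(v0 + h - 1), u0:(u0 + w - 1)] <- stats::runif(1, 0.05, 0.95)
    }
    img <- gaussianBlur(img, 0.8)
    clamp(img + matrix(stats::rnorm(height * width, 0, 0.01), height, width), 0, 1)
  })
}

# fill an ellipse (geometric parameters, optionally scaled) with a value
drawEllipse <- function(img, ell, value, scale = 1) {
  a <- ell$a * scale; b <- ell$b * scale
  ct <- cos(ell$theta); st <- sin(ell$theta)
  h <- nrow(img); w <- ncol(img)
  eu <- sqrt((a * ct)^2 + (b * st)^2)
  ev <- sqrt((a * st)^2 + (b * ct)^2)
  us <- max(0, floor(ell$center[1] - eu)):min(w - 1, ceiling(ell$center[1] + eu))
  vs <- max(0, floor(ell$center[2] - ev)):min(h - 1, ceiling(ell$center[2] + ev))
  if (!length(us) || !length(vs)) return(img)
  uu <- rep(us, each = length(vs)) - ell$center[1]
  vv <- rep(vs, times = length(us)) - ell$center[2]
  xe <- uu * ct + vv * st
  ye <- -uu * st + vv * ct
  inside <- (xe / a)^2 + (ye / b)^2 <= 1
  sub <- img[vs + 1, us + 1, drop = FALSE]
  sub[matrix(inside, length(vs), length(us))] <- value
  img[vs + 1, us + 1] <- sub
  img
}

#' Render one synthetic image triad
#'
#' Recomputes the event's exact geometry from the stored true gaze direction
#' and draws: the IR eye image (bright background, darker iris annulus, dark
#' pupil ellipse), the RGB eye image (iris disk with the corneal patch
#' composited over the true crop region), and the scene image (the texture
#' under the front camera's view). The corneal patch content at RGB pixel q
#' is the scene sampled at H_session q, then blurred and resolution-degraded
#' per the scenario.
#'
#' @param session output of [simulateSession()].
#' @param eventId id of the event to render (must not have been skipped).
#' @param texture scene texture; default [makeTexture()] under the scenario
#'   seed at the front camera size.
#' @return list(ir, rgb, scene) of grayscale matrices in [0, 1] at the rig's
#'   configured sizes.
#' @export
renderTriad <- function(session, eventId, texture = NULL) {
  scn <- session$scenario
  rig <- scn$rig
  if (is.null(texture))
    texture <- makeTexture(scn$seed, rig$Kfront@width, rig$Kfront@height)
  if (nrow(texture) < 256L || ncol(texture) < 256L)
    stop("renderTriad: texture must be at least 256x256")
  tr <- session$truth$events
  row <- tr[tr$eventId == eventId, ]
  if (!nrow(row)) stop("renderTriad: unknown or skipped eventId")
  ev <- eventGeometry(scn, c(row$gx, row$gy, row$gz))

  ## IR eye image
  ir <- matrix(0.82, rig$Kir@height, rig$Kir@width)
  pupilIr <- fitEllipseLS(ev$irRing)
  ir <- drawEllipse(ir, pupilIr, 0.45, scale = 2.2)   # iris annulus
  ir <- drawEllipse(ir, pupilIr, 0.05)                # pupil

  ## RGB eye image with corneal patch
  rgb <- matrix(0.75, rig$Krgb@height, rig$Krgb@width)
  pupilRgb <- fitEllipseLS(ev$rgbRing)
  rgb <- drawEllipse(rgb, pupilRgb, 0.4, scale = 2.5)
  bbox <- trueCropBbox(scn, ev$rgbRing)
  if (bbox[3] >= 2 && bbox[4] >= 2) {
    us <- bbox[1]:(bbox[1] + bbox[3] - 1)
    vs <- bbox[2]:(bbox[2] + bbox[4] - 1)
    uu <- rep(us, each = length(vs))
    vv <- rep(vs, times = length(us))
    sp <- homographyTransfer(session$truth$sessionHomography, cbind(uu, vv))
    patch <- matrix(bilinearSample(texture, sp[, 1], sp[, 2], fill = 0.5),
                    length(vs), length(us))
    patch <- gaussianBlur(patch, scn$cornealBlurSigma)
    patch <- degradeResolution(patch, scn$cornealDownsample)
    rgb[vs + 1, us + 1] <- patch
  }

  list(ir = ir, rgb = rgb, scene = texture)
}

#' Write a rendered triad as PNG files
#'
#' @param triad list(ir, rgb, scene) from [renderTriad()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix, e.g. the event id.
#' @return Invisibly, the three file paths.
#' @export
writeTriadPNG <- function(triad, dir, prefix = "triad") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_", c("ir", "rgb", "scene"), ".png"))
  png::writePNG(triad$ir, paths[1])
  png::writePNG(triad$rgb, paths[2])
  png::writePNG(triad$scene, paths[3])
  invisible(paths)
}
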