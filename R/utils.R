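## Internal helpers: scoped RNG, image utilities, bilinear sampling.

# Run code under a temporary RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Images are numeric matrices (grayscale) or h x w x 3 arrays in [0, 1];
# pixel (u, v) (0-based) lives at [v + 1, u + 1].
toGray <- function(img) {
  if (length(dim(img)) == 3L)
    0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  else img
}

# Otsu threshold of a value vector (maximizes between-class variance).
otsuThreshold <- function(x, nbins = 256L) {
  h <- tabulate(pmin(nbins, 1L + floor(x * (nbins - 1L) + 0.5)), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  muT <- mu[nbins]
  sigma2 <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigma2[!is.finite(sigma2)] <- 0
  (which.max(sigma2) - 0.5) / (nbins - 1L)
}

# Bilinear sampling of a grayscale matrix at 0-based (u, v); out-of-range
# samples return `fill`.
bilinearSample <- function(img, u, v, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  u0 <- floor(u); v0 <- floor(v)
  du <- u - u0; dv <- v - v0
  ok <- u0 >= 0 & v0 >= 0 & u0 <= w - 2 & v0 <= h - 2
  # clamp indices so the arithmetic stays in range, mask later
  u0c <- clamp(u0, 0, w - 2); v0c <- clamp(v0, 0, h - 2)
  i00 <- v0c + 1 + h * u0c          # column-major linear index of [v0+1, u0+1]
  i10 <- i00 + 1                    # v+1
  i01 <- i00 + h                    # u+1
  i11 <- i01 + 1
  val <- img[i00] * (1 - du) * (1 - dv) + img[i10] * (1 - du) * dv +
         img[i01] * du * (1 - dv) + img[i11] * du * dv
  val[!ok] <- fill
  val
}

# Gaussian blur via EBImage (which is x,y ordered; transpose around it).
gaussianBlur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  if (length(dim(img)) == 3L) {
    out <- img
    for (k in 1:3) out[, , k] <- gaussianBlur(img[, , k], sigma)
    return(out)
  }
  t(as.matrix(EBImage::gblur(t(img), sigma = sigma)))
}

# Nearest-area downsample by integer factor, then upsample back (models the
# resolution loss of the corneal reflection).
degradeResolution <- function(img, factor) {
  if (factor <= 1) return(img)
  h <- nrow(img); w <- ncol(img)
  vi <- (floor((seq_len(h) - 1) / factor) + 0.5) * factor - 0.5
  ui <- (floor((seq_len(w) - 1) / factor) + 0.5) * factor - 0.5
  uu <- rep(ui, each = h)
  vv <- rep(vi, times = w)
  matrix(bilinearSample(img, clamp(uu, 0, w - 1), clamp(vv, 0, h - 1)), h, w)
}

# Axis-aligned bbox intersection with image bounds; bbox = (u_min, v_min, w, h)
# covering pixels u_min .. u_min + w - 1 (exclusive upper edge at `width`).
clipBbox <- function(bbox, width, height) {
  u0 <- max(0, bbox[1]); v0 <- max(0, bbox[2])
  u1 <- min(width, bbox[1] + bbox[3])
  v1 <- min(height, bbox[2] + bbox[4])
  c(u0, v0, max(0, u1 - u0), max(0, v1 - v0))
}
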