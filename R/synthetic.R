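# Synthetic ground-truth generators. The image generator emulates the
# binary with-locust / without-locust field imagery: a textured vegetation
# background, optionally occluded by a dark elongated insect-like ellipse,
# plus additive Gaussian pixel noise. The table generator emulates the
# CNN-feature matrices fed to the selectors, with a known informative
# feature subset.

#' Generate a paired synthetic two-class image dataset
#'
#' Produces `nPerClass` "without locust" images (textured background plus
#' noise) and `nPerClass` "with locust" images. With/without images are
#' paired by index: pair i shares the same background, the with-image
#' additionally containing a dark rotated ellipse (the insect proxy) at a
#' random position and orientation. Metadata records the blob geometry.
#'
#' @param nPerClass images per class.
#' @param height,width image size in pixels (default 64, the fast test
#'   scale; 224 is supported for backbone-contract checks).
#' @param blobLength,blobWidth 2-vectors giving the sampling range of the
#'   ellipse major/minor axis lengths in pixels.
#' @param backgroundTexture `"grass_stripes"` (sinusoidal vegetation
#'   stripes) or `"speckle"` (smooth random blotches).
#' @param noiseSd standard deviation of additive Gaussian pixel noise
#'   (intensity units on the 0-255 scale).
#' @param seed integer RNG seed.
#' @return list with `samples` (list of [ImageSample-class], without-class
#'   first) and `metadata` (data.frame: id, label, pair, cx, cy, angle,
#'   semi-major `a`, semi-minor `b`, and blob bounding box).
#' @examples
#' gen <- genImages(nPerClass = 2, seed = 7)
#' length(gen$samples)
#' gen$metadata[, c("id", "label")]
#' @export
genImages <- function(nPerClass, height = 64, width = 64,
                      blobLength = c(12, 20), blobWidth = c(4, 8),
                      backgroundTexture = c("grass_stripes", "speckle"),
                      noiseSd = 8, seed = 1) {
  backgroundTexture <- match.arg(backgroundTexture)
  if (nPerClass < 1) stop("nPerClass must be >= 1")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (max(blobLength) >= min(height, width))
    stop("blob does not fit inside the frame")
  withSeed(seed, {
    samples <- vector("list", 2L * nPerClass)
    meta <- vector("list", nPerClass)
    for (i in seq_len(nPerClass)) {
      bg <- makeBackground(height, width, backgroundTexture)
      noiseless <- bg
      # without-class image
      pxw <- clip255(bg + array(rnorm(length(bg), sd = noiseSd), dim(bg)))
      samples[[i]] <- ImageSample(sprintf("without_%03d", i), pxw, 0L)
      # with-class image: same background plus the insect-proxy ellipse
      a <- runif(1, blobLength[1], blobLength[2]) / 2
      b <- runif(1, blobWidth[1], blobWidth[2]) / 2
      margin <- ceiling(a) + 1
      cx <- runif(1, margin, width - margin)
      cy <- runif(1, margin, height - margin)
      ang <- runif(1, 0, pi)
      withBlob <- drawEllipse(noiseless, cx, cy, a, b, ang)
      pxb <- clip255(withBlob +
                     array(rnorm(length(bg), sd = noiseSd), dim(bg)))
      samples[[nPerClass + i]] <-
        ImageSample(sprintf("with_%03d", i), pxb, 1L)
      meta[[i]] <- data.frame(
        id = sprintf("with_%03d", i), label = 1L, pair = i,
        cx = cx, cy = cy, angle = ang, a = a, b = b,
        bbox_x0 = max(1, floor(cx - a)), bbox_x1 = min(width, ceiling(cx + a)),
        bbox_y0 = max(1, floor(cy - a)), bbox_y1 = min(height, ceiling(cy + a)))
    }
    list(samples = samples, metadata = do.call(rbind, meta))
  })
}

clip255 <- function(x) round(pmin(pmax(x, 0), 255))

makeBackground <- function(height, width, texture) {
  px <- array(0, c(height, width, 3L))
  if (texture == "grass_stripes") {
    freq <- runif(1, 0.2, 0.6); phase <- runif(1, 0, 2 * pi)
    stripe <- 30 * sin(freq * seq_len(width) + phase)
    base <- c(70, 130, 60)  # vegetation green
    for (ch in 1:3)
      px[, , ch] <- matrix(rep(base[ch] + stripe, each = height),
                           height, width)
  } else {  # speckle: smooth blotches from coarse random grid upsampled
    coarse <- matrix(runif(64, 60, 180), 8, 8)
    img <- EBImage::resize(EBImage::Image(coarse), w = width, h = height,
                           filter = "bilinear")
    blot <- t(EBImage::imageData(img))
    base <- c(1.0, 1.1, 0.7)
    for (ch in 1:3) px[, , ch] <- pmin(blot * base[ch], 255)
  }
  px
}

# Paint a filled rotated ellipse in a dark body colour.
drawEllipse <- function(px, cx, cy, a, b, angle) {
  height <- dim(px)[1]; width <- dim(px)[2]
  xs <- matrix(rep(seq_len(width), each = height), height, width)
  ys <- matrix(rep(seq_len(height), width), height, width)
  dx <- xs - cx; dy <- ys - cy
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  body <- c(45, 35, 25)  # dark brown insect body
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[inside] <- body[ch]
    px[, , ch] <- plane
  }
  px
}

#' Generate a two-class feature table with known informative features
#'
#' Class-0 samples are standard normal in every feature; class-1 samples
#' are shifted by `effectSize` (a standardized mean difference) in the
#' `nInformative` randomly placed informative columns. Optionally the
#' non-informative columns share a latent factor giving them pairwise
#' correlation `noiseCorrelation`. Classes are exactly balanced.
#'
#' @param nSamples even total sample count.
#' @param nFeatures number of feature columns d.
#' @param nInformative number k of informative columns (1 <= k <= d).
#' @param effectSize standardized mean shift per informative feature.
#' @param noiseCorrelation pairwise correlation among noise columns.
#' @param seed integer RNG seed.
#' @return list with `features` (a [FeatureSet-class]) and `informative`
#'   (logical ground-truth mask over columns).
#' @examples
#' gen <- genFeatureTable(nSamples = 100, nFeatures = 10, nInformative = 2,
#'                        effectSize = 2, seed = 1)
#' gen$features
#' which(gen$informative)
#' @export
genFeatureTable <- function(nSamples, nFeatures, nInformative,
                            effectSize = 1, noiseCorrelation = 0, seed = 1) {
  if (nSamples %% 2L != 0L) stop("nSamples must be even (balanced classes)")
  if (nInformative < 1L || nInformative > nFeatures)
    stop("nInformative must be in [1, nFeatures]")
  if (effectSize < 0) stop("effectSize must be >= 0")
  if (noiseCorrelation < 0 || noiseCorrelation >= 1)
    stop("noiseCorrelation must be in [0, 1)")
  withSeed(seed, {
    labels <- rep(c(0L, 1L), each = nSamples %/% 2L)
    X <- matrix(rnorm(nSamples * nFeatures), nSamples, nFeatures)
    informative <- rep(FALSE, nFeatures)
    informative[sample.int(nFeatures, nInformative)] <- TRUE
    if (noiseCorrelation > 0) {
      noiseCols <- which(!informative)
      if (length(noiseCols)) {
        u <- rnorm(nSamples)
        X[, noiseCols] <- sqrt(1 - noiseCorrelation) * X[, noiseCols] +
          sqrt(noiseCorrelation) * u
      }
    }
    X[labels == 1L, informative] <- X[labels == 1L, informative] + effectSize
    list(features = FeatureSet(X, labels), informative = informative)
  })
}
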