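#' Load a labelled image dataset from a directory tree
#'
#' Reads a directory containing one subdirectory per class —
#' `with_locust` (label 1) and `without_locust` (label 0) — of PNG/JPEG
#' files, in deterministic lexicographic order by path. Files that cannot
#' be decoded are skipped with a warning.
#'
#' @param root path to the dataset directory.
#' @return list of [ImageSample-class] objects.
#' @examples
#' dir <- tempfile(); gen <- genImages(nPerClass = 2, seed = 1)
#' writeImageDataset(gen$samples, dir)
#' samples <- loadImageDataset(dir)
#' length(samples)
#' @export
loadImageDataset <- function(root) {
  if (!dir.exists(root)) stop("dataset directory does not exist: ", root)
  classes <- c(without_locust = 0L, with_locust = 1L)
  samples <- list()
  for (cls in names(classes)) {
    cdir <- file.path(root, cls)
    if (!dir.exists(cdir)) stop("missing class directory: ", cdir)
    files <- sort(list.files(cdir, pattern = "\\.(png|jpe?g)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("empty class directory: ", cdir)
    for (f in files) {
      px <- tryCatch(readImageFile(f), error = function(e) {
        warning("skipping unreadable image: ", f, call. = FALSE)
        NULL
      })
      if (is.null(px)) next
      id <- paste0(cls, "/", sub("\\.[^.]+$", "", basename(f)))
      samples[[length(samples) + 1L]] <- ImageSample(id, px, classes[[cls]])
    }
  }
  samples
}

# Read one PNG/JPEG file into an H x W x 3 array of [0, 255] values.
readImageFile <- function(path) {
  img <- EBImage::readImage(path)
  px <- EBImage::imageData(img)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  # EBImage stores [x, y, channel] in [0,1]; convert to [row, col, channel]
  round(255 * aperm(px, c(2L, 1L, 3L)))
}

#' Write ImageSamples to a class-directory tree of PNG files
#'
#' The inverse of [loadImageDataset()]: creates `with_locust/` and
#' `without_locust/` subdirectories and writes one PNG per sample.
#'
#' @param samples list of [ImageSample-class] objects.
#' @param root output directory (created if absent).
#' @return invisibly, the vector of written file paths.
#' @export
writeImageDataset <- function(samples, root) {
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(root, "with_locust"), showWarnings = FALSE)
  dir.create(file.path(root, "without_locust"), showWarnings = FALSE)
  paths <- vapply(samples, function(s) {
    cls <- if (s@label == 1L) "with_locust" else "without_locust"
    path <- file.path(root, cls, paste0(basename(s@id), ".png"))
    img <- EBImage::Image(aperm(s@pixels / 255, c(2L, 1L, 3L)),
                          colormode = "Color")
    EBImage::writeImage(img, path)
    path
  }, character(1))
  invisible(paths)
}

#' Resize an image to a backbone's input resolution
#'
#' Bilinear interpolation without aspect-ratio preservation; identifier and
#' label are preserved. Resizing to the current size is an exact identity.
#'
#' @param img an [ImageSample-class].
#' @param height,width target size in pixels.
#' @return the resized [ImageSample-class].
#' @examples
#' img <- ImageSample("ex", array(128, c(16, 16, 3)), 0L)
#' imageDim(resizeImage(img, 8, 8))
#' @export
resizeImage <- function(img, height, width) {
  if (height < 1 || width < 1) stop("target dimensions must be positive")
  d <- dim(img@pixels)
  if (d[1] == height && d[2] == width) return(img)
  x <- EBImage::Image(aperm(img@pixels / 255, c(2L, 1L, 3L)),
                      colormode = "Color")
  y <- EBImage::resize(x, w = width, h = height, filter = "bilinear")
  px <- pmin(pmax(255 * aperm(EBImage::imageData(y), c(2L, 1L, 3L)), 0), 255)
  ImageSample(img@id, px, img@label)
}

#' Mean squared error between two images
#'
#' @param a,b numeric arrays of identical shape.
#' @return non-negative mean of squared differences over all pixels and
#'   channels.
#' @examples
#' computeMSE(array(0, c(2, 2, 1)), array(2, c(2, 2, 1)))  # 4
#' @export
computeMSE <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("image shapes differ: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  mean((as.numeric(a) - as.numeric(b))^2)
}

#' Peak signal-to-noise ratio in decibels
#'
#' `PSNR = 10 * log10(maxValue^2 / MSE)`; identical images (MSE 0) return
#' the `Inf` sentinel.
#'
#' @param a,b numeric arrays of identical shape.
#' @param maxValue peak representable intensity (255 for 8-bit images).
#' @return PSNR in dB, `Inf` when the images are identical.
#' @examples
#' computePSNR(array(0, c(2, 2)), array(2, c(2, 2)), 255)
#' @export
computePSNR <- function(a, b, maxValue = 255) {
  if (maxValue <= 0) stop("maxValue must be positive")
  mse <- computeMSE(a, b)
  if (mse == 0) return(Inf)
  10 * log10(maxValue^2 / mse)
}

# 3x3 median filter with replicate border padding, applied per channel.
# Exact in integer arithmetic, so a constant image maps to itself.
medianSmooth3 <- function(px) {
  H <- dim(px)[1]; W <- dim(px)[2]; C <- dim(px)[3]
  ri <- c(1L, seq_len(H), H)   # replicate-padded row index
  ci <- c(1L, seq_len(W), W)
  out <- px
  for (ch in seq_len(C)) {
    xp <- px[ri, ci, ch]
    nbr <- matrix(0, H * W, 9L)
    k <- 1L
    for (dj in 0:2) for (di in 0:2) {
      nbr[, k] <- as.vector(xp[di + seq_len(H), dj + seq_len(W)])
      k <- k + 1L
    }
    out[, , ch] <- apply(nbr, 1L, median)
  }
  out
}

# 3x3 binomial (Gaussian-approximating) filter, kernel (1,2,1)/4 applied
# separably with replicate padding; exact on constant images.
gaussianSmooth3 <- function(px) {
  H <- dim(px)[1]; W <- dim(px)[2]; C <- dim(px)[3]
  ri <- c(1L, seq_len(H), H)
  ci <- c(1L, seq_len(W), W)
  out <- px
  for (ch in seq_len(C)) {
    xp <- px[ri, , ch]
    v <- (xp[seq_len(H), ] + 2 * xp[seq_len(H) + 1L, ] +
          xp[seq_len(H) + 2L, ]) / 4
    vp <- v[, ci]
    out[, , ch] <- (vp[, seq_len(W)] + 2 * vp[, seq_len(W) + 1L] +
                    vp[, seq_len(W) + 2L]) / 4
  }
  out
}

#' MSE/PSNR quality filtering of an image set
#'
#' For each image, the PSNR between the original and a smoothed copy of
#' itself is used as a no-reference noise proxy: heavy pixel noise is
#' removed by the smoother, giving a large MSE and a low PSNR, while clean
#' natural texture survives smoothing largely intact. Images whose PSNR
#' falls below `psnrThreshold` are dropped as too noisy.
#'
#' @param samples list of [ImageSample-class] objects.
#' @param smoother `"median3"` (3x3 median) or `"gaussian3"` (3x3 binomial).
#' @param psnrThreshold keep threshold in dB (default 20).
#' @return list with elements `kept` (the retained samples) and `report`, a
#'   data.frame with columns `image_id`, `mse`, `psnr_db`, `kept`, one row
#'   per input sample.
#' @examples
#' img <- ImageSample("flat", array(100, c(8, 8, 3)), 0L)
#' qualityFilter(list(img))$report
#' @export
qualityFilter <- function(samples, smoother = c("median3", "gaussian3"),
                          psnrThreshold = 20) {
  smoother <- match.arg(smoother)
  if (!is.finite(psnrThreshold) && psnrThreshold > 0)
    stop("psnrThreshold must not be +Inf")
  fn <- switch(smoother, median3 = medianSmooth3, gaussian3 = gaussianSmooth3)
  rows <- lapply(samples, function(s) {
    sm <- fn(s@pixels)
    mse <- computeMSE(s@pixels, sm)
    psnr <- if (mse == 0) Inf else 10 * log10(255^2 / mse)
    data.frame(image_id = s@id, mse = mse, psnr_db = psnr,
               kept = psnr >= psnrThreshold, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  list(kept = samples[report$kept], report = report)
}

#' Write a quality report to a delimited text file
#'
#' @param report data.frame as produced by [qualityFilter()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writeQualityReport <- function(report, path) {
  write.csv(report, path, row.names = FALSE)
  invisible(path)
}
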