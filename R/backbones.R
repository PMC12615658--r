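# Backbone registry: maps a name to list(spec = BackboneSpec,
# forward = function(pixels) -> numeric). Built-in backbones are created
# lazily on first request.
.backbones <- new.env(parent = emptyenv())

#' Register a feature-extraction backbone
#'
#' A backbone is a [BackboneSpec-class] plus a forward function mapping an
#' `inputHeight x inputWidth x 3` pixel array in [0, 255] to a numeric
#' feature vector. At registration the forward function is probed on a
#' mid-grey image and must return a finite vector of exactly
#' `spec@outputDim` values.
#'
#' @param spec a [BackboneSpec-class].
#' @param forward function taking a pixel array, returning a numeric vector.
#' @return invisibly, the spec.
#' @examples
#' sp <- backboneSpec("meanpool", 8, 8, 3, tapPoint = "channel means")
#' registerBackbone(sp, function(px) apply(px, 3, mean))
#' "meanpool" %in% listBackbones()
#' @export
registerBackbone <- function(spec, forward) {
  stopifnot(is(spec, "BackboneSpec"), is.function(forward))
  if (exists(spec@name, envir = .backbones, inherits = FALSE))
    stop("backbone '", spec@name, "' is already registered")
  probe <- array(127, c(spec@inputHeight, spec@inputWidth, 3L))
  out <- forward(probe)
  if (!is.numeric(out) || length(out) != spec@outputDim)
    stop("probe output length ", length(out), " does not match declared ",
         "outputDim ", spec@outputDim, " for backbone '", spec@name, "'")
  if (any(!is.finite(out)))
    stop("probe output contains non-finite values for '", spec@name, "'")
  assign(spec@name, list(spec = spec, forward = forward), envir = .backbones)
  invisible(spec)
}

#' List registered backbone names
#'
#' Built-in backbones (`tinycnn`, `vgg19`, `resnet50`, `inceptionv3`) are
#' instantiated on demand by [getBackbone()]; this lists what is currently
#' registered.
#'
#' @return character vector of names.
#' @export
listBackbones <- function() sort(ls(envir = .backbones))

#' Retrieve a backbone by name
#'
#' Built-in names are instantiated (with their fixed weights) on first use.
#'
#' @param name backbone name.
#' @return list with elements `spec` and `forward`.
#' @export
getBackbone <- function(name) {
  if (!exists(name, envir = .backbones, inherits = FALSE)) {
    maker <- switch(name,
      tinycnn = makeTinyCNN, vgg19 = makeVGG19Backbone,
      resnet50 = makeResNet50Backbone, inceptionv3 = makeInceptionV3Backbone,
      NULL)
    if (is.null(maker))
      stop("unknown backbone '", name, "'; registered: ",
           paste(listBackbones(), collapse = ", "))
    maker()
  }
  get(name, envir = .backbones, inherits = FALSE)
}

# Used by tests to restore a clean registry.
resetBackbones <- function() {
  rm(list = ls(envir = .backbones), envir = .backbones)
  invisible(NULL)
}

## ---- minimal CNN primitives (pure R, matrix-product convolutions) ----

# 3x3 same-padding convolution via im2col. x: H x W x Cin;
# W: (9*Cin) x Cout; returns H x W x Cout.
conv3x3 <- function(x, W, b) {
  H <- dim(x)[1]; Wd <- dim(x)[2]; Cin <- dim(x)[3]
  xp <- array(0, c(H + 2L, Wd + 2L, Cin))
  xp[2:(H + 1L), 2:(Wd + 1L), ] <- x
  cols <- matrix(0, H * Wd, 9L * Cin)
  k <- 1L
  for (ch in seq_len(Cin)) for (dj in 0:2) for (di in 0:2) {
    cols[, k] <- as.vector(xp[di + seq_len(H), dj + seq_len(Wd), ch])
    k <- k + 1L
  }
  out <- cols %*% W
  out <- out + rep(b, each = H * Wd)
  array(out, c(H, Wd, ncol(W)))
}

relu <- function(x) { x[x < 0] <- 0; x }

# 2x2 max pooling; odd trailing rows/columns are cropped.
maxpool2 <- function(x) {
  H <- dim(x)[1] - dim(x)[1] %% 2L
  W <- dim(x)[2] - dim(x)[2] %% 2L
  x <- x[seq_len(H), seq_len(W), , drop = FALSE]
  x1 <- pmax(x[seq(1L, H, 2L), , , drop = FALSE],
             x[seq(2L, H, 2L), , , drop = FALSE])
  pmax(x1[, seq(1L, W, 2L), , drop = FALSE],
       x1[, seq(2L, W, 2L), , drop = FALSE])
}

globalAvgPool <- function(x) apply(x, 3L, mean)

# He-scaled fixed random weights; each built-in backbone draws its weights
# from its own fixed seed so extraction is identical across sessions.
heWeights <- function(fanIn, fanOut) {
  matrix(rnorm(fanIn * fanOut, sd = sqrt(2 / fanIn)), fanIn, fanOut)
}

imagenetNormalize <- function(px) {
  x <- px / 255
  mu <- c(0.485, 0.456, 0.406); sg <- c(0.229, 0.224, 0.225)
  for (ch in 1:3) x[, , ch] <- (x[, , ch] - mu[ch]) / sg[ch]
  x
}

# Shared builder for plain conv->relu->pool stacks ending in a dense
# embedding layer.
buildConvStack <- function(channels, denseIn, denseOut, seed,
                           gapBeforeDense = FALSE) {
  withSeed(seed, {
    convs <- list()
    cin <- 3L
    for (i in seq_along(channels)) {
      convs[[i]] <- list(W = heWeights(9L * cin, channels[i]),
                         b = rnorm(channels[i], sd = 0.01))
      cin <- channels[i]
    }
    dense <- list(W = heWeights(denseIn, denseOut),
                  b = rnorm(denseOut, sd = 0.01))
    list(convs = convs, dense = dense, gap = gapBeforeDense)
  })
}

forwardConvStack <- function(net, x) {
  for (layer in net$convs) x <- maxpool2(relu(conv3x3(x, layer$W, layer$b)))
  v <- if (net$gap) globalAvgPool(x) else as.vector(x)
  relu(as.vector(v %*% net$dense$W) + net$dense$b)
}

## ---- built-in backbones ----
# The three named architectures are compact random-weight stand-alone
# feature extractors that honour the canonical input/output contracts of
# their namesakes (224x224x3 -> 4096 for the VGG19-style fully connected
# tap, 224x224x3 -> 2048 for the ResNet50-style pooled tap, 299x299x3 ->
# 2048 for the InceptionV3-style pooled tap). Channel widths are reduced
# for CPU practicality; weights are fixed random draws (untrained random
# convolutional features preserve class structure well enough to exercise
# every downstream stage deterministically).

makeTinyCNN <- function() {
  net <- buildConvStack(c(8L, 16L), denseIn = 16L, denseOut = 32L,
                        seed = 904211L, gapBeforeDense = TRUE)
  spec <- backboneSpec("tinycnn", 64, 64, 32,
    tapPoint = "global-average pool + 32-wide dense embedding",
    scaling = "[0,1]")
  registerBackbone(spec, function(px) forwardConvStack(net, px / 255))
}

makeVGG19Backbone <- function() {
  # 224 -> 112 -> 56 -> 28 -> 14 -> 7; flatten 7*7*32 = 1568 -> dense 4096
  net <- buildConvStack(c(8L, 16L, 32L, 32L, 32L), denseIn = 1568L,
                        denseOut = 4096L, seed = 190419L)
  spec <- backboneSpec("vgg19", 224, 224, 4096,
    tapPoint = "second fully connected layer (4096-wide), head removed",
    scaling = "[0,1] then ImageNet per-channel mean/sd")
  registerBackbone(spec,
    function(px) forwardConvStack(net, imagenetNormalize(px)))
}

makeResNet50Backbone <- function() {
  withSeed(500550L, {
    stem <- list(W = heWeights(27L, 32L), b = rnorm(32L, sd = 0.01))
    blocks <- lapply(1:4, function(i)
      list(W1 = heWeights(9L * 32L, 32L), b1 = rnorm(32L, sd = 0.01),
           W2 = heWeights(9L * 32L, 32L), b2 = rnorm(32L, sd = 0.01)))
    dense <- list(W = heWeights(32L, 2048L), b = rnorm(2048L, sd = 0.01))
    forward <- function(px) {
      x <- maxpool2(relu(conv3x3(imagenetNormalize(px), stem$W, stem$b)))
      for (blk in blocks) {
        # residual unit: conv-relu-conv plus identity skip, then pool
        y <- conv3x3(relu(conv3x3(x, blk$W1, blk$b1)), blk$W2, blk$b2)
        x <- maxpool2(relu(x + y))
      }
      relu(as.vector(globalAvgPool(x) %*% dense$W) + dense$b)
    }
    spec <- backboneSpec("resnet50", 224, 224, 2048,
      tapPoint = "global-average pool of final residual stage, 2048-wide embedding",
      scaling = "[0,1] then ImageNet per-channel mean/sd")
    registerBackbone(spec, forward)
  })
}

makeInceptionV3Backbone <- function() {
  withSeed(330033L, {
    stem <- list(W = heWeights(27L, 16L), b = rnorm(16L, sd = 0.01))
    # parallel 1x1 and 3x3 branches, concatenated
    b1x1 <- list(W = matrix(rnorm(16L * 16L, sd = sqrt(2 / 16)), 16L, 16L),
                 b = rnorm(16L, sd = 0.01))
    b3x3 <- list(W = heWeights(9L * 16L, 16L), b = rnorm(16L, sd = 0.01))
    dense <- list(W = heWeights(32L, 2048L), b = rnorm(2048L, sd = 0.01))
    forward <- function(px) {
      x <- maxpool2(relu(conv3x3(px / 255 * 2 - 1, stem$W, stem$b)))
      x <- maxpool2(x); x <- maxpool2(x)
      H <- dim(x)[1]; W <- dim(x)[2]
      flat <- matrix(x, H * W, dim(x)[3])
      br1 <- array(relu(flat %*% b1x1$W + rep(b1x1$b, each = H * W)),
                   c(H, W, 16L))
      br2 <- relu(conv3x3(x, b3x3$W, b3x3$b))
      x <- array(c(br1, br2), c(H, W, 32L))
      x <- maxpool2(x)
      relu(as.vector(globalAvgPool(x) %*% dense$W) + dense$b)
    }
    spec <- backboneSpec("inceptionv3", 299, 299, 2048,
      tapPoint = "pooled mixed (1x1 + 3x3) stage, 2048-wide embedding",
      scaling = "[-1,1]")
    registerBackbone(spec, forward)
  })
}

#' Extract a feature vector from one image
#'
#' Runs the named backbone's forward pass. The image must already be at the
#' backbone's input resolution (see [resizeImage()]); pixel normalization is
#' applied internally according to the backbone's declared scaling.
#'
#' @param backbone backbone name (see [getBackbone()]) or registry entry.
#' @param img an [ImageSample-class].
#' @return numeric vector of length `outputDim`.
#' @examples
#' img <- ImageSample("ex", array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3)), 0L)
#' length(extractFeatures("tinycnn", img))  # 32
#' @export
extractFeatures <- function(backbone, img) {
  entry <- if (is.character(backbone)) getBackbone(backbone) else backbone
  spec <- entry$spec
  d <- dim(img@pixels)
  if (d[1] != spec@inputHeight || d[2] != spec@inputWidth)
    stop("backbone '", spec@name, "' expects ", spec@inputHeight, "x",
         spec@inputWidth, "x3 input, got ", paste(d, collapse = "x"))
  v <- entry$forward(img@pixels)
  stopifnot(length(v) == spec@outputDim)
  v
}

#' Extract a FeatureSet from a collection of images
#'
#' Applies [extractFeatures()] to every sample; row order equals input
#' order. Images not at the backbone's input resolution are resized first.
#'
#' @param backbone backbone name or registry entry.
#' @param samples non-empty list of [ImageSample-class] objects.
#' @return a [FeatureSet-class] with feature ids `<backbone>_f0 ...`.
#' @export
extractDataset <- function(backbone, samples) {
  if (!length(samples)) stop("no samples to extract features from")
  entry <- if (is.character(backbone)) getBackbone(backbone) else backbone
  spec <- entry$spec
  vals <- t(vapply(samples, function(s) {
    d <- dim(s@pixels)
    if (d[1] != spec@inputHeight || d[2] != spec@inputWidth)
      s <- resizeImage(s, spec@inputHeight, spec@inputWidth)
    extractFeatures(entry, s)
  }, numeric(spec@outputDim)))
  FeatureSet(vals,
             labels = vapply(samples, function(s) s@label, integer(1)),
             featureIds = paste0(spec@name, "_f",
                                 seq_len(spec@outputDim) - 1L),
             sampleIds = vapply(samples, function(s) s@id, character(1)))
}
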