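# Shared fixtures, all generated in code at test time.

flatImage <- function(value = 100, h = 8, w = 8, label = 0L, id = "flat") {
  ImageSample(id, array(value, c(h, w, 3)), label)
}

noisyImage <- function(seed = 1, h = 16, w = 16, label = 0L, id = "noise") {
  px <- locustsel:::withSeed(seed,
    array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3)))
  ImageSample(id, px, label)
}

# Small feature set where feature 1 equals the +-1 class code and feature 2
# is constant: the classic separable toy for margin-weight checks.
toySeparable <- function() {
  lab <- c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L)
  X <- cbind(ifelse(lab == 1L, 1, -1), rep(2, 8))
  FeatureSet(X, lab, featureIds = c("signal", "flat"))
}

# Deterministic tiny image dataset on disk; returns the directory.
writtenImageDir <- function(nPerClass = 3, seed = 4) {
  dir <- tempfile("imgset")
  gen <- genImages(nPerClass = nPerClass, height = 24, width = 24,
                   blobLength = c(8, 12), blobWidth = c(3, 5),
                   noiseSd = 5, seed = seed)
  writeImageDataset(gen$samples, dir)
  dir
}
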