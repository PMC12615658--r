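test_that("image generation is balanced, deterministic and in-frame", {
  g1 <- genImages(nPerClass = 4, seed = 7)
  g2 <- genImages(nPerClass = 4, seed = 7)
  expect_length(g1$samples, 8)
  labs <- vapply(g1$samples, function(s) s@label, integer(1))
  expect_equal(sum(labs), 4)
  expect_identical(g1$samples[[3]]@pixels, g2$samples[[3]]@pixels)
  expect_identical(g1$metadata, g2$metadata)
  one <- genImages(nPerClass = 1, seed = 1)
  expect_length(one$samples, 2)
  expect_error(genImages(2, height = 16, width = 16,
                         blobLength = c(20, 30)), "fit")
})

test_that("with-class images differ from their paired background only at the blob", {
  g <- genImages(nPerClass = 3, noiseSd = 0, seed = 5)
  for (i in 1:3) {
    without <- g$samples[[i]]@pixels
    with <- g$samples[[3 + i]]@pixels
    diff <- abs(with - without)
    nz <- which(apply(diff, c(1, 2), max) > 0, arr.ind = TRUE)
    md <- g$metadata[i, ]
    expect_true(all(nz[, "col"] >= md$bbox_x0 & nz[, "col"] <= md$bbox_x1))
    expect_true(all(nz[, "row"] >= md$bbox_y0 & nz[, "row"] <= md$bbox_y1))
    expect_gt(nrow(nz), 0)  # the blob is actually painted
  }
})

test_that("speckle backgrounds are supported", {
  g <- genImages(nPerClass = 1, backgroundTexture = "speckle", seed = 2)
  expect_equal(imageDim(g$samples[[1]]), c(64L, 64L, 3L))
})

test_that("null-effect tables have no systematic class difference", {
  gen <- genFeatureTable(1000, 10, 3, effectSize = 0, seed = 23)
  X <- featureValues(gen$features)
  lab <- sampleLabels(gen$features)
  smd <- vapply(seq_len(ncol(X)), function(j) {
    (mean(X[lab == 1, j]) - mean(X[lab == 0, j])) / sd(X[, j])
  }, numeric(1))
  expect_true(all(abs(smd) < 0.2))
})

test_that("strong effects make the informative subset linearly separable", {
  gen <- genFeatureTable(500, 20, 5, effectSize = 3, seed = 31)
  sub <- gen$features[which(gen$informative), ]
  acc <- kfoldCV(sub, "lr", evalProtocol(seed = 31))
  expect_gte(mean(acc), 95)
})

test_that("table generation is deterministic with exact label balance", {
  g1 <- genFeatureTable(100, 8, 2, effectSize = 1, noiseCorrelation = 0.3,
                        seed = 3)
  g2 <- genFeatureTable(100, 8, 2, effectSize = 1, noiseCorrelation = 0.3,
                        seed = 3)
  expect_identical(featureValues(g1$features), featureValues(g2$features))
  expect_identical(g1$informative, g2$informative)
  expect_equal(sum(sampleLabels(g1$features)), 50)
  expect_error(genFeatureTable(99, 5, 2, seed = 1), "even")
  expect_error(genFeatureTable(100, 5, 6, seed = 1), "nInformative")
})

test_that("the true informative mask outperforms its strict subsets", {
  gen <- genFeatureTable(300, 8, 3, effectSize = 1, seed = 37)
  cfg <- abcConfig(seed = 37, parsimonyWeight = 0)
  full <- evaluateFitness(as.integer(gen$informative), gen$features, cfg)
  inf <- which(gen$informative)
  subFits <- vapply(inf, function(drop) {
    m <- gen$informative; m[drop] <- FALSE
    evaluateFitness(as.integer(m), gen$features, cfg)
  }, numeric(1))
  expect_gte(full, mean(subFits))
})
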