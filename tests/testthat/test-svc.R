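test_that("margin weights ignore constant features and find the signal", {
  fs <- toySeparable()
  w <- fitMarginWeights(fs)
  expect_gt(abs(w[["signal"]]), 0)
  expect_equal(abs(w[["flat"]]), 0)
  # pure noise yields weights smaller than the separable signal weight
  noise <- genFeatureTable(500, 2, 1, effectSize = 0, seed = 13)$features
  wn <- fitMarginWeights(noise)
  expect_lt(max(abs(wn)), abs(w[["signal"]]))
  expect_error(fitMarginWeights(FeatureSet(matrix(rnorm(8), 4, 2),
                                           c(0, 0, 0, 0))),
               "both classes")
})

test_that("duplicated feature columns receive equal weights", {
  gen <- genFeatureTable(80, 3, 1, effectSize = 2, seed = 3)
  X <- featureValues(gen$features)
  Xdup <- cbind(X, X[, 1])
  w <- fitMarginWeights(Xdup, labels = sampleLabels(gen$features))
  expect_equal(w[[1]], w[[4]], tolerance = 1e-6)
})

test_that("margin weight fitting is deterministic", {
  gen <- genFeatureTable(60, 5, 2, effectSize = 1, seed = 2)
  expect_identical(fitMarginWeights(gen$features),
                   fitMarginWeights(gen$features))
})

test_that("rankFeatures sorts by |weight| with index tie-breaks", {
  r <- rankFeatures(c(0.1, -0.9, 0.5))
  expect_identical(rankingOrder(r), c(2L, 3L, 1L))
  expect_equal(rankingScores(r), c(0.1, 0.9, 0.5))
  # ties broken by ascending index
  expect_identical(rankingOrder(rankFeatures(rep(0.3, 4))), 1:4)
  expect_identical(rankingOrder(rankFeatures(0.7)), 1L)
  expect_error(rankFeatures(numeric(0)), "empty")
  expect_error(rankFeatures(c(1, NaN)), "finite")
})

test_that("ranking order is invariant to positive rescaling", {
  w <- rnorm(20)
  expect_identical(rankingOrder(rankFeatures(w)),
                   rankingOrder(rankFeatures(17.3 * w)))
})

test_that("selectTop supports count and mean-threshold cutoffs", {
  r <- rankFeatures(c(4, 2, 0))
  expect_identical(as.logical(selectTop(r, "mean")), c(TRUE, TRUE, FALSE))
  r5 <- rankFeatures(c(5, 1, 4, 2, 3))
  expect_identical(which(as.logical(selectTop(r5, "count", k = 2))),
                   c(1L, 3L))
  expect_identical(as.logical(selectTop(r5, "count", k = 5)), rep(TRUE, 5))
  expect_error(selectTop(r5, "count", k = 0), "k must be")
  expect_error(selectTop(r5, "count", k = 6), "k must be")
})

test_that("top-k ranking recovers most informative features on average", {
  hits <- vapply(1:20, function(seed) {
    gen <- genFeatureTable(200, 25, 5, effectSize = 1.5, seed = seed)
    r <- rankFeatures(fitMarginWeights(gen$features))
    sum(rankingOrder(r)[1:5] %in% which(gen$informative))
  }, numeric(1))
  expect_gte(mean(hits) / 5, 0.8)
})

test_that("rankings serialize with per-feature rank and selection flags", {
  r <- rankFeatures(c(0.2, 0.9, 0.5), featureIds = c("a", "b", "c"))
  mask <- selectTop(r, "count", k = 2)
  path <- tempfile(fileext = ".csv")
  writeRanking(attr(mask, "ranking"), path)
  df <- read.csv(path)
  expect_identical(df$feature_id, c("a", "b", "c"))
  expect_identical(df$rank, c(3L, 1L, 2L))
  expect_identical(df$selected, c(FALSE, TRUE, TRUE))
})
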