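test_that("confusion counts match hand tallies", {
  cm <- confusionCounts(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(c(cm@TP, cm@TN, cm@FP, cm@FN), c(2L, 2L, 0L, 0L))
  cm2 <- confusionCounts(c(0, 0, 1, 1), c(1, 1, 0, 0))
  expect_equal(c(cm2@TP, cm2@TN), c(0L, 0L))
  cm3 <- confusionCounts(c(1, 0, 1, 0, 1), c(1, 1, 0, 0, 1))
  expect_equal(c(cm3@TP, cm3@FP, cm3@FN, cm3@TN), c(2L, 1L, 1L, 1L))
  expect_error(confusionCounts(c(1, 0), c(1)), "lengths differ")
  expect_error(confusionCounts(integer(0), integer(0)), "empty")
  expect_error(confusionCounts(c(1, 2), c(1, 0)), "binary")
})

test_that("metric formulas reproduce hand-computed percentages", {
  perfect <- classMetrics(new("ConfusionMatrix", TP = 5L, TN = 5L,
                              FP = 0L, FN = 0L))
  expect_equal(unname(perfect), c(100, 100, 100, 100))
  ninety <- classMetrics(new("ConfusionMatrix", TP = 45L, TN = 45L,
                             FP = 5L, FN = 5L))
  expect_equal(unname(ninety), c(90, 90, 90, 90))
  # degenerate precision/recall -> 0 with warning, accuracy unaffected
  expect_warning(
    degenerate <- classMetrics(new("ConfusionMatrix", TP = 0L, FP = 0L,
                                   FN = 10L, TN = 90L)),
    "precision")
  expect_equal(unname(degenerate), c(90, 0, 0, 0))
  expect_error(classMetrics(new("ConfusionMatrix", TP = 0L, FP = 0L,
                                FN = 0L, TN = 0L)), "empty")
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(42)
  for (i in 1:200) {
    counts <- as.integer(rmultinom(1, sample(10:500, 1), runif(4, 0.05, 1)))
    if (sum(counts) == 0) next
    cm <- new("ConfusionMatrix", TP = counts[1], FP = counts[2],
              FN = counts[3], TN = counts[4])
    m <- suppressWarnings(classMetrics(cm))
    n <- sum(counts)
    expect_equal(m[["accuracy"]], (counts[1] + counts[4]) / n * 100)
    if (m[["precision"]] + m[["recall"]] > 0)
      expect_equal(m[["f1"]],
                   2 / (1 / m[["precision"]] + 1 / m[["recall"]]),
                   tolerance = 1e-9)
    # label-swap symmetry: TP<->TN, FP<->FN leaves accuracy fixed
    sw <- new("ConfusionMatrix", TP = counts[4], FP = counts[3],
              FN = counts[2], TN = counts[1])
    expect_equal(suppressWarnings(classMetrics(sw))[["accuracy"]],
                 m[["accuracy"]])
  }
})

test_that("stratified split respects fraction, classes and determinism", {
  gen <- genFeatureTable(100, 4, 1, effectSize = 1, seed = 8)
  proto <- evalProtocol(seed = 8)
  sp <- splitDataset(gen$features, proto)
  expect_equal(ncol(sp$train), 80L)
  expect_equal(ncol(sp$test), 20L)
  expect_equal(unname(table(sampleLabels(sp$train))), c(40L, 40L),
               ignore_attr = TRUE)
  expect_equal(unname(table(sampleLabels(sp$test))), c(10L, 10L),
               ignore_attr = TRUE)
  # disjoint union
  expect_setequal(c(sampleIds(sp$train), sampleIds(sp$test)),
                  sampleIds(gen$features))
  sp2 <- splitDataset(gen$features, proto)
  expect_identical(sampleIds(sp$train), sampleIds(sp2$train))
  # half split on 10 samples
  gen10 <- genFeatureTable(10, 3, 1, seed = 1)
  sp10 <- splitDataset(gen10$features, evalProtocol(splitFraction = 0.5,
                                                    seed = 1))
  expect_equal(ncol(sp10$train), 5L)
})

test_that("the classifier zoo separates easy data and validates names", {
  gen <- genFeatureTable(200, 8, 3, effectSize = 3, seed = 12)
  sp <- splitDataset(gen$features, evalProtocol(seed = 12))
  zoo <- trainZoo(sp$train, sp$test, seed = 12)
  expect_equal(nrow(zoo), 7L)
  expect_true(all(zoo$accuracy >= 95))
  one <- trainZoo(sp$train, sp$test, "lr", seed = 12)
  expect_equal(nrow(one), 1L)
  expect_error(trainZoo(sp$train, sp$test, c("svm", "bogus")), "bogus")
  expect_error(trainZoo(sp$train, sp$test, character(0)), "no classifiers")
})

test_that("label-permuted data scores at chance", {
  gen <- genFeatureTable(500, 6, 2, effectSize = 2, seed = 19)
  X <- featureValues(gen$features)
  perm <- locustsel:::withSeed(19, sample(sampleLabels(gen$features)))
  fs <- FeatureSet(X, perm)
  sp <- splitDataset(fs, evalProtocol(seed = 19))
  zoo <- trainZoo(sp$train, sp$test, c("lr", "svm", "dt"), seed = 19)
  expect_true(all(zoo$accuracy >= 40 & zoo$accuracy <= 60))
})

test_that("k-fold CV partitions samples with one accuracy per fold", {
  gen <- genFeatureTable(100, 5, 2, effectSize = 5, seed = 6)
  proto <- evalProtocol(cvFolds = 5, seed = 6)
  acc <- kfoldCV(gen$features, "lr", proto)
  expect_length(acc, 5)
  expect_true(all(acc >= 90))  # easily separable
  expect_identical(acc, kfoldCV(gen$features, "lr", proto))
  # fold sizes differ by at most one
  folds <- locustsel:::withSeed(proto@seed,
    locustsel:::stratifiedFolds(sampleLabels(gen$features), 5))
  expect_lte(diff(range(table(folds))), 1)
  expect_error(kfoldCV(gen$features, "nope", proto), "unknown classifier")
})

test_that("technique comparison sorts by accuracy, F1, then label", {
  df <- data.frame(technique = c("a", "b", "c"),
                   accuracy = c(99.5, 98.0, 99.0),
                   precision = 0, recall = 0, f1 = c(99, 98, 99))
  expect_identical(compareTechniques(df)$technique, c("a", "c", "b"))
  tie <- data.frame(technique = c("low_f1", "high_f1"),
                    accuracy = c(99, 99), precision = 0, recall = 0,
                    f1 = c(90, 95))
  expect_identical(compareTechniques(tie)$technique,
                   c("high_f1", "low_f1"))
  single <- df[1, ]
  expect_equal(nrow(compareTechniques(single)), 1L)
  expect_error(compareTechniques(df[c(1, 1), ]), "duplicate")
})
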