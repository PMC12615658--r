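#' Confusion matrix of binary predictions
#'
#' "With locust" (1) is the positive class: TP counts pred = 1 & truth = 1,
#' FP pred = 1 & truth = 0, FN pred = 0 & truth = 1, TN pred = 0 & truth = 0.
#'
#' @param pred,truth binary vectors of equal nonzero length.
#' @return a [ConfusionMatrix-class].
#' @examples
#' confusionCounts(c(1, 0, 1, 0, 1), c(1, 1, 0, 0, 1))
#' @export
confusionCounts <- function(pred, truth) {
  if (!length(pred)) stop("empty prediction vector")
  if (length(pred) != length(truth))
    stop("pred and truth lengths differ")
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("pred and truth must be binary (0/1)")
  new("ConfusionMatrix",
      TP = as.integer(sum(pred == 1 & truth == 1)),
      FP = as.integer(sum(pred == 1 & truth == 0)),
      FN = as.integer(sum(pred == 0 & truth == 1)),
      TN = as.integer(sum(pred == 0 & truth == 0)))
}

#' Accuracy, precision, recall and F1 from a confusion matrix
#'
#' Percentages in [0, 100]:
#' `A = (TP+TN)/(TP+FP+FN+TN) * 100`, `P = TP/(TP+FP) * 100`,
#' `R = TP/(TP+FN) * 100`, and F1 the harmonic mean `2*P*R/(P+R)`.
#' A zero denominator in P or R yields 0 with a warning (and F1 = 0 when
#' P + R = 0).
#'
#' @param cm a [ConfusionMatrix-class].
#' @return named numeric vector `accuracy`, `precision`, `recall`, `f1`.
#' @examples
#' classMetrics(new("ConfusionMatrix", TP = 45L, TN = 45L, FP = 5L, FN = 5L))
#' @export
classMetrics <- function(cm) {
  total <- cm@TP + cm@FP + cm@FN + cm@TN
  if (total == 0L) stop("confusion matrix is empty")
  A <- (cm@TP + cm@TN) / total * 100
  P <- if (cm@TP + cm@FP == 0L) {
    warning("no positive predictions; precision set to 0", call. = FALSE)
    0
  } else cm@TP / (cm@TP + cm@FP) * 100
  R <- if (cm@TP + cm@FN == 0L) {
    warning("no positive truths; recall set to 0", call. = FALSE)
    0
  } else cm@TP / (cm@TP + cm@FN) * 100
  F1 <- if (P + R == 0) 0 else 2 * P * R / (P + R)
  c(accuracy = A, precision = P, recall = R, f1 = F1)
}

#' Stratified train/test split of a FeatureSet
#'
#' Splits at `splitFraction` within each class (count rounded per class),
#' deterministically under the protocol seed. Train and test are disjoint
#' and their union is the input.
#'
#' @param x a [FeatureSet-class].
#' @param proto an [EvalProtocol-class].
#' @return list with FeatureSet elements `train` and `test`.
#' @examples
#' gen <- genFeatureTable(nSamples = 100, nFeatures = 5, nInformative = 1,
#'                        effectSize = 1, seed = 3)
#' sp <- splitDataset(gen$features, evalProtocol(seed = 3))
#' ncol(sp$train); ncol(sp$test)
#' @export
splitDataset <- function(x, proto) {
  labels <- sampleLabels(x)
  if (length(unique(labels)) < 2L) stop("both classes required")
  if (min(table(labels)) < 2L) stop("each class needs at least 2 samples")
  # largest-remainder allocation: per-class training counts sum to the
  # overall target round(splitFraction * n)
  classes <- sort(unique(labels))
  nCls <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  exact <- proto@splitFraction * nCls
  nTr <- pmax(1L, pmin(nCls - 1L, floor(exact)))
  target <- floor(proto@splitFraction * length(labels) + 0.5)
  short <- target - sum(nTr)
  if (short > 0) {
    ord <- order(-(exact - floor(exact)), seq_along(classes))
    for (j in ord) {
      if (short == 0) break
      if (nTr[j] < nCls[j] - 1L) { nTr[j] <- nTr[j] + 1L; short <- short - 1L }
    }
  }
  trainIdx <- withSeed(proto@seed, {
    unlist(lapply(seq_along(classes), function(j) {
      sample(which(labels == classes[j]), nTr[j])
    }))
  })
  trainIdx <- sort(trainIdx)
  list(train = x[, trainIdx], test = x[, setdiff(seq_along(labels), trainIdx)])
}

# Classifier dispatch. Each fitter trains on (Xtr, ytr) and predicts 0/1 on
# Xte. Stochastic learners are seeded from `seed` so the zoo is
# reproducible. Hyperparameters are the documented package defaults; none
# are tuned per dataset.
.zooNames <- c("svm", "rf", "dt", "nb", "xgb", "knn", "lr")

fitPredict <- function(name, Xtr, ytr, Xte, seed = 1L) {
  yf <- factor(ytr, levels = c(0L, 1L))
  dtr <- data.frame(Xtr); dte <- data.frame(Xte)
  colnames(dte) <- colnames(dtr)
  switch(name,
    svm = {
      fit <- e1071::svm(Xtr, yf, kernel = "radial", cost = 1)
      as.integer(as.character(predict(fit, Xte)))
    },
    rf = withSeed(seed, {
      fit <- randomForest::randomForest(Xtr, yf, ntree = 200L)
      as.integer(as.character(predict(fit, Xte)))
    }),
    dt = {
      dtr$.y <- yf
      fit <- rpart::rpart(.y ~ ., data = dtr, method = "class")
      as.integer(as.character(predict(fit, dte, type = "class")))
    },
    nb = {
      fit <- e1071::naiveBayes(Xtr, yf)
      as.integer(as.character(predict(fit, Xte)))
    },
    xgb = withSeed(seed, {
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3L,
                      eta = 0.3, nthread = 1L),
        data = xgboost::xgb.DMatrix(as.matrix(Xtr), label = as.numeric(ytr)),
        nrounds = 50L)
      as.integer(predict(fit, xgboost::xgb.DMatrix(as.matrix(Xte))) > 0.5)
    }),
    knn = withSeed(seed, {
      as.integer(as.character(class::knn(Xtr, Xte, yf, k = 5L)))
    }),
    lr = {
      dtr$.y <- ytr
      fit <- suppressWarnings(glm(.y ~ ., data = dtr, family = binomial()))
      as.integer(suppressWarnings(
        predict(fit, dte, type = "response")) > 0.5)
    },
    stop("unknown classifier '", name, "'; valid: ",
         paste(.zooNames, collapse = ", ")))
}

#' Train and evaluate the classifier zoo on a hold-out split
#'
#' Fits each requested classifier on the training set and scores it on the
#' test set via [confusionCounts()] and [classMetrics()]. Valid classifier
#' names: `svm` (RBF support-vector machine), `rf` (random forest), `dt`
#' (decision tree), `nb` (naive Bayes), `xgb` (gradient-boosted trees),
#' `knn` (k-nearest neighbours, k = 5), `lr` (logistic regression).
#'
#' @param train,test [FeatureSet-class] objects sharing feature ids.
#' @param classifiers character vector of classifier names.
#' @param seed seed for the stochastic learners.
#' @return data.frame with one row per classifier and columns
#'   `classifier`, `accuracy`, `precision`, `recall`, `f1`; the list of
#'   [ConfusionMatrix-class] objects is attached as attribute
#'   `"confusions"`.
#' @export
trainZoo <- function(train, test, classifiers = .zooNames, seed = 1L) {
  if (!length(classifiers)) stop("no classifiers requested")
  classifiers <- tolower(classifiers)
  bad <- setdiff(classifiers, .zooNames)
  if (length(bad))
    stop("unknown classifier(s) ", paste(bad, collapse = ", "),
         "; valid: ", paste(.zooNames, collapse = ", "))
  if (!identical(featureIds(train), featureIds(test)))
    stop("train and test feature ids differ")
  Xtr <- featureValues(train); ytr <- sampleLabels(train)
  Xte <- featureValues(test); yte <- sampleLabels(test)
  confs <- list()
  rows <- lapply(classifiers, function(cl) {
    pred <- fitPredict(cl, Xtr, ytr, Xte, seed = seed)
    cm <- confusionCounts(pred, yte)
    confs[[cl]] <<- cm
    m <- classMetrics(cm)
    data.frame(classifier = cl, accuracy = m["accuracy"],
               precision = m["precision"], recall = m["recall"],
               f1 = m["f1"], row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "confusions") <- confs
  out
}

#' Stratified k-fold cross-validated accuracies
#'
#' Assigns stratified folds from the protocol seed and returns one held-out
#' accuracy per fold, in fold order.
#'
#' @param x a [FeatureSet-class].
#' @param classifier single classifier name (see [trainZoo()]).
#' @param proto an [EvalProtocol-class].
#' @return numeric vector of length `cvFolds`.
#' @export
kfoldCV <- function(x, classifier, proto) {
  classifier <- tolower(classifier)
  if (!classifier %in% .zooNames)
    stop("unknown classifier '", classifier, "'; valid: ",
         paste(.zooNames, collapse = ", "))
  labels <- sampleLabels(x)
  if (min(table(labels)) < proto@cvFolds)
    stop("too few samples per class for ", proto@cvFolds, "-fold CV")
  folds <- withSeed(proto@seed, stratifiedFolds(labels, proto@cvFolds))
  vals <- featureValues(x)
  vapply(seq_len(proto@cvFolds), function(f) {
    te <- folds == f
    pred <- fitPredict(classifier, vals[!te, , drop = FALSE], labels[!te],
                       vals[te, , drop = FALSE],
                       seed = deriveSeed(proto@seed, paste0("fold", f)))
    mean(pred == labels[te]) * 100
  }, numeric(1))
}

#' Rank technique results by accuracy
#'
#' Sorts a technique-comparison table by accuracy (descending), breaking
#' ties by F1 then by label. Labels must be unique.
#'
#' @param results data.frame with columns `technique`, `accuracy`,
#'   `precision`, `recall`, `f1` (additional columns are carried through).
#' @return the sorted data.frame.
#' @examples
#' df <- data.frame(technique = c("a", "b"), accuracy = c(98, 99.5),
#'                  precision = c(98, 99), recall = c(98, 99),
#'                  f1 = c(98, 99))
#' compareTechniques(df)$technique
#' @export
compareTechniques <- function(results) {
  if (!nrow(results)) stop("no results to compare")
  if (anyDuplicated(results$technique))
    stop("duplicate technique labels: ",
         paste(unique(results$technique[duplicated(results$technique)]),
               collapse = ", "))
  ord <- order(-results$accuracy, -results$f1, results$technique)
  out <- results[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
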