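#' Fit a linear soft-margin hyperplane and return per-feature weights
#'
#' Columns are standardized to zero mean / unit variance (constant columns
#' pass through as all-zero and receive weight exactly 0), then a linear
#' soft-margin support-vector classifier is fitted and its hyperplane
#' coefficient vector returned. The fit is deterministic for fixed data.
#'
#' @param x a [FeatureSet-class], or a samples x features matrix.
#' @param labels binary labels; taken from `x` when it is a FeatureSet.
#' @param cost soft-margin regularization parameter C (default 1).
#' @return numeric weight vector of length `n_features`, named by feature
#'   id when available.
#' @examples
#' gen <- genFeatureTable(nSamples = 60, nFeatures = 6, nInformative = 2,
#'                        effectSize = 2, seed = 1)
#' w <- fitMarginWeights(gen$features)
#' which(gen$informative)          # truly informative columns
#' order(-abs(w))[1:2]             # largest-magnitude weights
#' @export
fitMarginWeights <- function(x, labels = NULL, cost = 1) {
  if (is(x, "FeatureSet")) {
    labels <- sampleLabels(x)
    ids <- featureIds(x)
    x <- featureValues(x)
  } else {
    x <- as.matrix(x)
    ids <- colnames(x)
  }
  if (is.null(labels)) stop("labels are required")
  if (length(unique(labels)) < 2L)
    stop("need samples of both classes to fit a separating hyperplane")
  if (min(table(labels)) < 2L)
    stop("need at least 2 samples of each class")
  Xs <- standardizeTrainTest(x)$train
  fit <- e1071::svm(Xs, factor(labels, levels = sort(unique(labels))),
                    kernel = "linear", cost = cost, scale = FALSE)
  w <- as.numeric(drop(t(fit$coefs) %*% fit$SV))
  names(w) <- ids
  w
}

#' Rank features by absolute hyperplane coefficient
#'
#' Features are ordered by decreasing `|weight|`; ties are broken by
#' ascending feature index. The ranking is invariant to positive rescaling
#' of the weights.
#'
#' @param weights finite numeric weight vector.
#' @param featureIds optional feature names (defaults to names of
#'   `weights`, else `f0...`).
#' @return a [FeatureRanking-class] with all features initially selected.
#' @examples
#' rankingOrder(rankFeatures(c(0.1, -0.9, 0.5)))  # 2 3 1
#' @export
rankFeatures <- function(weights, featureIds = NULL) {
  if (!length(weights)) stop("empty weight vector")
  if (any(!is.finite(weights))) stop("weights must be finite")
  if (is.null(featureIds))
    featureIds <- names(weights) %||% paste0("f", seq_along(weights) - 1L)
  scores <- abs(as.numeric(weights))
  ord <- order(-scores, seq_along(scores))
  new("FeatureRanking", order = as.integer(ord), scores = scores,
      selected = rep(TRUE, length(scores)),
      featureIds = as.character(featureIds))
}

#' Select top features from a ranking
#'
#' Two cutoff modes: `"count"` keeps the best `k` features; `"mean"` keeps
#' every feature whose score is at least the mean score. At least one
#' feature is always selected.
#'
#' @param ranking a [FeatureRanking-class].
#' @param mode `"count"` or `"mean"`.
#' @param k number of features to keep (count mode).
#' @return logical mask in original feature order; also recorded in the
#'   returned ranking's `selected` slot via the attribute `"ranking"`.
#' @examples
#' r <- rankFeatures(c(4, 2, 0))
#' selectTop(r, "mean")   # scores >= 2: features 1 and 2
#' selectTop(r, "count", k = 1)
#' @export
selectTop <- function(ranking, mode = c("count", "mean"), k = NULL) {
  mode <- match.arg(mode)
  d <- length(ranking@scores)
  if (mode == "count") {
    if (is.null(k) || k < 1 || k > d)
      stop("k must be in [1, ", d, "]")
    mask <- seq_len(d) %in% ranking@order[seq_len(k)]
  } else {
    mask <- ranking@scores >= mean(ranking@scores)
    if (!any(mask)) mask[ranking@order[1L]] <- TRUE
  }
  ranking@selected <- mask
  structure(mask, ranking = ranking)
}

#' Write a feature ranking to a delimited text file
#'
#' Columns: `feature_id`, `score`, `rank`, `selected`, one row per feature
#' in original order.
#'
#' @param ranking a [FeatureRanking-class].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writeRanking <- function(ranking, path) {
  d <- length(ranking@scores)
  rank <- integer(d)
  rank[ranking@order] <- seq_len(d)
  df <- data.frame(feature_id = ranking@featureIds,
                   score = ranking@scores, rank = rank,
                   selected = ranking@selected, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
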