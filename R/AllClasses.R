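#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats predict rnorm runif rbinom sd glm binomial median quantile
#' @importFrom utils read.csv write.csv head
NULL

#' One labelled RGB image
#'
#' A single 8-bit RGB image together with its identifier and binary class
#' label. The positive class (`label = 1L`) is "with locust", the negative
#' class (`label = 0L`) is "without locust".
#'
#' @slot id character(1) identifier (typically the file path stem).
#' @slot pixels numeric H x W x 3 array with values in [0, 255].
#' @slot label integer(1), 0 or 1.
#'
#' @exportClass ImageSample
setClass("ImageSample",
  representation(id = "character", pixels = "array", label = "integer"))

setValidity("ImageSample", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "pixels must be an H x W x 3 array")
  if (anyNA(object@pixels) || min(object@pixels) < 0 || max(object@pixels) > 255)
    msg <- c(msg, "pixel values must lie in [0, 255]")
  if (length(object@label) != 1L || !object@label %in% c(0L, 1L))
    msg <- c(msg, "label must be 0 or 1")
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "id must be a non-empty string")
  if (length(msg)) msg else TRUE
})

#' Construct an ImageSample
#'
#' @param id character identifier.
#' @param pixels H x W x 3 numeric array, values in [0, 255].
#' @param label 0 (without locust) or 1 (with locust).
#' @return An [ImageSample-class] object.
#' @examples
#' img <- ImageSample("ex", array(128, c(8, 8, 3)), 1L)
#' imageDim(img)
#' @export
ImageSample <- function(id, pixels, label) {
  new("ImageSample", id = as.character(id), pixels = pixels,
      label = as.integer(label))
}

#' Feature matrix container
#'
#' Samples-by-features data produced by backbone feature extraction (or by
#' the synthetic table generator), stored as a
#' \linkS4class{SummarizedExperiment} with features in rows and samples in
#' columns, following the Bioconductor assay convention. The binary class
#' label lives in `colData(x)$label`. Use [featureValues()] to obtain the
#' samples x features matrix that the selectors and classifiers consume.
#'
#' @seealso [FeatureSet()], [featureValues()], [sampleLabels()]
#' @exportClass FeatureSet
setClass("FeatureSet", contains = "SummarizedExperiment")

setValidity("FeatureSet", function(object) {
  msg <- character()
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  else {
    a <- SummarizedExperiment::assay(object, "features")
    if (!is.numeric(a) || any(!is.finite(a)))
      msg <- c(msg, "feature values must all be finite numbers")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!"label" %in% colnames(cd))
    msg <- c(msg, "colData must contain a 'label' column")
  else if (!all(cd$label %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureSet
#'
#' @param values numeric samples x features matrix (note: sample-major, the
#'   transpose of the internal assay layout).
#' @param labels binary vector (0/1), one entry per sample.
#' @param featureIds optional character vector of feature names; defaults to
#'   `f0 ... f(d-1)`.
#' @param sampleIds optional character vector of sample names; defaults to
#'   `s1 ... sn`.
#' @return A [FeatureSet-class].
#' @examples
#' fs <- FeatureSet(matrix(rnorm(20), 5, 4), labels = c(0, 0, 1, 1, 1))
#' featureValues(fs)[1:2, ]
#' sampleLabels(fs)
#' @export
FeatureSet <- function(values, labels, featureIds = NULL, sampleIds = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != length(labels))
    stop("number of rows of 'values' must equal length of 'labels'")
  if (is.null(featureIds))
    featureIds <- paste0("f", seq_len(ncol(values)) - 1L)
  if (is.null(sampleIds))
    sampleIds <- paste0("s", seq_len(nrow(values)))
  if (length(featureIds) != ncol(values))
    stop("length of 'featureIds' must equal number of feature columns")
  if (length(sampleIds) != nrow(values))
    stop("length of 'sampleIds' must equal number of samples")
  assay <- t(values)
  dimnames(assay) <- list(featureIds, sampleIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = assay),
    colData = S4Vectors::DataFrame(label = as.integer(labels),
                                   row.names = sampleIds))
  new("FeatureSet", se)
}

#' Artificial Bee Colony search configuration
#'
#' @slot colonySize integer, number of food sources (SN).
#' @slot limit integer abandonment threshold: a source not improved in more
#'   than `limit` attempts is replaced by a scout.
#' @slot maxIterations integer number of employed/onlooker/scout cycles.
#' @slot seed integer RNG seed; every run is reproducible from it.
#' @slot parsimonyWeight numeric >= 0; fitness is cross-validated accuracy
#'   minus `parsimonyWeight * (selected features / total features)`.
#' @slot fitnessFolds integer >= 2, folds of the internal fitness CV.
#'
#' @exportClass ABCConfig
setClass("ABCConfig",
  representation(colonySize = "integer", limit = "integer",
                 maxIterations = "integer", seed = "integer",
                 parsimonyWeight = "numeric", fitnessFolds = "integer"))

setValidity("ABCConfig", function(object) {
  msg <- character()
  if (object@colonySize < 2L) msg <- c(msg, "colonySize must be >= 2")
  if (object@limit < 1L) msg <- c(msg, "limit must be >= 1")
  if (object@maxIterations < 1L) msg <- c(msg, "maxIterations must be >= 1")
  if (object@parsimonyWeight < 0) msg <- c(msg, "parsimonyWeight must be >= 0")
  if (object@fitnessFolds < 2L) msg <- c(msg, "fitnessFolds must be >= 2")
  if (is.na(object@seed)) msg <- c(msg, "seed is required")
  if (length(msg)) msg else TRUE
})

#' Construct an ABCConfig
#'
#' Defaults are desk-scale: a colony of 10 food sources, abandonment limit
#' 5, 50 cycles, a light parsimony penalty of 0.01 and 3-fold fitness CV.
#'
#' @param colonySize number of food sources.
#' @param limit abandonment threshold.
#' @param maxIterations number of search cycles.
#' @param seed integer RNG seed (mandatory).
#' @param parsimonyWeight penalty weight on the selected-feature fraction.
#' @param fitnessFolds folds for the cross-validated fitness.
#' @return An [ABCConfig-class].
#' @examples
#' abcConfig(seed = 1)
#' @export
abcConfig <- function(colonySize = 10, limit = 5, maxIterations = 50,
                      seed, parsimonyWeight = 0.01, fitnessFolds = 3) {
  if (missing(seed)) stop("'seed' is required: ABC is a stochastic search")
  new("ABCConfig", colonySize = as.integer(colonySize),
      limit = as.integer(limit), maxIterations = as.integer(maxIterations),
      seed = as.integer(seed), parsimonyWeight = as.numeric(parsimonyWeight),
      fitnessFolds = as.integer(fitnessFolds))
}

#' Result of an Artificial Bee Colony run
#'
#' @slot bestMask integer 0/1 vector over features; the elitist best mask.
#' @slot bestFitness numeric, fitness of `bestMask`.
#' @slot history numeric, best-so-far fitness after each cycle
#'   (non-decreasing by elitism).
#' @slot nSelected integer, number of selected features in `bestMask`.
#' @slot nEvaluations integer, number of distinct masks whose fitness was
#'   computed (cache misses).
#'
#' @exportClass ABCResult
setClass("ABCResult",
  representation(bestMask = "integer", bestFitness = "numeric",
                 history = "numeric", nSelected = "integer",
                 nEvaluations = "integer"))

setValidity("ABCResult", function(object) {
  msg <- character()
  if (any(diff(object@history) < -1e-12))
    msg <- c(msg, "history must be non-decreasing")
  if (length(object@history) &&
      abs(object@bestFitness - object@history[length(object@history)]) > 1e-12)
    msg <- c(msg, "bestFitness must equal the last history entry")
  if (object@nSelected != sum(object@bestMask))
    msg <- c(msg, "nSelected must equal the popcount of bestMask")
  if (object@nSelected < 1L)
    msg <- c(msg, "bestMask must select at least one feature")
  if (length(msg)) msg else TRUE
})

#' Ranking of features by hyperplane coefficient magnitude
#'
#' @slot order integer permutation of feature indices, best first.
#' @slot scores numeric per-feature importance (absolute standardized SVC
#'   coefficient), in original feature order.
#' @slot selected logical mask in original feature order for the applied
#'   cutoff (all TRUE before [selectTop()] is applied).
#' @slot featureIds character feature names, original order.
#'
#' @exportClass FeatureRanking
setClass("FeatureRanking",
  representation(order = "integer", scores = "numeric",
                 selected = "logical", featureIds = "character"))

setValidity("FeatureRanking", function(object) {
  msg <- character()
  d <- length(object@scores)
  if (!setequal(object@order, seq_len(d)))
    msg <- c(msg, "order must be a permutation of the feature indices")
  if (any(diff(object@scores[object@order]) > 1e-12))
    msg <- c(msg, "order must sort scores non-increasingly")
  if (any(object@scores < 0)) msg <- c(msg, "scores must be non-negative")
  if (length(object@selected) != d || length(object@featureIds) != d)
    msg <- c(msg, "selected and featureIds must match the number of features")
  if (length(msg)) msg else TRUE
})

#' Binary-classification confusion matrix
#'
#' Counts of true/false positives and negatives, with "with locust" as the
#' positive class.
#'
#' @slot TP,FP,FN,TN non-negative integer counts.
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
  representation(TP = "integer", FP = "integer", FN = "integer",
                 TN = "integer"))

setValidity("ConfusionMatrix", function(object) {
  counts <- c(object@TP, object@FP, object@FN, object@TN)
  if (any(counts < 0L)) return("all counts must be non-negative")
  TRUE
})

#' Hold-out / cross-validation protocol
#'
#' @slot splitFraction numeric in (0, 1), training proportion.
#' @slot cvFolds integer >= 2.
#' @slot stratified logical, preserve class balance in split and folds.
#' @slot seed integer RNG seed.
#' @exportClass EvalProtocol
setClass("EvalProtocol",
  representation(splitFraction = "numeric", cvFolds = "integer",
                 stratified = "logical", seed = "integer"))

setValidity("EvalProtocol", function(object) {
  msg <- character()
  if (object@splitFraction <= 0 || object@splitFraction >= 1)
    msg <- c(msg, "splitFraction must be in (0, 1)")
  if (object@cvFolds < 2L) msg <- c(msg, "cvFolds must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Construct an EvalProtocol
#'
#' Defaults follow the study protocol: an 80/20 stratified hold-out split
#' and 5-fold cross-validation.
#'
#' @param splitFraction training proportion.
#' @param cvFolds number of CV folds.
#' @param stratified preserve class proportions.
#' @param seed integer RNG seed.
#' @return An [EvalProtocol-class].
#' @examples
#' evalProtocol(seed = 7)
#' @export
evalProtocol <- function(splitFraction = 0.8, cvFolds = 5, stratified = TRUE,
                         seed = 1) {
  new("EvalProtocol", splitFraction = as.numeric(splitFraction),
      cvFolds = as.integer(cvFolds), stratified = as.logical(stratified),
      seed = as.integer(seed))
}

#' Specification of a feature-extraction backbone
#'
#' @slot name backbone name, unique in the registry.
#' @slot inputHeight,inputWidth expected input size in pixels.
#' @slot outputDim length of the emitted feature vector.
#' @slot tapPoint human-readable description of the layer whose activations
#'   are emitted.
#' @slot scaling description of the pixel normalization the backbone applies.
#' @exportClass BackboneSpec
setClass("BackboneSpec",
  representation(name = "character", inputHeight = "integer",
                 inputWidth = "integer", outputDim = "integer",
                 tapPoint = "character", scaling = "character"))

setValidity("BackboneSpec", function(object) {
  msg <- character()
  if (object@outputDim < 1L) msg <- c(msg, "outputDim must be positive")
  if (object@inputHeight < 1L || object@inputWidth < 1L)
    msg <- c(msg, "input dimensions must be positive")
  if (!nzchar(object@name)) msg <- c(msg, "name must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Construct a BackboneSpec
#'
#' @param name unique backbone name.
#' @param inputHeight,inputWidth input image size.
#' @param outputDim feature-vector length.
#' @param tapPoint description of the emitted layer.
#' @param scaling description of the pixel normalization.
#' @return A [BackboneSpec-class].
#' @export
backboneSpec <- function(name, inputHeight, inputWidth, outputDim,
                         tapPoint = "", scaling = "[0,1]") {
  new("BackboneSpec", name = name, inputHeight = as.integer(inputHeight),
      inputWidth = as.integer(inputWidth), outputDim = as.integer(outputDim),
      tapPoint = tapPoint, scaling = scaling)
}
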