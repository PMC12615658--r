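#' Samples-by-features matrix of a FeatureSet
#'
#' @param x a [FeatureSet-class].
#' @return numeric matrix, samples in rows, features in columns.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname featureValues
#' @aliases featureValues,FeatureSet-method
setMethod("featureValues", "FeatureSet", function(x) {
  t(SummarizedExperiment::assay(x, "features"))
})

#' Binary class labels of a FeatureSet
#'
#' @param x a [FeatureSet-class].
#' @return integer vector of 0/1 labels, one per sample.
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname sampleLabels
#' @aliases sampleLabels,FeatureSet-method
setMethod("sampleLabels", "FeatureSet", function(x) {
  as.integer(SummarizedExperiment::colData(x)$label)
})

#' Feature identifiers of a FeatureSet
#'
#' @param x a [FeatureSet-class].
#' @return character vector of feature names.
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname featureIds
#' @aliases featureIds,FeatureSet-method
setMethod("featureIds", "FeatureSet", function(x) rownames(x))

#' Sample identifiers of a FeatureSet
#'
#' @param x a [FeatureSet-class].
#' @return character vector of sample names.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname sampleIds
#' @aliases sampleIds,FeatureSet-method
setMethod("sampleIds", "FeatureSet", function(x) colnames(x))

#' Image dimensions of an ImageSample
#'
#' @param x an [ImageSample-class].
#' @return integer vector (height, width, channels).
#' @export
setGeneric("imageDim", function(x) standardGeneric("imageDim"))

#' @rdname imageDim
#' @aliases imageDim,ImageSample-method
setMethod("imageDim", "ImageSample", function(x) dim(x@pixels))

#' Accessors for ABC results
#'
#' @param x an [ABCResult-class].
#' @return `bestMask`: integer 0/1 vector; `bestFitness`: numeric;
#'   `fitnessHistory`: numeric vector of per-cycle best-so-far fitness.
#' @name ABCResult-accessors
NULL

#' @rdname ABCResult-accessors
#' @export
setGeneric("bestMask", function(x) standardGeneric("bestMask"))
#' @rdname ABCResult-accessors
#' @aliases bestMask,ABCResult-method
setMethod("bestMask", "ABCResult", function(x) x@bestMask)

#' @rdname ABCResult-accessors
#' @export
setGeneric("bestFitness", function(x) standardGeneric("bestFitness"))
#' @rdname ABCResult-accessors
#' @aliases bestFitness,ABCResult-method
setMethod("bestFitness", "ABCResult", function(x) x@bestFitness)

#' @rdname ABCResult-accessors
#' @export
setGeneric("fitnessHistory", function(x) standardGeneric("fitnessHistory"))
#' @rdname ABCResult-accessors
#' @aliases fitnessHistory,ABCResult-method
setMethod("fitnessHistory", "ABCResult", function(x) x@history)

#' Feature order of a ranking, best first
#'
#' @param x a [FeatureRanking-class].
#' @return integer permutation of feature indices.
#' @export
setGeneric("rankingOrder", function(x) standardGeneric("rankingOrder"))

#' @rdname rankingOrder
#' @aliases rankingOrder,FeatureRanking-method
setMethod("rankingOrder", "FeatureRanking", function(x) x@order)

#' Importance scores of a ranking (original feature order)
#'
#' @param x a [FeatureRanking-class].
#' @return numeric vector of absolute coefficients.
#' @export
setGeneric("rankingScores", function(x) standardGeneric("rankingScores"))

#' @rdname rankingScores
#' @aliases rankingScores,FeatureRanking-method
setMethod("rankingScores", "FeatureRanking", function(x) x@scores)

setMethod("show", "ImageSample", function(object) {
  d <- dim(object@pixels)
  cat("ImageSample '", object@id, "': ", d[1], "x", d[2], "x", d[3],
      ", label=", object@label,
      if (object@label == 1L) " (with locust)\n" else " (without locust)\n",
      sep = "")
})

setMethod("show", "FeatureSet", function(object) {
  cat("FeatureSet: ", ncol(object), " samples x ", nrow(object),
      " features\n", sep = "")
  lab <- sampleLabels(object)
  cat("  labels: ", sum(lab == 1L), " with locust / ", sum(lab == 0L),
      " without locust\n", sep = "")
})

setMethod("show", "ABCResult", function(object) {
  cat("ABCResult: ", object@nSelected, "/", length(object@bestMask),
      " features selected, fitness ", format(object@bestFitness, digits = 6),
      "\n  ", length(object@history), " cycles, ",
      object@nEvaluations, " distinct masks evaluated\n", sep = "")
})

setMethod("show", "FeatureRanking", function(object) {
  d <- length(object@scores)
  topn <- min(5L, d)
  cat("FeatureRanking over ", d, " features (", sum(object@selected),
      " selected)\n  top: ",
      paste(object@featureIds[object@order[seq_len(topn)]], collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix  TP=", object@TP, " FP=", object@FP,
      " FN=", object@FN, " TN=", object@TN, "\n", sep = "")
})

setMethod("show", "ABCConfig", function(object) {
  cat("ABCConfig: colony ", object@colonySize, ", limit ", object@limit,
      ", ", object@maxIterations, " cycles, lambda ",
      object@parsimonyWeight, ", ", object@fitnessFolds,
      "-fold fitness CV, seed ", object@seed, "\n", sep = "")
})

setMethod("show", "EvalProtocol", function(object) {
  cat("EvalProtocol: ", round(100 * object@splitFraction), "/",
      round(100 * (1 - object@splitFraction)),
      if (object@stratified) " stratified" else "", " split, ",
      object@cvFolds, "-fold CV, seed ", object@seed, "\n", sep = "")
})

setMethod("show", "BackboneSpec", function(object) {
  cat("BackboneSpec '", object@name, "': ", object@inputHeight, "x",
      object@inputWidth, "x3 -> ", object@outputDim, " features (",
      object@tapPoint, ")\n", sep = "")
})
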