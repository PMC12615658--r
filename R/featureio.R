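#' Write a FeatureSet to a delimited text table
#'
#' Comma-delimited with a header row; the first two columns are
#' `sample_id` and `label`, followed by one column per feature. Values are
#' written with 9 significant digits, which round-trips the double
#' precision used throughout the pipeline to well below classifier
#' sensitivity.
#'
#' @param fs a [FeatureSet-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @seealso [readFeatureTable()]
#' @export
writeFeatureTable <- function(fs, path) {
  vals <- featureValues(fs)
  txt <- matrix(sprintf("%.9g", vals), nrow(vals), ncol(vals))
  df <- data.frame(sample_id = sampleIds(fs), label = sampleLabels(fs),
                   txt, stringsAsFactors = FALSE, check.names = FALSE)
  colnames(df) <- c("sample_id", "label", featureIds(fs))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a FeatureSet from a delimited text table
#'
#' Expects the format written by [writeFeatureTable()]: a header row,
#' `sample_id` and `label` columns, then numeric feature columns.
#'
#' @param path input file path.
#' @return a [FeatureSet-class].
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("sample_id", "label")
  if (!all(req %in% colnames(df)))
    stop("feature table must have 'sample_id' and 'label' columns: ", path)
  featCols <- setdiff(colnames(df), req)
  if (!length(featCols)) stop("feature table has no feature columns: ", path)
  vals <- as.matrix(df[, featCols, drop = FALSE])
  storage.mode(vals) <- "double"
  FeatureSet(vals, labels = df$label, featureIds = featCols,
             sampleIds = as.character(df$sample_id))
}
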