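# End-to-end pipeline orchestration: features (extracted or synthetic) ->
# optional SVC ranking -> optional ABC subset search -> classifier zoo
# evaluation, with every artifact written to the output directory and a
# manifest of digests for reproducibility checks.

.selectorModes <- c("none", "svc", "abc", "abc+svc")

#' Parse a flat key = value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments are
#' ignored. Values are kept as strings and validated by
#' [validateConfig()].
#'
#' @param path configuration file path.
#' @return named character vector.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.+-]+)\\s*=\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, integer(1)) != 3L]
  if (length(bad))
    stop("unparseable config line(s): ", paste(bad, collapse = "; "))
  stats::setNames(vapply(kv, `[`, character(1), 3L),
                  vapply(kv, `[`, character(1), 2L))
}

#' Validate a raw pipeline configuration
#'
#' Resolves names against the backbone/selector/classifier registries,
#' fills defaults (backbone `tinycnn`, selector `none`, classifier `lr`,
#' split 0.8, folds 5) and aggregates every problem into a single error
#' report. A seed is mandatory whenever a stochastic stage (the ABC
#' selector, or the `rf`/`xgb`/`knn` learners) is requested.
#'
#' Recognized keys: `backbone`, `selector`, `classifiers` (comma list),
#' `split`, `folds`, `seed`, `images` or `features` (input; when both are
#' absent a synthetic table is generated from `synth_n`, `synth_d`,
#' `synth_k`, `synth_effect`), `quality_filter` (true/false),
#' `psnr_threshold`, `smoother`, `svc_topk` (0 = mean-threshold cut),
#' `abc_colony`, `abc_limit`, `abc_iters`, `abc_lambda`, `abc_cvfolds`,
#' `out`.
#'
#' @param raw named character vector or list, e.g. from
#'   [readPipelineConfig()].
#' @return validated configuration list with class `"PipelineConfig"`.
#' @examples
#' cfg <- validateConfig(c(backbone = "tinycnn", classifiers = "lr"))
#' cfg$split; cfg$folds
#' @export
validateConfig <- function(raw) {
  raw <- as.list(raw)
  errs <- character()
  num <- function(key, default) {
    v <- suppressWarnings(as.numeric(raw[[key]] %||% default))
    if (is.na(v)) errs <<- c(errs, paste0("'", key, "' is not numeric: ",
                                          raw[[key]]))
    v
  }
  cfg <- list()
  cfg$backbone <- raw$backbone %||% "tinycnn"
  if (!cfg$backbone %in% c("tinycnn", "vgg19", "resnet50", "inceptionv3") &&
      !cfg$backbone %in% listBackbones())
    errs <- c(errs, paste0("unknown backbone '", cfg$backbone, "'"))
  cfg$selector <- raw$selector %||% "none"
  if (!cfg$selector %in% .selectorModes)
    errs <- c(errs, paste0("unknown selector '", cfg$selector,
                           "'; valid: ", paste(.selectorModes, collapse = ", ")))
  cfg$classifiers <- tolower(trimws(strsplit(raw$classifiers %||% "lr",
                                             ",")[[1]]))
  badCl <- setdiff(cfg$classifiers, .zooNames)
  if (length(badCl))
    errs <- c(errs, paste0("unknown classifier(s): ",
                           paste(badCl, collapse = ", ")))
  cfg$split <- num("split", 0.8)
  if (!is.na(cfg$split) && (cfg$split <= 0 || cfg$split >= 1))
    errs <- c(errs, "'split' must be in (0, 1)")
  cfg$folds <- as.integer(num("folds", 5))
  stochastic <- cfg$selector %in% c("abc", "abc+svc") ||
    any(cfg$classifiers %in% c("rf", "xgb", "knn"))
  if (is.null(raw$seed)) {
    if (stochastic)
      errs <- c(errs, "a 'seed' is required: the configuration includes a stochastic stage")
    cfg$seed <- 1L
  } else cfg$seed <- as.integer(num("seed", 1))
  cfg$images <- raw$images
  cfg$features <- raw$features
  if (!is.null(cfg$images) && !dir.exists(cfg$images))
    errs <- c(errs, paste0("image directory not found: ", cfg$images))
  if (!is.null(cfg$features) && !file.exists(cfg$features))
    errs <- c(errs, paste0("feature table not found: ", cfg$features))
  cfg$synth_n <- as.integer(num("synth_n", 200))
  cfg$synth_d <- as.integer(num("synth_d", 20))
  cfg$synth_k <- as.integer(num("synth_k", 3))
  cfg$synth_effect <- num("synth_effect", 2)
  cfg$quality_filter <- tolower(raw$quality_filter %||% "false") %in%
    c("true", "1", "yes")
  cfg$psnr_threshold <- num("psnr_threshold", 20)
  cfg$smoother <- raw$smoother %||% "median3"
  if (!cfg$smoother %in% c("median3", "gaussian3"))
    errs <- c(errs, paste0("unknown smoother '", cfg$smoother, "'"))
  cfg$svc_topk <- as.integer(num("svc_topk", 0))
  cfg$abc_colony <- as.integer(num("abc_colony", 10))
  cfg$abc_limit <- as.integer(num("abc_limit", 5))
  cfg$abc_iters <- as.integer(num("abc_iters", 50))
  cfg$abc_lambda <- num("abc_lambda", 0.01)
  cfg$abc_cvfolds <- as.integer(num("abc_cvfolds", 3))
  cfg$out <- raw$out %||% "locustsel_run"
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  structure(cfg, class = "PipelineConfig")
}

#' Technique label for a (backbone, selector, classifier) triple
#'
#' Labels follow the comparison-table convention, e.g.
#' `techniqueLabel("vgg19", "abc+svc", "lr")` is `"VGG19 + ABC + LR"`.
#'
#' @param backbone,selector,classifier component names.
#' @return character label.
#' @export
techniqueLabel <- function(backbone, selector, classifier) {
  bb <- switch(backbone, vgg19 = "VGG19", resnet50 = "ResNet50",
               inceptionv3 = "InceptionV3", tinycnn = "TinyCNN", backbone)
  sel <- switch(selector, none = NULL, svc = "SVC", abc = "ABC",
                `abc+svc` = "ABC", selector)
  paste(c(bb, sel, toupper(classifier)), collapse = " + ")
}

#' Run the full detection pipeline
#'
#' Stages, in order: acquire features (from an image directory via the
#' configured backbone, from a feature table, or synthesized); optional
#' MSE/PSNR quality filtering of images; optional SVC ranking; optional
#' ABC subset search (mode `abc+svc` first reduces dimensionality by the
#' SVC mean-threshold cut, then searches the reduced set); hold-out
#' evaluation of the configured classifiers plus k-fold cross-validation.
#' Every stage writes its artifact under `cfg$out`, and a manifest of
#' MD5 digests, timings and the config snapshot is written at the end.
#' Re-running an identical configuration reproduces identical artifact
#' digests.
#'
#' @param cfg a `PipelineConfig` from [validateConfig()].
#' @return list with `results` (technique comparison data.frame, one row
#'   per classifier), `cvAccuracies` (per-classifier fold vectors), `mask`
#'   (selected-feature logical mask) and `manifest`.
#' @export
runPipeline <- function(cfg) {
  if (!inherits(cfg, "PipelineConfig")) cfg <- validateConfig(cfg)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(cfg), stages = list())
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, t0, files) {
    manifest$stages[[name]] <<- list(
      seconds = round(tic() - t0, 3),
      files = as.list(tools::md5sum(files)))
  }

  # --- features ---
  t0 <- tic()
  if (!is.null(cfg$features)) {
    fs <- readFeatureTable(cfg$features)
  } else if (!is.null(cfg$images)) {
    samples <- loadImageDataset(cfg$images)
    if (cfg$quality_filter) {
      qf <- qualityFilter(samples, smoother = cfg$smoother,
                          psnrThreshold = cfg$psnr_threshold)
      writeQualityReport(qf$report, file.path(cfg$out, "quality_report.csv"))
      samples <- qf$kept
    }
    fs <- extractDataset(cfg$backbone, samples)
  } else {
    fs <- genFeatureTable(cfg$synth_n, cfg$synth_d, cfg$synth_k,
                          effectSize = cfg$synth_effect,
                          seed = cfg$seed)$features
  }
  featPath <- file.path(cfg$out, "features.csv")
  writeFeatureTable(fs, featPath)
  stage("features", t0, featPath)

  # --- selection ---
  t0 <- tic()
  d <- nrow(fs)
  mask <- rep(TRUE, d)
  selFiles <- character()
  if (cfg$selector %in% c("svc", "abc+svc")) {
    ranking <- rankFeatures(fitMarginWeights(fs), featureIds = featureIds(fs))
    cut <- if (cfg$svc_topk > 0)
      selectTop(ranking, "count", k = cfg$svc_topk)
    else selectTop(ranking, "mean")
    mask <- as.logical(cut)
    rankPath <- file.path(cfg$out, "ranking.csv")
    writeRanking(attr(cut, "ranking"), rankPath)
    selFiles <- c(selFiles, rankPath)
  }
  if (cfg$selector %in% c("abc", "abc+svc")) {
    sub <- if (cfg$selector == "abc+svc") fs[mask, ] else fs
    abcCfg <- abcConfig(colonySize = cfg$abc_colony, limit = cfg$abc_limit,
                        maxIterations = cfg$abc_iters, seed = cfg$seed,
                        parsimonyWeight = cfg$abc_lambda,
                        fitnessFolds = cfg$abc_cvfolds)
    res <- runABC(sub, abcCfg)
    inner <- as.logical(bestMask(res))
    if (cfg$selector == "abc+svc") {
      full <- rep(FALSE, d); full[which(mask)[inner]] <- TRUE
      mask <- full
    } else mask <- inner
    abcPath <- file.path(cfg$out, "abc_result.json")
    writeABCResult(res, abcPath)
    selFiles <- c(selFiles, abcPath)
  }
  if (length(selFiles)) stage("selection", t0, selFiles)
  else manifest$stages$selection <- list(skipped = TRUE)

  # --- evaluation ---
  t0 <- tic()
  fsSel <- fs[mask, ]
  proto <- evalProtocol(splitFraction = cfg$split, cvFolds = cfg$folds,
                        seed = cfg$seed)
  sp <- splitDataset(fsSel, proto)
  zoo <- trainZoo(sp$train, sp$test, cfg$classifiers, seed = cfg$seed)
  cv <- lapply(stats::setNames(cfg$classifiers, cfg$classifiers),
               function(cl) kfoldCV(fsSel, cl, proto))
  results <- data.frame(
    technique = vapply(cfg$classifiers, function(cl)
      techniqueLabel(cfg$backbone, cfg$selector, cl), character(1)),
    zoo[, c("accuracy", "precision", "recall", "f1")],
    cv_mean_accuracy = vapply(cv, mean, numeric(1)),
    n_selected_features = sum(mask), row.names = NULL)
  results <- compareTechniques(results)
  compPath <- file.path(cfg$out, "comparison.csv")
  write.csv(results, compPath, row.names = FALSE)
  metricsPath <- file.path(cfg$out, "metrics.json")
  jsonlite::write_json(list(holdout = results, cv_fold_accuracies = cv),
                       metricsPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  stage("evaluation", t0, c(compPath, metricsPath))

  # --- manifest (written atomically) ---
  manifest$r_version <- as.character(getRversion())
  manPath <- file.path(cfg$out, "manifest.json")
  tmp <- paste0(manPath, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, manPath)
  list(results = results, cvAccuracies = cv, mask = mask,
       manifest = manifest)
}
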