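# Artificial Bee Colony search over binary feature masks.
#
# A food source is a candidate feature subset: list(mask, fitness, trial).
# Employed bees perturb each source; onlooker bees reinforce sources in
# proportion to fitness; scouts replace sources whose trial counter has
# exceeded the abandonment limit. The global best mask is kept outside the
# colony (elitism), so the reported optimum can never be lost to a scout.

#' Cross-validated subset-accuracy fitness of a feature mask
#'
#' Fitness is the stratified k-fold cross-validated accuracy of a linear
#' soft-margin SVC trained on the masked feature columns, minus a parsimony
#' penalty `parsimonyWeight * popcount(mask) / d`. Fold assignment is drawn
#' once from the configuration seed, so all masks are scored on identical
#' folds and the fitness is a deterministic function of the mask.
#'
#' @param mask integer/logical vector over features with at least one bit set.
#' @param x a [FeatureSet-class].
#' @param cfg an [ABCConfig-class].
#' @param cache optional environment used to memoize fitness per mask.
#' @param folds optional precomputed fold assignment (internal use).
#' @return numeric fitness (may be negative for large penalties).
#' @examples
#' gen <- genFeatureTable(nSamples = 40, nFeatures = 4, nInformative = 2,
#'                        effectSize = 3, seed = 1)
#' cfg <- abcConfig(seed = 1, parsimonyWeight = 0)
#' evaluateFitness(c(1, 1, 0, 0), gen$features, cfg)
#' @export
evaluateFitness <- function(mask, x, cfg, cache = NULL, folds = NULL) {
  mask <- as.integer(as.logical(mask))
  if (!sum(mask)) stop("mask must select at least one feature")
  key <- paste(mask, collapse = "")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  labels <- sampleLabels(x)
  if (length(unique(labels)) < 2L) stop("both classes required")
  if (is.null(folds))
    folds <- withSeed(cfg@seed, stratifiedFolds(labels, cfg@fitnessFolds))
  vals <- featureValues(x)[, mask == 1L, drop = FALSE]
  correct <- 0L
  for (f in seq_len(max(folds))) {
    te <- folds == f
    std <- standardizeTrainTest(vals[!te, , drop = FALSE],
                                vals[te, , drop = FALSE])
    fit <- e1071::svm(std$train, factor(labels[!te], levels = c(0L, 1L)),
                      kernel = "linear", cost = 1, scale = FALSE)
    pred <- predict(fit, std$test)
    correct <- correct + sum(as.integer(as.character(pred)) == labels[te])
  }
  acc <- correct / length(labels)
  fitness <- acc - cfg@parsimonyWeight * sum(mask) / length(mask)
  if (!is.null(cache)) cache[[key]] <- fitness
  fitness
}

# Neighbor operator: flip each bit independently with probability 1/d; at
# least one flip is forced, and an all-zero proposal gets one random bit
# turned back on.
proposeNeighbor <- function(mask) {
  d <- length(mask)
  flip <- runif(d) < 1 / d
  if (!any(flip)) flip[sample.int(d, 1L)] <- TRUE
  nb <- mask
  nb[flip] <- 1L - nb[flip]
  if (!sum(nb)) nb[sample.int(d, 1L)] <- 1L
  nb
}

randomMask <- function(d) {
  m <- rbinom(d, 1L, 0.5)
  if (!sum(m)) m[sample.int(d, 1L)] <- 1L
  as.integer(m)
}

#' Employed-bee phase
#'
#' Each food source proposes a neighbor mask (random bit flips); the
#' neighbor replaces the source only if strictly fitter (trial reset to 0),
#' otherwise the source's trial counter is incremented.
#'
#' @param colony list of food sources, each `list(mask, fitness, trial)`.
#' @param fitnessFun function(mask) -> numeric.
#' @return the updated colony. Randomness is drawn from the current RNG
#'   state; [runABC()] seeds it from the configuration.
#' @export
abcEmployedPhase <- function(colony, fitnessFun) {
  if (!length(colony)) stop("colony must be nonempty")
  for (i in seq_along(colony)) {
    src <- colony[[i]]
    nb <- proposeNeighbor(src$mask)
    fit <- fitnessFun(nb)
    if (fit > src$fitness) {
      colony[[i]] <- list(mask = nb, fitness = fit, trial = 0L)
    } else {
      colony[[i]]$trial <- src$trial + 1L
    }
  }
  colony
}

#' Onlooker-bee phase
#'
#' `length(colony)` onlooker proposals are allocated to food sources with
#' probability proportional to shifted fitness `fitness - min + eps`
#' (uniform when all fitnesses are equal), each applying the same
#' greedy-acceptance rule as the employed phase.
#'
#' @inheritParams abcEmployedPhase
#' @param eps small shift keeping probabilities positive.
#' @return the updated colony.
#' @export
abcOnlookerPhase <- function(colony, fitnessFun, eps = 1e-9) {
  if (!length(colony)) stop("colony must be nonempty")
  fits <- vapply(colony, `[[`, numeric(1), "fitness")
  p <- fits - min(fits) + eps
  picks <- sample.int(length(colony), length(colony), replace = TRUE,
                      prob = p / sum(p))
  for (i in picks) {
    src <- colony[[i]]
    nb <- proposeNeighbor(src$mask)
    fit <- fitnessFun(nb)
    if (fit > src$fitness) {
      colony[[i]] <- list(mask = nb, fitness = fit, trial = 0L)
    } else {
      colony[[i]]$trial <- src$trial + 1L
    }
  }
  colony
}

#' Scout-bee phase
#'
#' Every food source whose trial counter exceeds `limit` is abandoned and
#' replaced by a fresh uniform-random nonempty mask with trial 0. The
#' elitist global best is maintained outside the colony by [runABC()], so
#' abandonment never loses the reported optimum.
#'
#' @inheritParams abcEmployedPhase
#' @param limit abandonment threshold.
#' @return the updated colony.
#' @export
abcScoutPhase <- function(colony, limit, fitnessFun) {
  for (i in seq_along(colony)) {
    if (colony[[i]]$trial > limit) {
      m <- randomMask(length(colony[[i]]$mask))
      colony[[i]] <- list(mask = m, fitness = fitnessFun(m), trial = 0L)
    }
  }
  colony
}

#' Run the Artificial Bee Colony feature-subset search
#'
#' Initializes `colonySize` random nonempty masks, then cycles employed,
#' onlooker and scout phases for `maxIterations` iterations, maximizing the
#' cross-validated subset-accuracy fitness of [evaluateFitness()]. Fitness
#' values are memoized per mask, and the best mask ever accepted is tracked
#' elitistically. Fully reproducible from `cfg@seed`.
#'
#' @param x a [FeatureSet-class].
#' @param cfg an [ABCConfig-class].
#' @return an [ABCResult-class].
#' @examples
#' gen <- genFeatureTable(nSamples = 60, nFeatures = 6, nInformative = 2,
#'                        effectSize = 3, seed = 2)
#' res <- runABC(gen$features, abcConfig(maxIterations = 5, seed = 2))
#' bestMask(res)
#' @export
runABC <- function(x, cfg) {
  stopifnot(is(x, "FeatureSet"))
  validObject(cfg)
  d <- nrow(x)
  labels <- sampleLabels(x)
  if (length(unique(labels)) < 2L) stop("both classes required")
  cache <- new.env(parent = emptyenv())
  nEval <- 0L
  withSeed(cfg@seed, {
    folds <- stratifiedFolds(labels, cfg@fitnessFolds)
    fitnessFun <- function(mask) {
      key <- paste(mask, collapse = "")
      if (!is.null(cache[[key]])) return(cache[[key]])
      nEval <<- nEval + 1L
      evaluateFitness(mask, x, cfg, cache = cache, folds = folds)
    }
    colony <- lapply(seq_len(cfg@colonySize), function(i) {
      m <- randomMask(d)
      list(mask = m, fitness = fitnessFun(m), trial = 0L)
    })
    bestIdx <- which.max(vapply(colony, `[[`, numeric(1), "fitness"))
    best <- colony[[bestIdx]]
    history <- numeric(cfg@maxIterations)
    for (it in seq_len(cfg@maxIterations)) {
      colony <- abcEmployedPhase(colony, fitnessFun)
      colony <- abcOnlookerPhase(colony, fitnessFun)
      colony <- abcScoutPhase(colony, cfg@limit, fitnessFun)
      fits <- vapply(colony, `[[`, numeric(1), "fitness")
      if (max(fits) > best$fitness) best <- colony[[which.max(fits)]]
      history[it] <- best$fitness
    }
    new("ABCResult", bestMask = best$mask, bestFitness = best$fitness,
        history = history, nSelected = as.integer(sum(best$mask)),
        nEvaluations = nEval)
  })
}

#' Exhaustive best feature subset (brute-force reference)
#'
#' Enumerates all `2^d - 1` nonempty masks and returns the one maximizing
#' [evaluateFitness()] under the same folds as [runABC()] would use. Only
#' feasible for small `d`; used as the ground-truth optimum when assessing
#' the ABC search.
#'
#' @param x a [FeatureSet-class] with at most 20 features.
#' @param cfg an [ABCConfig-class].
#' @param cache optional memoization environment (share with a [runABC()]
#'   evaluation to avoid recomputing identical masks).
#' @return list with `mask` (integer 0/1) and `fitness`.
#' @export
exhaustiveBestSubset <- function(x, cfg, cache = NULL) {
  d <- nrow(x)
  if (d > 20L) stop("exhaustive search is limited to d <= 20 features")
  labels <- sampleLabels(x)
  folds <- withSeed(cfg@seed, stratifiedFolds(labels, cfg@fitnessFolds))
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  best <- NULL
  for (code in seq_len(2^d - 1L)) {
    mask <- as.integer(intToBits(code)[seq_len(d)] == 1L)
    fit <- evaluateFitness(mask, x, cfg, cache = cache, folds = folds)
    if (is.null(best) || fit > best$fitness)
      best <- list(mask = mask, fitness = fit)
  }
  best
}

#' Serialize an ABCResult to JSON
#'
#' Writes `best_mask` (as a 0/1 string), `best_fitness`, `n_selected` and
#' the per-cycle `history`.
#'
#' @param res an [ABCResult-class].
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
writeABCResult <- function(res, path) {
  jsonlite::write_json(list(
    best_mask = paste(res@bestMask, collapse = ""),
    best_fitness = res@bestFitness,
    n_selected = res@nSelected,
    n_evaluations = res@nEvaluations,
    history = res@history), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
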