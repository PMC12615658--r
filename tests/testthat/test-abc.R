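test_that("fitness is CV accuracy minus the parsimony penalty", {
  # feature identical to the label separates perfectly
  lab <- rep(c(0L, 1L), each = 15)
  X <- cbind(ifelse(lab == 1L, 1, -1) + 0.01 * rnorm(30),
             matrix(rnorm(60), 30, 2))
  fs <- FeatureSet(X, lab)
  cfg0 <- abcConfig(seed = 1, parsimonyWeight = 0)
  expect_equal(evaluateFitness(c(1, 0, 0), fs, cfg0), 1.0)
  # parsimony: lambda shifts fitness by lambda * popcount / d
  cfgL <- abcConfig(seed = 1, parsimonyWeight = 0.3)
  expect_equal(evaluateFitness(c(1, 0, 0), fs, cfgL), 1.0 - 0.3 / 3)
  expect_error(evaluateFitness(c(0, 0, 0), fs, cfg0), "at least one")
})

test_that("label-independent features score at chance level", {
  gen <- genFeatureTable(500, 4, 1, effectSize = 0, seed = 11)
  cfg <- abcConfig(seed = 11, parsimonyWeight = 0)
  fit <- evaluateFitness(c(1, 1, 1, 1), gen$features, cfg)
  expect_gte(fit, 0.4)
  expect_lte(fit, 0.6)
})

test_that("fitness is memoized and deterministic per mask", {
  gen <- genFeatureTable(40, 4, 2, effectSize = 2, seed = 5)
  cfg <- abcConfig(seed = 5)
  cache <- new.env()
  f1 <- evaluateFitness(c(1, 1, 0, 0), gen$features, cfg, cache = cache)
  f2 <- evaluateFitness(c(1, 1, 0, 0), gen$features, cfg, cache = cache)
  f3 <- evaluateFitness(c(1, 1, 0, 0), gen$features, cfg)
  expect_identical(f1, f2)
  expect_identical(f1, f3)
})

test_that("employed phase applies strict greedy acceptance", {
  colony <- list(list(mask = c(1L, 0L, 0L), fitness = 0.5, trial = 2L))
  # fitness function that always improves: source replaced, trial reset
  up <- locustsel:::withSeed(1,
    abcEmployedPhase(colony, function(m) 0.9))
  expect_equal(up[[1]]$fitness, 0.9)
  expect_equal(up[[1]]$trial, 0L)
  # never improves: source kept, trial incremented
  down <- locustsel:::withSeed(1,
    abcEmployedPhase(colony, function(m) 0.1))
  expect_equal(down[[1]]$mask, c(1L, 0L, 0L))
  expect_equal(down[[1]]$trial, 3L)
  # equal fitness also rejects (strict improvement)
  eq <- locustsel:::withSeed(1,
    abcEmployedPhase(colony, function(m) 0.5))
  expect_equal(eq[[1]]$trial, 3L)
})

test_that("every proposed mask is nonempty", {
  seen <- new.env(); seen$bad <- 0L
  colony <- lapply(1:4, function(i)
    list(mask = c(1L, 0L), fitness = 0.5, trial = 0L))
  fn <- function(m) { if (sum(m) == 0) seen$bad <- seen$bad + 1L; runif(1) }
  locustsel:::withSeed(2, {
    for (i in 1:50) {
      colony <- abcEmployedPhase(colony, fn)
      colony <- abcOnlookerPhase(colony, fn)
      colony <- abcScoutPhase(colony, 2, fn)
    }
  })
  expect_equal(seen$bad, 0L)
})

test_that("onlooker allocation is fitness-proportional", {
  # one dominant source receives essentially all proposals
  colony <- c(list(list(mask = c(1L, 0L, 0L, 0L), fitness = 1.0,
                        trial = 0L)),
              lapply(1:9, function(i)
                list(mask = c(0L, 1L, 0L, 0L), fitness = 0.0, trial = 0L)))
  touched <- integer(10)
  fn <- function(m) -1  # never accepted, so only trials move
  up <- locustsel:::withSeed(3, abcOnlookerPhase(colony, fn))
  trials <- vapply(up, `[[`, integer(1), "trial")
  expect_gte(trials[1], 9)  # dominant source got (almost) all proposals
  expect_lte(sum(trials[-1]), 1)
})

test_that("scouts replace only sources beyond the abandonment limit", {
  colony <- list(
    list(mask = c(1L, 0L), fitness = 0.2, trial = 6L),  # > limit 5
    list(mask = c(0L, 1L), fitness = 0.3, trial = 5L))  # at limit: kept
  up <- locustsel:::withSeed(4,
    abcScoutPhase(colony, 5, function(m) 0.7))
  expect_equal(up[[1]]$trial, 0L)
  expect_equal(up[[1]]$fitness, 0.7)
  expect_equal(up[[2]]$mask, c(0L, 1L))
  expect_equal(up[[2]]$trial, 5L)
})

test_that("runABC is reproducible, elitist and monotone in history", {
  gen <- genFeatureTable(60, 6, 2, effectSize = 2, seed = 7)
  cfg <- abcConfig(maxIterations = 10, seed = 7)
  r1 <- runABC(gen$features, cfg)
  r2 <- runABC(gen$features, cfg)
  expect_identical(bestMask(r1), bestMask(r2))
  expect_identical(fitnessHistory(r1), fitnessHistory(r2))
  expect_true(all(diff(fitnessHistory(r1)) >= 0))
  expect_equal(bestFitness(r1),
               fitnessHistory(r1)[length(fitnessHistory(r1))])
  expect_gte(sum(bestMask(r1)), 1)
  # minimal run: one cycle, history length 1
  rmin <- runABC(gen$features, abcConfig(maxIterations = 1, seed = 7))
  expect_length(fitnessHistory(rmin), 1)
  expect_error(abcConfig(maxIterations = 0, seed = 1))
})

test_that("ABC attains the exhaustive optimum on a small problem", {
  gen <- genFeatureTable(60, 4, 2, effectSize = 1.5, seed = 17)
  cfg <- abcConfig(maxIterations = 15, seed = 17)
  res <- runABC(gen$features, cfg)
  oracle <- exhaustiveBestSubset(gen$features, cfg)
  expect_equal(bestFitness(res), oracle$fitness, tolerance = 1e-12)
})

test_that("parsimony strictly prefers the smaller of two equal-accuracy masks", {
  # both masks contain the perfectly separating feature, so CV accuracy is
  # identical; the penalty must break the tie toward the smaller mask
  lab <- rep(c(0L, 1L), each = 20)
  X <- cbind(ifelse(lab == 1L, 3, -3), matrix(rnorm(80), 40, 2))
  fs <- FeatureSet(X, lab)
  cfg <- abcConfig(seed = 2, parsimonyWeight = 0.05)
  small <- evaluateFitness(c(1, 0, 0), fs, cfg)
  large <- evaluateFitness(c(1, 1, 1), fs, cfg)
  expect_gt(small, large)
})

test_that("ABC results serialize to JSON with a 0/1 mask string", {
  gen <- genFeatureTable(40, 5, 2, effectSize = 2, seed = 3)
  res <- runABC(gen$features, abcConfig(maxIterations = 3, seed = 3))
  path <- tempfile(fileext = ".json")
  writeABCResult(res, path)
  parsed <- jsonlite::read_json(path)
  expect_match(parsed$best_mask, "^[01]{5}$")
  expect_equal(parsed$n_selected, sum(bestMask(res)))
  expect_length(parsed$history, 3)
})
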