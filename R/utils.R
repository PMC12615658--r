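# Evaluate expr with a temporarily seeded RNG, restoring the caller's
# random-number state afterwards. All seeded entry points go through this so
# that package randomness never perturbs (or depends on) the session RNG.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Stratified fold assignment: within each class, shuffled samples are dealt
# round-robin so fold sizes differ by at most one per class.
stratifiedFolds <- function(labels, k) {
  k <- as.integer(k)
  if (k < 2L) stop("need at least 2 folds")
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop("class ", cl, " has fewer samples (", length(idx),
           ") than folds (", k, ")")
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Column-standardize a training matrix and apply the same transform to a
# test matrix; zero-variance columns are centered but left unscaled.
standardizeTrainTest <- function(Xtr, Xte = NULL) {
  mu <- colMeans(Xtr)
  sg <- apply(Xtr, 2L, sd)
  sg[!is.finite(sg) | sg == 0] <- 1
  Xtr <- sweep(sweep(Xtr, 2L, mu, "-"), 2L, sg, "/")
  if (!is.null(Xte))
    Xte <- sweep(sweep(Xte, 2L, mu, "-"), 2L, sg, "/")
  list(train = Xtr, test = Xte)
}

# Derive a child seed from a base seed and a stage tag, kept within the
# 32-bit integer range.
deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.double(seed) * 7919 + h) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
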