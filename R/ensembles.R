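# Training regimes over environments: singular (pool everything),
# environment ensemble (one submodel per training location), bagged
# ensembles for networks, and greedy single-dropout optimization against a
# validation baseline. Ensemble prediction is always the unweighted mean of
# submodel predictions.

# Fit one base learner on (X, y). control:
#   $lambda      fixed ridge penalty (skips CV)
#   $lambdaGrid  CV grid for ridge (default standard log grid)
#   $hp          NetworkHyperparams (fitted fresh when absent)
#   $tuneDraws   random-search size when hp is absent
#   $maxEpochs   network epoch cap
.fitBase <- function(X, y, base, seed = 1L, control = list()) {
  if (!nrow(as.matrix(X))) stop("no training rows")
  switch(base,
    linear = fitOLS(X, y),
    ridge = {
      lam <- control$lambda
      if (is.null(lam)) {
        grid <- control$lambdaGrid
        if (is.null(grid)) grid <- c(0.01, 0.1, 1, 10, 100, 1000)
        lam <- ridgeLambdaCV(X, y, lambdaGrid = grid, seed = seed)
      }
      fitRidge(X, y, lam)
    },
    network = {
      hp <- control$hp
      if (is.null(hp)) {
        nDraws <- if (is.null(control$tuneDraws)) 30 else control$tuneDraws
        hp <- tuneNetwork(X, y, nDraws = nDraws, seed = seed,
                          maxEpochs = control$maxEpochs %||% 50L)$best
      }
      fitNetwork(X, y, hp, seed = seed,
                 maxEpochs = control$maxEpochs %||% 50L)
    },
    stop("unknown base learner '", base, "'"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.trainingBlocks <- function(dataset, testLocation) {
  blocks <- datasetBlocks(dataset)
  if (!is.null(testLocation)) {
    if (!testLocation %in% names(blocks))
      stop("test location '", testLocation, "' not in the dataset")
    blocks <- blocks[setdiff(names(blocks), testLocation)]
  }
  if (!length(blocks)) stop("no training location left")
  blocks[sort(names(blocks))]   # canonical order: results independent of input order
}

.bindBlocks <- function(blocks) {
  list(X = do.call(rbind, lapply(blocks, `[[`, "X")),
       y = unlist(lapply(blocks, `[[`, "y"), use.names = FALSE))
}

#' Train a singular model (all training locations pooled)
#'
#' @param dataset a \linkS4class{ModelingDataset}.
#' @param base "linear", "ridge" or "network".
#' @param testLocation location excluded from training (NULL to use all).
#' @param seed integer seed for stochastic bases.
#' @param control base-learner options (see package vignette): fixed
#'   \code{lambda}, \code{lambdaGrid}, network \code{hp}, \code{tuneDraws},
#'   \code{maxEpochs}.
#' @return An \linkS4class{EnsembleModel} with one submodel whose
#'   membership lists every training location.
#' @export
trainSingular <- function(dataset, base = "linear", testLocation = NULL,
                          seed = 1L, control = list()) {
  blocks <- .trainingBlocks(dataset, testLocation)
  pooled <- .bindBlocks(blocks)
  model <- .fitBase(pooled$X, pooled$y, base, seed = seed, control = control)
  new("EnsembleModel", submodels = list(model),
      membership = list(names(blocks)), approach = "singular")
}

#' Train an environment ensemble (one submodel per training location)
#'
#' @inheritParams trainSingular
#' @return An \linkS4class{EnsembleModel} with as many submodels as
#'   training locations, in the dataset's location order.
#' @export
trainEnsemble <- function(dataset, base = "linear", testLocation = NULL,
                          seed = 1L, control = list()) {
  blocks <- .trainingBlocks(dataset, testLocation)
  subm <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    subm[[i]] <- .fitBase(b$X, b$y, base,
                          seed = .deriveSeed(seed, names(blocks)[i]),
                          control = control)
  }
  new("EnsembleModel", submodels = subm,
      membership = as.list(names(blocks)), approach = "ensemble")
}

#' Train a bagged environment ensemble
#'
#' Each submodel is trained on the concatenation of L location blocks drawn
#' with replacement from the L training locations (L = number of training
#' locations), the regime used for network ensembles where single locations
#' are too small to train a network.
#'
#' @inheritParams trainSingular
#' @param nSubmodels number of bagged submodels.
#' @return An \linkS4class{EnsembleModel} with approach "bagged"; each
#'   membership entry is the multiset of sampled locations.
#' @export
trainBaggedEnsemble <- function(dataset, base = "network", nSubmodels = 5L,
                                testLocation = NULL, seed = 1L,
                                control = list()) {
  stopifnot(nSubmodels >= 1)
  blocks <- .trainingBlocks(dataset, testLocation)
  L <- length(blocks)
  set.seed(.deriveSeed(seed, "bagging"))
  bags <- lapply(seq_len(nSubmodels), function(i)
    sample(names(blocks), L, replace = TRUE))
  subm <- vector("list", nSubmodels)
  for (i in seq_len(nSubmodels)) {
    bound <- .bindBlocks(blocks[bags[[i]]])
    subm[[i]] <- .fitBase(bound$X, bound$y, base,
                          seed = .deriveSeed(seed, paste0("bag", i)),
                          control = control)
  }
  new("EnsembleModel", submodels = subm, membership = bags,
      approach = "bagged")
}

#' Tune the bagged-ensemble size
#'
#' Scores each candidate size by validation accuracy of the resulting
#' bagged ensemble; ties keep the smaller size.
#'
#' @inheritParams trainBaggedEnsemble
#' @param sizes candidate submodel counts.
#' @param validationX,validationY held-out scoring set.
#' @return the selected size.
#' @export
tuneBagSize <- function(dataset, base = "network",
                        sizes = c(3L, 5L, 7L, 10L, 15L),
                        validationX, validationY, testLocation = NULL,
                        seed = 1L, control = list()) {
  score <- vapply(sizes, function(s) {
    em <- trainBaggedEnsemble(dataset, base, s, testLocation, seed, control)
    suppressWarnings(accuracy(validationY, predict(em, validationX)))
  }, numeric(1))
  score[is.na(score)] <- -Inf
  sizes[which.max(score)]
}

#' Greedy single-dropout ensemble optimization
#'
#' Scores the full ensemble on the validation set (Pearson accuracy), then
#' drops each submodel in turn from the FULL ensemble; a submodel is
#' excluded iff the ensemble without it scores strictly higher than the
#' baseline. Survivors form the optimized ensemble. If every submodel would
#' be excluded, the single most valuable one (lowest dropout accuracy) is
#' retained with a warning.
#'
#' @param full an \linkS4class{EnsembleModel} with >= 2 submodels.
#' @param validationX,validationY non-empty validation set.
#' @return list with \code{model} (the optimized
#'   \linkS4class{EnsembleModel}) and \code{decisions} (a data.frame
#'   logging, per submodel, baseline accuracy, dropout accuracy and the
#'   keep/exclude outcome).
#' @export
optimizeEnsemble <- function(full, validationX, validationY) {
  stopifnot(is(full, "EnsembleModel"))
  if (length(full@submodels) < 2) stop("need >= 2 submodels to optimize")
  if (!length(validationY)) stop("validation set is empty")
  preds <- vapply(full@submodels, function(m) predict(m, validationX),
                  numeric(length(validationY)))
  preds <- matrix(preds, nrow = length(validationY))
  baseline <- accuracy(validationY, rowMeans(preds))
  if (is.na(baseline))
    stop("validation correlation undefined (constant predictions or ",
         "constant truth); enlarge the validation split")
  k <- ncol(preds)
  dropAcc <- vapply(seq_len(k), function(j)
    accuracy(validationY, rowMeans(preds[, -j, drop = FALSE])), numeric(1))
  excluded <- !is.na(dropAcc) & dropAcc > baseline
  if (all(excluded)) {
    warning("every submodel excluded by the dropout rule; retaining the ",
            "most valuable one")
    keepIdx <- which.min(dropAcc)
    excluded[] <- TRUE
    excluded[keepIdx] <- FALSE
  }
  decisions <- data.frame(
    submodel = seq_len(k),
    membership = vapply(full@membership, function(m)
      paste(m, collapse = "+"), character(1)),
    baseline_accuracy = baseline, dropout_accuracy = dropAcc,
    excluded = excluded)
  model <- new("EnsembleModel",
               submodels = full@submodels[!excluded],
               membership = full@membership[!excluded],
               approach = "optimized")
  list(model = model, decisions = decisions)
}

#' Ensemble prediction: unweighted mean over submodels
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param X feature matrix.
#' @return numeric predictions, the arithmetic mean of the submodel
#'   predictions.
#' @export
ensemblePredict <- function(model, X) {
  stopifnot(is(model, "EnsembleModel"))
  preds <- vapply(model@submodels, function(m) predict(m, X),
                  numeric(nrow(as.matrix(X))))
  preds <- matrix(preds, nrow = nrow(as.matrix(X)))
  rowMeans(preds)
}

#' @describeIn ensemblePredict predict method
#' @param object an \linkS4class{EnsembleModel}
#' @param newdata feature matrix
#' @export
setMethod("predict", "EnsembleModel", function(object, newdata) {
  ensemblePredict(object, newdata)
})

# Deterministic small seed derived from a base seed and a string key, so
# fold/submodel seeds do not depend on iteration order.
.deriveSeed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(seed) %% 1000003) * 1009 + h) %% 2147483647L
}
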