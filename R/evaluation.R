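# Leave-one-location-out cross-validation over approaches x base learners,
# Pearson-correlation accuracy, and the phenotypic-variance threshold
# statistic contrasting ensemble vs singular wins.

#' Prediction accuracy: Pearson correlation
#'
#' Pearson product-moment correlation between observed and predicted
#' values. When either vector is constant the correlation is undefined and
#' NA is returned with a warning; callers record such folds as missing.
#'
#' @param yTrue,yPred equal-length numeric vectors (length >= 2).
#' @return Pearson r, or NA when undefined.
#' @examples
#' accuracy(c(1, 2, 3), c(1, 2, 4))
#' @export
accuracy <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  if (length(yTrue) < 2) stop("need at least 2 observations")
  if (anyNA(yTrue) || anyNA(yPred)) stop("missing values")
  if (sd(yTrue) == 0 || sd(yPred) == 0) {
    warning("correlation undefined for constant input; returning NA")
    return(NA_real_)
  }
  cor(yTrue, yPred)
}

# Carve a genotype-stratified validation split out of the training blocks:
# `frac` of the training genotypes are held out everywhere; their pooled
# rows form the validation set and the remaining rows a reduced dataset.
.validationSplit <- function(dataset, testLocation, frac = 0.2, seed = 1L) {
  blocks <- .trainingBlocks(dataset, testLocation)
  genos <- sort(unique(unlist(lapply(blocks, `[[`, "genotype_ids"))))
  nHold <- max(2L, round(frac * length(genos)))
  set.seed(seed)
  held <- sort(sample(genos, min(nHold, length(genos) - 2L)))
  valX <- NULL; valY <- numeric(0)
  reduced <- list()
  for (loc in names(blocks)) {
    b <- blocks[[loc]]
    inVal <- b$genotype_ids %in% held
    if (any(inVal)) {
      valX <- rbind(valX, b$X[inVal, , drop = FALSE])
      valY <- c(valY, b$y[inVal])
    }
    if (sum(!inVal) >= 2)
      reduced[[loc]] <- list(X = b$X[!inVal, , drop = FALSE],
                             y = b$y[!inVal],
                             genotype_ids = b$genotype_ids[!inVal])
    else reduced[[loc]] <- b   # too small to split; keep intact
  }
  list(valX = valX, valY = valY, blocks = reduced, held = held)
}

# Train the full ensemble for an approach/base pair and the matching
# optimized ensemble. Returns models keyed by approach name.
.fitFold <- function(dataset, testLocation, base, approaches, seed,
                     validationMode, control, bagSubmodels) {
  out <- list()
  useBagging <- identical(base, "network")
  makeFull <- function(ds, testLoc = testLocation)
    if (useBagging)
      trainBaggedEnsemble(ds, base, nSubmodels = bagSubmodels,
                          testLocation = testLoc, seed = seed,
                          control = control)
    else
      trainEnsemble(ds, base, testLocation = testLoc, seed = seed,
                    control = control)

  if ("singular" %in% approaches)
    out$singular <- trainSingular(dataset, base, testLocation, seed, control)
  needFull <- any(c("ensemble", "optimized") %in% approaches)
  full <- if (needFull) makeFull(dataset) else NULL
  if ("ensemble" %in% approaches) out$ensemble <- full
  if ("optimized" %in% approaches) {
    optResult <- tryCatch({
      if (validationMode == "leaky") {
        testBlock <- datasetBlocks(dataset)[[testLocation]]
        opt <- optimizeEnsemble(full, testBlock$X, testBlock$y)
        list(model = opt$model, decisions = opt$decisions)
      } else {
        split <- .validationSplit(dataset, testLocation,
                                  seed = .deriveSeed(seed, "holdout"))
        reducedDs <- new("ModelingDataset", trait = dataset@trait,
                         blocks = split$blocks,
                         selectedSnpIds = dataset@selectedSnpIds)
        reducedFull <- makeFull(reducedDs, testLoc = NULL)
        opt <- optimizeEnsemble(reducedFull, split$valX, split$valY)
        keep <- !opt$decisions$excluded
        list(model = new("EnsembleModel",
                         submodels = full@submodels[keep],
                         membership = full@membership[keep],
                         approach = "optimized"),
             decisions = opt$decisions)
      }
    }, error = function(e) {
      warning("ensemble optimization failed for test location '",
              testLocation, "': ", conditionMessage(e))
      NULL
    })
    if (!is.null(optResult)) {
      out$optimized <- optResult$model
      out$decisions <- optResult$decisions
    }
  }
  out
}

#' Leave-one-location-out cross-validation
#'
#' For each location in turn, trains every requested approach x base on the
#' remaining locations, predicts the held-out location's BLUEs and records
#' Pearson accuracy. The optimized ensemble scores single-dropout candidates
#' on a 20% genotype-stratified holdout carved from the training rows
#' (\code{validationMode = "holdout"}, default) or directly on the test
#' location (\code{"leaky"}). Network ensembles are bagged over
#' environments; network hyperparameters are tuned once per fold on the
#' pooled training rows and shared across approaches. All randomness is
#' derived from \code{seed} and the location name, so fold results do not
#' depend on location order.
#'
#' @param dataset a \linkS4class{ModelingDataset} with >= 2 locations.
#' @param approaches subset of \{"singular", "ensemble", "optimized"\}.
#' @param bases subset of \{"linear", "ridge", "network"\}.
#' @param seed integer seed.
#' @param bluesTable optional \linkS4class{BLUETable} supplying the
#'   \code{h2} column for the result rows.
#' @param validationMode "holdout" or "leaky".
#' @param tuningDraws network random-search size per fold.
#' @param bagSubmodels bagged-ensemble size for networks.
#' @param control extra base-learner options (fixed \code{lambda},
#'   \code{lambdaGrid}, \code{maxEpochs}).
#' @return A \linkS4class{CVResultTable} with one row per
#'   (trait, location, approach, base); folds whose accuracy is undefined
#'   are flagged NA and the run continues.
#' @export
looLocationCV <- function(dataset, approaches = c("singular", "ensemble",
                                                  "optimized"),
                          bases = c("linear", "ridge"), seed = 1L,
                          bluesTable = NULL,
                          validationMode = c("holdout", "leaky"),
                          tuningDraws = 30, bagSubmodels = 5L,
                          control = list()) {
  stopifnot(is(dataset, "ModelingDataset"))
  validationMode <- match.arg(validationMode)
  approaches <- match.arg(approaches, c("singular", "ensemble", "optimized"),
                          several.ok = TRUE)
  bases <- match.arg(bases, c("linear", "ridge", "network"),
                     several.ok = TRUE)
  locations <- sort(datasetLocations(dataset))
  if (length(locations) < 2) stop("need >= 2 locations for LOO CV")
  comps <- if (!is.null(bluesTable)) varianceComponents(bluesTable) else NULL

  rows <- list()
  for (loc in locations) {
    foldSeed <- .deriveSeed(seed, loc)
    testBlock <- datasetBlocks(dataset)[[loc]]
    for (base in bases) {
      ctl <- control
      ctl$tuneDraws <- tuningDraws
      if (base == "network" && is.null(ctl$hp)) {
        pooled <- .bindBlocks(.trainingBlocks(dataset, loc))
        ctl$hp <- tuneNetwork(pooled$X, pooled$y, nDraws = tuningDraws,
                              seed = foldSeed,
                              maxEpochs = ctl$maxEpochs %||% 50L)$best
      }
      models <- tryCatch(
        .fitFold(dataset, loc, base, approaches, foldSeed, validationMode,
                 ctl, bagSubmodels),
        error = function(e) {
          warning("fold '", loc, "', base '", base, "': ",
                  conditionMessage(e))
          list()
        })
      for (app in approaches) {
        acc <- if (is.null(models[[app]])) NA_real_ else
          suppressWarnings(accuracy(testBlock$y,
                                    predict(models[[app]], testBlock$X)))
        h2 <- NA_real_
        if (!is.null(comps)) {
          hit <- comps$location == loc & comps$trait == dataset@trait
          if (any(hit)) h2 <- comps$h2[hit][1]
        }
        rows[[length(rows) + 1]] <- data.frame(
          trait = dataset@trait, test_location = loc, approach = app,
          base = base, accuracy = acc, n_test = length(testBlock$y),
          phenotypic_variance = phenotypicVariance(testBlock$y), h2 = h2,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  new("CVResultTable", results = res)
}

#' Phenotypic-variance threshold statistic
#'
#' For each trait x base combination, locations are sorted by phenotypic
#' variance ascending and the threshold is the largest variance v* such
#' that the ensemble beats the singular model at every location with
#' variance <= v* (0 when the ensemble loses at the lowest-variance
#' location). The proportion is v* / max(variance) x 100; the overall
#' statistic is the mean proportion over combinations with a defined
#' threshold.
#'
#' @param results a \linkS4class{CVResultTable} (or its data.frame)
#'   containing both "ensemble" and "singular" rows.
#' @return list with \code{perCombination} (data.frame: trait, base,
#'   threshold_variance, proportion_pct) and \code{mean_proportion_pct}.
#' @export
varianceThresholdStat <- function(results) {
  r <- if (is(results, "CVResultTable")) cvResults(results) else results
  need <- c("ensemble", "singular")
  if (!all(need %in% r$approach))
    stop("results must contain both ensemble and singular rows")
  combos <- unique(r[, c("trait", "base")])
  out <- list()
  for (i in seq_len(nrow(combos))) {
    tr <- combos$trait[i]; ba <- combos$base[i]
    sub <- r[r$trait == tr & r$base == ba, , drop = FALSE]
    ens <- sub[sub$approach == "ensemble", ]
    sng <- sub[sub$approach == "singular", ]
    locs <- intersect(ens$test_location, sng$test_location)
    if (!length(locs)) next
    pv <- ens$phenotypic_variance[match(locs, ens$test_location)]
    if (anyNA(pv) || max(pv) <= 0) next
    ord <- order(pv)
    locs <- locs[ord]; pv <- pv[ord]
    eAcc <- ens$accuracy[match(locs, ens$test_location)]
    sAcc <- sng$accuracy[match(locs, sng$test_location)]
    thr <- 0
    for (j in seq_along(locs)) {
      win <- !is.na(eAcc[j]) && !is.na(sAcc[j]) && eAcc[j] > sAcc[j]
      if (win) thr <- pv[j] else break
    }
    out[[length(out) + 1]] <- data.frame(
      trait = tr, base = ba, threshold_variance = thr,
      proportion_pct = 100 * thr / max(pv), stringsAsFactors = FALSE)
  }
  if (!length(out))
    stop("no trait x base combination with a defined threshold")
  per <- do.call(rbind, out)
  rownames(per) <- NULL
  list(perCombination = per, mean_proportion_pct = mean(per$proportion_pct))
}
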