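# Shared fixture builders; everything is generated in code.

# A LinearModel that outputs an arbitrary prediction vector on the identity
# feature matrix (intercept 0, coefficients = desired predictions).
mkPredModel <- function(pred) {
  new("LinearModel", intercept = 0,
      coefficients = setNames(pred, paste0("f", seq_along(pred))),
      lambda = 0)
}

mkIdentityX <- function(n) {
  X <- diag(n)
  colnames(X) <- paste0("f", seq_len(n))
  X
}

# An ensemble whose submodels produce the columns of `predMatrix` on
# mkIdentityX(nrow(predMatrix)).
mkPredEnsemble <- function(predMatrix, approach = "ensemble") {
  k <- ncol(predMatrix)
  new("EnsembleModel",
      submodels = lapply(seq_len(k), function(j) mkPredModel(predMatrix[, j])),
      membership = as.list(paste0("loc", seq_len(k))),
      approach = approach)
}

# A small ModelingDataset with the given per-location blocks built from a
# common marker panel and linear signal plus noise.
mkDataset <- function(nGeno = 24, p = 6, locs = c("A", "B", "C"),
                      seed = 1, identicalBlocks = FALSE, noiseSd = 0.1) {
  set.seed(seed)
  X <- matrix(rbinom(nGeno * p, 2, 0.5), nGeno, p,
              dimnames = list(sprintf("G%03d", 1:nGeno), paste0("s", 1:p)))
  beta <- rnorm(p)
  blocks <- list()
  for (loc in locs) {
    noise <- if (identicalBlocks) 0 else rnorm(nGeno, 0, noiseSd)
    y <- drop(X %*% beta) + noise
    blocks[[loc]] <- list(X = X, y = setNames(y, rownames(X)),
                          genotype_ids = rownames(X))
  }
  new("ModelingDataset", trait = "trait", blocks = blocks,
      selectedSnpIds = colnames(X))
}

# Small synthetic MET end to end: config, genotypes, phenotypes, truth.
mkMET <- function(nGeno = 30, nMark = 30, L = 3, nYears = 3,
                  meanLoc = L, seed = 1, ...) {
  cfg <- syntheticConfig(nGenotypes = nGeno, nMarkers = nMark,
                         nLocations = L, nYears = nYears,
                         meanLocationsPerGenotype = meanLoc, seed = seed, ...)
  gen <- generateGenotypes(nGeno, nMark, cfg@mafRange, seed = seed)
  met <- generateMET(cfg, gen)
  list(cfg = cfg, gen = gen, phen = met$phenotypes, truth = met$truth)
}

# Independent brute-force PCA feature-selection oracle: explicit covariance,
# full eigen-decomposition, greedy per-component argmax |loading| with
# lexicographic tie-break and walk-down on collision.
oraclePcaSelect <- function(X, nComponents) {
  C <- cov(X)
  ev <- eigen(C, symmetric = TRUE)
  snps <- colnames(X)
  chosen <- character(0)
  for (k in seq_len(nComponents)) {
    load <- round(abs(ev$vectors[, k]), 9)
    ord <- order(-load, snps)
    for (cand in snps[ord]) {
      if (!cand %in% chosen) { chosen <- c(chosen, cand); break }
    }
  }
  chosen
}
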