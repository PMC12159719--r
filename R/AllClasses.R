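#' @import methods
#' @importFrom stats var sd cor predict rnorm runif rbinom coef setNames
#' @importFrom utils read.csv write.csv read.delim write.table head
NULL

# ---------------------------------------------------------------------------
# MarkerMatrix

#' SNP marker matrix with 0/1/2 dosage coding
#'
#' Genotypes in rows, SNP markers in columns. Each dosage is the number of
#' copies of the major allele carried by the genotype (0, 1 or 2).
#'
#' @slot dosages numeric matrix with values in \{0, 1, 2\}; rownames are
#'   genotype identifiers, colnames are SNP identifiers.
#' @export
setClass("MarkerMatrix", representation(dosages = "matrix"))

setValidity("MarkerMatrix", function(object) {
  d <- object@dosages
  msg <- character()
  if (is.null(rownames(d)) || is.null(colnames(d)))
    msg <- c(msg, "dosage matrix must carry genotype rownames and SNP colnames")
  else {
    if (anyDuplicated(rownames(d))) msg <- c(msg, "duplicate genotype ids")
    if (anyDuplicated(colnames(d))) msg <- c(msg, "duplicate SNP ids")
  }
  if (anyNA(d)) msg <- c(msg, "missing dosage values")
  else if (!all(d %in% c(0, 1, 2)))
    msg <- c(msg, "dosages must be 0, 1 or 2 (copies of the major allele)")
  if (length(msg)) msg else TRUE
})

#' Construct a MarkerMatrix
#'
#' @param dosages numeric matrix of allele dosages in \{0,1,2\} with genotype
#'   rownames and SNP colnames.
#' @return A \linkS4class{MarkerMatrix}.
#' @examples
#' m <- matrix(c(0, 1, 2, 1), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("snp1", "snp2")))
#' MarkerMatrix(m)
#' @export
MarkerMatrix <- function(dosages) {
  storage.mode(dosages) <- "double"
  new("MarkerMatrix", dosages = dosages)
}

#' @describeIn MarkerMatrix dosage matrix accessor
#' @param x a MarkerMatrix
#' @export
dosages <- function(x) x@dosages

#' @describeIn MarkerMatrix genotype identifiers
#' @export
genotypeIds <- function(x) rownames(x@dosages)

#' @describeIn MarkerMatrix SNP identifiers
#' @export
snpIds <- function(x) colnames(x@dosages)

setMethod("show", "MarkerMatrix", function(object) {
  d <- object@dosages
  cat("MarkerMatrix:", nrow(d), "genotypes x", ncol(d), "SNPs\n")
  f <- colSums(d) / (2 * nrow(d))
  maf <- pmin(f, 1 - f)
  cat("  MAF range:", sprintf("%.3f-%.3f", min(maf), max(maf)), "\n")
})

setMethod("dim", "MarkerMatrix", function(x) dim(x@dosages))

# ---------------------------------------------------------------------------
# PhenotypeTable

#' Long-format multi-environment trial phenotype records
#'
#' One row per (genotype, location, year, trait) observation, typically a
#' genotype-by-year cell mean within a location.
#'
#' @slot records data.frame with columns \code{genotype_id}, \code{location},
#'   \code{year}, \code{trait}, \code{value}.
#' @export
setClass("PhenotypeTable", representation(records = "data.frame"))

setValidity("PhenotypeTable", function(object) {
  r <- object@records
  need <- c("genotype_id", "location", "year", "trait", "value")
  if (!all(need %in% names(r)))
    return(paste("missing columns:", paste(setdiff(need, names(r)), collapse = ", ")))
  if (nrow(r) && !is.numeric(r$value)) return("value must be numeric")
  if (nrow(r) && anyNA(r$value)) return("missing phenotype values")
  TRUE
})

#' Construct a PhenotypeTable
#'
#' @param records data.frame with columns \code{genotype_id}, \code{location},
#'   \code{year}, \code{trait}, \code{value}.
#' @return A \linkS4class{PhenotypeTable}.
#' @export
PhenotypeTable <- function(records) {
  records$genotype_id <- as.character(records$genotype_id)
  records$location <- as.character(records$location)
  records$year <- as.integer(records$year)
  records$trait <- as.character(records$trait)
  rownames(records) <- NULL
  new("PhenotypeTable", records = records)
}

#' @describeIn PhenotypeTable records accessor
#' @param x a PhenotypeTable
#' @export
phenoRecords <- function(x) x@records

setMethod("show", "PhenotypeTable", function(object) {
  r <- object@records
  cat("PhenotypeTable:", nrow(r), "records;",
      length(unique(r$genotype_id)), "genotypes,",
      length(unique(r$location)), "locations,",
      length(unique(r$trait)), "trait(s)\n")
})

setMethod("dim", "PhenotypeTable", function(x) dim(x@records))

# ---------------------------------------------------------------------------
# SyntheticConfig

#' Configuration of the synthetic MET generator
#'
#' Holds every knob of the data-generating model: panel and marker counts,
#' trial sparsity, per-location target heritabilities, per-location
#' discriminativeness (genotypic-signal scale), the between-location genetic
#' correlation, and the year-effect scale. See \code{\link{syntheticConfig}}.
#'
#' @slot nGenotypes,nMarkers,nLocations,nYears integer counts.
#' @slot mafRange numeric(2), minor-allele-frequency sampling range in (0, 0.5].
#' @slot meanLocationsPerGenotype average number of locations each genotype
#'   is grown at.
#' @slot yearsPerGenotypeLocation consecutive years per genotype-location
#'   assignment.
#' @slot h2ByLocation named numeric, target broad-sense heritability per
#'   location, in [0, 1].
#' @slot discByLocation named numeric, nonnegative multiplier on the genotypic
#'   signal standard deviation per location.
#' @slot envCorrelation share rho in [0, 1] of marker-effect variance common
#'   to all locations.
#' @slot yearEffectSd standard deviation of random year effects (trait units).
#' @slot seed integer RNG seed.
#' @export
setClass("SyntheticConfig", representation(
  nGenotypes = "integer", nMarkers = "integer", nLocations = "integer",
  nYears = "integer", mafRange = "numeric",
  meanLocationsPerGenotype = "numeric", yearsPerGenotypeLocation = "integer",
  h2ByLocation = "numeric", discByLocation = "numeric",
  envCorrelation = "numeric", yearEffectSd = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  counts <- c(object@nGenotypes, object@nMarkers, object@nLocations,
              object@nYears, object@yearsPerGenotypeLocation)
  if (any(counts < 1L)) msg <- c(msg, "all counts must be >= 1")
  mr <- object@mafRange
  if (length(mr) != 2 || mr[1] > mr[2] || mr[1] <= 0 || mr[2] > 0.5)
    msg <- c(msg, "mafRange must be an increasing pair within (0, 0.5]")
  if (any(object@h2ByLocation < 0 | object@h2ByLocation > 1))
    msg <- c(msg, "h2 targets must lie in [0, 1]")
  if (any(object@discByLocation < 0))
    msg <- c(msg, "discriminativeness must be nonnegative")
  rho <- object@envCorrelation
  if (rho < 0 || rho > 1) msg <- c(msg, "envCorrelation must lie in [0, 1]")
  if (object@meanLocationsPerGenotype > object@nLocations)
    msg <- c(msg, "meanLocationsPerGenotype cannot exceed nLocations")
  if (object@yearsPerGenotypeLocation > object@nYears)
    msg <- c(msg, "yearsPerGenotypeLocation cannot exceed nYears")
  if (length(object@h2ByLocation) != object@nLocations ||
      length(object@discByLocation) != object@nLocations)
    msg <- c(msg, "h2ByLocation and discByLocation need one entry per location")
  if (object@yearEffectSd < 0) msg <- c(msg, "yearEffectSd must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig:", object@nGenotypes, "genotypes,", object@nMarkers,
      "markers,", object@nLocations, "locations,", object@nYears, "years\n")
  cat("  sparsity: mean", object@meanLocationsPerGenotype,
      "locations/genotype,", object@yearsPerGenotypeLocation,
      "consecutive year(s) each\n")
  cat(sprintf("  h2 targets %.2f-%.2f, rho = %.2f, year sd = %.2f, seed = %d\n",
              min(object@h2ByLocation), max(object@h2ByLocation),
              object@envCorrelation, object@yearEffectSd, object@seed))
})

#' @describeIn SyntheticConfig location names used by the generator
#' @param x a SyntheticConfig
#' @export
configLocations <- function(x) names(x@h2ByLocation)

# ---------------------------------------------------------------------------
# GroundTruth

#' Ground truth of a synthetic MET
#'
#' The exact quantities the generator drew, kept for parameter-recovery
#' checks: marker effects (shared and per location), location means, year
#' effects, per-genotype true genetic values, and the per-record
#' decomposition of every phenotype.
#'
#' @slot sharedEffects numeric, length nMarkers.
#' @slot locationEffects matrix nLocations x nMarkers of total (scaled)
#'   per-location marker effects.
#' @slot locationMeans named numeric.
#' @slot yearEffects matrix nLocations x nYears.
#' @slot trueGeneticValues matrix nGenotypes x nLocations; column j equals
#'   the marker matrix times \code{locationEffects[j, ]}.
#' @slot records data.frame mirroring the phenotype table with columns
#'   \code{genotype_id, location, year, genetic_value, year_effect, residual}.
#' @export
setClass("GroundTruth", representation(
  sharedEffects = "numeric", locationEffects = "matrix",
  locationMeans = "numeric", yearEffects = "matrix",
  trueGeneticValues = "matrix", records = "data.frame"))

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@trueGeneticValues), "genotypes x",
      ncol(object@trueGeneticValues), "locations;",
      nrow(object@records), "phenotype records decomposed\n")
})

#' @describeIn GroundTruth true genetic value matrix accessor
#' @param x a GroundTruth
#' @export
trueGeneticValues <- function(x) x@trueGeneticValues

# ---------------------------------------------------------------------------
# BLUETable

#' Per-location genotype BLUEs and variance components
#'
#' @slot blues data.frame with columns \code{location, genotype_id, trait,
#'   blue} (one adjusted mean per genotype per location).
#' @slot components data.frame with one row per location:
#'   \code{location, trait, sigma_g2, sigma_i2, sigma_e2, h2,
#'   phenotypic_variance, n_genotypes, n_years}.
#' @export
setClass("BLUETable", representation(blues = "data.frame",
                                     components = "data.frame"))

setValidity("BLUETable", function(object) {
  b <- object@blues
  msg <- character()
  need <- c("location", "genotype_id", "trait", "blue")
  if (!all(need %in% names(b)))
    return(paste("blues must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(b[c("location", "genotype_id", "trait")]))
    msg <- c(msg, "more than one BLUE for a genotype within a location")
  k <- object@components
  vc <- c("sigma_g2", "sigma_i2", "sigma_e2")
  if (all(vc %in% names(k)) && nrow(k)) {
    if (any(unlist(k[vc]) < 0, na.rm = TRUE))
      msg <- c(msg, "variance components must be nonnegative")
    if (any(k$h2 < 0 | k$h2 > 1, na.rm = TRUE))
      msg <- c(msg, "h2 must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn BLUETable BLUE rows accessor
#' @param x a BLUETable
#' @export
blues <- function(x) x@blues

#' @describeIn BLUETable per-location variance components accessor
#' @export
varianceComponents <- function(x) x@components

setMethod("show", "BLUETable", function(object) {
  cat("BLUETable:", nrow(object@blues), "BLUEs over",
      nrow(object@components), "locations\n")
  if (nrow(object@components))
    cat(sprintf("  H2 range %.2f-%.2f\n",
                min(object@components$h2), max(object@components$h2)))
})

# ---------------------------------------------------------------------------
# ModelingDataset

#' Per-location modeling blocks for one trait
#'
#' @slot trait trait name.
#' @slot blocks named list (by location); each element a list with entries
#'   \code{X} (feature matrix over selected SNPs), \code{y} (BLUE response
#'   vector) and \code{genotype_ids}.
#' @slot selectedSnpIds ordered character vector of the SNPs used as features.
#' @export
setClass("ModelingDataset", representation(
  trait = "character", blocks = "list", selectedSnpIds = "character"))

setValidity("ModelingDataset", function(object) {
  msg <- character()
  for (loc in names(object@blocks)) {
    b <- object@blocks[[loc]]
    if (nrow(b$X) != length(b$y) || length(b$y) != length(b$genotype_ids))
      msg <- c(msg, paste0("block '", loc, "': misaligned features/responses"))
    if (length(b$y) < 2)
      msg <- c(msg, paste0("block '", loc, "': fewer than 2 observations"))
    if (!identical(colnames(b$X), object@selectedSnpIds))
      msg <- c(msg, paste0("block '", loc, "': feature columns differ from selectedSnpIds"))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ModelingDataset location blocks accessor
#' @param x a ModelingDataset
#' @export
datasetBlocks <- function(x) x@blocks

#' @describeIn ModelingDataset location names
#' @export
datasetLocations <- function(x) names(x@blocks)

setMethod("show", "ModelingDataset", function(object) {
  ns <- vapply(object@blocks, function(b) length(b$y), integer(1))
  cat("ModelingDataset for trait '", object@trait, "': ",
      length(object@blocks), " locations, ",
      length(object@selectedSnpIds), " SNP features, block sizes ",
      min(ns), "-", max(ns), "\n", sep = "")
})

# ---------------------------------------------------------------------------
# Base models

#' Linear genomic prediction model (OLS or ridge)
#'
#' @slot intercept numeric scalar on the trait scale.
#' @slot coefficients named numeric vector of per-SNP effects.
#' @slot lambda nonnegative L2 penalty (0 for ordinary least squares).
#' @export
setClass("LinearModel", representation(
  intercept = "numeric", coefficients = "numeric", lambda = "numeric"))

setValidity("LinearModel", function(object) {
  if (object@lambda < 0) return("lambda must be nonnegative")
  TRUE
})

setMethod("show", "LinearModel", function(object) {
  cat(if (object@lambda > 0) "Ridge" else "OLS",
      "LinearModel:", length(object@coefficients), "coefficients",
      if (object@lambda > 0) sprintf("(lambda = %g)", object@lambda) else "",
      "\n")
})

#' Neural-network hyperparameter draw
#'
#' Bounds follow the random-search design: learning rate log-uniform on
#' [1e-4, 100], batch size a power of two in [4, 128], 3-8 hidden layers,
#' layer width 3-100.
#'
#' @slot learningRate positive scalar.
#' @slot batchSize integer power of two in \{4, ..., 128\}.
#' @slot nLayers integer in [3, 8].
#' @slot layerWidth integer in [3, 100].
#' @export
setClass("NetworkHyperparams", representation(
  learningRate = "numeric", batchSize = "integer",
  nLayers = "integer", layerWidth = "integer"))

setValidity("NetworkHyperparams", function(object) {
  msg <- character()
  if (object@learningRate < 1e-4 || object@learningRate > 100)
    msg <- c(msg, "learningRate out of [1e-4, 100]")
  if (!object@batchSize %in% as.integer(2^(2:7)))
    msg <- c(msg, "batchSize must be a power of two in {4,...,128}")
  if (object@nLayers < 3L || object@nLayers > 8L)
    msg <- c(msg, "nLayers out of [3, 8]")
  if (object@layerWidth < 3L || object@layerWidth > 100L)
    msg <- c(msg, "layerWidth out of [3, 100]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "NetworkHyperparams", function(object) {
  cat(sprintf("NetworkHyperparams: lr = %.4g, batch = %d, %d layers x %d\n",
              object@learningRate, object@batchSize, object@nLayers,
              object@layerWidth))
})

#' Feed-forward network model with ReLU activations
#'
#' Fully connected network; hidden layers use rectified-linear activation,
#' the output layer is linear. Inputs are standardized with statistics from
#' the training block.
#'
#' @slot weights list of weight matrices, input to output.
#' @slot biases list of bias vectors.
#' @slot widths integer vector of layer widths including input and output.
#' @slot center,scale feature standardization vectors from training data.
#' @slot lossLog per-epoch training mean-squared-error history.
#' @slot hyperparams the \linkS4class{NetworkHyperparams} used, or NULL.
#' @export
setClass("NetworkModel", representation(
  weights = "list", biases = "list", widths = "integer",
  center = "numeric", scale = "numeric", lossLog = "numeric",
  hyperparams = "ANY"))

setValidity("NetworkModel", function(object) {
  for (i in seq_along(object@weights)) {
    if (nrow(object@weights[[i]]) != object@widths[i] ||
        ncol(object@weights[[i]]) != object@widths[i + 1])
      return(sprintf("weight matrix %d inconsistent with layer widths", i))
    if (length(object@biases[[i]]) != object@widths[i + 1])
      return(sprintf("bias vector %d inconsistent with layer widths", i))
  }
  if (!length(object@lossLog)) return("training log is empty")
  TRUE
})

setMethod("show", "NetworkModel", function(object) {
  cat("NetworkModel:", paste(object@widths, collapse = "-"),
      sprintf("; %d epochs, final loss %.4g\n",
              length(object@lossLog), object@lossLog[length(object@lossLog)]))
})

# ---------------------------------------------------------------------------
# EnsembleModel

#' Ensemble of base genomic prediction models
#'
#' Prediction is always the unweighted arithmetic mean of the submodel
#' predictions. \code{membership} records which training locations each
#' submodel saw: a singleton per submodel for plain environment ensembles, a
#' with-replacement multiset for bagged ensembles, all training locations at
#' once for the singular approach.
#'
#' @slot submodels ordered list of fitted base models.
#' @slot membership list of character vectors of training locations.
#' @slot approach one of "singular", "ensemble", "optimized", "bagged".
#' @export
setClass("EnsembleModel", representation(
  submodels = "list", membership = "list", approach = "character"))

setValidity("EnsembleModel", function(object) {
  msg <- character()
  if (length(object@submodels) < 1) msg <- c(msg, "need at least one submodel")
  if (length(object@submodels) != length(object@membership))
    msg <- c(msg, "one membership entry per submodel required")
  if (!object@approach %in% c("singular", "ensemble", "optimized", "bagged"))
    msg <- c(msg, "unknown approach")
  if (length(msg)) msg else TRUE
})

#' @describeIn EnsembleModel submodel list accessor
#' @param x an EnsembleModel
#' @export
submodels <- function(x) x@submodels

#' @describeIn EnsembleModel per-submodel training-location membership
#' @export
membership <- function(x) x@membership

setMethod("show", "EnsembleModel", function(object) {
  cat("EnsembleModel (", object@approach, "): ",
      length(object@submodels), " submodel(s) [",
      paste(vapply(object@membership, function(m)
        paste(unique(m), collapse = "+"), character(1)), collapse = ", "),
      "]\n", sep = "")
})

# ---------------------------------------------------------------------------
# CVResultTable

#' Leave-one-location-out cross-validation results
#'
#' @slot results data.frame with one row per (trait, test location, approach,
#'   base): columns \code{trait, test_location, approach, base, accuracy,
#'   n_test, phenotypic_variance, h2}. Undefined correlations are stored as
#'   NA.
#' @export
setClass("CVResultTable", representation(results = "data.frame"))

setValidity("CVResultTable", function(object) {
  r <- object@results
  need <- c("trait", "test_location", "approach", "base", "accuracy",
            "n_test", "phenotypic_variance", "h2")
  if (!all(need %in% names(r)))
    return(paste("missing columns:", paste(setdiff(need, names(r)), collapse = ", ")))
  if (anyDuplicated(r[c("trait", "test_location", "approach", "base")]))
    return("duplicate (trait, location, approach, base) rows")
  ok <- is.na(r$accuracy) | (r$accuracy >= -1 & r$accuracy <= 1)
  if (!all(ok)) return("accuracy outside [-1, 1]")
  TRUE
})

#' @describeIn CVResultTable results accessor
#' @param x a CVResultTable
#' @export
cvResults <- function(x) x@results

setMethod("show", "CVResultTable", function(object) {
  r <- object@results
  cat("CVResultTable:", nrow(r), "rows;",
      length(unique(r$test_location)), "locations x",
      length(unique(r$approach)), "approaches x",
      length(unique(r$base)), "bases\n")
})

# ---------------------------------------------------------------------------
# GGEResult

#' GGE biplot decomposition of a genotype x environment matrix
#'
#' Environment-centered cell-mean matrix, its SVD, two-component scores
#' under the chosen singular value partitioning (SVP), and environment-vector
#' geometry.
#'
#' @slot cellMatrix genotype x environment BLUE means (after fill).
#' @slot centered the environment-centered matrix.
#' @slot svdU,svdD,svdV full SVD factors of the centered matrix.
#' @slot genotypeScores,environmentScores score matrices (all components;
#'   the first two are the plotted ones).
#' @slot svp "environment" or "genotype" focused partitioning.
#' @slot pcVarianceFractions fraction of G + GxE variance per component.
#' @slot envVectorLengths Euclidean norms of the 2-component environment
#'   vectors.
#' @slot envPairwiseCosines cosine of the angle between environment vectors
#'   (all components, so cosines approximate between-environment correlation).
#' @slot fillFraction fraction of cells that were mean-filled.
#' @export
setClass("GGEResult", representation(
  cellMatrix = "matrix", centered = "matrix",
  svdU = "matrix", svdD = "numeric", svdV = "matrix",
  genotypeScores = "matrix", environmentScores = "matrix",
  svp = "character", pcVarianceFractions = "numeric",
  envVectorLengths = "numeric", envPairwiseCosines = "matrix",
  fillFraction = "numeric"))

setMethod("show", "GGEResult", function(object) {
  cat("GGEResult:", nrow(object@cellMatrix), "genotypes x",
      ncol(object@cellMatrix), "environments (", object@svp, "-focused SVP)\n")
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of G+GxE; fill fraction %.3f\n",
              100 * object@pcVarianceFractions[1],
              100 * object@pcVarianceFractions[2], object@fillFraction))
})

#' @describeIn GGEResult environment score matrix accessor
#' @param x a GGEResult
#' @export
environmentScores <- function(x) x@environmentScores

#' @describeIn GGEResult genotype score matrix accessor
#' @export
genotypeScores <- function(x) x@genotypeScores
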