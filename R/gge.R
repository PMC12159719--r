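# GGE biplot geometry: genotype x environment cell means from BLUEs,
# environment-centering, SVD with singular value partitioning, and
# environment-vector statistics (discriminativeness = vector length,
# between-environment correlation = vector angle).

#' Build the genotype x environment cell matrix from BLUEs
#'
#' Cell (i, j) is the BLUE of genotype i in environment j. Environments
#' with fewer than two observed genotypes are dropped with a warning.
#' Genotypes absent from an environment get that environment's observed
#' mean (equivalently zero after centering); the fraction of filled cells
#' is attached as attribute \code{fillFraction}.
#'
#' @param bluesTable a \linkS4class{BLUETable}.
#' @param trait trait name.
#' @return numeric matrix with genotype rownames and environment colnames.
#' @export
buildGEMatrix <- function(bluesTable, trait) {
  stopifnot(is(bluesTable, "BLUETable"))
  b <- blues(bluesTable)
  b <- b[b$trait == trait, , drop = FALSE]
  if (!nrow(b)) stop("trait '", trait, "' absent from the BLUE table")
  if (anyDuplicated(b[c("location", "genotype_id")]))
    stop("duplicate (genotype, environment) BLUEs")
  keepLoc <- names(which(table(b$location) >= 2))
  dropped <- setdiff(unique(b$location), keepLoc)
  if (length(dropped))
    warning("environments with < 2 observed genotypes dropped: ",
            paste(dropped, collapse = ", "))
  b <- b[b$location %in% keepLoc, , drop = FALSE]
  if (length(unique(b$location)) < 2 || length(unique(b$genotype_id)) < 2)
    stop("need >= 2 genotypes and >= 2 environments")
  genos <- sort(unique(b$genotype_id))
  envs <- sort(unique(b$location))
  m <- matrix(NA_real_, length(genos), length(envs),
              dimnames = list(genos, envs))
  m[cbind(match(b$genotype_id, genos), match(b$location, envs))] <- b$blue
  nMissing <- sum(is.na(m))
  for (j in seq_along(envs)) {
    mu <- mean(m[, j], na.rm = TRUE)
    m[is.na(m[, j]), j] <- mu
  }
  attr(m, "fillFraction") <- nMissing / length(m)
  m
}

#' Center each environment column
#'
#' Subtracts the per-environment mean over genotypes, leaving the genotype
#' main effect plus genotype-by-environment interaction (the G + GxE part
#' the biplot displays). Idempotent and invariant to adding a constant to
#' any column.
#'
#' @param cellMatrix genotype x environment matrix, no missing values.
#' @return column-centered matrix.
#' @export
centerEnvironments <- function(cellMatrix) {
  stopifnot(is.matrix(cellMatrix), !anyNA(cellMatrix))
  sweep(cellMatrix, 2, colMeans(cellMatrix))
}

#' GGE singular value decomposition with score partitioning
#'
#' Computes the SVD of the environment-centered matrix and partitions the
#' singular values into scores: environment-focused SVP assigns them to the
#' environment side (environment scores V S, genotype scores U);
#' genotype-focused does the reverse. Each component's sign is fixed so its
#' largest-magnitude environment loading is positive. Vector lengths use
#' the first two components; pairwise cosines use all components, making
#' the environment-score inner products equal the centered cross-products.
#'
#' @param centered environment-centered matrix (from
#'   \code{\link{centerEnvironments}}); min dimension >= 2.
#' @param svp "environment" (default) or "genotype".
#' @param cellMatrix optional original cell matrix to store alongside.
#' @param fillFraction fraction of mean-filled cells (metadata).
#' @return A \linkS4class{GGEResult}.
#' @export
ggeSVD <- function(centered, svp = c("environment", "genotype"),
                   cellMatrix = centered, fillFraction = NA_real_) {
  svp <- match.arg(svp)
  stopifnot(is.matrix(centered), min(dim(centered)) >= 2)
  sv <- svd(centered)
  if (max(sv$d) == 0) stop("all-zero matrix has no GGE structure")
  # sign convention: largest |environment loading| positive per component
  for (k in seq_along(sv$d)) {
    j <- which.max(abs(sv$v[, k]))
    if (sv$v[j, k] < 0) {
      sv$v[, k] <- -sv$v[, k]
      sv$u[, k] <- -sv$u[, k]
    }
  }
  rownames(sv$u) <- rownames(centered)
  rownames(sv$v) <- colnames(centered)
  if (svp == "environment") {
    envScores <- sweep(sv$v, 2, sv$d, `*`)
    genScores <- sv$u
  } else {
    envScores <- sv$v
    genScores <- sweep(sv$u, 2, sv$d, `*`)
  }
  pcFrac <- sv$d^2 / sum(sv$d^2)
  len2 <- sqrt(rowSums(envScores[, 1:2, drop = FALSE]^2))
  # cosines over all components (environment-focused geometry)
  fullEnv <- sweep(sv$v, 2, sv$d, `*`)
  norms <- sqrt(rowSums(fullEnv^2))
  cosines <- tcrossprod(fullEnv) / tcrossprod(norms)
  zero <- norms == 0
  cosines[zero, ] <- NA_real_
  cosines[, zero] <- NA_real_
  diag(cosines) <- ifelse(zero, NA_real_, 1)
  new("GGEResult", cellMatrix = cellMatrix, centered = centered,
      svdU = sv$u, svdD = sv$d, svdV = sv$v,
      genotypeScores = genScores, environmentScores = envScores,
      svp = svp, pcVarianceFractions = pcFrac,
      envVectorLengths = setNames(len2, colnames(centered)),
      envPairwiseCosines = cosines,
      fillFraction = as.numeric(fillFraction))
}

#' Run the full GGE analysis from a BLUE table
#'
#' @param bluesTable a \linkS4class{BLUETable}.
#' @param trait trait name.
#' @param svp singular value partitioning, "environment" or "genotype".
#' @return A \linkS4class{GGEResult}.
#' @examples
#' cfg <- syntheticConfig(nGenotypes = 25, nMarkers = 20, nLocations = 4,
#'                        nYears = 3, meanLocationsPerGenotype = 4)
#' met <- generateMET(cfg)
#' bl <- computeBLUEs(met$phenotypes, "trait")
#' ggeAnalysis(bl, "trait")
#' @export
ggeAnalysis <- function(bluesTable, trait, svp = "environment") {
  cm <- buildGEMatrix(bluesTable, trait)
  fill <- attr(cm, "fillFraction")
  attr(cm, "fillFraction") <- NULL
  ggeSVD(centerEnvironments(cm), svp = svp, cellMatrix = cm,
         fillFraction = fill)
}

#' Environment-vector statistics
#'
#' Vector lengths (discriminativeness) from the 2-component
#' environment-focused scores and pairwise cosines between environment
#' vectors (approximate between-environment correlations). Zero-length
#' vectors give NA cosines.
#'
#' @param gge a \linkS4class{GGEResult} computed with environment-focused
#'   SVP.
#' @return list with \code{lengths} (named numeric) and \code{cosines}
#'   (environment x environment matrix).
#' @export
envVectorStats <- function(gge) {
  stopifnot(is(gge, "GGEResult"))
  if (gge@svp != "environment")
    stop("environment-vector statistics require environment-focused SVP")
  list(lengths = gge@envVectorLengths, cosines = gge@envPairwiseCosines)
}
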