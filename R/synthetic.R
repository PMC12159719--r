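# Synthetic sparse multi-environment trial generator with a known-truth
# channel. The forward model mirrors the decomposition the downstream
# estimators assume: phenotype = location mean + genetic value + year effect
# + residual, with genetic values driven by additive marker effects that mix
# a shared component (weight sqrt(rho)) and a location-specific component
# (weight sqrt(1 - rho)), scaled per location by its discriminativeness.

#' Default synthetic MET configuration
#'
#' Defaults emulate a sparse cooperative nursery trial: a panel of 300
#' genotypes scored at 18 locations for ~1,100 retained SNPs, each genotype
#' grown at a subset of locations for two consecutive years. Per-location
#' discriminativeness spans 0.2-5x geometrically and heritability targets
#' follow \code{h2 = d^2 / (d^2 + 1.01)} (constant unit residual variance),
#' which spans roughly 0.04-0.96 across locations.
#'
#' @param nGenotypes,nMarkers,nLocations,nYears panel, marker, location and
#'   calendar-year counts.
#' @param mafRange minor-allele-frequency sampling range, within (0, 0.5].
#' @param meanLocationsPerGenotype average number of locations per genotype.
#' @param yearsPerGenotypeLocation consecutive years per assignment.
#' @param discByLocation named nonnegative multipliers of the genotypic
#'   signal sd per location; default geometric 0.2-5.
#' @param h2ByLocation named target broad-sense heritabilities; default tied
#'   to discriminativeness as above.
#' @param envCorrelation rho in [0, 1]: share of marker-effect variance
#'   common to all locations.
#' @param yearEffectSd sd of random year effects, trait units.
#' @param seed integer RNG seed.
#' @return A validated \linkS4class{SyntheticConfig}.
#' @examples
#' cfg <- syntheticConfig(nGenotypes = 40, nMarkers = 60, nLocations = 4,
#'                        nYears = 3, seed = 7)
#' cfg
#' @export
syntheticConfig <- function(nGenotypes = 300L, nMarkers = 1100L,
                            nLocations = 18L, nYears = 6L,
                            mafRange = c(0.05, 0.5),
                            meanLocationsPerGenotype = 12,
                            yearsPerGenotypeLocation = 2L,
                            discByLocation = NULL, h2ByLocation = NULL,
                            envCorrelation = 0.5, yearEffectSd = 0.1,
                            seed = 1L) {
  locs <- sprintf("L%02d", seq_len(nLocations))
  if (is.null(discByLocation)) {
    d <- exp(seq(log(0.2), log(5), length.out = nLocations))
    if (nLocations == 1L) d <- 1
    discByLocation <- setNames(d, locs)
  }
  if (is.null(names(discByLocation))) names(discByLocation) <- locs
  if (is.null(h2ByLocation)) {
    d <- discByLocation
    h2ByLocation <- setNames(d^2 / (d^2 + 1 + yearEffectSd^2), names(d))
  }
  if (is.null(names(h2ByLocation))) names(h2ByLocation) <- locs
  new("SyntheticConfig",
      nGenotypes = as.integer(nGenotypes), nMarkers = as.integer(nMarkers),
      nLocations = as.integer(nLocations), nYears = as.integer(nYears),
      mafRange = as.numeric(mafRange),
      meanLocationsPerGenotype = as.numeric(meanLocationsPerGenotype),
      yearsPerGenotypeLocation = as.integer(yearsPerGenotypeLocation),
      h2ByLocation = h2ByLocation, discByLocation = discByLocation,
      envCorrelation = as.numeric(envCorrelation),
      yearEffectSd = as.numeric(yearEffectSd), seed = as.integer(seed))
}

#' Simulate a Hardy-Weinberg SNP dosage panel
#'
#' Per-marker minor-allele frequencies are drawn uniformly from
#' \code{mafRange}; dosages of the major allele are then two binomial draws
#' per genotype. Columns whose realized minor-allele frequency falls below
#' \code{min(mafRange) / 2} (including monomorphic columns) are resampled.
#' Markers are unlinked; no population structure is simulated.
#'
#' @param nGenotypes,nMarkers counts (>= 1).
#' @param mafRange pair of frequencies in (0, 0.5].
#' @param seed integer RNG seed.
#' @return A \linkS4class{MarkerMatrix} with ids \code{G0001...} and
#'   \code{snp0001...}.
#' @examples
#' gen <- generateGenotypes(50, 20, c(0.1, 0.5), seed = 1)
#' gen
#' @export
generateGenotypes <- function(nGenotypes, nMarkers, mafRange = c(0.05, 0.5),
                              seed = 1L) {
  stopifnot(nGenotypes >= 1, nMarkers >= 1,
            length(mafRange) == 2, mafRange[1] > 0, mafRange[2] <= 0.5,
            mafRange[1] <= mafRange[2])
  set.seed(seed)
  n <- as.integer(nGenotypes)
  p <- as.integer(nMarkers)
  X <- matrix(0, n, p)
  floorMaf <- mafRange[1] / 2
  for (j in seq_len(p)) {
    ok <- FALSE
    for (attempt in seq_len(100L)) {
      maf <- runif(1, mafRange[1], mafRange[2])
      col <- rbinom(n, 2L, 1 - maf)   # dosage of the major allele
      f <- sum(col) / (2 * n)
      if (min(f, 1 - f) >= floorMaf) { ok <- TRUE; break }
    }
    if (!ok)
      stop("could not generate a polymorphic column for marker ", j,
           " after 100 attempts")
    X[, j] <- col
  }
  dimnames(X) <- list(sprintf("G%04d", seq_len(n)), sprintf("snp%04d", seq_len(p)))
  MarkerMatrix(X)
}

#' Draw a sparse genotype x location x year trial design
#'
#' Each genotype is assigned to a uniformly sampled subset of locations whose
#' size is binomial with mean \code{meanLocationsPerGenotype} (at least one),
#' and each assignment spans \code{yearsPerGenotypeLocation} consecutive
#' years starting at a random year. Designs leaving any location with fewer
#' than two genotypes are redrawn.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return data.frame of incidence triples \code{genotype_id, location, year}.
#' @examples
#' cfg <- syntheticConfig(nGenotypes = 30, nMarkers = 10, nLocations = 3,
#'                        nYears = 4, meanLocationsPerGenotype = 2)
#' head(makeDesign(cfg))
#' @export
makeDesign <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  set.seed(config@seed + 1L)
  locs <- configLocations(config)
  L <- config@nLocations
  nG <- config@nGenotypes
  ypl <- config@yearsPerGenotypeLocation
  pAssign <- config@meanLocationsPerGenotype / L
  maxStart <- config@nYears - ypl + 1L
  for (attempt in seq_len(100L)) {
    rows <- vector("list", nG)
    for (i in seq_len(nG)) {
      k <- if (pAssign >= 1) L else max(1L, rbinom(1L, L, pAssign))
      myLocs <- if (k == L) locs else sample(locs, k)
      starts <- sample.int(maxStart, length(myLocs), replace = TRUE)
      rows[[i]] <- data.frame(
        genotype_id = sprintf("G%04d", i),
        location = rep(myLocs, each = ypl),
        year = as.integer(unlist(lapply(starts, function(s) s:(s + ypl - 1L)))),
        stringsAsFactors = FALSE)
    }
    design <- do.call(rbind, rows)
    perLoc <- tapply(design$genotype_id, design$location,
                     function(g) length(unique(g)))
    if (length(perLoc) == L && all(perLoc >= 2)) {
      rownames(design) <- NULL
      return(design)
    }
  }
  stop("failed to produce a design with >= 2 genotypes at every location ",
       "after 100 redraws; increase meanLocationsPerGenotype or nGenotypes")
}

#' Simulate phenotypes for a sparse MET with known ground truth
#'
#' Per-location total marker effects are
#' \code{d_l * (sqrt(rho) * shared + sqrt(1 - rho) * specific_l)}, rescaled so
#' that the genotypic standard deviation at location l equals its
#' discriminativeness \code{d_l}. Each phenotype record is location mean +
#' genetic value + year effect + Gaussian residual. The residual variance is
#' back-solved from the target broad-sense heritability
#' \code{h2 = sigma_g2 / (sigma_g2 + sigma_year2 + sigma_e2)}, i.e.
#' \code{sigma_e2 = sigma_g2 (1 - h2) / h2 - sigma_year2}, floored at 1e-8
#' with a warning when the year variance alone already exceeds the implied
#' non-genetic variance.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param genotypes a \linkS4class{MarkerMatrix} consistent with the config
#'   (defaults to a panel generated from the config).
#' @param design optional trial design from \code{\link{makeDesign}}.
#' @param trait trait label for the phenotype records.
#' @return list with elements \code{phenotypes} (\linkS4class{PhenotypeTable})
#'   and \code{truth} (\linkS4class{GroundTruth}).
#' @examples
#' cfg <- syntheticConfig(nGenotypes = 30, nMarkers = 20, nLocations = 3,
#'                        nYears = 3, meanLocationsPerGenotype = 3)
#' met <- generateMET(cfg)
#' met$phenotypes
#' @export
generateMET <- function(config, genotypes = NULL, design = NULL,
                        trait = "trait") {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  if (is.null(genotypes))
    genotypes <- generateGenotypes(config@nGenotypes, config@nMarkers,
                                   config@mafRange, seed = config@seed)
  X <- dosages(genotypes)
  if (nrow(X) != config@nGenotypes || ncol(X) != config@nMarkers)
    stop("genotype matrix dimensions do not match the config")
  if (is.null(design)) design <- makeDesign(config)

  locs <- configLocations(config)
  L <- config@nLocations
  p <- config@nMarkers
  rho <- config@envCorrelation
  h2 <- config@h2ByLocation
  disc <- config@discByLocation

  set.seed(config@seed + 2L)
  shared <- rnorm(p)
  specific <- matrix(rnorm(L * p), L, p, dimnames = list(locs, colnames(X)))
  locationMeans <- setNames(rnorm(L, 0, 1), locs)
  yearEffects <- matrix(rnorm(L * config@nYears, 0, config@yearEffectSd),
                        L, config@nYears,
                        dimnames = list(locs, as.character(seq_len(config@nYears))))

  effects <- matrix(0, L, p, dimnames = dimnames(specific))
  gval <- matrix(0, nrow(X), L, dimnames = list(rownames(X), locs))
  sigmaE2 <- setNames(numeric(L), locs)
  for (l in seq_len(L)) {
    raw <- sqrt(rho) * shared + sqrt(1 - rho) * specific[l, ]
    g <- drop(X %*% raw)
    sdg <- sd(g)
    scaleL <- if (sdg > 0) disc[l] / sdg else 0
    effects[l, ] <- raw * scaleL
    gval[, l] <- drop(X %*% effects[l, ])
    sg2 <- disc[l]^2
    if (h2[l] == 0) {
      if (sg2 > 0)
        stop("location ", locs[l], ": target H2 = 0 with nonzero genetic ",
             "variance implies infinite residual variance")
      sigmaE2[l] <- 1
    } else if (h2[l] == 1) {
      if (config@yearEffectSd > 0)
        stop("location ", locs[l], ": target H2 = 1 requires zero year ",
             "effect variance")
      sigmaE2[l] <- 0
    } else {
      se2 <- sg2 * (1 - h2[l]) / h2[l] - config@yearEffectSd^2
      if (se2 < 1e-8) {
        warning("location ", locs[l], ": year variance exceeds the ",
                "non-genetic variance implied by the H2 target; residual ",
                "variance floored at 1e-8")
        se2 <- 1e-8
      }
      sigmaE2[l] <- se2
    }
  }

  n <- nrow(design)
  gIdx <- match(design$genotype_id, rownames(X))
  lIdx <- match(design$location, locs)
  gv <- gval[cbind(gIdx, lIdx)]
  ye <- yearEffects[cbind(lIdx, design$year)]
  resid <- rnorm(n, 0, sqrt(sigmaE2[lIdx]))
  value <- locationMeans[lIdx] + gv + ye + resid

  phen <- PhenotypeTable(data.frame(
    genotype_id = design$genotype_id, location = design$location,
    year = design$year, trait = trait, value = value,
    stringsAsFactors = FALSE))
  truth <- new("GroundTruth",
               sharedEffects = shared, locationEffects = effects,
               locationMeans = locationMeans, yearEffects = yearEffects,
               trueGeneticValues = gval,
               records = data.frame(
                 genotype_id = design$genotype_id, location = design$location,
                 year = design$year, genetic_value = gv, year_effect = ye,
                 residual = resid, stringsAsFactors = FALSE))
  list(phenotypes = phen, truth = truth)
}
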