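# Per-location mixed models: genotype BLUEs adjusted for random year
# effects, REML variance components, broad-sense heritability.
#
# Two companion fits per location: genotype fixed + year random for the
# BLUEs (adjusted means), and genotype random + year random for the variance
# components, since a fixed effect carries no variance component.

#' Broad-sense heritability from variance components
#'
#' \code{H2 = sigma_g2 / (sigma_g2 + sigma_i2 + sigma_e2)}, where
#' \code{sigma_i2} is the within-location year variance.
#'
#' @param sigma_g2,sigma_i2,sigma_e2 nonnegative variance components.
#' @return Heritability in [0, 1].
#' @examples
#' heritability(1, 1, 2)  # 0.25
#' @export
heritability <- function(sigma_g2, sigma_i2, sigma_e2) {
  stopifnot(sigma_g2 >= 0, sigma_i2 >= 0, sigma_e2 >= 0)
  tot <- sigma_g2 + sigma_i2 + sigma_e2
  if (tot == 0) stop("all variance components are zero; H2 undefined")
  sigma_g2 / tot
}

#' Phenotypic variance of a location's BLUEs
#'
#' Sample variance (n - 1 denominator) of the genotype BLUEs at one
#' location.
#'
#' @param x numeric vector of BLUEs, length >= 2.
#' @return Sample variance.
#' @export
phenotypicVariance <- function(x) {
  if (length(x) < 2) stop("need at least 2 BLUEs")
  var(x)
}

#' Fit the per-location genotype/year model
#'
#' For records of a single location and trait, fits (i) genotype fixed +
#' year random by REML to obtain genotype BLUEs as adjusted means on the
#' grand-mean-plus-genotype-effect scale, and (ii) genotype random + year
#' random by REML for the variance components. With a single year (or a
#' single record per genotype) the year component is fixed at zero. REML
#' variance estimates at the zero boundary are reported as 0.
#'
#' @param records data.frame slice with columns \code{genotype_id},
#'   \code{year}, \code{value} (one location, one trait).
#' @return list with \code{blues} (named numeric per genotype),
#'   \code{sigma_g2}, \code{sigma_i2}, \code{sigma_e2}, \code{h2},
#'   \code{phenotypic_variance}, \code{n_genotypes}, \code{n_years}.
#' @export
fitLocationModel <- function(records) {
  stopifnot(all(c("genotype_id", "year", "value") %in% names(records)))
  records$genotype_id <- factor(records$genotype_id)
  records$year <- factor(records$year)
  nGeno <- nlevels(records$genotype_id)
  nYears <- nlevels(records$year)
  if (nGeno < 2) stop("need >= 2 genotypes to fit the location model")

  # (i) BLUEs: genotype fixed, year random (plain genotype means when only
  # one year is present)
  if (nYears > 1) {
    fitB <- suppressMessages(suppressWarnings(
      lme4::lmer(value ~ 0 + genotype_id + (1 | year), data = records,
                 REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    fe <- lme4::fixef(fitB)
    blueVals <- setNames(as.numeric(fe),
                         sub("^genotype_id", "", names(fe)))
  } else {
    blueVals <- tapply(records$value, records$genotype_id, mean)
    blueVals <- setNames(as.numeric(blueVals), names(blueVals))
  }
  blueVals <- blueVals[levels(records$genotype_id)]

  # (ii) variance components: genotype random (+ year random if estimable)
  replicated <- nrow(records) > nGeno
  if (nYears > 1) {
    fitV <- suppressMessages(suppressWarnings(
      lme4::lmer(value ~ 1 + (1 | genotype_id) + (1 | year), data = records,
                 REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    vc <- as.data.frame(lme4::VarCorr(fitV))
    sigma_g2 <- vc$vcov[vc$grp == "genotype_id"]
    sigma_i2 <- vc$vcov[vc$grp == "year"]
    sigma_e2 <- vc$vcov[vc$grp == "Residual"]
  } else if (replicated) {
    fitV <- suppressMessages(suppressWarnings(
      lme4::lmer(value ~ 1 + (1 | genotype_id), data = records, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    vc <- as.data.frame(lme4::VarCorr(fitV))
    sigma_g2 <- vc$vcov[vc$grp == "genotype_id"]
    sigma_i2 <- 0
    sigma_e2 <- vc$vcov[vc$grp == "Residual"]
  } else {
    # one record per genotype in a single year: genotypic and residual
    # variance are confounded; attribute the spread to genotypes
    warning("single unreplicated year: sigma_g2 and sigma_e2 are ",
            "confounded; reporting the sample variance as sigma_g2")
    sigma_g2 <- var(records$value)
    sigma_i2 <- 0
    sigma_e2 <- 0
  }
  sigma_g2 <- max(sigma_g2, 0)
  sigma_i2 <- max(sigma_i2, 0)
  sigma_e2 <- max(sigma_e2, 0)
  h2 <- if (sigma_g2 + sigma_i2 + sigma_e2 == 0) 0
        else heritability(sigma_g2, sigma_i2, sigma_e2)

  list(blues = blueVals, sigma_g2 = sigma_g2, sigma_i2 = sigma_i2,
       sigma_e2 = sigma_e2, h2 = h2,
       phenotypic_variance = phenotypicVariance(blueVals),
       n_genotypes = nGeno, n_years = nYears)
}

#' Compute per-location BLUEs and heritabilities for a trait
#'
#' Applies \code{\link{fitLocationModel}} to every location with at least
#' two genotypes (others are dropped with a warning).
#'
#' @param phenotypes a \linkS4class{PhenotypeTable}.
#' @param trait trait name present in the table.
#' @return A \linkS4class{BLUETable}.
#' @examples
#' cfg <- syntheticConfig(nGenotypes = 25, nMarkers = 15, nLocations = 3,
#'                        nYears = 3, meanLocationsPerGenotype = 3)
#' met <- generateMET(cfg)
#' computeBLUEs(met$phenotypes, "trait")
#' @export
computeBLUEs <- function(phenotypes, trait) {
  stopifnot(is(phenotypes, "PhenotypeTable"))
  rec <- phenoRecords(phenotypes)
  rec <- rec[rec$trait == trait, , drop = FALSE]
  if (!nrow(rec)) stop("trait '", trait, "' absent from the phenotype table")
  blueRows <- list(); compRows <- list()
  for (loc in sort(unique(rec$location))) {
    slice <- rec[rec$location == loc, , drop = FALSE]
    if (length(unique(slice$genotype_id)) < 2) {
      warning("location '", loc, "' has fewer than 2 genotypes; dropped")
      next
    }
    fit <- fitLocationModel(slice)
    blueRows[[loc]] <- data.frame(
      location = loc, genotype_id = names(fit$blues), trait = trait,
      blue = as.numeric(fit$blues), stringsAsFactors = FALSE)
    compRows[[loc]] <- data.frame(
      location = loc, trait = trait, sigma_g2 = fit$sigma_g2,
      sigma_i2 = fit$sigma_i2, sigma_e2 = fit$sigma_e2, h2 = fit$h2,
      phenotypic_variance = fit$phenotypic_variance,
      n_genotypes = fit$n_genotypes, n_years = fit$n_years,
      stringsAsFactors = FALSE)
  }
  if (!length(blueRows)) stop("no location with >= 2 genotypes")
  bl <- do.call(rbind, blueRows); rownames(bl) <- NULL
  cp <- do.call(rbind, compRows); rownames(cp) <- NULL
  new("BLUETable", blues = bl, components = cp)
}
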