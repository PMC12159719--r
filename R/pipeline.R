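# End-to-end orchestration: simulate (or read) -> MAF filter -> PCA feature
# selection -> per-location BLUEs -> leave-one-location-out CV -> GGE ->
# threshold statistic, with every table written as CSV under a deterministic
# directory layout and every seed logged.

.logLine <- function(log, ...) {
  cat(paste0(..., "\n"), file = log, append = TRUE)
}

#' Run the full environment-ensemble prediction pipeline
#'
#' Either simulates a synthetic MET from \code{config} or reads genotype /
#' phenotype files, then runs preprocessing, BLUE estimation,
#' leave-one-location-out cross-validation over the requested approaches
#' and base learners, the GGE analysis, and the variance-threshold
#' statistic. Outputs go to \code{outDir}: \code{blues/}, \code{cv_results/},
#' \code{gge/}, \code{manifests/} and \code{log.txt}. Reruns with the same
#' configuration and seed produce identical CSVs.
#'
#' @param outDir output directory (created; must be writable).
#' @param config optional \linkS4class{SyntheticConfig}; when given, the
#'   trial is simulated and the truth sidecars are written.
#' @param genotypeFile,phenotypeFile input paths used when \code{config} is
#'   NULL.
#' @param traits trait names to analyse (default: all in the phenotypes).
#' @param approaches,bases passed to \code{\link{looLocationCV}}.
#' @param mafThreshold minor-allele-frequency filter threshold.
#' @param nComponents number of PCA-selected SNPs (default: observation
#'   limit, min(n genotypes - 1, n SNPs)).
#' @param validationMode "holdout" or "leaky" for ensemble
#'   optimization.
#' @param tuningDraws network random-search size per fold (300 reproduces
#'   the full search; the default 30 keeps desk-scale runs fast).
#' @param bagSubmodels bagged network ensemble size.
#' @param seed integer master seed.
#' @return invisibly, a list with the per-trait \code{cv} tables,
#'   \code{blues}, \code{gge} results and the threshold statistic.
#' @export
runPipeline <- function(outDir, config = NULL, genotypeFile = NULL,
                        phenotypeFile = NULL, traits = NULL,
                        approaches = c("singular", "ensemble", "optimized"),
                        bases = c("linear", "ridge"),
                        mafThreshold = 0.05, nComponents = NULL,
                        validationMode = "holdout", tuningDraws = 30,
                        bagSubmodels = 5L, seed = 1L) {
  if (!length(approaches)) stop("at least one approach required")
  if (!length(bases)) stop("at least one base learner required")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (sub in c("blues", "cv_results", "gge", "manifests"))
    dir.create(file.path(outDir, sub), showWarnings = FALSE)
  log <- file.path(outDir, "log.txt")
  cat("", file = log)
  .logLine(log, "master seed: ", seed)

  if (!is.null(config)) {
    stopifnot(is(config, "SyntheticConfig"))
    .logLine(log, "stage simulate: seed ", config@seed)
    markers <- generateGenotypes(config@nGenotypes, config@nMarkers,
                                 config@mafRange, seed = config@seed)
    met <- generateMET(config, markers)
    phen <- met$phenotypes
    writeGenotypes(markers, file.path(outDir, "genotypes.tsv"))
    writePhenotypes(phen, file.path(outDir, "phenotypes.csv"))
    writeGroundTruth(met$truth, file.path(outDir, "manifests"))
  } else {
    if (is.null(genotypeFile) || is.null(phenotypeFile))
      stop("either a synthetic config or genotype + phenotype files required")
    .logLine(log, "stage ingest: ", genotypeFile, " + ", phenotypeFile)
    markers <- readGenotypes(genotypeFile)
    phen <- readPhenotypes(phenotypeFile, markers)
  }
  if (is.null(traits)) traits <- sort(unique(phenoRecords(phen)$trait))
  if (!length(traits)) stop("no trait to analyse")

  .logLine(log, "stage maf_filter: threshold ", mafThreshold)
  filtered <- filterMAF(markers, mafThreshold)
  .logLine(log, "  retained ", ncol(dosages(filtered)), " of ",
           ncol(dosages(markers)), " SNPs")

  results <- list()
  for (trait in traits) {
    .logLine(log, "trait ", trait)
    withCallingHandlers({
      bl <- computeBLUEs(phen, trait)
    }, warning = function(w) {
      .logLine(log, "  [warn] ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    writeBLUETable(bl,
                   file.path(outDir, "blues", paste0(trait, "_blues.csv")),
                   file.path(outDir, "blues", paste0(trait, "_components.csv")))

    # feature selection re-run independently per trait
    nc <- nComponents %||% min(nrow(dosages(filtered)) - 1L,
                               ncol(dosages(filtered)))
    selected <- pcaFeatureSelect(filtered, nc)
    writeLines(selected,
               file.path(outDir, "manifests", paste0(trait, "_selected_snps.txt")))
    .logLine(log, "  selected ", length(selected), " SNPs by PCA")

    ds <- assembleDataset(filtered, bl, trait, selected)
    .logLine(log, "  cv over ", length(datasetLocations(ds)),
             " locations; approaches ", paste(approaches, collapse = ","),
             "; bases ", paste(bases, collapse = ","),
             "; validation mode ", validationMode)
    cv <- looLocationCV(ds, approaches = approaches, bases = bases,
                        seed = seed, bluesTable = bl,
                        validationMode = validationMode,
                        tuningDraws = tuningDraws,
                        bagSubmodels = bagSubmodels)
    write.csv(cvResults(cv),
              file.path(outDir, "cv_results", paste0(trait, "_cv.csv")),
              row.names = FALSE, quote = FALSE)

    gge <- ggeAnalysis(bl, trait)
    stats <- envVectorStats(gge)
    scoreDf <- data.frame(environment = rownames(gge@environmentScores),
                          pc1 = gge@environmentScores[, 1],
                          pc2 = gge@environmentScores[, 2],
                          vector_length = stats$lengths)
    write.csv(scoreDf,
              file.path(outDir, "gge", paste0(trait, "_env_scores.csv")),
              row.names = FALSE, quote = FALSE)
    write.csv(data.frame(environment = rownames(stats$cosines),
                         stats$cosines, check.names = FALSE),
              file.path(outDir, "gge", paste0(trait, "_env_cosines.csv")),
              row.names = FALSE, quote = FALSE)
    .logLine(log, sprintf("  gge: PC1+PC2 = %.1f%% of G+GxE, fill %.3f",
                          100 * sum(gge@pcVarianceFractions[1:2]),
                          gge@fillFraction))
    results[[trait]] <- list(blues = bl, cv = cv, gge = gge)
  }

  allCv <- do.call(rbind, lapply(results, function(r) cvResults(r$cv)))
  thr <- NULL
  if (all(c("ensemble", "singular") %in% allCv$approach)) {
    thr <- tryCatch(varianceThresholdStat(allCv), error = function(e) {
      .logLine(log, "  [warn] threshold statistic: ", conditionMessage(e))
      NULL
    })
    if (!is.null(thr)) {
      write.csv(thr$perCombination,
                file.path(outDir, "cv_results", "variance_threshold.csv"),
                row.names = FALSE, quote = FALSE)
      .logLine(log, sprintf("threshold statistic: mean %.2f%% of max variance",
                            thr$mean_proportion_pct))
    }
  }
  invisible(list(traits = results, threshold = thr, outDir = outDir))
}
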