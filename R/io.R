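# Plain-text readers/writers for the two tabular inputs and the ground-truth
# sidecars. All numeric output is written in full double precision with a
# locale-independent decimal point.

#' Write a genotype matrix to TSV
#'
#' Layout: a `genotype_id` column followed by one integer column per SNP id.
#'
#' @param markers a \linkS4class{MarkerMatrix}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGenotypes <- function(markers, path) {
  stopifnot(is(markers, "MarkerMatrix"))
  d <- dosages(markers)
  df <- data.frame(genotype_id = rownames(d), d, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a genotype TSV
#'
#' Rejects duplicate genotype or SNP ids, missing values, and any dosage
#' outside \{0, 1, 2\}, naming the offending cell.
#'
#' @param path TSV written in the \code{\link{writeGenotypes}} layout.
#' @return A \linkS4class{MarkerMatrix}.
#' @export
readGenotypes <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "genotype_id")
    stop("genotype file must start with a 'genotype_id' column")
  ids <- as.character(df$genotype_id)
  if (anyDuplicated(ids))
    stop("duplicate genotype ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stop("duplicate SNP ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (!is.numeric(m)) stop("non-numeric dosage values in ", path)
  bad <- which(is.na(m) | !(m %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad))
    stop("invalid dosage at genotype '", ids[bad[1, 1]], "', SNP '",
         colnames(m)[bad[1, 2]], "': ", m[bad[1, , drop = FALSE]],
         " (must be 0, 1 or 2)")
  rownames(m) <- ids
  MarkerMatrix(m)
}

#' Write phenotype records to CSV
#'
#' Header: \code{genotype_id,location,year,trait,value}.
#'
#' @param phenotypes a \linkS4class{PhenotypeTable}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePhenotypes <- function(phenotypes, path) {
  stopifnot(is(phenotypes, "PhenotypeTable"))
  rec <- phenoRecords(phenotypes)
  # %.17g round-trips doubles exactly, so re-ingested runs are bit-identical
  rec$value <- sprintf("%.17g", rec$value)
  write.csv(rec, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a phenotype CSV
#'
#' @param path CSV with header \code{genotype_id,location,year,trait,value}.
#' @param markers optional \linkS4class{MarkerMatrix}; when given, phenotype
#'   rows referencing genotypes absent from the marker panel are an error
#'   (the orphan ids are listed).
#' @return A \linkS4class{PhenotypeTable}.
#' @export
readPhenotypes <- function(path, markers = NULL) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("genotype_id", "location", "year", "trait", "value")
  if (!all(need %in% names(df)))
    stop("phenotype file missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (!is.numeric(df$value))
    stop("phenotype 'value' column must be numeric")
  if (anyNA(df$value))
    stop("missing phenotype values at rows: ",
         paste(head(which(is.na(df$value)), 5), collapse = ", "))
  if (!is.null(markers)) {
    orphans <- setdiff(unique(df$genotype_id), genotypeIds(markers))
    if (length(orphans))
      stop("phenotype rows reference genotypes absent from the marker ",
           "panel: ", paste(orphans, collapse = ", "))
  }
  PhenotypeTable(df)
}

#' Write ground-truth sidecar CSVs
#'
#' Emits \code{truth_records.csv} (per-record decomposition),
#' \code{truth_genetic_values.csv}, \code{truth_location_effects.csv} and
#' \code{truth_year_effects.csv} into \code{dir}.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeGroundTruth <- function(truth, dir) {
  stopifnot(is(truth, "GroundTruth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(truth@records, file.path(dir, "truth_records.csv"),
            row.names = FALSE, quote = FALSE)
  gv <- data.frame(genotype_id = rownames(truth@trueGeneticValues),
                   truth@trueGeneticValues, check.names = FALSE)
  write.csv(gv, file.path(dir, "truth_genetic_values.csv"),
            row.names = FALSE, quote = FALSE)
  le <- data.frame(location = rownames(truth@locationEffects),
                   location_mean = truth@locationMeans[rownames(truth@locationEffects)],
                   truth@locationEffects, check.names = FALSE)
  write.csv(le, file.path(dir, "truth_location_effects.csv"),
            row.names = FALSE, quote = FALSE)
  ye <- data.frame(location = rownames(truth@yearEffects),
                   truth@yearEffects, check.names = FALSE)
  write.csv(ye, file.path(dir, "truth_year_effects.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Write a BLUETable to CSV files
#'
#' @param x a \linkS4class{BLUETable}.
#' @param bluesPath CSV path for the per-genotype BLUEs
#'   (\code{location,genotype_id,trait,blue}).
#' @param componentsPath CSV path for the per-location variance components.
#' @return invisibly, the two paths.
#' @export
writeBLUETable <- function(x, bluesPath, componentsPath) {
  stopifnot(is(x, "BLUETable"))
  write.csv(blues(x), bluesPath, row.names = FALSE, quote = FALSE)
  write.csv(varianceComponents(x), componentsPath, row.names = FALSE,
            quote = FALSE)
  invisible(c(bluesPath, componentsPath))
}
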