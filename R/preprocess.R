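# Marker preprocessing: minor-allele-frequency filter, PCA-based feature
# selection, and assembly of per-location modeling blocks.

#' Filter SNPs by minor-allele frequency
#'
#' Retains exactly the columns whose minor-allele frequency is strictly
#' greater than \code{threshold}, where \code{MAF = min(f, 1 - f)} and
#' \code{f} is the mean dosage divided by two.
#'
#' @param markers a \linkS4class{MarkerMatrix}.
#' @param threshold frequency in [0, 0.5].
#' @return A \linkS4class{MarkerMatrix} with the retained columns. Filtering
#'   is idempotent.
#' @examples
#' gen <- generateGenotypes(50, 30, c(0.02, 0.5), seed = 2)
#' filterMAF(gen, 0.05)
#' @export
filterMAF <- function(markers, threshold = 0.05) {
  stopifnot(is(markers, "MarkerMatrix"),
            threshold >= 0, threshold <= 0.5)
  d <- dosages(markers)
  f <- colSums(d) / (2 * nrow(d))
  keep <- pmin(f, 1 - f) > threshold
  if (!any(keep))
    stop("no SNP passes the MAF threshold ", threshold)
  MarkerMatrix(d[, keep, drop = FALSE])
}

#' PCA-based SNP feature selection
#'
#' Mean-centers the dosage columns (no unit-variance scaling, so
#' allele-frequency-driven variance weighting is preserved), ranks principal
#' components by eigenvalue, and maps each of the top \code{nComponents}
#' eigenvectors to one SNP: the SNP with the largest absolute loading on
#' that component not already selected, walking down the component's
#' |loading| ranking on collision. Ties in |loading| break lexicographically
#' by SNP id, making the selection invariant to column order.
#'
#' @param markers a \linkS4class{MarkerMatrix}.
#' @param nComponents number of SNPs to select; at most
#'   \code{min(n genotypes, n SNPs)}. Defaults to
#'   \code{min(n genotypes - 1, n SNPs)}, the observation-limited component
#'   count.
#' @return Character vector of the selected SNP ids, in selection order.
#' @examples
#' gen <- generateGenotypes(30, 12, c(0.1, 0.5), seed = 3)
#' pcaFeatureSelect(gen, 4)
#' @export
pcaFeatureSelect <- function(markers, nComponents = NULL) {
  stopifnot(is(markers, "MarkerMatrix"))
  X <- dosages(markers)
  n <- nrow(X); p <- ncol(X)
  if (is.null(nComponents)) nComponents <- min(n - 1L, p)
  if (nComponents < 1 || nComponents > min(n, p))
    stop("nComponents must satisfy 1 <= nComponents <= min(n genotypes, ",
         "n SNPs) = ", min(n, p))
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0)          # right singular vectors = PC loadings
  snps <- colnames(X)
  selected <- character(0)
  for (comp in seq_len(nComponents)) {
    # quantize |loadings| so algebraically tied loadings (e.g. duplicated
    # columns) compare equal despite floating-point noise
    load <- round(abs(sv$v[, comp]), 9)
    ord <- order(-load, snps)    # |loading| desc, snp id asc on ties
    pick <- snps[ord][!snps[ord] %in% selected][1]
    selected <- c(selected, pick)
  }
  selected
}

#' Assemble per-location modeling blocks for one trait
#'
#' Joins genotype features (restricted to the selected SNPs) with the
#' per-location genotype BLUEs. Locations with fewer than two BLUEs are
#' dropped with a warning.
#'
#' @param markers a \linkS4class{MarkerMatrix}.
#' @param bluesTable a \linkS4class{BLUETable}.
#' @param trait trait name present in the BLUE table.
#' @param selectedSnps character vector of SNP ids to use as features
#'   (defaults to all).
#' @return A \linkS4class{ModelingDataset}.
#' @export
assembleDataset <- function(markers, bluesTable, trait,
                            selectedSnps = snpIds(markers)) {
  stopifnot(is(markers, "MarkerMatrix"), is(bluesTable, "BLUETable"))
  b <- blues(bluesTable)
  b <- b[b$trait == trait, , drop = FALSE]
  if (!nrow(b)) stop("trait '", trait, "' absent from the BLUE table")
  missingSnps <- setdiff(selectedSnps, snpIds(markers))
  if (length(missingSnps))
    stop("selected SNPs not in the marker matrix: ",
         paste(head(missingSnps, 5), collapse = ", "))
  X <- dosages(markers)[, selectedSnps, drop = FALSE]
  blocks <- list()
  for (loc in unique(b$location)) {
    bl <- b[b$location == loc, , drop = FALSE]
    known <- bl$genotype_id %in% rownames(X)
    if (!all(known))
      stop("location '", loc, "': BLUEs for genotypes missing from the ",
           "marker panel: ", paste(head(bl$genotype_id[!known], 5), collapse = ", "))
    if (nrow(bl) < 2) {
      warning("location '", loc, "' has fewer than 2 BLUEs; dropped")
      next
    }
    blocks[[loc]] <- list(
      X = X[bl$genotype_id, , drop = FALSE],
      y = setNames(bl$blue, bl$genotype_id),
      genotype_ids = bl$genotype_id)
  }
  if (!length(blocks)) stop("no location retained >= 2 BLUEs")
  new("ModelingDataset", trait = trait, blocks = blocks,
      selectedSnpIds = selectedSnps)
}
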