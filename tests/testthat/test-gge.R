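mkBlueTable <- function(m, trait = "t") {
  df <- expand.grid(genotype_id = rownames(m), location = colnames(m),
                    stringsAsFactors = FALSE)
  df$trait <- trait
  df$blue <- m[cbind(df$genotype_id, df$location)]
  df <- df[!is.na(df$blue), c("location", "genotype_id", "trait", "blue")]
  new("BLUETable", blues = df, components = data.frame())
}

test_that("cell matrix construction fills missing cells with the env mean", {
  set.seed(51)
  m <- matrix(rnorm(20), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("E", 1:4)))
  bt <- mkBlueTable(m)
  cm <- buildGEMatrix(bt, "t")
  expect_equal(attr(cm, "fillFraction"), 0)
  attr(cm, "fillFraction") <- NULL
  expect_equal(cm, m[rownames(cm), colnames(cm)])
  # knock out one cell: filled with the environment mean, centered value 0
  m2 <- m; m2["g2", "E3"] <- NA
  cm2 <- buildGEMatrix(mkBlueTable(m2), "t")
  expect_equal(attr(cm2, "fillFraction"), 1 / 20)
  expect_equal(cm2["g2", "E3"], mean(m2[-2, "E3"]))
  cc <- centerEnvironments(`attr<-`(cm2, "fillFraction", NULL))
  expect_lt(abs(cc["g2", "E3"]), 1e-10)
  # duplicate BLUEs violate the table invariant upstream
  dup <- blues(bt)
  expect_error(new("BLUETable", blues = rbind(dup, dup[1, ]),
                   components = data.frame()), "more than one BLUE")
})

test_that("environment centering is exact, idempotent and shift-invariant", {
  set.seed(52)
  m <- matrix(rnorm(30), 6, 5)
  cc <- centerEnvironments(m)
  expect_lt(max(abs(colMeans(cc))), 1e-10)
  expect_equal(centerEnvironments(cc), cc, tolerance = 1e-12)
  shifted <- m; shifted[, 2] <- shifted[, 2] + 100
  expect_equal(centerEnvironments(shifted), cc, tolerance = 1e-10)
})

test_that("GGE scores reconstruct the matrix and match the eigen oracle", {
  set.seed(53)
  # exact rank-2 matrix
  A <- matrix(rnorm(14), 7, 2) %*% matrix(rnorm(8), 2, 4)
  dimnames(A) <- list(paste0("g", 1:7), paste0("E", 1:4))
  cc <- centerEnvironments(A)
  for (svp in c("environment", "genotype")) {
    g <- ggeSVD(cc, svp = svp)
    recon <- if (svp == "environment")
      g@genotypeScores[, 1:2] %*% t(g@environmentScores[, 1:2])
    else
      g@genotypeScores[, 1:2] %*% t(g@environmentScores[, 1:2])
    expect_lt(max(abs(recon - cc)), 1e-10)
    # SVP never changes the underlying factorization
    expect_lt(max(abs(g@svdU %*% diag(g@svdD) %*% t(g@svdV) - cc)), 1e-10)
  }
  # full-rank environment-score inner products = centered cross-products
  set.seed(54)
  B <- matrix(rnorm(48), 12, 4,
              dimnames = list(paste0("g", 1:12), paste0("E", 1:4)))
  ccB <- centerEnvironments(B)
  gB <- ggeSVD(ccB)
  full <- gB@svdV %*% diag(gB@svdD)
  expect_lt(max(abs(tcrossprod(full) - crossprod(ccB))), 1e-8)
  # singular values match an independent eigen-decomposition of X'X
  ev <- sort(eigen(crossprod(ccB), symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(gB@svdD^2, ev, tolerance = 1e-8)
  expect_true(all(diff(gB@svdD) <= 1e-12))
  # sign convention: largest-magnitude environment loading positive
  for (k in seq_along(gB@svdD))
    expect_gte(gB@svdV[which.max(abs(gB@svdV[, k])), k], 0)
  expect_error(ggeSVD(matrix(0, 3, 3)), "all-zero")
})

test_that("environment vectors read as discriminativeness and correlation", {
  set.seed(55)
  g <- rnorm(10)
  # proportional columns (same sign): cosine ~ 1
  m <- cbind(E1 = 2 * g, E2 = 5 * g, E3 = rnorm(10))
  rownames(m) <- paste0("g", 1:10)
  gg <- ggeSVD(centerEnvironments(m))
  st <- envVectorStats(gg)
  expect_gt(st$cosines["E1", "E2"], 0.999)
  # negating a column flips its cosines
  m2 <- m; m2[, "E1"] <- -m2[, "E1"]
  st2 <- envVectorStats(ggeSVD(centerEnvironments(m2)))
  expect_equal(st2$cosines["E1", "E2"], -st$cosines["E1", "E2"],
               tolerance = 1e-8)
  expect_equal(st2$cosines["E2", "E3"], st$cosines["E2", "E3"],
               tolerance = 1e-8)
  # rank-2 data: vector-length order equals column-SD order
  A <- matrix(rnorm(18), 9, 2) %*% matrix(rnorm(10), 2, 5)
  dimnames(A) <- list(paste0("g", 1:9), paste0("E", 1:5))
  ggA <- ggeSVD(centerEnvironments(A))
  lens <- envVectorStats(ggA)$lengths
  sds <- apply(A, 2, sd)
  expect_equal(order(lens), order(sds))
  # genotype-focused results refuse environment-vector statistics
  expect_error(envVectorStats(ggeSVD(centerEnvironments(A), svp = "genotype")),
               "environment-focused")
})

test_that("more discriminative locations show longer environment vectors", {
  ranks <- vapply(1:20, function(s) {
    locs <- sprintf("L%02d", 1:5)
    disc <- setNames(c(0.5, 1, 2, 3.5, 5), locs)
    cfg <- syntheticConfig(nGenotypes = 35, nMarkers = 25, nLocations = 5,
                           nYears = 2, meanLocationsPerGenotype = 5,
                           discByLocation = disc,
                           h2ByLocation = setNames(rep(0.8, 5), locs),
                           seed = s)
    met <- generateMET(cfg)
    bl <- suppressWarnings(computeBLUEs(met$phenotypes, "trait"))
    gg <- ggeAnalysis(bl, "trait")
    cor(rank(disc[names(gg@envVectorLengths)]), rank(gg@envVectorLengths))
  }, numeric(1))
  expect_gt(mean(ranks), 0.8)
})
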