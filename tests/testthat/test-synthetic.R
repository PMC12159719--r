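test_that("genotype generation is reproducible and respects the dosage coding", {
  g1 <- generateGenotypes(40, 25, c(0.05, 0.5), seed = 11)
  g2 <- generateGenotypes(40, 25, c(0.05, 0.5), seed = 11)
  expect_identical(dosages(g1), dosages(g2))
  expect_true(all(dosages(g1) %in% c(0, 1, 2)))
  f <- colSums(dosages(g1)) / (2 * 40)
  expect_true(all(pmin(f, 1 - f) >= 0.05 / 2))
  expect_false(anyDuplicated(genotypeIds(g1)) > 0)
})

test_that("mean dosage is about 1 when the allele frequency is pinned at 0.5", {
  g <- generateGenotypes(600, 20, c(0.5, 0.5), seed = 2)
  expect_true(all(abs(colMeans(dosages(g)) - 1) < 0.15))
})

test_that("realized MAF distribution matches the uniform sampling oracle", {
  g <- generateGenotypes(300, 2000, c(0.05, 0.5), seed = 1)
  f <- colSums(dosages(g)) / (2 * 300)
  maf <- pmin(f, 1 - f)
  set.seed(42)
  oracle <- runif(20000, 0.05, 0.5)
  ks <- suppressWarnings(stats::ks.test(maf, oracle))
  expect_gt(ks$p.value, 0.01)
})

test_that("trial design honors sparsity targets and degenerate limits", {
  # complete-design limit
  cfg <- syntheticConfig(nGenotypes = 20, nMarkers = 5, nLocations = 4,
                         nYears = 3, meanLocationsPerGenotype = 4,
                         yearsPerGenotypeLocation = 2, seed = 3)
  d <- makeDesign(cfg)
  expect_equal(nrow(d), 20 * 4 * 2)
  # single-location degenerate case
  cfg1 <- syntheticConfig(nGenotypes = 10, nMarkers = 5, nLocations = 1,
                          nYears = 2, meanLocationsPerGenotype = 1,
                          yearsPerGenotypeLocation = 1, seed = 3)
  d1 <- makeDesign(cfg1)
  expect_equal(unique(d1$location), "L01")
  expect_equal(sort(unique(d1$genotype_id)), sprintf("G%04d", 1:10))
  # realized mean locations per genotype tracks the configured mean
  means <- vapply(1:10, function(s) {
    cfg <- syntheticConfig(nGenotypes = 120, nMarkers = 5, nLocations = 8,
                           nYears = 3, meanLocationsPerGenotype = 5,
                           yearsPerGenotypeLocation = 1, seed = s)
    d <- makeDesign(cfg)
    mean(tapply(d$location, d$genotype_id, function(x) length(unique(x))))
  }, numeric(1))
  expect_lt(abs(mean(means) - 5), 0.5)
})

test_that("phenotypes decompose exactly into the stored truth components", {
  m <- mkMET(nGeno = 25, nMark = 20, L = 3, seed = 7, meanLoc = 2)
  rec <- phenoRecords(m$phen)
  tr <- m$truth@records
  reconstructed <- m$truth@locationMeans[tr$location] + tr$genetic_value +
    tr$year_effect + tr$residual
  expect_lt(max(abs(rec$value - reconstructed)), 1e-10)
  # genetic values are exactly marker matrix times per-location effects
  g <- dosages(m$gen) %*% t(m$truth@locationEffects)
  expect_lt(max(abs(g - m$truth@trueGeneticValues)), 1e-10)
  # bitwise reproducibility
  m2 <- mkMET(nGeno = 25, nMark = 20, L = 3, seed = 7, meanLoc = 2)
  expect_identical(phenoRecords(m$phen), phenoRecords(m2$phen))
})

test_that("rho = 1 removes GxE and rho = 0 decorrelates locations", {
  locs <- sprintf("L%02d", 1:3)
  same <- setNames(rep(1, 3), locs)
  cfg1 <- syntheticConfig(nGenotypes = 30, nMarkers = 20, nLocations = 3,
                          nYears = 2, meanLocationsPerGenotype = 3,
                          discByLocation = same,
                          h2ByLocation = setNames(rep(0.5, 3), locs),
                          envCorrelation = 1, seed = 5)
  met1 <- generateMET(cfg1)
  gv <- met1$truth@trueGeneticValues
  expect_lt(max(abs(gv[, 1] - gv[, 2])), 1e-10)
  expect_lt(max(abs(gv[, 1] - gv[, 3])), 1e-10)

  cors <- vapply(1:20, function(s) {
    cfg0 <- syntheticConfig(nGenotypes = 40, nMarkers = 30, nLocations = 2,
                            nYears = 2, meanLocationsPerGenotype = 2,
                            discByLocation = setNames(rep(1, 2), c("L01", "L02")),
                            h2ByLocation = setNames(rep(0.5, 2), c("L01", "L02")),
                            envCorrelation = 0, seed = s)
    gv0 <- generateMET(cfg0)$truth@trueGeneticValues
    cor(gv0[, 1], gv0[, 2])
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.1)
})

test_that("raising a location's discriminativeness raises its genetic variance", {
  locs <- sprintf("L%02d", 1:3)
  base <- setNames(c(1, 1, 1), locs)
  up <- setNames(c(1, 2.5, 1), locs)
  h2 <- setNames(rep(0.5, 3), locs)
  cfgA <- syntheticConfig(nGenotypes = 40, nMarkers = 30, nLocations = 3,
                          nYears = 2, meanLocationsPerGenotype = 3,
                          discByLocation = base, h2ByLocation = h2, seed = 9)
  cfgB <- syntheticConfig(nGenotypes = 40, nMarkers = 30, nLocations = 3,
                          nYears = 2, meanLocationsPerGenotype = 3,
                          discByLocation = up, h2ByLocation = h2, seed = 9)
  vA <- var(generateMET(cfgA)$truth@trueGeneticValues[, 2])
  vB <- var(generateMET(cfgB)$truth@trueGeneticValues[, 2])
  expect_gt(vB, vA)
})

test_that("impossible heritability targets are rejected", {
  locs <- c("L01", "L02")
  mk <- function(h2, ysd) syntheticConfig(
    nGenotypes = 10, nMarkers = 5, nLocations = 2, nYears = 2,
    meanLocationsPerGenotype = 2,
    discByLocation = setNames(c(1, 1), locs),
    h2ByLocation = setNames(h2, locs), yearEffectSd = ysd, seed = 1)
  expect_error(generateMET(mk(c(0, 0.5), 0.1)), "H2 = 0")
  expect_error(generateMET(mk(c(1, 0.5), 0.1)), "H2 = 1")
  # H2 = 1 is fine without year effects: noise-free phenotypes
  met <- generateMET(mk(c(1, 1), 0))
  expect_lt(max(abs(met$truth@records$residual)), 1e-12)
})

test_that("configuration invariants are enforced", {
  expect_error(syntheticConfig(nGenotypes = 10, nMarkers = 5, nLocations = 4,
                               nYears = 2, meanLocationsPerGenotype = 9),
               "exceed")
  expect_error(syntheticConfig(nGenotypes = 10, nMarkers = 5, nLocations = 2,
                               nYears = 2, mafRange = c(0, 0.6)),
               "mafRange")
  expect_error(syntheticConfig(nGenotypes = 10, nMarkers = 5, nLocations = 2,
                               nYears = 2, envCorrelation = 1.2),
               "envCorrelation")
})
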