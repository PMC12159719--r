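test_that("ensemble prediction is the arithmetic mean of submodels", {
  set.seed(31)
  preds <- cbind(rnorm(6), rnorm(6), rnorm(6))
  em <- mkPredEnsemble(preds)
  X <- mkIdentityX(6)
  expect_equal(ensemblePredict(em, X), rowMeans(preds), tolerance = 1e-12)
  expect_equal(predict(em, X), rowMeans(preds), tolerance = 1e-12)
  # two submodels at 1 and 3 average to 2
  em2 <- mkPredEnsemble(cbind(rep(1, 4), rep(3, 4)))
  expect_equal(unname(ensemblePredict(em2, mkIdentityX(4))), rep(2, 4))
  # order symmetry
  emR <- new("EnsembleModel", submodels = rev(em@submodels),
             membership = rev(em@membership), approach = "ensemble")
  expect_equal(ensemblePredict(emR, X), ensemblePredict(em, X))
  # single submodel equals the base model
  em1 <- mkPredEnsemble(preds[, 1, drop = FALSE])
  expect_equal(ensemblePredict(em1, X), predict(em1@submodels[[1]], X))
})

test_that("singular training pools all non-test blocks and never sees the test", {
  ds <- mkDataset(locs = c("A", "B", "C"), seed = 32)
  em <- trainSingular(ds, "linear", testLocation = "B", seed = 1)
  expect_equal(length(submodels(em)), 1)
  expect_setequal(membership(em)[[1]], c("A", "C"))
  tb <- datasetBlocks(ds)$B
  expect_equal(length(predict(em, tb$X)), length(tb$y))
  # duplication invariance: two identical blocks give the one-block OLS fit
  dsDup <- mkDataset(locs = c("A", "B"), seed = 33, identicalBlocks = TRUE)
  pooled <- trainSingular(dsDup, "linear", testLocation = NULL, seed = 1)
  single <- fitOLS(datasetBlocks(dsDup)$A$X, datasetBlocks(dsDup)$A$y)
  expect_equal(pooled@submodels[[1]]@coefficients, single@coefficients,
               tolerance = 1e-8)
})

test_that("environment ensembles hold one submodel per training location", {
  ds <- mkDataset(locs = c("A", "B", "C", "D"), seed = 34)
  em <- trainEnsemble(ds, "linear", testLocation = "D", seed = 1)
  expect_equal(length(submodels(em)), 3)
  expect_setequal(unlist(membership(em)), c("A", "B", "C"))
  # identical blocks: ensemble equals singular for a linear base
  dsI <- mkDataset(locs = c("A", "B", "C"), seed = 35, identicalBlocks = TRUE)
  X <- datasetBlocks(dsI)$A$X
  pe <- predict(trainEnsemble(dsI, "linear", NULL, seed = 1), X)
  ps <- predict(trainSingular(dsI, "linear", NULL, seed = 1), X)
  expect_equal(pe, ps, tolerance = 1e-8)
})

test_that("bagged ensembles resample locations reproducibly", {
  ds <- mkDataset(locs = c("A", "B", "C", "D", "E"), seed = 36)
  b1 <- trainBaggedEnsemble(ds, "linear", nSubmodels = 4, testLocation = "E",
                            seed = 2)
  b2 <- trainBaggedEnsemble(ds, "linear", nSubmodels = 4, testLocation = "E",
                            seed = 2)
  expect_identical(membership(b1), membership(b2))
  expect_true(all(vapply(membership(b1), length, integer(1)) == 4))
  expect_false(all(vapply(membership(b1), function(m)
    identical(sort(unique(m)), c("A", "B", "C", "D")), logical(1))))
  # degenerate bagging with one training location
  dsAB <- mkDataset(locs = c("A", "B"), seed = 37)
  b3 <- trainBaggedEnsemble(dsAB, "linear", nSubmodels = 3,
                            testLocation = "B", seed = 2)
  expect_true(all(unlist(membership(b3)) == "A"))
  # bootstrap exclusion probability approaches (1 - 1/L)^L
  L <- 5
  set.seed(38)
  manyBags <- trainBaggedEnsemble(ds, "linear", nSubmodels = 60,
                                  testLocation = NULL, seed = 3)
  absent <- mean(vapply(membership(manyBags), function(m)
    mean(!c("A", "B", "C", "D", "E") %in% m), numeric(1)))
  expect_lt(abs(absent - (1 - 1 / L)^L), 0.06)
})

test_that("greedy dropout removes an adversarial submodel", {
  set.seed(39)
  y <- rnorm(50)
  preds <- cbind(y + rnorm(50, 0, 0.05),
                 y + rnorm(50, 0, 0.05),
                 -y + rnorm(50, 0, 0.05))
  full <- mkPredEnsemble(preds)
  opt <- optimizeEnsemble(full, mkIdentityX(50), y)
  expect_equal(which(opt$decisions$excluded), 3)
  expect_equal(length(submodels(opt$model)), 2)
  # survivors' fitted parameters are the very same objects
  expect_identical(opt$model@submodels[[1]], full@submodels[[1]])
  # optimized validation accuracy beats the full baseline here
  accOpt <- accuracy(y, predict(opt$model, mkIdentityX(50)))
  expect_gt(accOpt, opt$decisions$baseline_accuracy[1])
  # exhaustive subset search agrees on this construction
  k <- 3
  best <- NULL; bestAcc <- -Inf
  for (m in 1:(2^k - 1)) {
    idx <- which(bitwAnd(m, 2^(0:(k - 1))) > 0)
    a <- suppressWarnings(accuracy(y, rowMeans(preds[, idx, drop = FALSE])))
    if (!is.na(a) && a > bestAcc) { bestAcc <- a; best <- idx }
  }
  expect_equal(sort(which(!opt$decisions$excluded)), sort(best))
})

test_that("ties keep every identical submodel (strict-improvement rule)", {
  y <- c(1, 2, 3, 4, 5)
  preds <- cbind(y, y, y)
  full <- mkPredEnsemble(preds)
  opt <- optimizeEnsemble(full, mkIdentityX(5), y)
  expect_equal(length(submodels(opt$model)), 3)
  expect_false(any(opt$decisions$excluded))
})

test_that("optimization guards its inputs", {
  y <- rnorm(10)
  one <- mkPredEnsemble(matrix(y, ncol = 1))
  expect_error(optimizeEnsemble(one, mkIdentityX(10), y), ">= 2")
  two <- mkPredEnsemble(cbind(y, y))
  expect_error(
    suppressWarnings(optimizeEnsemble(two, mkIdentityX(10), rep(1, 10))),
    "enlarge the validation")
})

test_that("averaging reduces prediction variance across seeds", {
  # independent location-specific noise: ensemble predictions vary less
  # across seeds than single-location submodels do on average
  set.seed(40)
  X <- matrix(rbinom(30 * 5, 2, 0.5), 30, 5,
              dimnames = list(sprintf("G%03d", 1:30), paste0("s", 1:5)))
  beta <- rnorm(5)
  newX <- X[1:10, , drop = FALSE]
  ensP <- list(); subP <- list()
  for (s in 1:15) {
    set.seed(200 + s)
    blocks <- lapply(c(A = 1, B = 2, C = 3), function(i) {
      y <- drop(X %*% beta) + rnorm(30, 0, 1)
      list(X = X, y = setNames(y, rownames(X)), genotype_ids = rownames(X))
    })
    ds <- new("ModelingDataset", trait = "t", blocks = blocks,
              selectedSnpIds = colnames(X))
    em <- trainEnsemble(ds, "linear", NULL, seed = 1)
    ensP[[s]] <- predict(em, newX)
    subP[[s]] <- lapply(em@submodels, predict, newdata = newX)
  }
  ensVar <- mean(apply(do.call(rbind, ensP), 2, var))
  subVar <- mean(sapply(1:3, function(j)
    mean(apply(do.call(rbind, lapply(subP, `[[`, j)), 2, var))))
  expect_lt(ensVar, subVar)
})
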