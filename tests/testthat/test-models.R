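test_that("OLS interpolates exactly and handles degenerate responses", {
  X <- matrix(1:3, dimnames = list(NULL, "x"))
  m <- fitOLS(X, 2 * (1:3) + 1)
  expect_equal(m@intercept, 1, tolerance = 1e-10)
  expect_equal(unname(m@coefficients), 2, tolerance = 1e-10)
  # constant response: minimum-norm solution is the intercept alone
  mc <- fitOLS(matrix(rnorm(12), 4, 3), rep(5, 4))
  expect_equal(mc@intercept, 5, tolerance = 1e-10)
  expect_equal(max(abs(mc@coefficients)), 0, tolerance = 1e-10)
  expect_error(fitOLS(matrix(numeric(0), 0, 2), numeric(0)), "empty")
})

test_that("OLS matches the normal-equations oracle on full-rank systems", {
  set.seed(21)
  X <- matrix(rnorm(100), 20, 5, dimnames = list(NULL, paste0("s", 1:5)))
  y <- rnorm(20)
  m <- fitOLS(X, y)
  Z <- cbind(1, X)
  oracle <- solve(crossprod(Z), crossprod(Z, y))
  expect_equal(unname(c(m@intercept, m@coefficients)),
               unname(drop(oracle)), tolerance = 1e-8)
  # residual orthogonality to the column space
  r <- y - predict(m, X)
  expect_lt(max(abs(crossprod(Z, r))), 1e-6)
})

test_that("ridge reduces to OLS at zero penalty and to the mean at huge penalty", {
  set.seed(22)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("s", 1:3)))
  y <- rnorm(20)
  expect_equal(fitRidge(X, y, 0)@coefficients, fitOLS(X, y)@coefficients,
               tolerance = 1e-8)
  big <- fitRidge(X, y, 1e9)
  expect_lt(max(abs(big@coefficients)), 1e-6)
  expect_equal(unname(predict(big, X)), rep(mean(y), 20), tolerance = 1e-4)
  expect_error(fitRidge(X, y, -1), "nonnegative")
})

test_that("ridge matches the closed-form centered solution, including p > n", {
  set.seed(23)
  X <- matrix(rnorm(20 * 50), 20, 50, dimnames = list(NULL, paste0("s", 1:50)))
  y <- rnorm(20)
  lam <- 3.7
  m <- fitRidge(X, y, lam)
  Xc <- scale(X, scale = FALSE)
  beta <- solve(crossprod(Xc) + lam * diag(50), crossprod(Xc, y - mean(y)))
  expect_equal(unname(m@coefficients), unname(drop(beta)), tolerance = 1e-8)
})

test_that("ridge agrees with glmnet on its own objective scaling", {
  skip_if_not_installed("glmnet")
  set.seed(24)
  X <- matrix(rnorm(50 * 8), 50, 8, dimnames = list(NULL, paste0("s", 1:8)))
  y <- rnorm(50)
  lam <- 3.7
  ours <- fitRidge(X, y, lam)
  g <- glmnet::glmnet(X, y, alpha = 0, lambda = lam / 50,
                      standardize = FALSE, intercept = TRUE, thresh = 1e-14)
  expect_equal(unname(ours@coefficients), as.numeric(stats::coef(g))[-1],
               tolerance = 1e-2)
})

test_that("ridge coefficient norm is non-increasing in lambda", {
  set.seed(25)
  for (i in 1:20) {
    X <- matrix(rnorm(15 * 6), 15, 6, dimnames = list(NULL, paste0("s", 1:6)))
    y <- rnorm(15)
    norms <- vapply(c(0, 0.1, 1, 10, 100),
                    function(l) sqrt(sum(fitRidge(X, y, l)@coefficients^2)),
                    numeric(1))
    expect_true(all(diff(norms) <= 1e-10))
  }
})

test_that("linear prediction is plain arithmetic and checks dimensions", {
  m <- new("LinearModel", intercept = 1, coefficients = c(s1 = 2), lambda = 0)
  expect_equal(unname(predict(m, matrix(3))), 7)
  expect_error(predict(m, matrix(1, 1, 2)), "mismatch")
})

test_that("the early-stopping rule fires on a convex slowing loss tail", {
  expect_true(stoppingRuleFired(c(10.0, 9.8, 9.7)))
  expect_false(stoppingRuleFired(c(10.0, 9.8)))          # too short
  expect_false(stoppingRuleFired(c(10.0, 9.0, 7.5)))     # accelerating
  expect_false(stoppingRuleFired(c(10.0, 9.7, 9.8)))     # increasing tail
  expect_false(stoppingRuleFired(c(10.0, 4.0, 1.0)))     # big relative drop
})

test_that("network training is seeded, capped and better than the mean", {
  set.seed(1)
  X <- matrix(rnorm(40 * 5), 40, 5)
  y <- rnorm(40)
  hp <- new("NetworkHyperparams", learningRate = 5, batchSize = 4L,
            nLayers = 3L, layerWidth = 5L)
  n1 <- fitNetwork(X, y, hp, seed = 3)
  n2 <- fitNetwork(X, y, hp, seed = 3)
  expect_identical(n1@lossLog, n2@lossLog)
  expect_lte(length(n1@lossLog), 50)
  # a run where the stopping rule never fires hits the 50-epoch cap
  capped <- fitNetwork(X, y, hp, seed = 4)
  expect_equal(length(capped@lossLog), 50L)
  # linear signal: final training MSE beats the mean-only predictor
  hpFit <- new("NetworkHyperparams", learningRate = 0.01, batchSize = 8L,
               nLayers = 3L, layerWidth = 10L)
  wins <- vapply(1:5, function(s) {
    set.seed(100 + s)
    Xl <- matrix(rnorm(60 * 4), 60, 4)
    yl <- drop(Xl %*% c(1, -2, 0.5, 1)) + rnorm(60, 0, 0.2)
    nm <- fitNetwork(Xl, yl, hpFit, seed = s)
    nm@lossLog[length(nm@lossLog)] < mean((yl - mean(yl))^2)
  }, logical(1))
  expect_true(all(wins))
})

test_that("hand-built networks evaluate exactly as written", {
  relu1 <- new("NetworkModel",
               weights = list(matrix(1), matrix(1)),
               biases = list(0, 0), widths = c(1L, 1L, 1L),
               center = 0, scale = 1, lossLog = 0, hyperparams = NULL)
  x <- matrix(c(-2, -0.5, 0, 1.5))
  expect_equal(unname(predict(relu1, x)), pmax(x[, 1], 0))
  zero <- new("NetworkModel",
              weights = list(matrix(0, 2, 3), matrix(0, 3, 1)),
              biases = list(rep(0, 3), 0), widths = c(2L, 3L, 1L),
              center = c(0, 0), scale = c(1, 1), lossLog = 0,
              hyperparams = NULL)
  expect_equal(unname(predict(zero, matrix(rnorm(10), 5, 2))), rep(0, 5))
})

test_that("hyperparameter draws respect the stated bounds", {
  draws <- sampleHyperparams(500, seed = 6)
  lr <- vapply(draws, function(h) h@learningRate, numeric(1))
  bs <- vapply(draws, function(h) h@batchSize, integer(1))
  nl <- vapply(draws, function(h) h@nLayers, integer(1))
  lw <- vapply(draws, function(h) h@layerWidth, integer(1))
  expect_true(all(lr >= 1e-4 & lr <= 100))
  expect_true(all(bs %in% c(4L, 8L, 16L, 32L, 64L, 128L)))
  expect_true(all(nl >= 3 & nl <= 8))
  expect_true(all(lw >= 3 & lw <= 100))
})

test_that("tuning returns the single draw when there is only one", {
  set.seed(7)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- drop(X %*% rnorm(4)) + rnorm(30, 0, 0.2)
  tn <- tuneNetwork(X, y, nDraws = 1, seed = 8)
  expect_identical(tn$best, sampleHyperparams(1, seed = 8)[[1]])
  expect_error(tuneNetwork(X[1:2, ], y[1:2], nDraws = 1, k = 3), "folds")
})
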