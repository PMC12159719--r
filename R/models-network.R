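# Feed-forward network base learner: ReLU hidden layers, linear output,
# mean-squared-error loss minimized by Adam on minibatches. Training stops
# when the recent loss history is convex (consecutive decrements shrinking
# over a 3-epoch window) AND the last relative decrease is below 5%, or at
# the 50-epoch cap, whichever comes first.

.ADAM_BETA1 <- 0.9
.ADAM_BETA2 <- 0.999
.ADAM_EPS <- 1e-8
.MAX_EPOCHS <- 50L

#' Draw random network hyperparameters
#'
#' The four stated search distributions: learning rate log10-uniform on
#' [-4, 2]; batch size 2^k with k discrete-uniform on \{2,...,7\}; number of
#' hidden layers discrete-uniform on [3, 8]; layer width discrete-uniform
#' on [3, 100].
#'
#' @param nDraws number of hyperparameter combinations.
#' @param seed integer RNG seed.
#' @return list of \linkS4class{NetworkHyperparams}.
#' @export
sampleHyperparams <- function(nDraws, seed = 1L) {
  stopifnot(nDraws >= 1)
  set.seed(seed)
  lapply(seq_len(nDraws), function(i)
    new("NetworkHyperparams",
        learningRate = 10^runif(1, -4, 2),
        batchSize = as.integer(2^sample(2:7, 1)),
        nLayers = as.integer(sample(3:8, 1)),
        layerWidth = as.integer(sample(3:100, 1))))
}

#' Early-stopping rule on a loss history
#'
#' Fires when the last three epochs show shrinking, nonnegative decrements
#' (a convex, decreasing-at-a-slowing-rate tail) and the relative decrease
#' between the last two epochs is below \code{relTol}.
#'
#' @param lossHistory numeric vector of per-epoch losses.
#' @param relTol relative-decrease threshold (default 5%).
#' @return TRUE when training should stop.
#' @examples
#' stoppingRuleFired(c(10.0, 9.8, 9.7))  # TRUE
#' @export
stoppingRuleFired <- function(lossHistory, relTol = 0.05) {
  n <- length(lossHistory)
  if (n < 3) return(FALSE)
  l <- lossHistory[(n - 2):n]
  d1 <- l[1] - l[2]
  d2 <- l[2] - l[3]
  convex <- d1 >= d2 && d2 >= 0
  relDecrease <- if (l[2] > 0) d2 / l[2] else 0
  convex && relDecrease < relTol
}

.relu <- function(z) pmax(z, 0)

.forward <- function(weights, biases, A) {
  H <- length(weights)
  acts <- vector("list", H + 1)
  acts[[1]] <- A
  for (i in seq_len(H)) {
    Z <- sweep(acts[[i]] %*% weights[[i]], 2, biases[[i]], `+`)
    acts[[i + 1]] <- if (i < H) .relu(Z) else Z
  }
  acts
}

#' Fit a feed-forward network by Adam
#'
#' Features are standardized with training-block statistics (constant
#' columns get unit scale). Weights use scaled-uniform fan-in
#' initialization under the run seed; minibatch order is reshuffled each
#' epoch. The per-epoch full-data MSE is recorded in the training log.
#'
#' @param X feature matrix.
#' @param y numeric response.
#' @param hp a \linkS4class{NetworkHyperparams}.
#' @param seed integer RNG seed (initialization and shuffling).
#' @param maxEpochs epoch cap (default 50).
#' @return A \linkS4class{NetworkModel}.
#' @export
fitNetwork <- function(X, y, hp, seed = 1L, maxEpochs = .MAX_EPOCHS) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n >= 1, p >= 1, length(y) == n)
  validObject(hp)
  set.seed(seed)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0 | is.na(scl)] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)

  widths <- as.integer(c(p, rep(hp@layerWidth, hp@nLayers), 1L))
  H <- length(widths) - 1L
  weights <- vector("list", H); biases <- vector("list", H)
  mW <- vW <- vector("list", H); mB <- vB <- vector("list", H)
  for (i in seq_len(H)) {
    lim <- sqrt(6 / widths[i])
    weights[[i]] <- matrix(runif(widths[i] * widths[i + 1], -lim, lim),
                           widths[i], widths[i + 1])
    biases[[i]] <- rep(0, widths[i + 1])
    mW[[i]] <- vW[[i]] <- matrix(0, widths[i], widths[i + 1])
    mB[[i]] <- vB[[i]] <- rep(0, widths[i + 1])
  }

  batch <- min(hp@batchSize, n)
  lr <- hp@learningRate
  lossLog <- numeric(0)
  t <- 0L
  for (epoch in seq_len(maxEpochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch)) {
      idx <- ord[start:min(start + batch - 1L, n)]
      A <- Xs[idx, , drop = FALSE]
      yb <- y[idx]
      acts <- .forward(weights, biases, A)
      pred <- drop(acts[[H + 1]])
      delta <- matrix(2 * (pred - yb) / length(yb), ncol = 1)
      t <- t + 1L
      for (i in H:1) {
        gW <- crossprod(acts[[i]], delta)
        gB <- colSums(delta)
        if (i > 1)
          delta <- (delta %*% t(weights[[i]])) * (acts[[i]] > 0)
        mW[[i]] <- .ADAM_BETA1 * mW[[i]] + (1 - .ADAM_BETA1) * gW
        vW[[i]] <- .ADAM_BETA2 * vW[[i]] + (1 - .ADAM_BETA2) * gW^2
        mB[[i]] <- .ADAM_BETA1 * mB[[i]] + (1 - .ADAM_BETA1) * gB
        vB[[i]] <- .ADAM_BETA2 * vB[[i]] + (1 - .ADAM_BETA2) * gB^2
        mhW <- mW[[i]] / (1 - .ADAM_BETA1^t)
        vhW <- vW[[i]] / (1 - .ADAM_BETA2^t)
        mhB <- mB[[i]] / (1 - .ADAM_BETA1^t)
        vhB <- vB[[i]] / (1 - .ADAM_BETA2^t)
        weights[[i]] <- weights[[i]] - lr * mhW / (sqrt(vhW) + .ADAM_EPS)
        biases[[i]] <- biases[[i]] - lr * mhB / (sqrt(vhB) + .ADAM_EPS)
      }
    }
    fullPred <- drop(.forward(weights, biases, Xs)[[H + 1]])
    loss <- mean((fullPred - y)^2)
    if (!is.finite(loss))
      stop("network training diverged (non-finite loss) at epoch ", epoch)
    lossLog <- c(lossLog, loss)
    if (stoppingRuleFired(lossLog)) break
  }
  new("NetworkModel", weights = weights, biases = biases, widths = widths,
      center = ctr, scale = scl, lossLog = lossLog, hyperparams = hp)
}

#' Tune network hyperparameters by random search with k-fold CV
#'
#' Draws \code{nDraws} combinations from the stated distributions and scores
#' each by the mean Pearson correlation between held-out responses and
#' predictions across \code{k} folds. Diverging draws score -Inf. Ties keep
#' the first draw.
#'
#' @param X feature matrix.
#' @param y numeric response.
#' @param nDraws number of random combinations (300 in the full search;
#'   smaller values keep desk-scale runs fast).
#' @param k number of folds.
#' @param seed integer RNG seed.
#' @param maxEpochs epoch cap passed to \code{\link{fitNetwork}}.
#' @return list with \code{best} (a \linkS4class{NetworkHyperparams}) and
#'   \code{log} (data.frame of draws and mean CV accuracy).
#' @export
tuneNetwork <- function(X, y, nDraws = 300, k = 3, seed = 1L,
                        maxEpochs = .MAX_EPOCHS) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < k) stop("fewer rows than folds")
  draws <- sampleHyperparams(nDraws, seed = seed)
  set.seed(seed + 1L)
  fold <- sample(rep_len(seq_len(k), n))
  score <- numeric(nDraws)
  for (j in seq_len(nDraws)) {
    hp <- draws[[j]]
    rs <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      if (sum(!tr) < 2) return(NA_real_)
      m <- tryCatch(
        fitNetwork(X[tr, , drop = FALSE], y[tr], hp,
                   seed = seed + 100L * j + f, maxEpochs = maxEpochs),
        error = function(e) NULL)
      if (is.null(m)) return(NA_real_)
      suppressWarnings(accuracy(y[!tr], predict(m, X[!tr, , drop = FALSE])))
    }, numeric(1))
    score[j] <- if (all(is.na(rs))) -Inf else mean(rs, na.rm = TRUE)
  }
  log <- data.frame(
    draw = seq_len(nDraws),
    learning_rate = vapply(draws, function(h) h@learningRate, numeric(1)),
    batch_size = vapply(draws, function(h) h@batchSize, integer(1)),
    n_layers = vapply(draws, function(h) h@nLayers, integer(1)),
    layer_width = vapply(draws, function(h) h@layerWidth, integer(1)),
    mean_cv_accuracy = score)
  list(best = draws[[which.max(score)]], log = log)
}

#' @describeIn fitNetwork predict from a fitted network
#' @param object a \linkS4class{NetworkModel}
#' @param newdata feature matrix matching the input width
#' @export
setMethod("predict", "NetworkModel", function(object, newdata) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object@widths[1])
    stop("feature count mismatch: model expects ", object@widths[1],
         ", data has ", ncol(newdata))
  Xs <- sweep(sweep(newdata, 2, object@center), 2, object@scale, `/`)
  drop(.forward(object@weights, object@biases, Xs)[[length(object@weights) + 1]])
})
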