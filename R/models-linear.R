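# Linear base learners. Both fits center the features internally and leave
# the intercept unpenalized; the SVD route gives the minimum-norm solution
# for rank-deficient OLS and the exact closed-form ridge solution.

#' Ordinary least squares fit
#'
#' Minimizes \code{||y - b0 - X beta||^2}; rank-deficient systems resolve to
#' the minimum-norm coefficient vector.
#'
#' @param X feature matrix (rows = observations).
#' @param y numeric response.
#' @return A \linkS4class{LinearModel} with \code{lambda = 0}.
#' @examples
#' X <- matrix(1:3, dimnames = list(NULL, "x"))
#' fitOLS(X, 2 * (1:3) + 1)   # intercept 1, slope 2
#' @export
fitOLS <- function(X, y) fitRidge(X, y, lambda = 0)

#' Ridge regression fit (closed form)
#'
#' Minimizes \code{||y - b0 - X beta||^2 + lambda ||beta||^2} with the
#' intercept unpenalized: features are centered internally and the intercept
#' is the response mean on centered features. \code{lambda = 0} reduces to
#' the minimum-norm OLS solution.
#'
#' @param X feature matrix.
#' @param y numeric response.
#' @param lambda nonnegative L2 penalty.
#' @return A \linkS4class{LinearModel}.
#' @export
fitRidge <- function(X, y, lambda) {
  X <- as.matrix(X)
  if (!nrow(X) || !ncol(X)) stop("empty feature matrix")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (anyNA(X) || anyNA(y)) stop("missing values in X or y")
  if (lambda < 0) stop("lambda must be nonnegative")
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  ybar <- mean(y)
  yc <- y - ybar
  sv <- svd(Xc)
  d <- sv$d
  if (lambda == 0) {
    tol <- max(dim(X)) * .Machine$double.eps * max(d, 0)
    shrink <- ifelse(d > tol, 1 / d, 0)
  } else {
    shrink <- d / (d^2 + lambda)
  }
  beta <- drop(sv$v %*% (shrink * crossprod(sv$u, yc)))
  names(beta) <- colnames(X)
  new("LinearModel", intercept = ybar - sum(xbar * beta),
      coefficients = beta, lambda = as.numeric(lambda))
}

#' Choose a ridge penalty by k-fold cross-validation
#'
#' Grid search over \code{lambdaGrid}; the score is the mean Pearson
#' correlation between held-out responses and predictions across folds.
#' Ties keep the first (smallest) grid value.
#'
#' @param X feature matrix.
#' @param y numeric response.
#' @param lambdaGrid candidate penalties.
#' @param k number of folds.
#' @param seed integer seed for the fold assignment.
#' @return The selected lambda.
#' @export
ridgeLambdaCV <- function(X, y, lambdaGrid = c(0.01, 0.1, 1, 10, 100, 1000),
                          k = 3, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < k) stop("fewer rows than folds")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  score <- vapply(lambdaGrid, function(lam) {
    rs <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      if (sum(tr) < 1 || sum(!tr) < 2) return(NA_real_)
      m <- fitRidge(X[tr, , drop = FALSE], y[tr], lam)
      suppressWarnings(accuracy(y[!tr], predict(m, X[!tr, , drop = FALSE])))
    }, numeric(1))
    if (all(is.na(rs))) -Inf else mean(rs, na.rm = TRUE)
  }, numeric(1))
  lambdaGrid[which.max(score)]
}

#' @describeIn fitRidge predict from a fitted linear model
#' @param object a \linkS4class{LinearModel}
#' @param newdata feature matrix with the model's feature count
#' @export
setMethod("predict", "LinearModel", function(object, newdata) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object@coefficients))
    stop("feature count mismatch: model has ", length(object@coefficients),
         ", data has ", ncol(newdata))
  drop(object@intercept + newdata %*% object@coefficients)
})
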