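# 10-8-1 feedforward fatigue predictor, written from first principles:
# tanh hidden layer, linear output, full-batch gradient descent on the MSE
# with the inputs and target min-max scaled to [-1, 1] on the training split.

#' Training configuration for the fatigue network
#'
#' Defaults follow the published training regime: learning rate 0.01, at most
#' 1000 epochs, stopping early when the training MSE (on the scaled target)
#' falls below 1e-5, 8 hidden nodes.
#'
#' @param learningRate gradient-descent step size (> 0).
#' @param maxEpochs maximum training epochs (>= 1).
#' @param goalMse early-stopping MSE goal on the scaled target (> 0).
#' @param hiddenNodes hidden layer width (>= 1).
#' @param seed integer seed for weight initialization.
#' @return A validated list of class `TrainConfig`.
#' @export
trainConfig <- function(learningRate = 0.01, maxEpochs = 1000, goalMse = 1e-5,
                        hiddenNodes = 8, seed = 1) {
  assertScalarNumber(learningRate, "learningRate", lower = 1e-12)
  assertScalarNumber(maxEpochs, "maxEpochs", lower = 1, integer = TRUE)
  assertScalarNumber(goalMse, "goalMse", lower = 1e-300)
  assertScalarNumber(hiddenNodes, "hiddenNodes", lower = 1, integer = TRUE)
  assertScalarNumber(seed, "seed", integer = TRUE)
  structure(list(learningRate = learningRate, maxEpochs = as.integer(maxEpochs),
                 goalMse = goalMse, hiddenNodes = as.integer(hiddenNodes),
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Min-max scaling to \[-1, 1\]
#'
#' `scaleFit()` records the per-column minimum and maximum of a training
#' matrix; `scaleApply()` maps columns linearly so the recorded minimum goes
#' to -1 and the maximum to +1; `scaleInvert()` is its exact inverse. A
#' constant column is mapped to 0 with a warning (and inverts back to the
#' constant).
#'
#' @param x numeric matrix (samples x features), or for `scaleInvert` the
#'   scaled matrix/vector.
#' @param scaling a scaling object from `scaleFit()`.
#' @return `scaleFit`: a list with `lo` and `hi`; `scaleApply`/`scaleInvert`:
#'   the transformed matrix.
#' @examples
#' sc <- scaleFit(cbind(a = c(0, 5, 10)))
#' scaleApply(cbind(a = c(0, 5, 10)), sc)
#' @export
scaleFit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows to fit scaling", call. = FALSE)
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  if (any(hi == lo))
    warning("constant feature(s) mapped to 0: ",
            paste(colnames(x)[hi == lo], collapse = ", "))
  list(lo = lo, hi = hi)
}

#' @rdname scaleFit
#' @export
scaleApply <- function(x, scaling) {
  x <- as.matrix(x)
  span <- scaling$hi - scaling$lo
  out <- x
  for (j in seq_len(ncol(x)))
    out[, j] <- if (span[j] == 0) 0 else 2 * (x[, j] - scaling$lo[j]) / span[j] - 1
  out
}

#' @rdname scaleFit
#' @export
scaleInvert <- function(x, scaling) {
  x <- as.matrix(x)
  span <- scaling$hi - scaling$lo
  out <- x
  for (j in seq_len(ncol(x)))
    out[, j] <- if (span[j] == 0) scaling$lo[j] else
      (x[, j] + 1) / 2 * span[j] + scaling$lo[j]
  out
}

# raw parameter list used during training; promoted to FatigueMLP at the end
mlpInit <- function(nIn, nHidden, seed) {
  withLocalSeed(seed, list(
    W1 = matrix(stats::runif(nHidden * nIn, -0.5, 0.5), nHidden, nIn),
    b1 = stats::runif(nHidden, -0.5, 0.5),
    W2 = matrix(stats::runif(nHidden, -0.5, 0.5), 1, nHidden),
    b2 = stats::runif(1, -0.5, 0.5)
  ))
}

#' Forward pass of the fatigue network
#'
#' `y = W2 tanh(W1 x + b1) + b2` on already-scaled inputs. Exposed (together
#' with [mlpGradient()]) so the backpropagation can be checked against a
#' finite-difference oracle.
#'
#' @param params list with `W1` (hidden x inputs), `b1`, `W2` (1 x hidden),
#'   `b2`, or a [FatigueMLP-class].
#' @param X scaled input matrix (samples x inputs) or a single vector.
#' @return Numeric vector of network outputs (scaled scale).
#' @export
mlpForward <- function(params, X) {
  if (is(params, "FatigueMLP"))
    params <- list(W1 = params@W1, b1 = params@b1, W2 = params@W2, b2 = params@b2)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != ncol(params$W1))
    stop(sprintf("input has %d columns; network expects %d",
                 ncol(X), ncol(params$W1)), call. = FALSE)
  H <- tanh(X %*% t(params$W1) + matrix(params$b1, nrow(X), length(params$b1),
                                        byrow = TRUE))
  as.vector(H %*% t(params$W2)) + params$b2
}

#' Analytic gradient of the training MSE
#'
#' Backpropagation gradients of `mean((forward(X) - y)^2)` with respect to
#' every parameter.
#'
#' @inheritParams mlpForward
#' @param y scaled target vector.
#' @return List with gradients `W1`, `b1`, `W2`, `b2` and the current `mse`.
#' @export
mlpGradient <- function(params, X, y) {
  n <- nrow(X)
  H <- tanh(X %*% t(params$W1) + matrix(params$b1, n, length(params$b1),
                                        byrow = TRUE))
  yhat <- as.vector(H %*% t(params$W2)) + params$b2
  err <- yhat - y
  gy <- 2 * err / n
  gW2 <- matrix(gy, 1, n) %*% H
  gb2 <- sum(gy)
  D <- (gy %o% as.vector(params$W2)) * (1 - H^2)
  list(W1 = t(D) %*% X, b1 = colSums(D), W2 = gW2, b2 = gb2,
       mse = mean(err^2))
}

#' Train the 10-8-1 fatigue network
#'
#' Scales inputs and target to \[-1, 1\] (fit on the given data, i.e. the
#' training split), initializes weights uniformly on (-0.5, 0.5) from the
#' seeded stream, and runs full-batch gradient descent on the MSE with an
#' adaptive step size: starting from `learningRate`, a step that would
#' increase the loss is halved and retried, a successful step is probed at
#' double the size while that keeps improving, and the working rate carries
#' over to the next epoch. Every accepted step lowers the loss, so the
#' recorded history is monotone non-increasing. Training stops at `goalMse`
#' (measured on the scaled target, as is conventional) or `maxEpochs`; an
#' MSE above 1e6 aborts with a divergence error.
#'
#' @param X numeric feature matrix (samples x features), raw units.
#' @param y target fatigue index values in \[0, 1\], one per row of `X`.
#' @param config a [trainConfig()].
#' @return A [FatigueMLP-class].
#' @examples
#' \donttest{
#' X <- matrix(rnorm(420), 42, 10)
#' y <- pmin(1, pmax(0, 0.5 + 0.3 * X[, 1]))
#' fit <- trainFatigueMLP(X, y, trainConfig(seed = 1))
#' }
#' @export
trainFatigueMLP <- function(X, y, config = trainConfig()) {
  if (!inherits(config, "TrainConfig"))
    stop("'config' must come from trainConfig()", call. = FALSE)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X rows and y length differ", call. = FALSE)
  if (any(y < -1e-9 | y > 1 + 1e-9))
    stop("targets must be fatigue index values in [0, 1]", call. = FALSE)
  if (nrow(X) < config$hiddenNodes)
    stop("need at least as many samples as hidden nodes", call. = FALSE)
  xScale <- scaleFit(X)
  yScale <- scaleFit(matrix(y, ncol = 1))
  Xs <- scaleApply(X, xScale)
  ys <- as.vector(scaleApply(matrix(y, ncol = 1), yScale))
  params <- mlpInit(ncol(X), config$hiddenNodes, config$seed)
  g <- mlpGradient(params, Xs, ys)
  history <- g$mse
  takeStep <- function(lr) {
    cand <- list(W1 = params$W1 - lr * g$W1, b1 = params$b1 - lr * g$b1,
                 W2 = params$W2 - lr * g$W2, b2 = params$b2 - lr * g$b2)
    list(params = cand, g = mlpGradient(cand, Xs, ys))
  }
  lr <- config$learningRate
  for (epoch in seq_len(config$maxEpochs)) {
    if (g$mse <= config$goalMse) break
    if (g$mse > 1e6)
      stop("training diverged (MSE > 1e6); try a smaller learning rate",
           call. = FALSE)
    cand <- takeStep(lr)
    tries <- 0L
    while (cand$g$mse > g$mse && tries < 60L) {
      lr <- lr / 2
      cand <- takeStep(lr)
      tries <- tries + 1L
    }
    if (cand$g$mse > g$mse) break  # at a (numerical) local minimum
    repeat {  # probe larger steps while they keep improving
      up <- takeStep(lr * 2)
      if (up$g$mse < cand$g$mse) { lr <- lr * 2; cand <- up } else break
    }
    params <- cand$params
    g <- cand$g
    history <- c(history, g$mse)
  }
  new("FatigueMLP", W1 = params$W1, b1 = params$b1, W2 = params$W2,
      b2 = params$b2, xScale = xScale,
      yScale = list(lo = unname(yScale$lo), hi = unname(yScale$hi)),
      config = unclass(config), history = history,
      seed = as.integer(config$seed))
}

#' Predict fatigue index values from HRV features
#'
#' Applies the training-split scaling to `newdata`, runs the forward pass and
#' inverts the target scaling, returning fatigue index predictions on the
#' original \[0, 1\] scale.
#'
#' @param object a [FatigueMLP-class].
#' @param newdata numeric feature matrix (samples x features), raw units.
#' @return Numeric vector of predicted fatigue index values.
#' @export
setMethod("predict", "FatigueMLP", function(object, newdata) {
  newdata <- as.matrix(newdata)
  ys <- mlpForward(object, scaleApply(newdata, object@xScale))
  as.vector(scaleInvert(matrix(ys, ncol = 1), object@yScale))
})

#' Regression evaluation metrics
#'
#' MAE, MSE, RMSE (= sqrt(MSE)) and the coefficient of determination
#' `r2 = 1 - SS_res / SS_tot`. With zero-variance observations `r2` is
#' undefined and returned as `NA`.
#'
#' @param predictions,observed numeric vectors of equal length >= 2.
#' @return Named list `mae`, `mse`, `rmse`, `r2`.
#' @examples
#' evaluateRegression(c(0.5, 0.5), c(0, 1))
#' @export
evaluateRegression <- function(predictions, observed) {
  if (length(predictions) != length(observed) || length(observed) < 2)
    stop("need two equal-length vectors of at least 2 values", call. = FALSE)
  err <- predictions - observed
  mse <- mean(err^2)
  ssTot <- sum((observed - mean(observed))^2)
  list(mae = mean(abs(err)), mse = mse, rmse = sqrt(mse),
       r2 = if (ssTot > 0) 1 - sum(err^2) / ssTot else NA_real_)
}

#' Hold-out split evaluation
#'
#' Splits the samples into a seeded random train/test partition (default
#' 38:4, the 19:2 ratio on 42 samples), trains on the training split and
#' evaluates on both splits.
#'
#' @inheritParams trainFatigueMLP
#' @param nTest number of held-out samples.
#' @param seed seed for the partition (weight initialization comes from
#'   `config`).
#' @return List with `model`, `train` and `test` metric lists, and the
#'   held-out `testIdx`.
#' @export
holdoutEvaluate <- function(X, y, config = trainConfig(), nTest = 4, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (nTest < 1 || nTest >= n) stop("nTest must be in [1, n - 1]", call. = FALSE)
  testIdx <- withLocalSeed(seed, sort(sample.int(n, nTest)))
  fit <- trainFatigueMLP(X[-testIdx, , drop = FALSE], y[-testIdx], config)
  list(model = fit,
       train = evaluateRegression(predict(fit, X[-testIdx, , drop = FALSE]),
                                  y[-testIdx]),
       test = evaluateRegression(predict(fit, X[testIdx, , drop = FALSE]),
                                 y[testIdx]),
       testIdx = testIdx)
}

#' K-fold cross-validation of the fatigue network
#'
#' Seeded partition into `folds` folds; each fold is predicted by a network
#' trained on the remaining folds. Reports per-fold metrics, their mean, and
#' the pooled held-out metrics computed over all samples at once (every
#' prediction coming from a model that never saw that sample).
#'
#' @inheritParams trainFatigueMLP
#' @param folds number of folds (2..n; `folds = n` is leave-one-out).
#' @param seed seed for the fold partition.
#' @return List with `folds` (per-fold metric lists), `mean` (mean of the
#'   per-fold metrics), `pooled` (metrics of the pooled held-out
#'   predictions), `predictions` and `foldId`.
#' @export
crossValidate <- function(X, y, folds = 5, config = trainConfig(), seed = 1) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  assertScalarNumber(folds, "folds", lower = 2, integer = TRUE)
  if (folds > n) stop("more folds than samples", call. = FALSE)
  foldId <- withLocalSeed(seed, sample(rep(seq_len(folds), length.out = n)))
  pred <- numeric(n)
  perFold <- vector("list", folds)
  for (k in seq_len(folds)) {
    hold <- foldId == k
    cfg <- config
    cfg$seed <- deriveSeed(config$seed, k)
    class(cfg) <- "TrainConfig"
    fit <- trainFatigueMLP(X[!hold, , drop = FALSE], y[!hold], cfg)
    pred[hold] <- predict(fit, X[hold, , drop = FALSE])
    perFold[[k]] <- if (sum(hold) >= 2)
      evaluateRegression(pred[hold], y[hold])
    else list(mae = abs(pred[hold] - y[hold]),
              mse = (pred[hold] - y[hold])^2,
              rmse = abs(pred[hold] - y[hold]), r2 = NA_real_)
  }
  meanOf <- function(field) mean(vapply(perFold, function(f)
    as.numeric(f[[field]]), numeric(1)), na.rm = TRUE)
  list(folds = perFold,
       mean = list(mae = meanOf("mae"), mse = meanOf("mse"),
                   rmse = meanOf("rmse"), r2 = meanOf("r2")),
       pooled = evaluateRegression(pred, y),
       predictions = pred, foldId = foldId)
}
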