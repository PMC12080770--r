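test_that("mapminmax scaling maps endpoints and round-trips exactly", {
  sc <- scaleFit(cbind(a = c(0, 10)))
  expect_equal(unname(scaleApply(cbind(a = c(0, 10)), sc)[, 1]), c(-1, 1))
  expect_equal(unname(scaleApply(cbind(a = c(0, 5, 10)), sc)[, 1]), c(-1, 0, 1))
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(30), 10, 3)
    sc <- scaleFit(x)
    expect_equal(scaleInvert(scaleApply(x, sc), sc), x, tolerance = 1e-12)
  }
  expect_warning(sc <- scaleFit(cbind(k = c(2, 2, 2))), "constant")
  expect_equal(unname(scaleApply(cbind(k = c(2, 2)), sc)[, 1]), c(0, 0))
  expect_equal(unname(scaleInvert(cbind(k = c(0, 0)), sc)[, 1]), c(2, 2))
})

test_that("the forward pass computes W2 tanh(W1 x + b1) + b2", {
  z <- list(W1 = matrix(0, 8, 10), b1 = rep(0, 8),
            W2 = matrix(0, 1, 8), b2 = 0.3)
  set.seed(1)
  expect_equal(mlpForward(z, matrix(rnorm(30), 3, 10)), rep(0.3, 3))

  p <- list(W1 = rbind(c(1, -1), c(0.5, 2)), b1 = c(0.1, -0.2),
            W2 = matrix(c(0.3, 0.7), 1, 2), b2 = 0.05)
  x <- c(0.4, -0.6)
  manual <- 0.3 * tanh(1 * 0.4 + (-1) * (-0.6) + 0.1) +
            0.7 * tanh(0.5 * 0.4 + 2 * (-0.6) - 0.2) + 0.05
  expect_equal(mlpForward(p, x), manual, tolerance = 1e-15)
  expect_error(mlpForward(p, c(1, 2, 3)), "expects")
})

test_that("backpropagation matches central finite differences to 1e-6", {
  set.seed(7)
  X <- matrix(runif(20 * 10, -1, 1), 20, 10)
  y <- runif(20, -1, 1)
  params <- hrvFatigue:::mlpInit(10, 8, seed = 7)
  g <- mlpGradient(params, X, y)
  eps <- 1e-5
  mseAt <- function(p) mlpGradient(p, X, y)$mse
  for (nm in c("W1", "b1", "W2", "b2")) {
    fd <- params[[nm]]
    for (i in seq_along(params[[nm]])) {
      up <- params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
      fd[i] <- (mseAt(up) - mseAt(dn)) / (2 * eps)
    }
    expect_lt(max(abs(fd - g[[nm]])), 1e-6)
  }
})

test_that("a noiseless linear target is fit to MSE below 1e-4", {
  set.seed(42)
  X <- matrix(runif(42 * 10, -1, 1), 42, 10)
  lin <- X %*% runif(10, -1, 1)
  y <- as.vector((lin - min(lin)) / (max(lin) - min(lin)))
  for (s in c(1, 5, 9)) {
    fit <- trainFatigueMLP(X, y, trainConfig(seed = s))
    expect_lt(evaluateRegression(predict(fit, X), y)$mse, 1e-4)
  }
})

test_that("training is reproducible and its loss history monotone", {
  set.seed(2)
  X <- matrix(rnorm(42 * 10), 42, 10)
  y <- runif(42)
  a <- trainFatigueMLP(X, y, trainConfig(seed = 3, maxEpochs = 200))
  b <- trainFatigueMLP(X, y, trainConfig(seed = 3, maxEpochs = 200))
  expect_identical(a@W1, b@W1)
  expect_identical(a@history, b@history)
  expect_true(all(diff(a@history) <= 1e-12))
  c2 <- trainFatigueMLP(X, y, trainConfig(seed = 4, maxEpochs = 200))
  expect_false(identical(a@W1, c2@W1))
})

test_that("training rejects malformed inputs", {
  X <- matrix(rnorm(42 * 10), 42, 10)
  expect_error(trainFatigueMLP(X, runif(10)), "differ")
  expect_error(trainFatigueMLP(X, runif(42) + 2), "\\[0, 1\\]")
  expect_error(trainFatigueMLP(X[1:5, ], runif(5)), "hidden nodes")
  expect_error(trainFatigueMLP(X, runif(42), config = list(learningRate = 1)),
               "trainConfig")
})

test_that("evaluation metrics follow their definitions", {
  perfect <- evaluateRegression(c(0.2, 0.5, 0.9), c(0.2, 0.5, 0.9))
  expect_equal(unlist(perfect), c(mae = 0, mse = 0, rmse = 0, r2 = 1))

  obs <- c(0.1, 0.4, 0.7, 1)
  atMean <- evaluateRegression(rep(mean(obs), 4), obs)
  expect_equal(atMean$r2, 0)

  e <- evaluateRegression(c(0.5, 0.5), c(0, 1))
  expect_equal(e$mae, 0.5)
  expect_equal(e$mse, 0.25)
  expect_equal(e$rmse, 0.5)
  expect_equal(e$r2, 0)

  expect_true(is.na(evaluateRegression(c(1, 2), c(3, 3))$r2))
  expect_error(evaluateRegression(1:3, 1:2), "equal-length")
})

test_that("rmse^2 = mse and mae <= rmse on random inputs", {
  for (seed in 1:10) {
    set.seed(seed)
    e <- evaluateRegression(runif(20), runif(20))
    expect_equal(e$rmse^2, e$mse, tolerance = 1e-12)
    expect_lte(e$mae, e$rmse + 1e-12)
  }
})

test_that("cross-validation partitions correctly and is reproducible", {
  set.seed(5)
  X <- matrix(rnorm(20 * 10), 20, 10)
  y <- runif(20)
  cfg <- trainConfig(seed = 1, maxEpochs = 50)
  loo <- crossValidate(X, y, folds = 20, config = cfg, seed = 2)
  expect_length(loo$folds, 20L)
  expect_equal(sort(unique(loo$foldId)), 1:20)

  a <- crossValidate(X, y, folds = 5, config = cfg, seed = 3)
  b <- crossValidate(X, y, folds = 5, config = cfg, seed = 3)
  expect_identical(a$predictions, b$predictions)
  expect_error(crossValidate(X, y, folds = 21, config = cfg), "folds")
})

test_that("a noiseless cohort is predicted to mean MAE below 0.02", {
  pr <- subjectProfile(restingHr = 65, maxHr = 190, hrPerKmh = 14,
                       baselineSdnn = 65, baselineRt = 300)
  cfg <- protocolConfig(seed = 3, profile = pr,
                        noiseSd = list(borg = 0, rt = 0, hr = 0, sdnn = 0))
  cohort <- simulateCohort(cfg)
  se <- cohortFeatures(cohort)
  X <- t(SummarizedExperiment::assay(se))
  obs <- observations(cohort)
  raw <- cbind(reaction_time = obs$rt_ms, borg = as.numeric(obs$borg))
  nm <- featureValues(minmaxNormalize(raw))
  f <- compositeIndex(nm[, "reaction_time"], nm[, "borg"], computeWeights(raw))
  cv <- crossValidate(X, f, folds = 5, config = trainConfig(seed = 11), seed = 7)
  expect_lt(cv$mean$mae, 0.02)
})
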