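test_that("min-max normalization maps endpoints, constants and is idempotent", {
  m <- minmaxNormalize(cbind(a = c(0, 5, 10)))
  expect_equal(unname(featureValues(m)[, 1]), c(0, 0.5, 1))
  expect_identical(processingStage(m), "normalized")

  m <- minmaxNormalize(cbind(a = c(7, 7, 7)))
  expect_equal(unname(featureValues(m)[, 1]), c(0, 0, 0))

  spanning <- cbind(a = c(0, 0.3, 1))
  once <- featureValues(minmaxNormalize(spanning))
  expect_equal(unname(once[, 1]), unname(spanning[, 1]))

  expect_error(minmaxNormalize(matrix(1, 1, 2)), "at least 2")
})

test_that("the +0.001 shift is exact and stage-guarded", {
  norm <- minmaxNormalize(cbind(a = c(0, 1), b = c(2, 5)))
  sh <- shiftFeatures(norm)
  expect_identical(processingStage(sh), "shifted")
  expect_equal(min(featureValues(sh)), 0.001)
  expect_equal(max(featureValues(sh)), 1.001)
  expect_equal(featureValues(sh), featureValues(norm) + 0.001)
  expect_error(shiftFeatures(sh), "normalized")                 # double shift
  expect_error(shiftFeatures(FeatureMatrix(cbind(1:3))), "normalized")
  expect_error(entropyWeights(norm), "shifted")
})

test_that("entropy weights: constant features get zero, symmetry gives 0.5/0.5", {
  w1 <- computeWeights(cbind(flat = c(3, 3, 3, 3), vary = c(1, 2, 3, 4)))
  expect_equal(unname(featureWeights(w1)), c(0, 1))
  expect_equal(unname(featureEntropy(w1)[1]), 1)

  w2 <- computeWeights(cbind(a = c(1, 5, 9), b = c(1, 5, 9)))
  expect_equal(unname(featureWeights(w2)), c(0.5, 0.5))

  sh <- FeatureMatrix(rbind(c(0.001, 1.001), c(0.501, 0.501), c(1.001, 0.001)),
                      stage = "shifted")
  ew <- entropyWeights(sh)
  orc <- entropyOracle(featureValues(sh))
  expect_equal(unname(featureWeights(ew)), c(0.5, 0.5))
  expect_equal(unname(featureEntropy(ew)), orc$e, tolerance = 1e-12)

  expect_error(computeWeights(cbind(a = c(2, 2), b = c(9, 9))),
               "no discriminating feature")
})

test_that("entropy weights match the naive formula transcription to 1e-12", {
  for (seed in 1:20) {
    set.seed(seed)
    raw <- matrix(runif(15, 0, 100), 5, 3)
    sh <- shiftFeatures(minmaxNormalize(raw))
    ew <- entropyWeights(sh)
    orc <- entropyOracle(featureValues(sh))
    expect_equal(unname(featureWeights(ew)), orc$w, tolerance = 1e-12)
    expect_equal(unname(featureEntropy(ew)), orc$e, tolerance = 1e-12)
    expect_equal(ew@p, orc$p, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("weights are valid and invariant to affine feature rescaling", {
  for (seed in 1:15) {
    set.seed(seed)
    raw <- matrix(rnorm(8 * 3), 8, 3)
    w <- featureWeights(computeWeights(raw))
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-12)
    resc <- sweep(sweep(raw, 2, c(2, 0.1, 7), "*"), 2, c(-3, 40, 0), "+")
    expect_equal(featureWeights(computeWeights(resc)), w, tolerance = 1e-10)
  }
})

test_that("composite index is the weighted sum with guarded domain", {
  expect_equal(compositeIndex(1, 1), 1)
  expect_equal(compositeIndex(0, 0), 0)
  expect_equal(compositeIndex(0.21, 0.31), 0.39 * 0.21 + 0.61 * 0.31)
  expect_equal(compositeIndex(0.21, 0.31), 0.271)
  expect_equal(compositeIndex(c(0, 1), c(1, 0)), c(0.61, 0.39))
  expect_error(compositeIndex(1.2, 0.5), "\\[0, 1\\]")
  expect_error(compositeIndex(0.5, -0.2), "\\[0, 1\\]")
  expect_error(compositeIndex(0.5, 0.5, weights = c(0.4, 0.6)), "named")
  expect_error(compositeIndex(0.5, 0.5,
                              weights = c(reaction_time = 0.5, borg = 0.6)),
               "sum to 1")
})

test_that("3-level classification uses half-open bands, boundaries upward", {
  expect_equal(classifyLevel(0.10), 1L)
  expect_equal(classifyLevel(0.27), 2L)
  expect_equal(classifyLevel(0.66), 3L)
  expect_equal(classifyLevel(0.80), 3L)
  expect_equal(classifyLevel(c(0, 1)), c(1L, 3L))
  expect_error(classifyLevel(1.5), "\\[0, 1\\]")
})

test_that("classification is monotone in the index", {
  f <- sort(runif(200))
  lv <- classifyLevel(f)
  expect_true(all(diff(lv) >= 0))
})
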