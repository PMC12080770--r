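test_that("constant series gives zero variability and flagged ratios", {
  x <- rep(1000, 240)
  td <- timeDomain(x)
  expect_equal(unname(td), c(1000, 60, 0, 0))
  pc <- poincare(x)
  expect_equal(unname(pc[c("sd1", "sd2")]), c(0, 0))
  expect_true(is.na(pc[["sd2_sd1"]]))
  fd <- frequencyDomain(x)
  expect_lt(fd[["lf"]], 1e-12)
  expect_lt(fd[["hf"]], 1e-12)
  expect_true(is.na(fd[["lf_hf"]]))
  v <- hrvFeatures(x)
  expect_identical(names(v), hrvFeatureNames())
  expect_equal(unname(v[c("sdnn", "rmssd", "sd1", "sd2")]), rep(0, 4))
})

test_that("alternating 990/1010 series matches hand-derived values", {
  x <- alternatingSeries(240)
  td <- timeDomain(x)
  # diffs are all +-20 -> rmssd exactly 20; sample sd of +-10 about the mean
  expect_equal(td[["rmssd"]], 20)
  expect_equal(td[["sdnn"]], sqrt(240 * 100 / 239), tolerance = 1e-12)
  expect_equal(td[["hr"]], 60, tolerance = 1e-12)
  pc <- poincare(x)
  # population convention: sd1 = rmssd / sqrt(2) up to the tiny nonzero mean
  # of the 239 alternating differences
  expect_equal(pc[["sd1"]], 20 / sqrt(2), tolerance = 1e-4)
})

test_that("sdnn and rmssd are homogeneous of degree 1", {
  set.seed(3)
  x <- 1000 + rnorm(120, 0, 30)
  for (cc in c(0.5, 1.7)) {
    a <- timeDomain(x)
    b <- timeDomain(cc * x)
    expect_equal(b[["sdnn"]], cc * a[["sdnn"]], tolerance = 1e-12)
    expect_equal(b[["rmssd"]], cc * a[["rmssd"]], tolerance = 1e-12)
  }
})

test_that("time reversal leaves dispersion features unchanged", {
  set.seed(4)
  x <- 900 + rnorm(150, 0, 40)
  f <- c("sdnn", "rmssd")
  expect_equal(timeDomain(rev(x))[f], timeDomain(x)[f])
  p <- c("sd1", "sd2")
  expect_equal(poincare(rev(x))[p], poincare(x)[p])
})

test_that("Poincare identity 2 sdnn_pop^2 = sd1^2 + sd2^2 holds by construction", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- 800 + rnorm(100, 0, 50)
    pc <- poincare(x)
    sdnnPop2 <- mean((x - mean(x))^2)
    expect_equal(pc[["sd1"]]^2 + pc[["sd2"]]^2, 2 * sdnnPop2, tolerance = 1e-9)
  }
})

test_that("a pure ramp has no short-term variability", {
  ramp <- seq(900, 1190, by = 10)  # constant successive differences
  pc <- poincare(ramp)
  expect_equal(pc[["sd1"]], 0)
  expect_gt(pc[["sd2"]], 50)
  expect_true(is.na(pc[["sd2_sd1"]]))
  # with a whisper of alternation the ratio becomes finite and very large
  jig <- ramp + rep(c(-0.5, 0.5), length.out = length(ramp))
  expect_gt(poincare(jig)[["sd2_sd1"]], 10)
})

test_that("band power attributes pure tones to the correct band", {
  tt <- cumsum(rep(0.8, 300))
  hfTone <- 800 + 30 * sin(2 * pi * 0.25 * tt)
  fd <- frequencyDomain(hfTone)
  expect_gt(fd[["hf"]], fd[["lf"]])
  expect_lt(fd[["lf_hf"]], 0.2)
  lfTone <- 800 + 30 * sin(2 * pi * 0.10 * tt)
  fd <- frequencyDomain(lfTone)
  expect_gt(fd[["lf_hf"]], 5)
})

test_that("short or implausible series are rejected with informative errors", {
  expect_error(timeDomain(rep(1000, 10)), "at least 30")
  expect_error(poincare(rep(1000, 5)), "at least 30")
  bad <- c(rep(1000, 100), 250)
  expect_error(timeDomain(bad), "plausibility guard")
  expect_error(frequencyDomain(rep(1000, 60)), "120 s")
})

test_that("the feature vector recovers the generator's targets", {
  rri <- simulateRR(100, 20, lfHfTarget = 2, duration = 240, seed = 5)
  v <- hrvFeatures(rri)
  expect_length(v, 10L)
  expect_lt(abs(v[["hr"]] - 100) / 100, 0.02)
  expect_lt(abs(v[["sdnn"]] - 20) / 20, 0.10)
  expect_equal(v[["hr"]], 60000 / v[["rri_mean"]], tolerance = 1e-12)
})

test_that("cohortFeatures assembles a 10 x n SummarizedExperiment", {
  se <- cohortFeatures(defaultCohort())
  expect_s4_class(se, "SummarizedExperiment")
  expect_equal(dim(se), c(10L, 42L))
  expect_identical(rownames(se), hrvFeatureNames())
  cd <- SummarizedExperiment::colData(se)
  expect_true(all(c("subject", "stage", "borg", "rt_ms", "true_fatigue") %in%
                    colnames(cd)))
  expect_true(all(is.finite(SummarizedExperiment::assay(se))))
})
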