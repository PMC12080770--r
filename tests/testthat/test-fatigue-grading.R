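test_that("euclidean distance satisfies its contract", {
  expect_equal(euclideanDist(c(0, 0), c(3, 4)), 5)
  expect_equal(euclideanDist(c(1, 2), c(1, 2)), 0)
  expect_equal(euclideanDist(c(1, 2), c(4, 6)), 5)
  expect_equal(euclideanDist(c(1, 2), c(4, 6)), euclideanDist(c(4, 6), c(1, 2)))
  expect_error(euclideanDist(c(1, 2), c(1, 2, 3)), "dimension")
})

test_that("k-means recovers separated blobs and degenerate cases", {
  pts <- makeBlobs(rbind(c(0, 0), c(10, 10)), nPer = 10, sd = 0.1, seed = 2)
  fit <- kmeansFit(pts, 2, seed = 1)
  lab <- clusterLabels(fit)
  expect_true(all(lab[1:10] == lab[1]) && all(lab[11:20] == lab[11]))
  expect_false(lab[1] == lab[11])

  set.seed(9)
  pts <- matrix(runif(12), 6, 2)
  fit <- kmeansFit(pts, 6, seed = 1)
  expect_equal(withinSS(fit), 0)
  expect_equal(sort(clusterLabels(fit)), 1:6)

  expect_error(kmeansFit(pts, 7, seed = 1), "exceeds")
  expect_error(kmeansFit(rbind(c(1, NA), c(2, 3)), 2), "finite")
})

test_that("k-means matches the exhaustive best 2-partition on small sets", {
  for (seed in 1:5) {
    set.seed(seed)
    pts <- matrix(rnorm(16), 8, 2)
    fit <- kmeansFit(pts, 2, replicates = 10, seed = seed)
    expect_equal(withinSS(fit), bruteForceBestSS2(pts), tolerance = 1e-9)
  }
})

test_that("the Lloyd within-SS trace never increases", {
  for (seed in 1:10) {
    set.seed(seed)
    pts <- matrix(rnorm(60), 30, 2)
    fit <- kmeansFit(pts, sample(2:5, 1), replicates = 3, seed = seed)
    expect_true(all(diff(fit@ssHistory) <= 1e-12))
  }
})

test_that("silhouette widths match hand-computed values and stay in [-1, 1]", {
  # two tight 2-point clusters, separation ~1000x internal spread
  pts <- cbind(c(0, 0.001, 1000, 1000.001), 0)
  s <- silhouetteWidths(pts, c(1, 1, 2, 2))
  expect_gt(s$mean, 0.99)

  # a point whose own-cluster and other-cluster mean distances tie
  pts <- cbind(c(0, 4, 2, 6), 0)
  s <- silhouetteWidths(pts, c(1, 1, 2, 2))
  expect_equal(s$widths[1], 0)

  # 5 points in 1-D with a singleton cluster: a_i/b_i evaluated by hand
  pts <- cbind(c(0, 1, 5, 6, 10), 0)
  s <- silhouetteWidths(pts, c(1, 1, 2, 2, 3))
  expect_equal(s$widths,
               c((5.5 - 1) / 5.5, (4.5 - 1) / 4.5, (4.5 - 1) / 4.5,
                 (4 - 1) / 4, 0),
               tolerance = 1e-12)
  expect_error(silhouetteWidths(pts, rep(1, 5)), "2 clusters")

  for (seed in 1:8) {
    set.seed(seed)
    p <- matrix(rnorm(40), 20, 2)
    lab <- sample(1:3, 20, replace = TRUE)
    if (length(unique(lab)) < 2) next
    w <- silhouetteWidths(p, lab)$widths
    expect_true(all(w >= -1 & w <= 1))
  }
})

test_that("silhouette agrees with the cluster package on random data", {
  skip_if_not_installed("cluster")
  set.seed(6)
  pts <- matrix(rnorm(60), 30, 2)
  lab <- kmeansFit(pts, 3, seed = 2)@labels
  ours <- silhouetteWidths(pts, lab)$widths
  ref <- cluster::silhouette(lab, stats::dist(pts))[, "sil_width"]
  expect_equal(ours, unname(ref), tolerance = 1e-12)
})

test_that("silhouette scan selects the planted number of blobs", {
  two <- makeBlobs(rbind(c(0, 0), c(8, 8)), nPer = 12, sd = 0.3, seed = 3)
  sel <- selectK(two, kRange = 2:6, seed = 1)
  expect_equal(sel$bestK, 2L)
  expect_equal(nrow(sel$table), 5L)

  centers <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10), c(5, 20))
  five <- makeBlobs(centers, nPer = 8, sd = 0.2, seed = 4)
  sel <- selectK(five, kRange = 2:8, seed = 1)
  expect_equal(sel$bestK, 5L)

  one <- selectK(two, kRange = 2, seed = 1)
  expect_equal(nrow(one$table), 1L)

  # deterministic under a fixed seed
  expect_identical(selectK(two, kRange = 2:4, seed = 9),
                   selectK(two, kRange = 2:4, seed = 9))
})

test_that("cluster thresholds are member min/max ordered by weighted centroid", {
  pts <- cbind(reaction_time = c(0.1, 0.2, 0.3, 0.8, 0.9, 0.5),
               borg = c(0.15, 0.1, 0.2, 0.85, 0.95, 0.5))
  lab <- c(1, 1, 1, 2, 2, 3)
  gt <- clusterThresholds(pts, lab)
  iv <- levelIntervals(gt)
  expect_equal(unname(iv$reaction_time[1, ]), c(0.1, 0.3))   # low cluster first
  expect_equal(unname(iv$reaction_time[3, ]), c(0.8, 0.9))   # high cluster last
  expect_equal(unname(iv$borg[2, ]), c(0.5, 0.5))            # singleton degenerate
  expect_error(clusterThresholds(pts * 3, lab), "normalized")
  expect_error(clusterThresholds(pts, c(1, 1, 1, 3, 3, 3)), "empty")
})

test_that("weighted threshold combination reproduces the published moderate band", {
  gt <- weightedThresholds(referenceThresholds(), referenceWeights())
  band3 <- fatigueBands(gt)[3, ]
  expect_equal(unname(band3), c(0.39 * 0.21 + 0.61 * 0.31,
                                0.39 * 0.79 + 0.61 * 0.58), tolerance = 1e-12)
  expect_equal(round(unname(band3), 2), c(0.27, 0.66))

  wOne <- weightedThresholds(referenceThresholds(),
                             c(reaction_time = 1, borg = 0))
  expect_equal(fatigueBands(wOne),
               levelIntervals(referenceThresholds())$reaction_time,
               ignore_attr = TRUE)

  sym <- new("GradeThresholds",
             intervals = list(a = cbind(lo = c(0, 0.5), hi = c(0.4, 1)),
                              b = cbind(lo = c(0, 0.5), hi = c(0.4, 1))),
             map = 1:2)
  expect_equal(fatigueBands(weightedThresholds(sym, c(a = 0.5, b = 0.5))),
               cbind(lo = c(0, 0.5), hi = c(0.4, 1)))

  expect_error(weightedThresholds(referenceThresholds(), c(0.2, 0.3, 0.5)),
               "weights")
})

test_that("consolidation merges the published five bands into three levels", {
  gt3 <- consolidateLevels(referenceThresholds())
  expect_equal(consolidationMap(gt3), c(1L, 1L, 2L, 3L, 3L))
  expect_equal(nrow(fatigueBands(gt3)), 3L)
  # merged bands span the unions and stay ordered
  expect_equal(unname(fatigueBands(gt3)[1, ]), c(0.00, 0.30))
  expect_equal(unname(fatigueBands(gt3)[2, ]), c(0.27, 0.66))
  expect_equal(unname(fatigueBands(gt3)[3, ]), c(0.66, 0.92))
  expect_true(all(diff(fatigueBands(gt3)[, "lo"]) >= 0))
})

test_that("consolidation leaves disjoint bands alone and merges nested ones", {
  disjoint <- cbind(c(0, 0.4, 0.8), c(0.3, 0.7, 1))
  out <- consolidateLevels(disjoint)
  expect_equal(out$map, 1:3)
  expect_equal(unname(out$intervals), unname(disjoint))

  nested <- cbind(c(0.1, 0.2), c(0.9, 0.5))
  out <- consolidateLevels(nested)
  expect_equal(out$map, c(1L, 1L))
  expect_equal(unname(out$intervals), cbind(0.1, 0.9), ignore_attr = TRUE)
})
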