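test_that("native labelling thresholds count exactly as expected", {
  ds <- featureSet(matrix(1:3, ncol = 1), energies = c(0, 0, 0),
                   nativeDist = c(1.0, 2.5, 3.0))
  expect_equal(sum(labelNatives(ds, 2)), 1L)
  expect_equal(sum(labelNatives(ds, 0.5)), 0L)
  expect_equal(sum(labelNatives(ds, 3)), 3L)
  expect_equal(attr(labelNatives(ds, 2.5), "total"), 2L)
  noNative <- featureSet(matrix(1:3, ncol = 1))
  expect_error(labelNatives(noNative, 2), "native")
})

test_that("dist_thresh follows the easy / medium / hard difficulty rules", {
  # easy: min_dist 0.5 -> 2 A regardless of the clusters
  dsEasy <- threshFixture(minDist = 0.5, clumpMinDist = 3.1)
  cfg <- chooseDistThresh(dsEasy, leaderCluster(dsEasy, 1))
  expect_equal(cfg$difficulty, "easy")
  expect_equal(cfg$dist_thresh, 2)
  # medium: min_dist 1.3, nearest clump member at 3.1 -> first scanned 3.5
  dsMed <- threshFixture(minDist = 1.3, clumpMinDist = 3.1)
  cfg <- chooseDistThresh(dsMed, leaderCluster(dsMed, 1))
  expect_equal(cfg$difficulty, "medium")
  expect_equal(cfg$dist_thresh, 3.5)
  expect_false(cfg$scan_exhausted)
  # medium with an unreachable clump: scan exhausts at 4.5 with a flag
  dsFar <- threshFixture(minDist = 1.3, clumpMinDist = 30)
  cfg <- chooseDistThresh(dsFar, leaderCluster(dsFar, 1))
  expect_equal(cfg$dist_thresh, 4.5)
  expect_true(cfg$scan_exhausted)
  # hard: min_dist 8.53 -> at least 6 A and natives exist in the largest
  # cluster at the returned threshold
  dsHard <- threshFixture(minDist = 8.53, clumpMinDist = 9.0)
  cfg <- chooseDistThresh(dsHard, leaderCluster(dsHard, 1))
  expect_equal(cfg$difficulty, "hard")
  expect_gte(cfg$dist_thresh, 6)
  expect_equal(cfg$dist_thresh, 9)
  # hard with a close largest cluster still returns the 6 A floor
  dsHard2 <- threshFixture(minDist = 2.5, clumpMinDist = 2.5)
  cfg <- chooseDistThresh(dsHard2, leaderCluster(dsHard2, 1))
  expect_equal(cfg$dist_thresh, 6)
})

test_that("n, p, s reproduce the worked arithmetic on a constructed fixture", {
  # 100 decoys, 20 natives; G1 of 10 decoys holds 4 natives
  labels <- rep(FALSE, 100)
  labels[1:20] <- TRUE
  sel <- new("RankedGroups", strategy = "Basin-Size",
             groups = list(c(1:4, 51:56)), provenance = data.frame(),
             runs = list(), truncated = FALSE)
  sc <- scoreGroups(sel, labels, xMax = 1)
  expect_equal(sc$n, 20)
  expect_equal(sc$p, 40)
  expect_equal(sc$s, 10)
})

test_that("the full-set union and the no-native union hit the metric extremes", {
  labels <- c(rep(TRUE, 20), rep(FALSE, 80))
  full <- new("RankedGroups", strategy = "Basin-Size",
              groups = list(1:100), provenance = data.frame(),
              runs = list(), truncated = FALSE)
  sc <- scoreGroups(full, labels, xMax = 1)
  expect_equal(unlist(sc[1, c("n", "p", "s")]), c(n = 100, p = 20, s = 100))
  empty <- new("RankedGroups", strategy = "Basin-Size",
               groups = list(21:30), provenance = data.frame(),
               runs = list(), truncated = FALSE)
  sc0 <- scoreGroups(empty, labels, xMax = 1)
  expect_equal(sc0$n, 0)
  expect_equal(sc0$p, 0)
})

test_that("zero total natives reports NA metrics, never silent zeros", {
  labels <- rep(FALSE, 50)
  sel <- new("RankedGroups", strategy = "Basin-Size",
             groups = list(1:5), provenance = data.frame(),
             runs = list(), truncated = FALSE)
  sc <- scoreGroups(sel, labels, xMax = 1)
  expect_true(is.na(sc$n))
  expect_true(is.na(sc$p))
  expect_equal(sc$s, 10)
})

test_that("n and s are non-decreasing in x and p is the size-weighted mean of group purities", {
  withr::with_seed(404, {
    for (rep in 1:10) {
      labels <- runif(80) < 0.3
      pool <- sample.int(80)
      groups <- split(pool[1:30], rep(1:3, c(12, 10, 8)))
      sel <- new("RankedGroups", strategy = "Basin-Size",
                 groups = unname(groups), provenance = data.frame(),
                 runs = list(), truncated = FALSE)
      sc <- scoreGroups(sel, labels, xMax = 3)
      expect_true(all(diff(sc$n) >= 0))
      expect_true(all(diff(sc$s) >= 0))
      perGroup <- vapply(groups, function(g) mean(labels[g]), numeric(1))
      weighted <- 100 * sum(perGroup * lengths(groups)) /
        sum(lengths(groups))
      expect_equal(sc$p[3], weighted)
    }
  })
})

test_that("Cluster-Random metrics average over runs and converge to the native fraction", {
  sim <- generatePlanted(plantedLandscapeSpec(2, samplesPerBasin = 100L,
                                              seed = 17))
  labels <- labelNatives(sim$decoys, 2)
  frac <- 100 * mean(labels)
  sel <- clusterRandom(sim$decoys, 50, runs = 400, seed = 3)
  sc <- scoreGroups(sel, labels, xMax = 1)
  se <- 100 * sd(vapply(sel@runs, function(r) mean(labels[r[[1]]]),
                        numeric(1))) / sqrt(400)
  expect_lt(abs(sc$p - frac), 3 * se)
})

test_that("evaluateStrategies returns one metrics row per strategy and x", {
  sim <- generatePlanted(plantedLandscapeSpec(3, samplesPerBasin = 50L,
                                              seed = 23))
  out <- evaluateStrategies(sim$decoys, strategies = c("Cluster-Size",
                                                       "Basin-PR"),
                            epsilon = landscapeEpsilon(sim$decoys),
                            distThresh = 2, x = 3)
  expect_equal(nrow(out$metrics), 6L)
  expect_setequal(unique(out$metrics$strategy),
                  c("Cluster-Size", "Basin-PR"))
  expect_true(all(out$metrics$p >= 0 & out$metrics$p <= 100))
})
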