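abc_basins <- function() {
  data.frame(basin = 1:3, focal = 1:3, size = c(100L, 80L, 50L),
             focalEnergy = c(-50, -60, -40))
}

test_that("strong dominance needs strict improvement in both size and energy", {
  expect_true(dominates(list(size = 100, focalEnergy = -50),
                        list(size = 50, focalEnergy = -40)))
  # one objective each: mutual non-dominance
  expect_false(dominates(list(size = 100, focalEnergy = -50),
                         list(size = 80, focalEnergy = -60)))
  expect_false(dominates(list(size = 80, focalEnergy = -60),
                         list(size = 100, focalEnergy = -50)))
  # irreflexive
  a <- list(size = 10, focalEnergy = -5)
  expect_false(dominates(a, a))
})

test_that("Pareto rank and count match the exhaustive pairwise definition", {
  sc <- paretoScores(abc_basins())
  expect_equal(sc$PR, c(0L, 0L, 2L))
  expect_equal(sc$PC, c(1L, 1L, 0L))
  # identical basins: nobody dominates anybody
  same <- data.frame(basin = 1:4, focal = 1:4, size = rep(7L, 4),
                     focalEnergy = rep(-1, 4))
  expect_equal(paretoScores(same)$PR, rep(0L, 4))
  expect_equal(paretoScores(same)$PC, rep(0L, 4))
})

test_that("PR/PC equal brute force and sum identically on random basin lists", {
  withr::with_seed(42, {
    for (rep in 1:30) {
      nb <- sample(2:50, 1)
      b <- data.frame(basin = seq_len(nb), focal = seq_len(nb),
                      size = sample(1:200, nb, replace = TRUE),
                      focalEnergy = round(rnorm(nb, -30, 10), 2))
      sc <- paretoScores(b)
      oracle <- oraclePareto(b)
      expect_identical(sc$PR, oracle$PR)
      expect_identical(sc$PC, oracle$PC)
      expect_equal(sum(sc$PR), sum(sc$PC))
      expect_identical(which(sc$PR == 0L), oracle$front)
    }
  })
})

fakeBasinSet <- function(b) {
  # BasinSet whose assignment gives each basin row `size` members
  assignment <- rep(b$basin, b$size)
  f <- rep(0, length(assignment))
  focal <- integer(nrow(b))
  pos <- cumsum(c(0, b$size))
  for (i in seq_len(nrow(b))) {
    focal[i] <- pos[i] + 1L
    f[focal[i]] <- b$focalEnergy[i]
    if (b$size[i] > 1L)
      f[(pos[i] + 2L):pos[i + 1L]] <- b$focalEnergy[i] + 1
  }
  b$focal <- focal
  b$saddleVertex <- NA_integer_; b$saddleEnergy <- NA_real_
  b$persistence <- Inf; b$stability <- Inf
  new("BasinSet", assignment = as.integer(assignment), basins = b,
      energies = f, epsilon = 1)
}

test_that("Basin-Size ranks by size and truncation is flagged", {
  bs <- fakeBasinSet(data.frame(basin = 1:3, size = c(5L, 9L, 2L),
                                focalEnergy = c(-1, -2, -3)))
  sel <- rankBasins(bs, "Basin-Size", x = 2)
  expect_equal(sel@provenance$size, c(9L, 5L))
  expect_false(sel@truncated)
  all3 <- rankBasins(bs, "Basin-Size", x = 10)
  expect_length(groupMembers(all3), 3L)
  expect_true(all3@truncated)
})

test_that("Basin-Size+Energy reorders only within the size-top-10 pool", {
  # 12 basins; the 10th-largest has the lowest energy and must lead
  b <- data.frame(basin = 1:12, size = as.integer(101:112),
                  focalEnergy = seq(-1, -12))
  # sizes descending are basins 12..1; top-10 pool = basins 12..3
  # give basin 3 (the 10th largest) the lowest energy
  b$focalEnergy[3] <- -100
  sel <- rankBasins(fakeBasinSet(b), "Basin-Size+Energy", x = 1)
  expect_equal(sel@provenance$basin, 3L)
  # basin 1 and 2 are outside the pool even though basin 1 could rank by energy
  b2 <- b; b2$focalEnergy[1] <- -200
  sel2 <- rankBasins(fakeBasinSet(b2), "Basin-Size+Energy", x = 12)
  expect_false(1L %in% sel2@provenance$basin)
})

test_that("Pareto strategies order the worked A/B/C example with the declared tie-breaks", {
  bs <- fakeBasinSet(abc_basins())
  sel <- rankBasins(bs, "Basin-PR+PC", x = 3)
  # A and B tie on PR=0, PC=1; energy ascending puts B (-60) first; C last
  expect_equal(sel@provenance$basin, c(2L, 1L, 3L))
  selPR <- rankBasins(bs, "Basin-PR", x = 3)
  expect_equal(selPR@provenance$basin, c(2L, 1L, 3L))
  expect_equal(selPR@provenance$PR, c(0L, 0L, 2L))
})

test_that("a basin with strictly maximal size and minimal energy is first under every basin strategy", {
  withr::with_seed(77, {
    for (rep in 1:10) {
      nb <- sample(3:20, 1)
      b <- data.frame(basin = seq_len(nb),
                      size = sample(2:50, nb, replace = TRUE),
                      focalEnergy = rnorm(nb))
      b$size[1] <- max(b$size) + 1L
      b$focalEnergy[1] <- min(b$focalEnergy) - 1
      bs <- fakeBasinSet(b)
      for (s in c("Basin-Size", "Basin-Size+Energy", "Basin-PR",
                  "Basin-PR+PC"))
        expect_equal(rankBasins(bs, s, x = 1)@provenance$basin, 1L)
    }
  })
})

test_that("the end-to-end driver is deterministic and respects the strategy contracts", {
  sim <- generatePlanted(plantedLandscapeSpec(3, samplesPerBasin = 60L,
                                              seed = 12))
  ds <- sim$decoys
  d <- decoyDistances(ds)
  eps <- landscapeEpsilon(d)
  a <- selectDecoys(ds, "Basin-Size", epsilon = eps, distances = d)
  b <- selectDecoys(ds, "Basin-Size", epsilon = eps, distances = d)
  expect_identical(groupMembers(a), groupMembers(b))
  # Cluster-Size: a tight clump dominates G1
  cs <- selectDecoys(ds, "Cluster-Size", epsilon = eps, distances = d)
  expect_equal(length(groupMembers(cs)[[1]]), max(clusterSizes(
    leaderCluster(ds, eps, 1L, d))))
  # Cluster-Random runs match the top cluster sizes
  cr <- selectDecoys(ds, "Cluster-Random", epsilon = eps, distances = d,
                     runs = 5)
  expect_length(cr@runs, 5L)
  sizes <- clusterSizes(leaderCluster(ds, eps, 1L, d))[1:3]
  for (run in cr@runs)
    expect_equal(unname(lengths(run)), unname(sizes))
  expect_error(selectDecoys(ds, "Basin-Weird"), "one of")
})

test_that("when the largest basin is also deepest, size and Pareto rankings agree", {
  sim <- generatePlanted(plantedLandscapeSpec(
    2, samplesPerBasin = c(120L, 40L), depths = c(10, 5), seed = 5))
  ds <- sim$decoys
  d <- decoyDistances(ds)
  eps <- landscapeEpsilon(d)
  g1size <- selectDecoys(ds, "Basin-Size", epsilon = eps, distances = d,
                         x = 1)
  g1pr <- selectDecoys(ds, "Basin-PR", epsilon = eps, distances = d, x = 1)
  expect_identical(sort(groupMembers(g1size)[[1]]),
                   sort(groupMembers(g1pr)[[1]]))
  expect_equal(g1pr@provenance$PR, 0L)
})

test_that("selection tables list one row per selected decoy", {
  sim <- generatePlanted(plantedLandscapeSpec(2, samplesPerBasin = 30L,
                                              seed = 3))
  sel <- selectDecoys(sim$decoys, "Basin-Size", x = 2,
                      epsilon = landscapeEpsilon(sim$decoys))
  tab <- selectionTable(sel, sim$decoys)
  expect_equal(nrow(tab), sum(lengths(groupMembers(sel))))
  expect_true(all(c("rank", "strategy", "id", "PR") %in% names(tab)))
})
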