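test_that("the epsilon graph contains all and only the close pairs", {
  ds <- featureSet(matrix(c(0, 1, 2, 10), ncol = 1),
                   energies = c(1, 2, 3, 4))
  g <- buildNNGraph(ds, 1.5)
  edges <- apply(g@edges, 1, paste, collapse = "-")
  expect_setequal(edges, c("1-2", "2-3"))
  expect_equal(nComponents(g), 2L)
  # complete graph above the diameter, edgeless below the minimum gap
  expect_equal(nrow(buildNNGraph(ds, 100)@edges), 6L)
  expect_equal(nComponents(buildNNGraph(ds, 100)), 1L)
  tiny <- buildNNGraph(ds, 0.5)
  expect_equal(nrow(tiny@edges), 0L)
  expect_equal(nComponents(tiny), 4L)
  expect_error(buildNNGraph(ds, 0), "positive")
})

test_that("local minima follow the non-strict neighborhood rule", {
  p <- pathLandscape()
  expect_equal(findLocalMinima(p$g, p$f), c(2L, 4L))
  # constant energies: every vertex is a local minimum
  expect_equal(findLocalMinima(p$g, rep(1, 4)), 1:4)
  # edgeless graph: all vertices are minima
  ds <- featureSet(matrix(c(0, 10, 20), ncol = 1))
  g0 <- buildNNGraph(ds, 1)
  expect_equal(findLocalMinima(g0, c(5, 1, 3)), 1:3)
})

test_that("the hand-traced path landscape yields the known basins, saddle and persistence", {
  p <- pathLandscape()
  bs <- assignBasins(p$g, p$f)
  expect_equal(basinAssignment(bs), c(1L, 1L, 2L, 2L))
  b <- basinTable(bs)
  expect_equal(b$focal, c(2L, 4L))
  expect_equal(b$focalEnergy, c(1, 0.5))
  # vertex 3 descends to 4: ratio (2-0.5)/1 beats (2-1)/1
  bs <- computeSaddles(p$g, bs)
  b <- basinTable(bs)
  expect_equal(b$saddleVertex, c(NA_integer_, 3L))
  expect_equal(b$persistence, c(Inf, 1.5))
  bs <- computeStability(bs)
  expect_equal(basinTable(bs)$stability, c(Inf, 1.5 / sqrt(2)))
})

test_that("a single vertex forms one basin with infinite persistence", {
  ds <- featureSet(matrix(0, 1, 1), energies = -3)
  g <- buildNNGraph(ds, 1)
  bs <- computeStability(computeSaddles(g, assignBasins(g, -3)))
  expect_equal(length(bs), 1L)
  expect_equal(basinTable(bs)$persistence, Inf)
})

test_that("basin assignment equals the exhaustive steepest-ratio descent oracle on random graphs", {
  withr::with_seed(101, {
    for (rep in 1:50) {
      case <- randomGraphCase(sample(5:30, 1))
      bs <- assignBasins(case$g, case$f)
      target <- oracleDescent(case$g, case$f)
      expect_identical(basinAssignment(bs),
                       as.integer(match(target, sort(unique(target)))))
      # partition invariants
      b <- basinTable(bs)
      expect_equal(sum(b$size), length(case$g))
      expect_true(all(b$focal %in% findLocalMinima(case$g, case$f)))
    }
  })
})

test_that("descent paths never cross component boundaries and energies are non-increasing", {
  withr::with_seed(55, {
    case <- randomGraphCase(40)
  })
  bs <- assignBasins(case$g, case$f)
  b <- basinTable(bs)
  expect_true(all(case$g@membership[b$focal[basinAssignment(bs)]] ==
                  case$g@membership))
  # focal energy is the basin minimum
  for (bi in b$basin)
    expect_equal(b$focalEnergy[bi],
                 min(case$f[basinAssignment(bs) == bi]))
})

test_that("saddles carry the minimal escape barrier, cross-checked exhaustively", {
  withr::with_seed(77, {
    for (rep in 1:20) {
      case <- randomGraphCase(sample(8:25, 1))
      bs <- computeSaddles(case$g, assignBasins(case$g, case$f))
      a <- basinAssignment(bs)
      b <- basinTable(bs)
      f <- case$f
      e <- case$g@edges
      for (bi in b$basin) {
        # brute force over all vertices of the basin
        qual <- Inf
        for (u in which(a == bi)) {
          sel <- which(e[, 1L] == u | e[, 2L] == u)
          nb <- ifelse(e[sel, 1L] == u, e[sel, 2L], e[sel, 1L])
          if (any(f[nb] < f[u] & a[nb] != bi)) qual <- min(qual, f[u])
        }
        if (is.finite(qual)) {
          expect_equal(b$saddleEnergy[bi], qual)
          expect_equal(b$persistence[bi], qual - b$focalEnergy[bi])
          expect_gte(b$persistence[bi], 0)
        } else {
          expect_true(is.infinite(b$persistence[bi]))
        }
      }
    }
  })
})

test_that("stability is persistence over sqrt(2), hence strictly monotone in persistence", {
  withr::with_seed(13, {
    case <- randomGraphCase(30)
  })
  bs <- computeStability(computeSaddles(case$g,
                                        assignBasins(case$g, case$f)))
  b <- basinTable(bs)
  expect_equal(b$stability, b$persistence / sqrt(2))
  fin <- is.finite(b$persistence)
  if (sum(fin) > 1) {
    o <- order(b$persistence[fin])
    expect_true(all(diff(b$stability[fin][o]) >= 0))
  }
})

test_that("persistence merging respects thresholds and component structure", {
  p <- pathLandscape()
  bs <- assignBasins(p$g, p$f)
  # p_thresh = 0: nothing merges
  expect_equal(length(mergeByPersistence(p$g, bs, 0)), 2L)
  # threshold above the energy range: one basin per component
  merged <- mergeByPersistence(p$g, bs, 100)
  expect_equal(length(merged), 1L)
  expect_equal(basinTable(merged)$focalEnergy, 0.5)
  withr::with_seed(202, {
    case <- randomGraphCase(40)
  })
  all_merged <- mergeByPersistence(case$g, assignBasins(case$g, case$f),
                                   diff(range(case$f)) + 1)
  expect_equal(length(all_merged), case$g@nComponents)
})

test_that("a shallow middle well merges into its saddle-adjacent neighbor at the analytic threshold", {
  # deterministic 1D three-well landscape, well depths 5, 1, 4
  spec <- plantedLandscapeSpec(3, dim = 1L, samplesPerBasin = 1L,
                               centers = matrix(c(0, 6, 12), ncol = 1),
                               depths = c(5, 1, 4), noiseSd = 0,
                               separation = 6)
  x <- matrix(seq(-2, 14, by = 0.1), ncol = 1)
  ds <- featureSet(x, energies = plantedEnergy(spec, x))
  g <- buildNNGraph(ds, 0.15)
  bs <- computeSaddles(g, assignBasins(g, unname(energies(ds))))
  expect_equal(length(bs), 3L)
  # middle well depth ~1 (minus tails): persistence below 2, others above
  merged <- mergeByPersistence(g, bs, 2)
  expect_equal(length(merged), 2L)
  expect_equal(sort(merged@basins$focalEnergy),
               sort(bs@basins$focalEnergy[c(1, 3)]), tolerance = 1e-6)
})

test_that("persistence filtration is idempotent: merging at p1 then p2 equals merging at p2", {
  spec <- plantedLandscapeSpec(4, samplesPerBasin = 80L, seed = 31)
  sim <- generatePlanted(spec)
  d <- decoyDistances(sim$decoys)
  g <- buildNNGraph(d, landscapeEpsilon(d))
  bs <- assignBasins(g, unname(energies(sim$decoys)))
  p1 <- spec$noiseSd; p2 <- 3 * spec$noiseSd
  twostep <- mergeByPersistence(g, mergeByPersistence(g, bs, p1), p2)
  onestep <- mergeByPersistence(g, bs, p2)
  expect_identical(basinAssignment(twostep), basinAssignment(onestep))
  expect_equal(basinTable(twostep), basinTable(onestep))
})

test_that("basin export table matches the assignment", {
  p <- pathLandscape()
  bs <- computeStability(computeSaddles(p$g, assignBasins(p$g, p$f)))
  tab <- basinAssignmentTable(bs, p$ds)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$basin, basinAssignment(bs))
  expect_equal(tab$focal_id[3], decoyIds(p$ds)[4])
})
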