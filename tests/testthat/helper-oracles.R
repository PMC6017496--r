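# Independent oracles and fixture builders shared across test files.

# DecoySet over 1D/ND feature points
featureSet <- function(points, energies = NULL, nativeDist = NULL) {
  pts <- as.matrix(points)
  DecoySet(energies = energies %||% rep(0, nrow(pts)),
           nativeDist = nativeDist, features = pts,
           distanceMode = "precomputed_features")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# the 4-vertex path landscape: energies 3, 1, 2, 0.5 at unit spacing
pathLandscape <- function() {
  ds <- featureSet(matrix(0:3, ncol = 1), energies = c(3, 1, 2, 0.5))
  list(ds = ds, g = buildNNGraph(ds, 1), f = c(3, 1, 2, 0.5))
}

# random connected-ish epsilon graph over random feature points
randomGraphCase <- function(n, dim = 2L) {
  pts <- matrix(runif(n * dim, 0, 3), n, dim)
  f <- rnorm(n)
  d <- as.matrix(dist(pts))
  eps <- runif(1, 0.8, 2.5)
  list(g = buildNNGraph(d, eps), f = f, d = d)
}

# exhaustive per-vertex steepest-ratio descent, independent of assignBasins
oracleDescent <- function(g, f) {
  n <- length(g)
  adj <- lapply(seq_len(n), function(u) {
    sel <- which(g@edges[, 1L] == u | g@edges[, 2L] == u)
    v <- ifelse(g@edges[sel, 1L] == u, g@edges[sel, 2L], g@edges[sel, 1L])
    o <- order(v)
    list(v = v[o], d = g@dists[sel][o])
  })
  vapply(seq_len(n), function(u) {
    repeat {
      nb <- adj[[u]]
      if (!length(nb$v)) return(u)
      ratio <- (f[u] - f[nb$v]) / nb$d
      if (max(ratio) <= 0) return(u)
      u <- nb$v[which.max(ratio)]
    }
  }, integer(1))
}

# O(B^2) brute-force Pareto rank/count on a basin table
oraclePareto <- function(b) {
  n <- nrow(b)
  PR <- PC <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && b$size[i] > b$size[j] &&
        b$focalEnergy[i] < b$focalEnergy[j]) {
      PC[i] <- PC[i] + 1L
      PR[j] <- PR[j] + 1L
    }
  }
  list(PR = PR, PC = PC,
       front = which(PR == 0L))
}

# least-RMSD oracle: coarse Euler-angle grid + Nelder-Mead refinement,
# independent of the Kabsch route
oracleLrmsd <- function(a, b) {
  ac <- scale(a, scale = FALSE)
  bc <- scale(b, scale = FALSE)
  rotmat <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((bc %*% t(rotmat(ang)) - ac)^2)))
  grid <- seq(0, 2 * pi, length.out = 13L)[-13L]
  best <- c(0, 0, 0); bestv <- obj(best)
  for (x in grid) for (y in grid) for (z in grid) {
    v <- obj(c(x, y, z))
    if (v < bestv) { bestv <- v; best <- c(x, y, z) }
  }
  opt <- optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# fixture with controlled native distances and a controlled largest cluster:
# a clump of `clumpN` nearby points (the largest cluster at epsilon = 1)
# whose nearest member sits clumpMinDist from the native, plus two far
# singletons, one at the overall min_dist
threshFixture <- function(minDist, clumpMinDist, clumpN = 6L) {
  clump <- seq(0, by = 0.1, length.out = clumpN)
  x <- matrix(c(clump, 100, 200), ncol = 1)
  nd <- c(seq(clumpMinDist, by = 0.3, length.out = clumpN), minDist, 50)
  featureSet(x, nativeDist = nd)
}

# tight two-well + broad-well landscape used for the headline contrast
contrastSpec <- function(seed) {
  plantedLandscapeSpec(2, samplesPerBasin = c(60L, 400L),
                       depths = c(10, 6), widths = c(1, 2.5),
                       centers = rbind(c(0, 0), c(12, 0)),
                       nativeIndex = 1L, seed = seed)
}
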