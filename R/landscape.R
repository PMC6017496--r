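#' Build the epsilon-nearest-neighbor graph of a decoy set
#'
#' Embeds the decoy set in an undirected graph: vertices are decoys and every
#' pair at conformational distance at most \code{epsilon} is joined by an
#' edge storing that distance. A small epsilon can leave the graph
#' disconnected under non-uniform sampling; the component count is reported
#' (and printed by \code{show}) so the caller can decide to raise epsilon —
#' see [connectEpsilon()] — but nothing is repaired silently.
#'
#' @param x a [DecoySet-class], or a symmetric pairwise distance matrix
#' @param epsilon neighborhood radius (> 0)
#' @return an [NNGraph-class]
#' @examples
#' ds <- DecoySet(energies = c(3, 1, 2, 0.5),
#'                features = matrix(c(0, 1, 2, 10), ncol = 1))
#' g <- buildNNGraph(ds, epsilon = 1.5)
#' nComponents(g)  # 2: {1,2,3} and {4}
#' @export
buildNNGraph <- function(x, epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0 ||
      !is.finite(epsilon))
    stop("epsilon must be a single positive number")
  d <- if (is.matrix(x)) x else decoyDistances(x)
  n <- nrow(d)
  if (n < 1L) stop("empty decoy set")
  idx <- which(upper.tri(d) & d <= epsilon, arr.ind = TRUE)
  edges <- matrix(as.integer(idx), ncol = 2L,
                  dimnames = list(NULL, c("u", "v")))
  dists <- d[idx]
  ig <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) ig <- igraph::add_edges(ig, t(edges))
  comp <- igraph::components(ig)
  new("NNGraph", epsilon = as.numeric(epsilon), edges = edges,
      dists = as.numeric(dists), nVertices = as.integer(n),
      membership = as.integer(comp$membership),
      nComponents = as.integer(comp$no))
}

#' @describeIn buildNNGraph number of vertices
#' @export
setMethod("length", "NNGraph", function(x) as.integer(x@nVertices))

#' @rdname nComponents
#' @export
setMethod("nComponents", "NNGraph", function(x) x@nComponents)

#' @rdname epsilon
#' @export
setMethod("epsilon", "NNGraph", function(x) x@epsilon)

setMethod("show", "NNGraph", function(object) {
  cat("NNGraph:", object@nVertices, "vertices,", nrow(object@edges),
      "edges (epsilon =", object@epsilon, ")\n")
  cat("  connected components:", object@nComponents, "\n")
})

#' Edge list of an NNGraph
#' @param g an [NNGraph-class]
#' @param path optional TSV output path
#' @return data.frame with columns u, v, dist
#' @export
graphEdgeList <- function(g, path = NULL) {
  stopifnot(is(g, "NNGraph"))
  tab <- data.frame(u = g@edges[, 1L], v = g@edges[, 2L], dist = g@dists)
  if (!is.null(path))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  tab
}

# adjacency list: per vertex, integer neighbors (ascending) + edge distances
.adjacency <- function(g) {
  n <- g@nVertices
  nbr <- vector("list", n)
  dst <- vector("list", n)
  if (nrow(g@edges)) {
    e <- g@edges
    for (k in seq_len(nrow(e))) {
      u <- e[k, 1L]; v <- e[k, 2L]; w <- g@dists[k]
      nbr[[u]] <- c(nbr[[u]], v); dst[[u]] <- c(dst[[u]], w)
      nbr[[v]] <- c(nbr[[v]], u); dst[[v]] <- c(dst[[v]], w)
    }
    for (u in seq_len(n)) {
      if (is.null(nbr[[u]])) next  # isolated vertex
      o <- order(nbr[[u]])
      nbr[[u]] <- nbr[[u]][o]; dst[[u]] <- dst[[u]][o]
    }
  }
  list(nbr = nbr, dst = dst)
}

.check_energies <- function(g, f) {
  if (length(f) != g@nVertices)
    stop("need one energy per vertex")
  if (!all(is.finite(f))) stop("energies must be finite")
  as.numeric(f)
}

#' Local minima of energies on an NNGraph
#'
#' A vertex u is a local minimum when f(u) <= f(v) for every neighbor v;
#' equivalently, when no neighbor lies strictly below it. Isolated vertices
#' have an empty neighborhood and are local minima vacuously; on an
#' equal-energy plateau every vertex is a local minimum.
#'
#' @param g an [NNGraph-class]
#' @param f numeric vector of per-vertex energies
#' @return integer vector of local-minimum vertex indices
#' @export
findLocalMinima <- function(g, f) {
  f <- .check_energies(g, f)
  adj <- .adjacency(g)
  which(vapply(seq_len(g@nVertices), function(u) {
    nb <- adj$nbr[[u]]
    !length(nb) || !any(f[nb] < f[u])
  }, logical(1)))
}

# per-vertex descent step: index of the steepest-ratio strictly-lower
# neighbor, or 0 when the vertex is a local minimum. Ties on the maximal
# ratio go to the lowest-index neighbor (neighbors are stored ascending).
.descent_step <- function(u, f, adj) {
  nb <- adj$nbr[[u]]
  if (!length(nb)) return(0L)
  ratio <- (f[u] - f[nb]) / adj$dst[[u]]
  best <- max(ratio)
  if (best <= 0) return(0L)
  nb[which.max(ratio)]
}

#' Assign decoys to basins by discrete negative-gradient descent
#'
#' Every vertex that is not a local minimum follows, iteratively, the edge
#' (u, v) maximizing the ratio (f(u) - f(v)) / d(u, v) until a local minimum
#' is reached; vertices reaching the same minimum form one basin, with that
#' minimum as the basin's focal minimum. Each local minimum founds its own
#' basin, so basins partition the vertices of every connected component.
#' Ties on the maximal ratio are broken toward the lowest-index neighbor,
#' which (with descent only along strictly decreasing edges) guarantees
#' finite, acyclic descent paths.
#'
#' Basins are numbered 1..B in order of their focal vertex index. Saddles,
#' persistence and stability are filled in by [computeSaddles()] and
#' [computeStability()].
#'
#' @param g an [NNGraph-class]
#' @param f numeric vector of per-vertex energies
#' @return a [BasinSet-class]
#' @examples
#' ds <- DecoySet(energies = c(3, 1, 2, 0.5),
#'                features = matrix(0:3, ncol = 1))
#' bs <- assignBasins(buildNNGraph(ds, 1), energies(ds))
#' basinAssignment(bs)  # 1 1 2 2
#' @export
assignBasins <- function(g, f) {
  f <- .check_energies(g, f)
  adj <- .adjacency(g)
  n <- g@nVertices
  step <- vapply(seq_len(n), .descent_step, integer(1), f = f, adj = adj)
  target <- integer(n)  # focal minimum reached from each vertex
  for (u in seq_len(n)) {
    v <- u
    path <- integer(0)
    while (step[v] != 0L && target[v] == 0L) {
      path <- c(path, v)
      v <- step[v]
      if (length(path) > n)
        stop("internal error: cycle detected in the descent map")
    }
    focus <- if (target[v] != 0L) target[v] else v
    target[c(path, u)] <- focus
  }
  foci <- sort(unique(target))
  assignment <- match(target, foci)
  basins <- data.frame(
    basin = seq_along(foci),
    focal = foci,
    size = as.vector(table(factor(assignment, levels = seq_along(foci)))),
    focalEnergy = f[foci],
    saddleVertex = NA_integer_,
    saddleEnergy = NA_real_,
    persistence = NA_real_,
    stability = NA_real_)
  new("BasinSet", assignment = as.integer(assignment), basins = basins,
      energies = f, epsilon = g@epsilon)
}

#' @rdname basinTable
#' @export
setMethod("basinTable", "BasinSet", function(x) x@basins)

#' @rdname basinAssignment
#' @export
setMethod("basinAssignment", "BasinSet", function(x) x@assignment)

#' @describeIn assignBasins number of basins
#' @param x a BasinSet
#' @export
setMethod("length", "BasinSet", function(x) nrow(x@basins))

#' @rdname epsilon
#' @export
setMethod("epsilon", "BasinSet", function(x) x@epsilon)

setMethod("show", "BasinSet", function(object) {
  b <- object@basins
  cat("BasinSet:", nrow(b), "basins over", length(object@assignment),
      "decoys (epsilon =", object@epsilon, ")\n")
  top <- utils::head(b[order(-b$size), ], 3L)
  cat("  largest: size", paste(top$size, collapse = ", "),
      "| focal energies:",
      paste(format(top$focalEnergy, digits = 4), collapse = ", "), "\n")
})

#' Pseudo-saddles and persistence of basins
#'
#' For each basin B, a pseudo-saddle is a vertex u assigned to B that has a
#' neighbor v with f(v) < f(u) assigned to a different basin; among all such
#' vertices the one with the lowest energy is taken as the saddle, making the
#' basin's persistence f(saddle) - f(focal) the minimal barrier out of the
#' basin. Basins with no such escape vertex (e.g. the deepest basin of a
#' connected component) get infinite persistence.
#'
#' @param g the [NNGraph-class] the basins were computed on
#' @param bs a [BasinSet-class]
#' @return \code{bs} with saddleVertex, saddleEnergy and persistence filled
#' @export
computeSaddles <- function(g, bs) {
  stopifnot(is(g, "NNGraph"), is(bs, "BasinSet"))
  f <- bs@energies
  a <- bs@assignment
  b <- bs@basins
  b$saddleVertex <- NA_integer_
  b$saddleEnergy <- NA_real_
  if (nrow(g@edges)) {
    e <- g@edges
    for (k in seq_len(nrow(e))) {
      u <- e[k, 1L]; v <- e[k, 2L]
      if (a[u] == a[v]) next
      # the higher endpoint qualifies as an escape vertex of its basin
      if (f[v] < f[u]) {
        hi <- u
      } else if (f[u] < f[v]) {
        hi <- v
      } else next
      bi <- a[hi]
      cur <- b$saddleEnergy[bi]
      if (is.na(cur) || f[hi] < cur ||
          (f[hi] == cur && hi < b$saddleVertex[bi])) {
        b$saddleVertex[bi] <- hi
        b$saddleEnergy[bi] <- f[hi]
      }
    }
  }
  b$persistence <- ifelse(is.na(b$saddleEnergy), Inf,
                          b$saddleEnergy - b$focalEnergy)
  bs@basins <- b
  bs
}

#' Basin stability
#'
#' In the plane of (focal energy, saddle energy), each basin sits above the
#' identity line; its perpendicular distance from that line,
#' |f(saddle) - f(focal)| / sqrt(2), is the basin's stability — a rescaled
#' persistence. Infinite-persistence basins have infinite stability.
#'
#' @param bs a [BasinSet-class] with saddles computed
#' @return \code{bs} with the stability column filled
#' @export
computeStability <- function(bs) {
  stopifnot(is(bs, "BasinSet"))
  if (anyNA(bs@basins$persistence))
    stop("compute saddles before stability")
  bs@basins$stability <- abs(bs@basins$persistence) / sqrt(2)
  bs
}

# rebuild the basin table from an assignment vector, renumbering basins
# 1..B by focal vertex index; saddles left unfilled
.rebuild_basins <- function(assignment, f, epsilon) {
  ids <- sort(unique(assignment))
  foci <- vapply(ids, function(b) {
    m <- which(assignment == b)
    m[which.min(f[m])]
  }, integer(1))
  o <- order(foci)
  ids <- ids[o]; foci <- foci[o]
  assignment <- match(assignment, ids)
  basins <- data.frame(
    basin = seq_along(ids), focal = foci,
    size = as.vector(table(factor(assignment, levels = seq_along(ids)))),
    focalEnergy = f[foci],
    saddleVertex = NA_integer_, saddleEnergy = NA_real_,
    persistence = NA_real_, stability = NA_real_)
  new("BasinSet", assignment = as.integer(assignment), basins = basins,
      energies = f, epsilon = epsilon)
}

#' Merge shallow basins by topological persistence
#'
#' Iteratively merges away basins shallower than \code{pThresh}: at each
#' step the surviving basin with the lowest persistence below the threshold
#' is absorbed into the basin reached across its saddle (the basin of the
#' saddle's lowest strictly-lower neighbor on the other side). Saddles and
#' persistence are recomputed after every merge, and the process stops when
#' all surviving basins have persistence >= pThresh. Infinite-persistence
#' basins never merge, so each connected component keeps at least one basin.
#'
#' Low thresholds (1 to 3 energy units, close to no filtering) retain the
#' basin structure that matters for decoy selection; the package default is
#' \code{pThresh = 1}.
#'
#' @param g the [NNGraph-class] the basins were computed on
#' @param bs a [BasinSet-class]
#' @param pThresh persistence threshold (>= 0)
#' @return the merged [BasinSet-class] with saddles and stability filled
#' @export
mergeByPersistence <- function(g, bs, pThresh) {
  stopifnot(is(g, "NNGraph"), is(bs, "BasinSet"), pThresh >= 0)
  f <- bs@energies
  adj <- NULL
  bs <- computeSaddles(g, bs)
  repeat {
    b <- bs@basins
    cand <- which(is.finite(b$persistence) & b$persistence < pThresh)
    if (!length(cand)) break
    victim <- cand[order(b$persistence[cand], b$basin[cand])][1L]
    u <- b$saddleVertex[victim]
    if (is.null(adj)) adj <- .adjacency(g)
    nb <- adj$nbr[[u]]
    out <- nb[f[nb] < f[u] & bs@assignment[nb] != victim]
    v <- out[order(f[out], out)][1L]
    assignment <- bs@assignment
    assignment[assignment == victim] <- assignment[v]
    bs <- computeSaddles(g, .rebuild_basins(assignment, f, g@epsilon))
  }
  computeStability(bs)
}

#' Export basin assignments as a table
#'
#' @param bs a [BasinSet-class] (saddles/stability computed or not)
#' @param ds the underlying [DecoySet-class] (for ids)
#' @param path optional TSV output path
#' @return data.frame with columns id, basin, focal_id, focal_energy,
#'   persistence, stability
#' @export
basinAssignmentTable <- function(bs, ds, path = NULL) {
  stopifnot(is(bs, "BasinSet"), is(ds, "DecoySet"))
  b <- bs@basins
  a <- bs@assignment
  tab <- data.frame(
    id = decoyIds(ds),
    basin = a,
    focal_id = decoyIds(ds)[b$focal[a]],
    focal_energy = b$focalEnergy[a],
    persistence = b$persistence[a],
    stability = b$stability[a],
    stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  tab
}
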