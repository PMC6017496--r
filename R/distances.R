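.as_xyz <- function(m) as.vector(t(m))

.check_conformation_pair <- function(a, b) {
  if (!is.matrix(a) || !is.matrix(b) || ncol(a) != 3L || ncol(b) != 3L)
    stop("conformations must be n x 3 coordinate matrices")
  if (nrow(a) < 3L || nrow(b) < 3L)
    stop("conformations need at least 3 points")
  if (nrow(a) != nrow(b))
    stop("conformations have mismatched point counts (", nrow(a), " vs ",
         nrow(b), ")")
}

#' Least RMSD between two conformations
#'
#' Root-mean-squared deviation after the optimal rigid-body (Kabsch)
#' superposition of \code{b} onto \code{a}. Points must correspond in order.
#' The result is symmetric, non-negative, and zero iff the two conformations
#' differ only by a rigid motion.
#'
#' @param a,b n x 3 coordinate matrices (Angstrom), equal point counts.
#' @return least RMSD in Angstrom
#' @examples
#' helix <- referenceHelix(12)
#' rot <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
#' lrmsd(helix, helix %*% rot + 5)  # rigid motion: 0
#' @export
lrmsd <- function(a, b) {
  .check_conformation_pair(a, b)
  inds <- seq_len(3L * nrow(a))
  fitted <- bio3d::fit.xyz(.as_xyz(a), .as_xyz(b),
                           fixed.inds = inds, mobile.inds = inds)
  sqrt(mean(rowSums((matrix(fitted, ncol = 3L, byrow = TRUE) - a)^2)))
}

#' Plain (superposition-free) RMSD between two conformations
#'
#' Coordinate RMSD with no superposition; an upper bound on [lrmsd()]. Used
#' between decoys that have already been superposed onto a common reference.
#'
#' @inheritParams lrmsd
#' @return RMSD in Angstrom
#' @export
plainRmsd <- function(a, b) {
  .check_conformation_pair(a, b)
  sqrt(mean(rowSums((a - b)^2)))
}

#' Superpose every decoy onto one reference decoy
#'
#' Rigid-body superposes all conformations (and the native, if present) onto
#' the conformation of \code{refIndex}, minimizing RMSD to it. After this,
#' pairwise distances can be computed as plain RMSD between any two decoys,
#' which trades a per-pair superposition for a single pass; the first decoy
#' is the default reference.
#'
#' @param ds a [DecoySet-class] carrying coordinates
#' @param refIndex index of the reference decoy (default 1)
#' @return the superposed [DecoySet-class]
#' @export
superposeToReference <- function(ds, refIndex = 1L) {
  stopifnot(is(ds, "DecoySet"))
  if (!length(ds@coords)) stop("this DecoySet carries no coordinates")
  n <- length(ds)
  if (length(refIndex) != 1L || is.na(refIndex) || refIndex < 1L ||
      refIndex > n)
    stop("invalid reference index: ", refIndex)
  ref <- ds@coords[[refIndex]]
  inds <- seq_len(3L * nrow(ref))
  fit_one <- function(m) {
    matrix(bio3d::fit.xyz(.as_xyz(ref), .as_xyz(m),
                          fixed.inds = inds, mobile.inds = inds),
           ncol = 3L, byrow = TRUE)
  }
  ds@coords <- lapply(ds@coords, fit_one)
  if (!is.null(ds@native)) ds@native <- fit_one(ds@native)
  validObject(ds)
  ds
}

#' @rdname decoyDistances
#' @export
setMethod("decoyDistances", "DecoySet", function(x, mode = distanceMode(x)) {
  mode <- match.arg(mode, .distanceModes)
  n <- length(x)
  if (mode == "precomputed_features") {
    if (is.null(x@features))
      stop("precomputed_features mode requires a feature matrix")
    d <- as.matrix(stats::dist(x@features))
  } else {
    if (!length(x@coords)) stop("this DecoySet carries no coordinates")
    d <- matrix(0, n, n)
    if (mode == "reference_superposed_rmsd") {
      xs <- superposeToReference(x, 1L)
      flat <- t(vapply(xs@coords, .as_xyz, numeric(3L * nrow(xs@coords[[1L]]))))
      d <- as.matrix(stats::dist(flat)) / sqrt(nrow(xs@coords[[1L]]))
    } else {
      for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
        d[i, j] <- d[j, i] <- lrmsd(x@coords[[i]], x@coords[[j]])
      }
    }
  }
  dimnames(d) <- list(x@ids, x@ids)
  d
})

#' Smallest epsilon producing a connected neighborhood graph
#'
#' Non-uniform sampling can leave the epsilon-graph disconnected; the remedy
#' is a larger epsilon. This helper returns the smallest radius under which
#' the graph is connected: the longest edge of a minimum spanning tree of the
#' pairwise distances (times a tiny slack so the edge itself qualifies).
#'
#' @param x a [DecoySet-class] or a symmetric distance matrix
#' @param slack multiplicative slack on the critical radius (default 1.001)
#' @return epsilon (Angstrom, or feature units)
#' @export
connectEpsilon <- function(x, slack = 1.001) {
  d <- if (is.matrix(x)) x else decoyDistances(x)
  if (nrow(d) < 2L) return(1)
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  max(igraph::E(mst)$weight) * slack
}

#' Default neighborhood radius for landscape analysis
#'
#' A graph at the bare connectivity radius ([connectEpsilon()]) is too
#' sparse where sampling thins out: rim vertices with no downhill neighbor
#' become spurious local minima, some of them unmergeable (a singleton
#' minimum has no escape vertex, hence infinite persistence). Densifying
#' the neighborhoods suppresses these artifacts, while a radius approaching
#' the inter-basin scale starts bridging distinct basins. The default of
#' 1.5 times the connectivity radius sits between the two regimes and is
#' the radius the package uses when none is supplied for feature-space
#' sets.
#'
#' @inheritParams connectEpsilon
#' @param factor densification factor over the connectivity radius
#'   (default 1.5)
#' @return epsilon (Angstrom, or feature units)
#' @export
landscapeEpsilon <- function(x, factor = 1.5) {
  stopifnot(factor >= 1)
  connectEpsilon(x) * factor
}
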