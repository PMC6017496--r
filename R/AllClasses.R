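#' @import methods
NULL

#' DecoySet: a set of decoy conformations with energies
#'
#' Container for a decoy ensemble \eqn{\Omega}: one candidate conformation per
#' decoy (optionally Calpha-only), a scalar energy per decoy (e.g. Rosetta
#' score12 REU, but any score works), an optional native reference
#' conformation, optional cached distances to the native, and an optional
#' feature matrix for sets that come pre-digested as low-dimensional vectors
#' rather than coordinates.
#'
#' The \code{distanceMode} slot selects how pairwise conformational distances
#' are computed downstream:
#' \describe{
#'   \item{\code{"reference_superposed_rmsd"}}{the default: all decoys are
#'     rigid-body superposed onto one reference decoy once, after which plain
#'     (superposition-free) RMSD is used between any two decoys.}
#'   \item{\code{"full_lrmsd"}}{exact pairwise least-RMSD with a Kabsch
#'     superposition per pair (O(n^2) superpositions).}
#'   \item{\code{"precomputed_features"}}{Euclidean distance on the rows of
#'     the \code{features} matrix; used for tabular/synthetic sets that carry
#'     no coordinates.}
#' }
#'
#' @slot ids character vector of unique decoy identifiers.
#' @slot energies numeric vector of per-decoy energies (finite).
#' @slot coords list of n_atoms x 3 coordinate matrices (Angstrom), one per
#'   decoy, or an empty list for tabular sets.
#' @slot atomLabels character vector of atom labels shared by all decoys
#'   (\code{"<resno>:<atom name>"}), empty for tabular sets.
#' @slot native optional n_atoms x 3 matrix with the native reference
#'   conformation, or \code{NULL}.
#' @slot nativeDist numeric vector of distances to the native (Angstrom),
#'   \code{NA} where unknown.
#' @slot features optional numeric matrix (decoys x features), or \code{NULL}.
#' @slot distanceMode one of \code{"reference_superposed_rmsd"},
#'   \code{"full_lrmsd"}, \code{"precomputed_features"}.
#'
#' @seealso [DecoySet()] for the user-facing constructor, [readDecoySet()],
#'   [decoyDistances()].
#' @export
setClass("DecoySet",
  slots = c(
    ids = "character",
    energies = "numeric",
    coords = "list",
    atomLabels = "character",
    native = "ANY",
    nativeDist = "numeric",
    features = "ANY",
    distanceMode = "character"
  )
)

.distanceModes <- c("reference_superposed_rmsd", "full_lrmsd",
                    "precomputed_features")

setValidity("DecoySet", function(object) {
  msg <- character(0)
  n <- length(object@ids)
  if (n < 1L) msg <- c(msg, "a DecoySet must contain at least one decoy")
  if (anyDuplicated(object@ids)) msg <- c(msg, "decoy ids must be unique")
  if (length(object@energies) != n)
    msg <- c(msg, "energies must have one value per decoy")
  if (!all(is.finite(object@energies)))
    msg <- c(msg, "energies must be finite")
  if (length(object@nativeDist) != n)
    msg <- c(msg, "nativeDist must have one value per decoy (NA allowed)")
  if (any(object@nativeDist < 0, na.rm = TRUE))
    msg <- c(msg, "nativeDist values must be non-negative")
  if (!object@distanceMode %in% .distanceModes)
    msg <- c(msg, paste("distanceMode must be one of:",
                        paste(.distanceModes, collapse = ", ")))
  if (length(object@coords)) {
    if (length(object@coords) != n)
      msg <- c(msg, "coords must have one matrix per decoy")
    na <- nrow(object@coords[[1L]])
    ok <- vapply(object@coords, function(m) {
      is.matrix(m) && ncol(m) == 3L && nrow(m) == na && all(is.finite(m))
    }, logical(1))
    if (!all(ok))
      msg <- c(msg, "each coords entry must be a finite n_atoms x 3 matrix with a common atom count")
    else if (na < 3L)
      msg <- c(msg, "conformations need at least 3 atoms")
    if (length(object@atomLabels) && length(object@atomLabels) != na)
      msg <- c(msg, "atomLabels must match the atom count")
    if (!is.null(object@native) &&
        (!is.matrix(object@native) || ncol(object@native) != 3L))
      msg <- c(msg, "native must be an n_atoms x 3 matrix or NULL")
  }
  if (object@distanceMode == "precomputed_features") {
    f <- object@features
    if (is.null(f) || !is.matrix(f) || nrow(f) != n || !all(is.finite(f)))
      msg <- c(msg, "precomputed_features mode requires a finite feature matrix with one row per decoy")
  }
  if (length(msg)) msg else TRUE
})

#' NNGraph: epsilon-nearest-neighbor graph over a decoy set
#'
#' The neighborhood structure N(X) of the sampled landscape: vertices are
#' decoys, and an undirected edge joins every pair at conformational distance
#' at most \code{epsilon}, storing that distance.
#'
#' @slot epsilon neighborhood radius (Angstrom, or feature units).
#' @slot edges two-column integer matrix of vertex pairs (u < v).
#' @slot dists numeric vector of edge distances, parallel to \code{edges}.
#' @slot nVertices number of vertices.
#' @slot membership integer vector: connected-component id per vertex.
#' @slot nComponents number of connected components.
#' @seealso [buildNNGraph()], [assignBasins()]
#' @export
setClass("NNGraph",
  slots = c(
    epsilon = "numeric",
    edges = "matrix",
    dists = "numeric",
    nVertices = "integer",
    membership = "integer",
    nComponents = "integer"
  )
)

setValidity("NNGraph", function(object) {
  msg <- character(0)
  if (length(object@epsilon) != 1L || !is.finite(object@epsilon) ||
      object@epsilon <= 0)
    msg <- c(msg, "epsilon must be a single positive number")
  e <- object@edges
  if (!is.numeric(e) || ncol(e) != 2L)
    msg <- c(msg, "edges must be a two-column matrix")
  else if (nrow(e)) {
    if (any(e[, 1L] == e[, 2L])) msg <- c(msg, "self-loops are not allowed")
    if (any(e < 1L | e > object@nVertices))
      msg <- c(msg, "edge endpoints out of range")
    if (length(object@dists) != nrow(e))
      msg <- c(msg, "dists must be parallel to edges")
    else if (any(object@dists > object@epsilon + 1e-12))
      msg <- c(msg, "all edge distances must be <= epsilon")
  }
  if (length(object@membership) != object@nVertices)
    msg <- c(msg, "membership must cover every vertex")
  if (length(msg)) msg else TRUE
})

#' BasinSet: basins of attraction of a sampled energy landscape
#'
#' The result of discrete negative-gradient descent on an [NNGraph-class]:
#' every vertex is assigned to the basin of the local minimum its
#' steepest-ratio descent path reaches. Basins are characterized by their
#' size, focal (minimum) energy, pseudo-saddle, persistence
#' (\eqn{f(saddle) - f(focal)}) and stability (persistence divided by
#' \eqn{\sqrt 2}, the perpendicular distance of the (focal, saddle) energy
#' pair from the identity line).
#'
#' @slot assignment integer vector: basin index per vertex.
#' @slot basins data.frame with one row per basin: \code{basin}, \code{focal}
#'   (vertex index of the focal minimum), \code{size}, \code{focalEnergy},
#'   \code{saddleVertex}, \code{saddleEnergy}, \code{persistence},
#'   \code{stability}. Saddle columns are \code{NA} and persistence/stability
#'   \code{Inf} for basins with no escape vertex (e.g. the deepest basin of a
#'   connected component).
#' @slot energies per-vertex energies the basins were computed from.
#' @slot epsilon the graph radius used.
#' @seealso [assignBasins()], [computeSaddles()], [mergeByPersistence()]
#' @export
setClass("BasinSet",
  slots = c(
    assignment = "integer",
    basins = "data.frame",
    energies = "numeric",
    epsilon = "numeric"
  )
)

setValidity("BasinSet", function(object) {
  msg <- character(0)
  b <- object@basins
  need <- c("basin", "focal", "size", "focalEnergy")
  if (!all(need %in% names(b)))
    msg <- c(msg, paste("basins must carry columns:", paste(need, collapse = ", ")))
  else {
    if (length(object@assignment) != length(object@energies))
      msg <- c(msg, "assignment must cover every vertex")
    if (nrow(b) && !setequal(unique(object@assignment), b$basin))
      msg <- c(msg, "assignment ids must match basin table ids")
    if (nrow(b)) {
      sizes <- as.vector(table(factor(object@assignment, levels = b$basin)))
      if (!all(sizes == b$size))
        msg <- c(msg, "basin sizes must equal assignment counts")
      if (!all(object@assignment[b$focal] == b$basin))
        msg <- c(msg, "each focal vertex must belong to its own basin")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ClusterSet: follow-the-leader clustering of a decoy set
#'
#' @slot members list of integer vectors (decoy indices), ordered by cluster
#'   size (largest first; ties by founding order).
#' @slot representatives integer vector: the representative (first-mapped)
#'   decoy of each cluster.
#' @slot epsilon clustering radius (Angstrom).
#' @slot seed shuffle seed used before the single scan.
#' @seealso [leaderCluster()]
#' @export
setClass("ClusterSet",
  slots = c(
    members = "list",
    representatives = "integer",
    epsilon = "numeric",
    seed = "integer"
  )
)

setValidity("ClusterSet", function(object) {
  msg <- character(0)
  if (length(object@members) != length(object@representatives))
    msg <- c(msg, "one representative per cluster required")
  all_members <- unlist(object@members)
  if (anyDuplicated(all_members))
    msg <- c(msg, "clusters must partition the decoy set (no overlaps)")
  ok <- mapply(function(m, r) r %in% m, object@members,
               object@representatives)
  if (length(ok) && !all(ok))
    msg <- c(msg, "each representative must belong to its cluster")
  if (length(msg)) msg else TRUE
})

#' RankedGroups: ordered decoy groups selected by one strategy
#'
#' The output of a selection strategy: groups G1..Gx of decoy indices in the
#' strategy's sort order, plus per-group provenance (basin/cluster metadata).
#' For the Cluster-Random baseline, \code{runs} holds one group list per
#' independent random draw and \code{groups} holds the first run;
#' [scoreGroups()] averages metrics over runs.
#'
#' @slot strategy one of the six selection strategy names.
#' @slot groups list of integer vectors (decoy indices), ordered.
#' @slot provenance data.frame with one row per group (rank, size, and for
#'   basin strategies focal energy, PR, PC).
#' @slot runs list of group lists (non-empty only for Cluster-Random).
#' @slot truncated TRUE when fewer groups than requested were available.
#' @seealso [selectDecoys()], [rankBasins()], [scoreGroups()]
#' @export
setClass("RankedGroups",
  slots = c(
    strategy = "character",
    groups = "list",
    provenance = "data.frame",
    runs = "list",
    truncated = "logical"
  )
)

.strategies <- c("Cluster-Size", "Cluster-Random", "Basin-Size",
                 "Basin-Size+Energy", "Basin-PR", "Basin-PR+PC")

setValidity("RankedGroups", function(object) {
  msg <- character(0)
  if (!object@strategy %in% .strategies)
    msg <- c(msg, paste("strategy must be one of:",
                        paste(.strategies, collapse = ", ")))
  if (anyDuplicated(unlist(object@groups)))
    msg <- c(msg, "no decoy may appear in two groups")
  if (length(msg)) msg else TRUE
})
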