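#' Decoy identifiers
#' @param x a [DecoySet-class]
#' @return character vector of decoy ids
#' @export
setGeneric("decoyIds", function(x) standardGeneric("decoyIds"))

#' Per-decoy energies
#' @param x a [DecoySet-class]
#' @return numeric vector of energies (score units, e.g. REU)
#' @export
setGeneric("energies", function(x) standardGeneric("energies"))

#' Per-decoy distances to the native reference
#'
#' Returns cached native distances where present; otherwise computes the
#' least RMSD of each decoy to the native conformation.
#'
#' @param x a [DecoySet-class]
#' @return numeric vector of distances (Angstrom); errors if no native
#'   information is available
#' @export
setGeneric("nativeDistances", function(x) standardGeneric("nativeDistances"))

#' Native reference conformation
#' @param x a [DecoySet-class]
#' @return n_atoms x 3 coordinate matrix, or NULL
#' @export
setGeneric("nativeConformation",
           function(x) standardGeneric("nativeConformation"))

#' Distance mode of a decoy set
#' @param x a [DecoySet-class]
#' @return one of "reference_superposed_rmsd", "full_lrmsd",
#'   "precomputed_features"
#' @export
setGeneric("distanceMode", function(x) standardGeneric("distanceMode"))

#' Coordinates of one decoy
#' @param x a [DecoySet-class]
#' @param i decoy index or id
#' @return n_atoms x 3 coordinate matrix
#' @export
setGeneric("coordsOf", function(x, i) standardGeneric("coordsOf"))

#' Pairwise conformational distance matrix
#'
#' Computes the full symmetric matrix of decoy-decoy distances under the
#' set's distance mode (see [DecoySet-class]).
#'
#' @param x a [DecoySet-class]
#' @param mode override the set's distance mode (optional)
#' @return n x n symmetric numeric matrix with zero diagonal
#' @export
setGeneric("decoyDistances",
           function(x, mode = distanceMode(x)) standardGeneric("decoyDistances"))

#' Graph/neighborhood radius
#' @param x an [NNGraph-class], [BasinSet-class] or [ClusterSet-class]
#' @return the epsilon radius (Angstrom)
#' @export
setGeneric("epsilon", function(x) standardGeneric("epsilon"))

#' Number of connected components
#' @param x an [NNGraph-class]
#' @return integer count
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' Basin summary table
#' @param x a [BasinSet-class]
#' @return data.frame with one row per basin (focal vertex, size, focal
#'   energy, saddle, persistence, stability)
#' @export
setGeneric("basinTable", function(x) standardGeneric("basinTable"))

#' Basin membership per vertex
#' @param x a [BasinSet-class]
#' @return integer vector of basin ids, one per decoy
#' @export
setGeneric("basinAssignment", function(x) standardGeneric("basinAssignment"))

#' Cluster membership lists
#' @param x a [ClusterSet-class]
#' @return list of integer vectors of decoy indices
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))

#' Cluster sizes
#' @param x a [ClusterSet-class]
#' @return integer vector of cluster sizes, largest first
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' Selected groups of decoys
#' @param x a [RankedGroups-class]
#' @return list of integer vectors of decoy indices, in rank order
#' @export
setGeneric("groupMembers", function(x) standardGeneric("groupMembers"))
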