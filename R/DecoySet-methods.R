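#' Construct a DecoySet
#'
#' User-facing constructor. Supply either per-decoy coordinate matrices
#' (\code{coords}), or a feature matrix (\code{features}) for tabular /
#' synthetic sets; energies are required either way.
#'
#' @param ids character vector of unique decoy ids; defaults to
#'   \code{"d1".."dn"}.
#' @param energies numeric vector of per-decoy energies (finite).
#' @param coords optional list of n_atoms x 3 matrices (Angstrom).
#' @param atomLabels optional character vector of atom labels
#'   (\code{"<resno>:<name>"}) shared by all decoys.
#' @param native optional n_atoms x 3 native reference matrix.
#' @param nativeDist optional numeric vector of distances to the native.
#' @param features optional numeric matrix (decoys x features).
#' @param distanceMode distance backend; defaults to
#'   \code{"reference_superposed_rmsd"} when coordinates are given and
#'   \code{"precomputed_features"} otherwise.
#' @return a [DecoySet-class]
#' @examples
#' ds <- DecoySet(energies = c(-5, -4, -1),
#'                features = matrix(c(0, 0.5, 10), ncol = 1))
#' length(ds)
#' @export
DecoySet <- function(ids = NULL, energies, coords = list(),
                     atomLabels = character(0), native = NULL,
                     nativeDist = NULL, features = NULL,
                     distanceMode = NULL) {
  n <- length(energies)
  if (is.null(ids)) ids <- paste0("d", seq_len(n))
  if (is.null(nativeDist)) nativeDist <- rep(NA_real_, n)
  if (!is.null(features)) features <- as.matrix(features)
  if (is.null(distanceMode))
    distanceMode <- if (length(coords)) "reference_superposed_rmsd"
                    else "precomputed_features"
  new("DecoySet", ids = as.character(ids), energies = as.numeric(energies),
      coords = coords, atomLabels = atomLabels, native = native,
      nativeDist = as.numeric(nativeDist), features = features,
      distanceMode = distanceMode)
}

#' @describeIn DecoySet number of decoys in the set
#' @param x a DecoySet
#' @export
setMethod("length", "DecoySet", function(x) length(x@ids))

#' @rdname decoyIds
#' @export
setMethod("decoyIds", "DecoySet", function(x) x@ids)

#' @rdname energies
#' @export
setMethod("energies", "DecoySet", function(x) {
  stats::setNames(x@energies, x@ids)
})

#' @rdname distanceMode
#' @export
setMethod("distanceMode", "DecoySet", function(x) x@distanceMode)

#' @rdname nativeConformation
#' @export
setMethod("nativeConformation", "DecoySet", function(x) x@native)

#' @rdname coordsOf
#' @export
setMethod("coordsOf", "DecoySet", function(x, i) {
  if (is.character(i)) i <- match(i, x@ids)
  if (is.na(i) || i < 1L || i > length(x))
    stop("invalid decoy index")
  if (!length(x@coords)) stop("this DecoySet carries no coordinates")
  x@coords[[i]]
})

#' @rdname nativeDistances
#' @export
setMethod("nativeDistances", "DecoySet", function(x) {
  nd <- x@nativeDist
  if (!anyNA(nd)) return(stats::setNames(nd, x@ids))
  if (is.null(x@native) || !length(x@coords))
    stop("no native information: supply a native conformation or precomputed native_dist values")
  miss <- which(is.na(nd))
  nd[miss] <- vapply(miss, function(i) lrmsd(x@coords[[i]], x@native),
                     numeric(1))
  stats::setNames(nd, x@ids)
})

#' @describeIn DecoySet subset a DecoySet by index, id or logical mask
#' @param i indices, ids, or logical vector
#' @param j,drop,... ignored
#' @export
setMethod("[", "DecoySet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@ids)
  if (is.logical(i)) i <- which(i)
  if (anyNA(i) || !length(i)) stop("invalid decoy subset")
  initialize(x,
    ids = x@ids[i], energies = x@energies[i],
    coords = if (length(x@coords)) x@coords[i] else list(),
    nativeDist = x@nativeDist[i],
    features = if (!is.null(x@features)) x@features[i, , drop = FALSE]
               else NULL)
})

setMethod("show", "DecoySet", function(object) {
  n <- length(object)
  cat("DecoySet with", n, "decoys\n")
  cat("  distance mode:", object@distanceMode, "\n")
  if (length(object@coords))
    cat("  atoms per conformation:", nrow(object@coords[[1L]]), "\n")
  if (!is.null(object@features))
    cat("  feature dimension:", ncol(object@features), "\n")
  cat("  energy range: [", format(min(object@energies), digits = 4), ", ",
      format(max(object@energies), digits = 4), "]\n", sep = "")
  cat("  native reference:",
      if (!is.null(object@native)) "present"
      else if (!anyNA(object@nativeDist)) "distances precomputed"
      else "absent", "\n")
})

#' Drop the highest-energy decoys before landscape analysis
#'
#' Optional prefilter that removes the top \code{q} percent of decoys by
#' energy. Removing low-energy decoys would delete focal minima and destroy
#' basin structure, so only a high-energy filter is offered; it is off by
#' default throughout the package.
#'
#' @param ds a [DecoySet-class]
#' @param q percentage of highest-energy decoys to drop, in [0, 100)
#' @return the filtered [DecoySet-class]
#' @export
prefilterHighEnergy <- function(ds, q) {
  stopifnot(is(ds, "DecoySet"), q >= 0, q < 100)
  if (q == 0) return(ds)
  keep <- ds@energies <= stats::quantile(ds@energies, 1 - q / 100,
                                         names = FALSE)
  if (!any(keep)) stop("prefilter would remove every decoy")
  ds[keep]
}

#' Read the canonical tabular decoy dialect
#'
#' Reads a whitespace/tab-delimited table with a header and columns
#' \code{id}, \code{energy} and optionally \code{native_dist}, plus any
#' number of feature columns named \code{f1, f2, ...}. This is the package's
#' canonical intermediate format; sets read this way use the
#' \code{precomputed_features} distance mode when feature columns are
#' present.
#'
#' @param path path to the TSV file
#' @return a [DecoySet-class]
#' @seealso [writeDecoyTable()]
#' @export
readDecoyTable <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("id", "energy") %in% names(tab)))
    stop("decoy table must have columns 'id' and 'energy'")
  if (!is.numeric(tab$energy))
    stop("unparseable energy column in ", path)
  fcols <- grep("^f[0-9]+$", names(tab), value = TRUE)
  feats <- if (length(fcols)) as.matrix(tab[, fcols, drop = FALSE]) else NULL
  nd <- if ("native_dist" %in% names(tab)) tab$native_dist else NULL
  DecoySet(ids = tab$id, energies = tab$energy, nativeDist = nd,
           features = feats,
           distanceMode = if (!is.null(feats)) "precomputed_features"
                          else "reference_superposed_rmsd")
}

#' Write the canonical tabular decoy dialect
#'
#' Writes id, energy, native_dist (when known) and feature columns at six
#' significant digits; [readDecoyTable()] round-trips the result.
#'
#' @param ds a [DecoySet-class]
#' @param path output path
#' @return the path, invisibly
#' @export
writeDecoyTable <- function(ds, path) {
  stopifnot(is(ds, "DecoySet"))
  tab <- data.frame(id = ds@ids,
                    energy = signif(ds@energies, 6),
                    stringsAsFactors = FALSE)
  if (!anyNA(ds@nativeDist)) tab$native_dist <- signif(ds@nativeDist, 6)
  if (!is.null(ds@features)) {
    f <- signif(ds@features, 6)
    colnames(f) <- paste0("f", seq_len(ncol(f)))
    tab <- cbind(tab, f)
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
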