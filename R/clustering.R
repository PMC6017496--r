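#' Follow-the-leader clustering of a decoy set
#'
#' Order-dependent, single-scan clustering: the decoys are shuffled (with an
#' explicit seed, recorded in the result for reproducibility), then scanned
#' once; each decoy joins the first existing cluster whose representative
#' (the first decoy mapped to it) lies within \code{epsilon}, and otherwise
#' founds a new cluster with itself as representative. Clusters are returned
#' sorted by size, largest first, ties broken by founding order.
#'
#' @param ds a [DecoySet-class]
#' @param epsilon clustering radius (Angstrom) (> 0)
#' @param shuffleSeed seed for the pre-scan shuffle (default 1)
#' @param distances optional precomputed distance matrix from
#'   [decoyDistances()], to avoid recomputation across calls
#' @return a [ClusterSet-class]
#' @examples
#' ds <- DecoySet(energies = rep(0, 5),
#'                features = matrix(c(0, 0.5, 10, 10.4, 20), ncol = 1))
#' clusterSizes(leaderCluster(ds, epsilon = 1))  # 2, 2, 1
#' @export
leaderCluster <- function(ds, epsilon, shuffleSeed = 1L, distances = NULL) {
  stopifnot(is(ds, "DecoySet"))
  n <- length(ds)
  if (n < 1L) stop("cannot cluster an empty decoy set")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("epsilon must be a single positive number")
  d <- if (is.null(distances)) decoyDistances(ds) else distances
  ord <- withr::with_seed(shuffleSeed, sample.int(n))
  reps <- integer(0)
  members <- list()
  for (i in ord) {
    hit <- 0L
    for (k in seq_along(reps)) {
      if (d[i, reps[k]] <= epsilon) { hit <- k; break }
    }
    if (hit) {
      members[[hit]] <- c(members[[hit]], i)
    } else {
      reps <- c(reps, i)
      members[[length(reps)]] <- i
    }
  }
  sizes <- lengths(members)
  o <- order(-sizes, seq_along(sizes))
  new("ClusterSet", members = members[o], representatives = reps[o],
      epsilon = as.numeric(epsilon), seed = as.integer(shuffleSeed))
}

#' @rdname clusterMembers
#' @export
setMethod("clusterMembers", "ClusterSet", function(x) x@members)

#' @rdname clusterSizes
#' @export
setMethod("clusterSizes", "ClusterSet", function(x) lengths(x@members))

#' @rdname epsilon
#' @export
setMethod("epsilon", "ClusterSet", function(x) x@epsilon)

setMethod("show", "ClusterSet", function(object) {
  sz <- lengths(object@members)
  cat("ClusterSet:", length(sz), "clusters over", sum(sz),
      "decoys (epsilon =", object@epsilon, ")\n")
  cat("  largest sizes:", paste(utils::head(sz, 5L), collapse = ", "), "\n")
})

#' Export cluster assignments as a table
#'
#' @param cl a [ClusterSet-class]
#' @param ds the clustered [DecoySet-class] (for ids)
#' @param path optional TSV output path
#' @return data.frame with columns id, cluster, representative
#' @export
clusterAssignmentTable <- function(cl, ds, path = NULL) {
  stopifnot(is(cl, "ClusterSet"), is(ds, "DecoySet"))
  idx <- unlist(cl@members)
  tab <- data.frame(
    id = decoyIds(ds)[idx],
    cluster = rep(seq_along(cl@members), lengths(cl@members)),
    representative = decoyIds(ds)[rep(cl@representatives,
                                      lengths(cl@members))],
    stringsAsFactors = FALSE)
  tab <- tab[order(match(tab$id, decoyIds(ds))), ]
  rownames(tab) <- NULL
  if (!is.null(path))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  tab
}

#' Adapt the clustering radius until a non-singleton cluster appears
#'
#' Starting from \code{epsilon0} (1 Angstrom by default), increases epsilon
#' in fixed steps until the largest leader cluster has at least two members.
#' A singleton "cluster" exists for any radius, so the stopping rule is read
#' as requiring a genuinely populated cluster.
#'
#' @inheritParams leaderCluster
#' @param epsilon0 initial radius (default 1)
#' @param step increment per attempt (default 0.5)
#' @param cap largest radius to try (default 10); exceeding it is an error
#' @return the adapted epsilon
#' @export
adaptEpsilon <- function(ds, epsilon0 = 1, step = 0.5, cap = 10,
                         shuffleSeed = 1L, distances = NULL) {
  stopifnot(is(ds, "DecoySet"), epsilon0 > 0, step > 0)
  if (is.null(distances)) distances <- decoyDistances(ds)
  eps <- epsilon0
  while (eps <= cap + 1e-9) {
    cl <- leaderCluster(ds, eps, shuffleSeed, distances)
    if (max(lengths(cl@members)) >= 2L) return(eps)
    eps <- eps + step
  }
  stop("no epsilon below the cap (", cap,
       ") produced a non-singleton cluster")
}

#' Uniform-random baseline draws
#'
#' Draws groups of the given sizes uniformly at random from the whole decoy
#' set, without replacement (so the groups of one run are disjoint, like the
#' clusters they are size-matched to), independently across runs. Group
#' sizes are typically the sizes of the largest leader clusters, so that
#' random selection is compared at matched size; evaluation metrics are
#' averaged over the runs.
#'
#' @param ds a [DecoySet-class]
#' @param groupSizes integer vector of group sizes (summing to at most the
#'   number of decoys)
#' @param runs number of independent repetitions (default 5)
#' @param seed RNG seed
#' @return a [RankedGroups-class] with strategy \code{"Cluster-Random"};
#'   \code{x@runs} holds one group list per run
#' @export
clusterRandom <- function(ds, groupSizes, runs = 5L, seed = 1L) {
  stopifnot(is(ds, "DecoySet"))
  n <- length(ds)
  groupSizes <- as.integer(groupSizes)
  if (any(groupSizes < 1L) || any(groupSizes > n))
    stop("each group size must be between 1 and the decoy set size (", n, ")")
  if (sum(groupSizes) > n)
    stop("group sizes sum to more than the decoy set size (", n, ")")
  draws <- withr::with_seed(seed, {
    lapply(seq_len(runs), function(r) {
      picked <- sample.int(n, sum(groupSizes))
      split(picked, rep(seq_along(groupSizes), groupSizes))
    })
  })
  prov <- data.frame(rank = seq_along(groupSizes), size = groupSizes)
  new("RankedGroups", strategy = "Cluster-Random", groups = draws[[1L]],
      provenance = prov, runs = draws, truncated = FALSE)
}
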