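#' Label near-native decoys
#'
#' A decoy counts as a native conformation when its least RMSD to the native
#' reference is within \code{distThresh}; these labels are the positives
#' against which selection strategies are evaluated.
#'
#' @param ds a [DecoySet-class] with a native reference or precomputed
#'   native distances
#' @param distThresh distance threshold (Angstrom)
#' @return logical vector (TRUE = native), with attribute \code{"total"} =
#'   native count
#' @export
labelNatives <- function(ds, distThresh) {
  stopifnot(is(ds, "DecoySet"), distThresh > 0)
  nd <- nativeDistances(ds)
  labels <- unname(nd <= distThresh)
  attr(labels, "total") <- sum(labels)
  labels
}

#' Choose the native-labelling threshold per target difficulty
#'
#' The threshold adapts to how close the sampling got to the native:
#' \describe{
#'   \item{easy (min_dist <= 0.7 A)}{dist_thresh = 2 A.}
#'   \item{medium (0.7 < min_dist < 2 A)}{the smallest value in a 0.5
#'     A-stepped scan of [2, 4.5] A for which the largest leader cluster
#'     contains at least one native; if the scan exhausts the range, its
#'     maximum is returned with a warning flag.}
#'   \item{hard (min_dist >= 2 A)}{at least 6 A: the scan starts at 6 A and
#'     rises in 0.5 A steps until the largest cluster admits a native, so a
#'     non-zero positive set always exists.}
#' }
#'
#' @param ds a [DecoySet-class] with native information
#' @param clusters a [ClusterSet-class] from [leaderCluster()]; the scan
#'   rule looks at its largest cluster
#' @param step scan step (default 0.5 A)
#' @return list with \code{dist_thresh}, \code{min_dist},
#'   \code{difficulty} ("easy"/"medium"/"hard") and \code{scan_exhausted}
#' @export
chooseDistThresh <- function(ds, clusters, step = 0.5) {
  stopifnot(is(ds, "DecoySet"), is(clusters, "ClusterSet"))
  nd <- unname(nativeDistances(ds))
  minDist <- min(nd)
  largest <- clusterMembers(clusters)[[1L]]
  scan_first <- function(grid) {
    for (t in grid) if (any(nd[largest] <= t)) return(t)
    NA_real_
  }
  exhausted <- FALSE
  if (minDist <= 0.7) {
    difficulty <- "easy"
    thresh <- 2
  } else if (minDist < 2) {
    difficulty <- "medium"
    thresh <- scan_first(seq(2, 4.5, by = step))
    if (is.na(thresh)) { thresh <- 4.5; exhausted <- TRUE }
  } else {
    difficulty <- "hard"
    lo <- min(nd[largest])
    thresh <- scan_first(seq(6, max(6, lo + step), by = step))
  }
  list(dist_thresh = thresh, min_dist = minDist, difficulty = difficulty,
       scan_exhausted = exhausted)
}

#' Score selected groups with the n / p / s metrics
#'
#' For each x from 1 to \code{xMax}, the union U = G1 ... Gx of the top x
#' groups is scored by:
#' \describe{
#'   \item{n}{percentage of all natives captured: 100 |natives in U| /
#'     |natives in the decoy set|.}
#'   \item{p}{purity: 100 |natives in U| / |U|.}
#'   \item{s}{relative size: 100 |U| / |decoy set|.}
#' }
#' For the Cluster-Random baseline the metrics are averaged over the
#' independent runs. When the decoy set contains no natives at all, n and p
#' are reported as NA — a failure mode deliberately kept distinct from a
#' selection that captures zero natives.
#'
#' @param sel a [RankedGroups-class]
#' @param labels logical native labels from [labelNatives()]
#' @param xMax deepest union to evaluate (default 3, capped at the number of
#'   available groups)
#' @return data.frame with columns x, n, p, s (percent)
#' @export
scoreGroups <- function(sel, labels, xMax = 3L) {
  stopifnot(is(sel, "RankedGroups"), is.logical(labels))
  total <- sum(labels)
  nAll <- length(labels)
  runs <- if (length(sel@runs)) sel@runs else list(sel@groups)
  xMax <- min(xMax, max(lengths(runs)))
  score_run <- function(groups, x) {
    U <- unique(unlist(groups[seq_len(min(x, length(groups)))]))
    hits <- sum(labels[U])
    c(n = if (total) 100 * hits / total else NA_real_,
      p = if (total) 100 * hits / length(U) else NA_real_,
      s = 100 * length(U) / nAll)
  }
  rows <- lapply(seq_len(xMax), function(x) {
    m <- rowMeans(vapply(runs, score_run, numeric(3), x = x))
    data.frame(x = x, n = m[["n"]], p = m[["p"]], s = m[["s"]])
  })
  do.call(rbind, rows)
}

#' Evaluate several strategies on one decoy set
#'
#' Convenience wrapper: runs [selectDecoys()] for each strategy and scores
#' the result, returning the long table of (strategy, x, n, p, s) rows that
#' mirrors how selection strategies are compared per target.
#'
#' @inheritParams selectDecoys
#' @param strategies character vector of strategy names
#' @param distThresh native-labelling threshold; \code{NULL} (default)
#'   chooses it with [chooseDistThresh()]
#' @param xMax deepest union to evaluate
#' @return list with \code{metrics} (data.frame), \code{config} (the
#'   resolved thresholds) and \code{selections} (named list of
#'   [RankedGroups-class])
#' @export
evaluateStrategies <- function(ds, strategies = .strategies, epsilon = NULL,
                               distThresh = NULL, x = 3L, xMax = x,
                               seed = 1L, pThresh = 1, runs = 5L) {
  stopifnot(is(ds, "DecoySet"))
  distances <- decoyDistances(ds)
  if (is.null(epsilon))
    epsilon <- adaptEpsilon(ds, shuffleSeed = seed, distances = distances)
  cl <- leaderCluster(ds, epsilon, shuffleSeed = seed, distances = distances)
  cfg <- NULL
  if (is.null(distThresh)) {
    cfg <- chooseDistThresh(ds, cl)
    distThresh <- cfg$dist_thresh
  }
  labels <- labelNatives(ds, distThresh)
  sels <- lapply(strategies, function(s)
    selectDecoys(ds, s, epsilon = epsilon, x = x, seed = seed,
                 pThresh = pThresh, runs = runs, distances = distances))
  names(sels) <- strategies
  metrics <- do.call(rbind, lapply(strategies, function(s) {
    m <- scoreGroups(sels[[s]], labels, xMax = xMax)
    cbind(strategy = s, m)
  }))
  rownames(metrics) <- NULL
  list(metrics = metrics,
       config = c(list(epsilon = epsilon, dist_thresh = distThresh,
                       total_natives = attr(labels, "total")), cfg),
       selections = sels)
}
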