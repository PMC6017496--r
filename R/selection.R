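#' Strong Pareto dominance between two basins
#'
#' Basin selection treats size and negative focal energy as two competing
#' objectives. Basin \code{a} strongly dominates basin \code{b} when it is
#' strictly better on both: size(a) > size(b) and focalEnergy(a) <
#' focalEnergy(b). Strong dominance is irreflexive, so no basin dominates
#' itself or an identical twin.
#'
#' @param a,b single rows of a basin table (lists or data.frames with
#'   \code{size} and \code{focalEnergy})
#' @return TRUE iff a strongly dominates b
#' @examples
#' dominates(list(size = 100, focalEnergy = -50),
#'           list(size = 50, focalEnergy = -40))  # TRUE
#' @export
dominates <- function(a, b) {
  isTRUE(a$size > b$size && a$focalEnergy < b$focalEnergy)
}

#' Pareto rank and count of every basin
#'
#' By exhaustive pairwise strong-dominance comparison on (size, -energy):
#' the Pareto rank (PR) of a basin is the number of basins that dominate it
#' (PR 0 = non-dominated, the Pareto front), and the Pareto count (PC) is
#' the number of basins it dominates. The total PR always equals the total
#' PC (both count the ordered dominating pairs).
#'
#' @param basins a basin table ([basinTable()]) or a [BasinSet-class]
#' @return the table with integer columns \code{PR} and \code{PC} added
#' @export
paretoScores <- function(basins) {
  if (is(basins, "BasinSet")) basins <- basinTable(basins)
  stopifnot(all(c("size", "focalEnergy") %in% names(basins)))
  sz <- basins$size
  en <- basins$focalEnergy
  dom <- outer(sz, sz, `>`) & outer(en, en, `<`)  # dom[i,j]: i dominates j
  basins$PR <- as.integer(colSums(dom))
  basins$PC <- as.integer(rowSums(dom))
  basins
}

# order of the basin rows under one strategy; after the strategy's stated
# keys, ties break by focal energy (ascending) then basin index
.strategy_order <- function(b, strategy, poolSize = 10L) {
  switch(strategy,
    "Basin-Size" = order(-b$size, b$focalEnergy, b$basin),
    "Basin-Size+Energy" = {
      pool <- order(-b$size, b$focalEnergy, b$basin)
      pool <- pool[seq_len(min(poolSize, length(pool)))]
      pool[order(b$focalEnergy[pool], b$basin[pool])]
    },
    "Basin-PR" = order(b$PR, b$focalEnergy, b$basin),
    "Basin-PR+PC" = order(b$PR, -b$PC, b$focalEnergy, b$basin),
    stop("unknown basin strategy: ", strategy))
}

#' Rank basins under one selection strategy
#'
#' Implements the four basin-based orderings:
#' \describe{
#'   \item{Basin-Size}{by size, largest first.}
#'   \item{Basin-Size+Energy}{the \code{poolSize} (default ten) largest
#'     basins, reordered by focal energy from low to high.}
#'   \item{Basin-PR}{by Pareto rank, lowest first.}
#'   \item{Basin-PR+PC}{by Pareto rank, lowest first; equal ranks by Pareto
#'     count, highest first.}
#' }
#' Remaining ties break by focal energy (ascending), then basin index, so
#' the ordering is a deterministic total order. The top \code{x} basins
#' become groups G1..Gx; if fewer basins exist, all are returned and the
#' result is flagged as truncated.
#'
#' @param bs a [BasinSet-class]
#' @param strategy one of \code{"Basin-Size"}, \code{"Basin-Size+Energy"},
#'   \code{"Basin-PR"}, \code{"Basin-PR+PC"}
#' @param x number of groups to select (default 3)
#' @param poolSize size pool reordered by energy in Basin-Size+Energy
#' @return a [RankedGroups-class]
#' @export
rankBasins <- function(bs, strategy, x = 3L, poolSize = 10L) {
  stopifnot(is(bs, "BasinSet"), x >= 1L)
  b <- paretoScores(basinTable(bs))
  o <- .strategy_order(b, strategy, poolSize)
  truncated <- length(o) < x
  o <- o[seq_len(min(x, length(o)))]
  groups <- lapply(b$basin[o], function(bi) which(bs@assignment == bi))
  prov <- data.frame(rank = seq_along(o), basin = b$basin[o],
                     size = b$size[o], focalEnergy = b$focalEnergy[o],
                     PR = b$PR[o], PC = b$PC[o])
  new("RankedGroups", strategy = strategy, groups = groups,
      provenance = prov, runs = list(), truncated = truncated)
}

#' @rdname groupMembers
#' @export
setMethod("groupMembers", "RankedGroups", function(x) x@groups)

#' @describeIn rankBasins number of selected groups
#' @export
setMethod("length", "RankedGroups", function(x) length(x@groups))

setMethod("show", "RankedGroups", function(object) {
  cat("RankedGroups [", object@strategy, "]: ", length(object@groups),
      " group(s) of sizes ",
      paste(lengths(object@groups), collapse = ", "), "\n", sep = "")
  if (length(object@runs) > 1L)
    cat("  random baseline with", length(object@runs), "runs\n")
  if (object@truncated)
    cat("  note: fewer groups were available than requested\n")
})

#' End-to-end decoy selection under one strategy
#'
#' Driver that builds what the strategy needs — leader clusters for the
#' cluster baselines, or the epsilon-graph, basins and persistence merging
#' for the basin strategies — and returns the top \code{x} groups.
#' Deterministic given \code{seed}.
#'
#' @param ds a [DecoySet-class]
#' @param strategy one of the six strategy names (see [RankedGroups-class])
#' @param epsilon neighborhood/clustering radius; \code{NULL} (default)
#'   adapts it with [adaptEpsilon()] starting from 1 Angstrom
#' @param x number of groups (default 3)
#' @param seed shuffle/draw seed (default 1)
#' @param pThresh persistence-merge threshold for basin strategies
#'   (default 1, close to no filtering)
#' @param runs Cluster-Random repetitions (default 5)
#' @param distances optional precomputed [decoyDistances()] matrix
#' @param poolSize Basin-Size+Energy pool (default 10)
#' @return a [RankedGroups-class]
#' @export
selectDecoys <- function(ds, strategy, epsilon = NULL, x = 3L, seed = 1L,
                         pThresh = 1, runs = 5L, distances = NULL,
                         poolSize = 10L) {
  stopifnot(is(ds, "DecoySet"))
  strategy <- match.arg(strategy, .strategies)
  if (is.null(distances)) distances <- decoyDistances(ds)
  if (is.null(epsilon))
    epsilon <- adaptEpsilon(ds, shuffleSeed = seed, distances = distances)
  if (strategy %in% c("Cluster-Size", "Cluster-Random")) {
    cl <- leaderCluster(ds, epsilon, shuffleSeed = seed,
                        distances = distances)
    sizes <- clusterSizes(cl)
    truncated <- length(sizes) < x
    top <- seq_len(min(x, length(sizes)))
    if (strategy == "Cluster-Random")
      return(clusterRandom(ds, sizes[top], runs = runs, seed = seed))
    prov <- data.frame(rank = top, size = sizes[top],
                       representative = decoyIds(ds)[cl@representatives[top]])
    return(new("RankedGroups", strategy = strategy,
               groups = clusterMembers(cl)[top], provenance = prov,
               runs = list(), truncated = truncated))
  }
  g <- buildNNGraph(distances, epsilon)
  bs <- mergeByPersistence(g, assignBasins(g, energies(ds)), pThresh)
  rankBasins(bs, strategy, x = x, poolSize = poolSize)
}

#' Export a selection as a table
#'
#' @param sel a [RankedGroups-class]
#' @param ds the underlying [DecoySet-class]
#' @param path optional TSV output path
#' @return data.frame with one row per selected decoy: rank, strategy,
#'   group size, and the group metadata available for the strategy
#' @export
selectionTable <- function(sel, ds, path = NULL) {
  stopifnot(is(sel, "RankedGroups"), is(ds, "DecoySet"))
  rows <- lapply(seq_along(sel@groups), function(k) {
    m <- sel@groups[[k]]
    out <- data.frame(rank = k, strategy = sel@strategy,
                      group_size = length(m), id = decoyIds(ds)[m],
                      stringsAsFactors = FALSE)
    for (col in c("focalEnergy", "PR", "PC"))
      if (col %in% names(sel@provenance)) out[[col]] <- sel@provenance[[col]][k]
    out
  })
  tab <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  tab
}
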