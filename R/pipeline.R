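#' Run the full decoy-selection pipeline
#'
#' Executes read -> (superpose) -> cluster / basins -> select -> evaluate
#' from a single configuration, writing TSV/JSON reports plus the resolved
#' configuration next to them, and logging the adapted epsilon, component
#' and basin counts, and the chosen dist_thresh.
#'
#' The configuration is a named list (or path to a YAML/JSON file) with
#' fields:
#' \describe{
#'   \item{input}{either \code{table} (path to the tabular dialect, see
#'     [readDecoyTable()]) or \code{pdb_dir} + \code{score_table} (+
#'     optional \code{native_pdb}), see [readDecoySet()].}
#'   \item{epsilon}{neighborhood radius; omit to adapt from 1 Angstrom.}
#'   \item{p_thresh}{persistence-merge threshold (default 1).}
#'   \item{dist_thresh}{native-labelling threshold; omit to choose by the
#'     difficulty rules of [chooseDistThresh()].}
#'   \item{strategies}{strategy names (default: all six).}
#'   \item{x_max}{deepest group union evaluated (default 3).}
#'   \item{seed}{shuffle/draw seed (default 1).}
#'   \item{runs}{Cluster-Random repetitions (default 5).}
#'   \item{prefilter_q}{optional high-energy prefilter percentage
#'     (default 0 = off).}
#'   \item{out_dir}{output directory.}
#' }
#'
#' @param config named list or path to a YAML/JSON config file
#' @param quiet suppress progress messages (default FALSE)
#' @return (invisibly) list with \code{metrics}, \code{config},
#'   \code{selections}, \code{basins} and the output file paths
#' @export
runPipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::yaml.load_file(config)
              else jsonlite::fromJSON(config)
  }
  stopifnot(is.list(config), !is.null(config$out_dir))
  say <- function(...) if (!quiet) message("[basinselect] ", ...)
  cfg <- utils::modifyList(
    list(p_thresh = 1, x_max = 3L, seed = 1L, runs = 5L, prefilter_q = 0,
         strategies = .strategies),
    config)
  bad <- setdiff(cfg$strategies, .strategies)
  if (length(bad))
    stop("unknown strategy name(s): ", paste(bad, collapse = ", "),
         "; valid strategies are: ", paste(.strategies, collapse = ", "))

  t0 <- proc.time()[["elapsed"]]
  ds <- if (!is.null(cfg$input$table)) readDecoyTable(cfg$input$table)
        else readDecoySet(cfg$input$pdb_dir, cfg$input$score_table,
                          cfg$input$native_pdb)
  say("read ", length(ds), " decoys (mode: ", distanceMode(ds), ")")
  if (cfg$prefilter_q > 0) {
    ds <- prefilterHighEnergy(ds, cfg$prefilter_q)
    say("high-energy prefilter kept ", length(ds), " decoys")
  }
  if (distanceMode(ds) == "reference_superposed_rmsd" && length(ds@coords)) {
    ds <- superposeToReference(ds, 1L)
    say("superposed all decoys onto the first decoy")
  }
  distances <- decoyDistances(ds)
  eps <- cfg$epsilon
  if (is.null(eps)) {
    eps <- adaptEpsilon(ds, shuffleSeed = cfg$seed, distances = distances)
    say("adapted epsilon: ", format(eps))
  }
  cl <- leaderCluster(ds, eps, shuffleSeed = cfg$seed, distances = distances)
  say(length(clusterMembers(cl)), " leader clusters; largest size ",
      clusterSizes(cl)[1L])
  g <- buildNNGraph(distances, eps)
  say("nngraph: ", nrow(g@edges), " edges, ", nComponents(g),
      " connected component(s)")
  bs <- mergeByPersistence(g, assignBasins(g, energies(ds)), cfg$p_thresh)
  say(length(bs), " basins after persistence merging at p_thresh = ",
      cfg$p_thresh)

  distThresh <- cfg$dist_thresh
  cfgThresh <- NULL
  if (is.null(distThresh)) {
    cfgThresh <- chooseDistThresh(ds, cl)
    distThresh <- cfgThresh$dist_thresh
    say("dist_thresh: ", distThresh, " (", cfgThresh$difficulty,
        ", min_dist = ", format(cfgThresh$min_dist, digits = 3), ")")
  }
  labels <- labelNatives(ds, distThresh)
  say(attr(labels, "total"), " native-labelled decoys")

  sels <- lapply(cfg$strategies, function(s)
    selectDecoys(ds, s, epsilon = eps, x = cfg$x_max, seed = cfg$seed,
                 pThresh = cfg$p_thresh, runs = cfg$runs,
                 distances = distances))
  names(sels) <- cfg$strategies
  metrics <- do.call(rbind, lapply(cfg$strategies, function(s)
    cbind(strategy = s, scoreGroups(sels[[s]], labels, xMax = cfg$x_max))))
  rownames(metrics) <- NULL

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    metrics = file.path(cfg$out_dir, "metrics.tsv"),
    basins = file.path(cfg$out_dir, "basins.tsv"),
    clusters = file.path(cfg$out_dir, "clusters.tsv"),
    summary = file.path(cfg$out_dir, "summary.json"),
    config = file.path(cfg$out_dir, "config.json"))
  utils::write.table(metrics, paths$metrics, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  basinAssignmentTable(bs, ds, paths$basins)
  clusterAssignmentTable(cl, ds, paths$clusters)
  resolved <- c(cfg[setdiff(names(cfg), "input")],
                list(epsilon = eps, dist_thresh = distThresh,
                     total_natives = attr(labels, "total"),
                     n_components = nComponents(g), n_basins = length(bs)))
  jsonlite::write_json(resolved, paths$config, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(metrics, paths$summary, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  say("done in ", round(proc.time()[["elapsed"]] - t0, 2), " s; reports in ",
      cfg$out_dir)
  invisible(list(metrics = metrics, config = resolved, selections = sels,
                 basins = bs, clusters = cl, labels = labels,
                 paths = paths))
}
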