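.read_pdb_coords <- function(path, atoms = c("calpha", "all")) {
  atoms <- match.arg(atoms)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type %in% c("ATOM", "HETATM") &
    at$resid %in% bio3d::aa.table$aa3
  if (atoms == "calpha") keep <- keep & at$elety == "CA"
  at <- at[keep, , drop = FALSE]
  if (!nrow(at)) stop("no usable ATOM records in ", path)
  list(coords = as.matrix(at[, c("x", "y", "z")]),
       labels = paste0(at$resno, ":", at$elety))
}

#' Read a decoy set from PDB files and a score table
#'
#' Loads one conformation per row of the score table (columns \code{id},
#' \code{energy}, optionally \code{native_dist}; whitespace- or
#' tab-delimited with a header). Each \code{id} names a PDB file in
#' \code{pdbDir} (with or without the \code{.pdb} extension). Missing
#' occupancy/B-factor columns are tolerated; only ATOM/HETATM records of
#' standard amino acids are used, Calpha atoms only by default.
#'
#' If \code{scoreTable} has feature columns or no \code{pdbDir} is given,
#' use [readDecoyTable()] instead for the tabular dialect.
#'
#' @param pdbDir directory containing the decoy PDB files
#' @param scoreTable path to the score table
#' @param nativePdb optional path to the native reference PDB
#' @param atoms \code{"calpha"} (default) or \code{"all"}
#' @return a [DecoySet-class] in \code{reference_superposed_rmsd} mode
#' @export
readDecoySet <- function(pdbDir, scoreTable, nativePdb = NULL,
                         atoms = c("calpha", "all")) {
  atoms <- match.arg(atoms)
  tab <- utils::read.table(scoreTable, header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("id", "energy") %in% names(tab)))
    stop("score table must have columns 'id' and 'energy'")
  if (!is.numeric(tab$energy)) stop("unparseable energy column")
  paths <- file.path(pdbDir, ifelse(grepl("\\.pdb$", tab$id), tab$id,
                                    paste0(tab$id, ".pdb")))
  missing <- !file.exists(paths)
  if (any(missing))
    stop("no PDB file for decoy id(s): ",
         paste(tab$id[missing], collapse = ", "))
  parsed <- lapply(paths, .read_pdb_coords, atoms = atoms)
  counts <- vapply(parsed, function(p) nrow(p$coords), integer(1))
  if (length(unique(counts)) != 1L)
    stop("decoys have differing atom counts under ", atoms, " selection")
  native <- NULL
  if (!is.null(nativePdb)) {
    nat <- .read_pdb_coords(nativePdb, atoms = atoms)
    if (nrow(nat$coords) != counts[1L])
      stop("atom-count mismatch between decoys (", counts[1L],
           ") and native (", nrow(nat$coords), ") under ", atoms,
           " selection")
    native <- nat$coords
  }
  DecoySet(ids = sub("\\.pdb$", "", tab$id), energies = tab$energy,
           coords = lapply(parsed, `[[`, "coords"),
           atomLabels = parsed[[1L]]$labels, native = native,
           nativeDist = if ("native_dist" %in% names(tab)) tab$native_dist,
           distanceMode = "reference_superposed_rmsd")
}

#' Write a decoy set as PDB files plus a score table
#'
#' One Calpha-trace PDB per decoy (named \code{<id>.pdb}) and a
#' \code{scores.tsv} table; [readDecoySet()] round-trips the result up to
#' PDB coordinate rounding (three decimals, so RMSDs agree to ~1e-3 A).
#'
#' @param ds a [DecoySet-class] carrying coordinates
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
writeDecoyPdbs <- function(ds, dir) {
  stopifnot(is(ds, "DecoySet"))
  if (!length(ds@coords)) stop("this DecoySet carries no coordinates")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  na <- nrow(ds@coords[[1L]])
  resno <- if (length(ds@atomLabels))
    as.integer(sub(":.*", "", ds@atomLabels)) else seq_len(na)
  resid <- rep("ALA", na)
  elety <- rep("CA", na)
  for (i in seq_along(ds@coords)) {
    bio3d::write.pdb(file = file.path(dir, paste0(ds@ids[i], ".pdb")),
                     xyz = .as_xyz(ds@coords[[i]]), resno = resno,
                     resid = resid, elety = elety)
  }
  if (!is.null(ds@native))
    bio3d::write.pdb(file = file.path(dir, "native.pdb"),
                     xyz = .as_xyz(ds@native), resno = resno,
                     resid = resid, elety = elety)
  tab <- data.frame(id = ds@ids, energy = signif(ds@energies, 6))
  if (!anyNA(ds@nativeDist)) tab$native_dist <- signif(ds@nativeDist, 6)
  utils::write.table(tab, file.path(dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
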