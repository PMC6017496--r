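#' Specify a planted multi-well landscape
#'
#' Describes a synthetic decoy set with known basin structure: Gaussian
#' wells in a low-dimensional feature space, sampled isotropically around
#' their centers, with the energy at a point given by a sum of negative
#' Gaussian well terms plus additive noise. One well plays the role of the
#' native state, and each decoy's distance to that well's center stands in
#' for its distance to the native.
#'
#' Defaults describe the conditions the package is validated under: two
#' feature dimensions, 150 samples per well, unit well widths, centers
#' equally spaced on a circle so that neighbors sit 6 sigma apart, depths
#' evenly spaced from 10 down to 6 energy units, noise at 5% of the
#' shallowest depth (so persistence thresholds of 1-3 noise SDs separate
#' noise basins from planted ones), and the deepest well as the native.
#'
#' @param nBasins number of planted wells
#' @param dim feature-space dimension (default 2)
#' @param samplesPerBasin decoys per well (scalar or one count per well)
#' @param centers optional nBasins x dim matrix of well centers
#' @param depths well depths (energy units, > 0); default evenly spaced
#'   from 10 down to 6
#' @param widths per-well sigma (default 1)
#' @param noiseSd additive energy noise SD; default 5% of the shallowest
#'   depth
#' @param nativeIndex which well is the native (default: the deepest)
#' @param separation center spacing used when centers are auto-placed
#'   (default 6 sigma); wells must be at least \code{minSeparation} apart
#' @param minSeparation separation invariant, default 4 times the largest
#'   sigma
#' @param seed RNG seed (fixed seed gives byte-identical output)
#' @return a \code{plantedLandscapeSpec} list, validated
#' @export
plantedLandscapeSpec <- function(nBasins, dim = 2L, samplesPerBasin = 150L,
                                 centers = NULL, depths = NULL, widths = 1,
                                 noiseSd = NULL, nativeIndex = NULL,
                                 separation = NULL, minSeparation = NULL,
                                 seed = 1L) {
  stopifnot(nBasins >= 1L, dim >= 1L)
  widths <- rep_len(widths, nBasins)
  stopifnot(all(widths > 0))
  if (is.null(depths))
    depths <- if (nBasins == 1L) 10 else seq(10, 6, length.out = nBasins)
  depths <- rep_len(depths, nBasins)
  if (any(depths <= 0)) stop("well depths must be positive")
  samplesPerBasin <- rep_len(as.integer(samplesPerBasin), nBasins)
  stopifnot(all(samplesPerBasin >= 1L))
  if (is.null(separation)) separation <- 6 * max(widths)
  if (is.null(minSeparation)) minSeparation <- 4 * max(widths)
  if (is.null(centers)) {
    centers <- matrix(0, nBasins, dim)
    if (nBasins > 1L) {
      if (dim >= 2L) {
        # equally spaced on a circle with neighbor distance = separation
        ang <- 2 * pi * (seq_len(nBasins) - 1L) / nBasins
        r <- separation / (2 * sin(pi / nBasins))
        centers[, 1L] <- r * cos(ang)
        centers[, 2L] <- r * sin(ang)
      } else {
        centers[, 1L] <- separation * (seq_len(nBasins) - 1L)
      }
    }
  }
  centers <- as.matrix(centers)
  if (nrow(centers) != nBasins || ncol(centers) != dim)
    stop("centers must be an nBasins x dim matrix")
  if (nBasins > 1L) {
    cd <- as.matrix(stats::dist(centers))
    if (min(cd[upper.tri(cd)]) < minSeparation - 1e-9)
      stop("well centers closer than the minimum separation (",
           minSeparation, ")")
  }
  if (is.null(noiseSd)) noiseSd <- 0.05 * min(depths)
  if (is.null(nativeIndex)) nativeIndex <- which.max(depths)
  stopifnot(nativeIndex >= 1L, nativeIndex <= nBasins, noiseSd >= 0)
  structure(list(nBasins = as.integer(nBasins), dim = as.integer(dim),
                 samplesPerBasin = samplesPerBasin, centers = centers,
                 depths = depths, widths = widths, noiseSd = noiseSd,
                 nativeIndex = as.integer(nativeIndex),
                 seed = as.integer(seed)),
            class = "plantedLandscapeSpec")
}

#' Analytic energy of a planted landscape
#'
#' The noise-free energy surface: a sum of negative Gaussian wells,
#' \eqn{e(x) = -\sum_w depth_w \exp(-||x - c_w||^2 / (2 \sigma_w^2))}.
#'
#' @param spec a [plantedLandscapeSpec()]
#' @param X points as an n x dim matrix
#' @return numeric vector of energies
#' @export
plantedEnergy <- function(spec, X) {
  X <- as.matrix(X)
  terms <- vapply(seq_len(spec$nBasins), function(w) {
    d2 <- rowSums((X - matrix(spec$centers[w, ], nrow(X), spec$dim,
                              byrow = TRUE))^2)
    -spec$depths[w] * exp(-d2 / (2 * spec$widths[w]^2))
  }, numeric(nrow(X)))
  rowSums(matrix(terms, nrow = nrow(X)))
}

#' Analytic watershed label of a planted landscape
#'
#' Assigns each point to the well whose (negative) energy term dominates at
#' that point — for well-separated Gaussians this is the basin of attraction
#' of the noise-free surface, and serves as the ground-truth oracle that
#' basin recovery is checked against.
#'
#' @inheritParams plantedEnergy
#' @return integer vector of well indices
#' @export
plantedWatershed <- function(spec, X) {
  X <- as.matrix(X)
  terms <- vapply(seq_len(spec$nBasins), function(w) {
    d2 <- rowSums((X - matrix(spec$centers[w, ], nrow(X), spec$dim,
                              byrow = TRUE))^2)
    spec$depths[w] * exp(-d2 / (2 * spec$widths[w]^2))
  }, numeric(nrow(X)))
  max.col(matrix(terms, nrow = nrow(X)), ties.method = "first")
}

#' Generate a planted-landscape decoy set
#'
#' Samples each well isotropically (Gaussian, sigma = well width) around its
#' center, assigns energies from the analytic surface plus Gaussian noise,
#' and records each decoy's Euclidean distance to the native well's center
#' as its native distance. The result uses the \code{precomputed_features}
#' distance mode, so every downstream stage (graph, basins, clustering,
#' selection, evaluation) runs on it unchanged.
#'
#' @param spec a [plantedLandscapeSpec()]
#' @return list with \code{decoys} (a [DecoySet-class]) and \code{labels}
#'   (integer ground-truth well index per decoy)
#' @examples
#' sim <- generatePlanted(plantedLandscapeSpec(3, seed = 7))
#' table(sim$labels)
#' @export
generatePlanted <- function(spec) {
  stopifnot(inherits(spec, "plantedLandscapeSpec"))
  withr::with_seed(spec$seed, {
    X <- do.call(rbind, lapply(seq_len(spec$nBasins), function(w) {
      n <- spec$samplesPerBasin[w]
      matrix(stats::rnorm(n * spec$dim, sd = spec$widths[w]), n, spec$dim) +
        matrix(spec$centers[w, ], n, spec$dim, byrow = TRUE)
    }))
    labels <- rep(seq_len(spec$nBasins), spec$samplesPerBasin)
    energy <- plantedEnergy(spec, X) +
      if (spec$noiseSd > 0) stats::rnorm(nrow(X), sd = spec$noiseSd) else 0
    nd <- sqrt(rowSums((X - matrix(spec$centers[spec$nativeIndex, ],
                                   nrow(X), spec$dim, byrow = TRUE))^2))
    ds <- DecoySet(ids = sprintf("d%04d", seq_len(nrow(X))),
                   energies = energy, nativeDist = nd, features = X,
                   distanceMode = "precomputed_features")
    list(decoys = ds, labels = labels)
  })
}

#' Reference helical Calpha trace
#'
#' An ideal alpha-helix-like Calpha chain (2.3 A radius, 1.5 A rise and 100
#' degrees of twist per residue), used as the unperturbed parent of the toy
#' conformational ensembles.
#'
#' @param nResidues chain length (default 20)
#' @return nResidues x 3 coordinate matrix (Angstrom)
#' @export
referenceHelix <- function(nResidues = 20L) {
  stopifnot(nResidues >= 3L)
  t <- (seq_len(nResidues) - 1L) * 100 * pi / 180
  cbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * (seq_len(nResidues) - 1L))
}

#' Generate toy conformational decoys around a helix
#'
#' Perturbs the [referenceHelix()] with per-group isotropic Gaussian
#' coordinate jitter (one group per entry of \code{jitterSchedule}) and
#' attaches a smooth pseudo-energy that increases with each decoy's
#' deviation from the reference. This exercises the full PDB / least-RMSD
#' path end to end on data whose distance structure is known by
#' construction; the unperturbed reference doubles as the native.
#'
#' @param n number of decoys (split as evenly as possible across groups)
#' @param jitterSchedule per-group jitter SDs in Angstrom
#'   (default 0, 0.5, 1, 2)
#' @param seed RNG seed
#' @param nResidues chain length (default 20)
#' @return list with \code{decoys} (a [DecoySet-class] carrying coordinates
#'   and the native) and \code{groups} (integer jitter-group index)
#' @export
generateToyConformations <- function(n, jitterSchedule = c(0, 0.5, 1, 2),
                                     seed = 1L, nResidues = 20L) {
  stopifnot(n >= 1L, all(jitterSchedule >= 0))
  ref <- referenceHelix(nResidues)
  groups <- rep_len(seq_along(jitterSchedule), n)
  groups <- sort(groups)
  withr::with_seed(seed, {
    coords <- lapply(groups, function(gidx) {
      s <- jitterSchedule[gidx]
      ref + if (s > 0) matrix(stats::rnorm(3L * nResidues, sd = s),
                              nResidues, 3L) else 0
    })
    dev <- vapply(coords, function(m) sqrt(mean((m - ref)^2)), numeric(1))
    energy <- -20 * exp(-dev) + stats::rnorm(n, sd = 0.05)
    list(decoys = DecoySet(ids = sprintf("toy%04d", seq_len(n)),
                           energies = energy, coords = coords,
                           atomLabels = paste0(seq_len(nResidues), ":CA"),
                           native = ref,
                           distanceMode = "reference_superposed_rmsd"),
         groups = groups)
  })
}
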