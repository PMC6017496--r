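---
title: "Basin-based decoy selection: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Basin-based decoy selection: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(basinselect)
```

## The model

A decoy set Ω is a sample of a protein's energy landscape: each decoy x
carries a conformation and a scalar energy f(x). `basinselect` organizes Ω
into the landscape's local structure in three steps.

**1. Neighborhood graph.** Ω is embedded in an ε-nearest-neighbor graph:
an undirected edge joins every pair of decoys at conformational distance
≤ ε, storing the distance (`buildNNGraph()`). Distances come from one of
three backends (`decoyDistances()`): exact pairwise least RMSD (Kabsch
superposition per pair), plain RMSD after a single superposition of all
decoys onto one reference — the default for coordinate sets, since the
superposition-free RMSD upper-bounds lRMSD and is dramatically cheaper at
O(n²) pairs — or Euclidean distance on feature vectors for tabular and
synthetic sets.

**2. Basins.** A vertex u is a local minimum iff no neighbor lies strictly
below it (`findLocalMinima()`); every other vertex follows the edge
maximizing the discrete negative gradient [f(u) − f(v)]/d(u, v), iterated
until a local minimum is reached (`assignBasins()`). Vertices reaching the
same minimum form its basin of attraction. For each basin the
pseudo-saddle is the lowest member vertex that has a strictly lower
neighbor assigned to a different basin; persistence = f(saddle) −
f(focal), and stability = persistence/√2 (`computeSaddles()`,
`computeStability()`). `mergeByPersistence()` iteratively absorbs the
shallowest sub-threshold basin into the basin across its saddle,
recomputing saddles after every merge.

**3. Selection and evaluation.** Basins are ranked by Basin-Size,
Basin-Size+Energy, Basin-PR or Basin-PR+PC (`rankBasins()`); leader
clustering and size-matched uniform draws provide the Cluster-Size and
Cluster-Random baselines. The top-x groups are scored by n (% of all
natives captured), p (purity) and s (relative size) over the union G1..Gx
(`scoreGroups()`), with natives defined by a difficulty-adaptive
`dist_thresh` (`chooseDistThresh()`).

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| ε (graph/cluster radius) | adapted from 1 Å in 0.5 Å steps (cap 10 Å); or `landscapeEpsilon()` for feature sets | Å / feature units | neighborhood scale of the landscape |
| p_thresh | 1 | energy units (REU) | persistence below which basins merge |
| x | 3 | — | number of groups offered as prediction |
| dist_thresh | difficulty rule | Å | native labelling radius |
| poolSize | 10 | — | size pool re-sorted by energy in Basin-Size+Energy |
| prefilter q | 0 (off) | % | optional high-energy decoy prefilter |

Low persistence thresholds (1–3 energy units, "close to no filtering")
preserve the basin structure that carries selection-relevant signal;
aggressive merging hurts purity, which is why 1 is the default and why
stability is *not* a selection objective: shallow (low-stability) basins
are often large and pure, so filtering or ranking on stability discards
good predictions.

The dist_thresh rule: easy targets (min over Ω of the native distance
≤ 0.7 Å) use 2 Å; medium targets (0.7–2 Å) scan 2–4.5 Å in 0.5 Å steps and
take the first threshold that puts a native inside the largest leader
cluster; hard targets (≥ 2 Å) start that scan at 6 Å so a non-empty
positive set always exists. Taking the scan literally for hard targets
(rather than clamping to exactly 6 Å) is deliberate: a fixed 6 Å threshold
can label zero decoys native when sampling never came within 6 Å, which
would make every strategy's metrics undefined.

## The ε choice

ε controls everything downstream, and two regimes fail: below the
connectivity radius the graph fragments and artifact minima appear at the
sparse rims of the sample (a vertex with no strictly-lower neighbor is a
local minimum; if nothing descends into it, it is a singleton basin with
*no* escape vertex, hence infinite persistence — unmergeable by
construction). Far above it, descent paths jump across ridges and distinct
basins fuse. `landscapeEpsilon()` therefore returns 1.5× the connectivity
radius (the longest minimum-spanning-tree edge of the pairwise distances):
dense enough that rim vertices see a downhill neighbor, well below the
inter-basin scale. On the planted benchmark below, 1.5× recovers every
planted basin exactly while 2× begins to bridge wells. For coordinate
decoy sets the clustering adaptation (start at 1 Å, grow by 0.5 Å until a
non-singleton cluster exists) is used instead, and the same ε serves both
clustering and the graph so the baselines are compared at matched scale.
"Until a non-singleton cluster exists" is our reading of the adaptation
stopping rule: a singleton cluster exists for any ε, so only the ≥2-member
reading can fail and force growth.

## The synthetic generator

`generatePlanted()` emulates the one structural property the method rests
on: a multi-modal landscape with wells of known location, depth and
population. Decoys are points in a low-dimensional feature space sampled
isotropically (σ = well width) around k centers; the energy is
−Σ_w depth_w · exp(−‖x − c_w‖²/(2σ_w²)) plus Gaussian noise, and the
distance to the "native" well's center stands in for the native distance.
Defaults — dim 2, 150 samples/well, unit widths, neighboring centers 6σ
apart (the generator refuses anything under 4·max σ), depths evenly spaced
10→6 energy units, noise at 5% of the shallowest depth, native = deepest
well — are chosen so that persistence thresholds of 1–3 noise SDs separate
noise basins from planted ones, mirroring realistic score noise relative
to well depth. `plantedWatershed()` gives the analytic ground truth
(the well whose energy term dominates at a point) used as the oracle in
the tests.

What the generator does *not* emulate: the anisotropy and intrinsic
dimensionality of real conformation spaces, heavy-tailed Rosetta score
errors, the strong density gradients of biased sampling, and any
relationship between geometry and energy beyond the planted wells. Tests
passing on it show the machinery is correct (graph, descent, saddles,
merging, ranking, metrics), not that basin selection will succeed on any
particular real target. `generateToyConformations()` complements it on the
coordinate side: helix perturbations with jitter-graded pseudo-energies
exercise PDB I/O, Kabsch superposition and the reference-superposed
distance path on data whose distance structure is known.

Problem sizes used throughout the validation suite — 100–150 samples per
well, k ≤ 6 wells, 200 random graphs of ≤ 30 vertices, 200 random basin
lists of ≤ 50 basins, 10,000 random draws for the baseline calibration —
are large enough for each property to be sharp (e.g. the random-draw
purity check sits within 3 standard errors of the planted native
fraction) while keeping the whole suite around a minute.

## Numerical and degenerate-case choices

* **Plateaus.** With non-strict minima (f(u) ≤ neighbors), an
  equal-energy plateau makes every plateau vertex its own basin; descent
  only ever moves strictly downhill, so paths terminate and no cycles are
  possible (a guard errors if one ever appeared). Ties among equally steep
  descent edges go to the lowest-index neighbor — determinism is required
  for testing.
* **Saddle multiplicity.** Many vertices can qualify as escape points; the
  lowest-energy qualifier is taken, making persistence the *minimal*
  barrier, the standard topological-persistence convention.
* **Merging.** The victim is the lowest-persistence sub-threshold basin;
  it is absorbed into the basin of the saddle's lowest strictly-lower
  cross-neighbor, and saddles are recomputed after every merge (merging
  changes escape routes, so stale saddles would mis-merge); the filtration
  is idempotent: merging at p1 then p2 ≥ p1 equals merging at p2 directly,
  which the tests assert.
* **Ranking ties.** After each strategy's stated keys, ties break by focal
  energy ascending, then basin index, making every ordering total and
  reproducible.
* **Zero natives.** n and p are reported as NA, never 0 — "no natives
  exist" and "the selection missed them all" are different failures.
* **Cluster-Random.** Draws are without replacement and disjoint within a
  run, so the union sizes match the size-matched clusters exactly; metrics
  average over 5 runs by default.
* **lRMSD.** Calpha atoms with uniform weights by default (atom selection
  is configurable); the superposition backend is bio3d's Kabsch fit, with
  the RMSD computed from the fitted coordinates at full precision.
* **High-energy prefilter.** Off by default. Dropping *low*-energy decoys
  removes focal minima and fabricates spurious basins, so only the
  high-energy tail may be filtered, and only on request.

## A worked miniature

The 4-vertex path landscape with energies 3, 1, 2, 0.5 at unit spacing is
small enough to trace by hand and is pinned exactly in the tests:

```{r}
ds <- DecoySet(energies = c(3, 1, 2, 0.5), features = matrix(0:3, ncol = 1))
g <- buildNNGraph(ds, 1)
bs <- computeStability(computeSaddles(g, assignBasins(g, c(3, 1, 2, 0.5))))
basinTable(bs)
```

Vertex 3 (energy 2) descends to vertex 4: the ratio (2 − 0.5)/1 beats
(2 − 1)/1. Two basins result — {1, 2} with focal energy 1 and {3, 4} with
focal energy 0.5; vertex 3 is the shallower basin's pseudo-saddle
(persistence 2 − 0.5 = 1.5), and the deepest basin has no escape vertex,
hence infinite persistence.

## Known limitations

* Pairwise distance matrices are materialized in memory, so sets beyond a
  few tens of thousands of decoys need the reference-superposed mode and
  patience; neighbor queries are not spatially indexed.
* Only ε-graphs are implemented; a k-nearest-neighbor fallback for very
  non-uniform sampling is a documented hook, not a feature.
* Strong dominance on exactly two objectives (size, −energy) is built in;
  the experimental third objective (stability) is exposed only through the
  basin table, reflecting its lack of selection value.
* The native-label machinery assumes a single native reference; multiple
  native conformations per target are not modelled.
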