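---
title: "Reconstructing fusome topology and growth in germline cysts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing fusome topology and growth in germline cysts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusomekit)
```

## The biological problem

Insect germ cells develop inside *germline cysts*: clusters of cells left
interconnected by ring canals (intercellular bridges) because each mitotic
division completes without abscission. After `k` synchronous divisions a
cyst has `2^k` cells joined by `2^k - 1` canals, so its connectivity graph
is always a tree. Threading through every canal is the *fusome*, a
membranous organelle that grows from the founder cell's spectrosome by
adding a "plug" of new material in each nascent ring canal. In *Drosophila*
females the fusome orients every spindle so that each division buds a new
terminal cell, producing an invariant, *maximally branched* 16-cell tree in
which exactly two cells (the pro-oocytes) carry four ring canals. In males
the same machinery is looser: divisions may occur "in line", the fusome
fragments, and cyst topology becomes variable.

`fusomekit` implements the quantitative machinery this biology calls for:

1. **topology** — cyst lineage trees, the division rules, enumeration of
   reachable topologies up to isomorphism, and subtree embeddability;
2. **segmentation** — recovering per-cell fusome fragments, volumes and
   canonical cell labels from two-channel 3D masks;
3. **growth model** — a two-parameter additive model of fusome growth and
   inheritance, fitted to measured per-cell volume fractions;
4. **synthetic data** — a generator for both model-drawn volume tables and
   rendered voxel images with exact ground truth.

## Cyst trees and the division rules

A division replaces each cell by two daughters joined by a new canal and
partitions the mother's existing canals between them. A degree-`d` cell
therefore has `2^(d-1)` distinct unordered choices; handing the daughter no
existing canal is the *branching* choice, anything else is *in line*.
`enumerate_topologies()` takes the Cartesian product of all cells' choices
and collapses the products to isomorphism classes:

```{r enumerate}
enumerate_topologies(canonical_max_branched(4))$n_classes   # 3 eight-cell trees
enumerate_topologies(canonical_max_branched(8))$n_classes   # 36 sixteen-cell trees
```

Isomorphism classes are counted over *unlabelled* trees (daughters are
interchangeable, cells carry no identity). This convention is not forced by
first principles, but it is the one that reproduces both published counts
(3 and 36), and is validated in the test suite against a brute-force
partition of the labelled product space using an independent graph library.

Canonical forms use the classic AHU encoding of the unrooted tree rooted at
its centroid; when two centroids exist both rootings are encoded and the
lexicographically smaller string is kept. `is_embeddable()` answers whether
a (possibly fragmented) fusome's tree can sit inside a host topology as a
connected subtree, via the standard rooted dynamic programme with a
bipartite matching of children at every step; it is cross-checked against
exhaustive subtree enumeration on small hosts.

## The additive growth model

Let `v0` be the spectrosome volume (normalised to 1) and `v_k` the volume
of each plug added at division `k`. A fraction `beta` of every plug stays
with the mother; `1 - beta` goes to the daughter. With `alpha` defined as
cell 1's volume fraction at the 2-cell stage,

```
alpha = (v0 + beta v1) / (v0 + v1)   =>   v1 = v0 (1 - alpha) / (alpha - beta),
```

which requires `beta < alpha` for a positive `v1` (the *feasibility mask*
used everywhere). The measured 16-cell groupwise fractions — cells 1–2 :
3–4 : 5–8 : 9–16 close to 2:1:1:1 — close a linear system for
`v2, v3, v4`. Fractions at any stage follow by bookkeeping: a cell born at
division `b` holds `(1-beta) v_b` plus `beta` of every later plug.

```{r model}
plugs <- solve_plug_volumes(alpha = 0.7, beta = 0.5)
plugs$v
predict_fractions(plugs, 16)[1:4]
ratio_trajectory(plugs)        # cell 1 : cell 2, decreasing towards parity
```

`fit_fusome_growth()` is the package's model-fitting front end, in the
classic R idiom: it returns a classed object with `coef()`, `summary()`,
`predict()`, `plot()` (the error surface), `residuals()` and `simulate()`
methods. The fit minimises the summed squared residuals between measured
and predicted fractions over every cell at all cyst sizes on a regular
`(alpha, beta)` grid, and reports the region within 5% of the minimum
error as a parameter-uncertainty band.

Numerical choices, made once:

* **Grid**: `alpha, beta` in `[0.25, 0.75]`, step 0.005. The published
  optimum (`beta = 0.515`) is only expressible on a grid at least this
  fine; the step is not stated in the source material, so 0.005 is the
  coarsest grid consistent with the printed value.
* **Residual mode**: residuals are taken against *stage-wise mean*
  per-cell fractions (one residual per cell per stage), because means are
  what the published comparison displays; a per-sample variant is behind
  `per_sample = TRUE`. On simulated data the two agree closely.
* **Cell ordering**: measured cysts are put in canonical order with the
  pro-oocyte pair sorted descending (`f1 >= f2`), matching the labelling
  convention that cell 1 is the larger fragment with the most ring canals.
  Cells born at the same division have equal predicted fractions, so
  within-group ordering does not affect the fit.
* **Feasibility**: grid points with `alpha - beta < 0.01` or any negative
  solved plug volume get infinite error rather than being silently
  dropped.

## Segmentation of voxel data

The segmentation stage starts from per-voxel class probabilities (or binary
masks) for two channels, fusome and ring canals, with anisotropic voxel
sizes (defaults 70 x 70 x 210 nm, as in high-resolution confocal stacks).
All geometry is computed in physical nm coordinates.

* **Thresholding** at probability 0.5 (configurable).
* **Ring detection**: each connected component of the ring channel is kept
  iff it contains a cycle. With no skeletonisation library available in
  this environment, the test is homological rather than skeleton-based:
  the Euler characteristic of the component's cubical complex is 1 for any
  blob without a handle and 0 (or less) for a closed loop, so `chi <= 0`
  detects rings exactly, with no thinning pass and no tuning parameter.
  This assumes the ring tube is at least two voxels thick, which holds for
  real ring canals (~1 µm across) at confocal resolution.
* **Recursive splitting**: each ring defines a cutting disk — its PCA
  best-fit plane, disk radius 1.25 x the measured loop radius, slab
  half-thickness `0.55 * sum(|n_i| * voxel_i)` (one voxel step projected
  onto the cut normal; a fixed two-voxel slab fails to sever 26-connected
  paths when the plane tilts toward the coarse z axis). Removing the disk
  must split the component in two; remaining rings are dealt to the side
  nearest their centroid and the recursion continues. Cut voxels are
  reassigned to the nearest final fragment afterwards, so fragment volumes
  sum to the component volume *exactly* (integer voxel counts).
* **Labelling**: the larger-volume fragment among those of maximal degree
  is cell 1; remaining labels come from a Hungarian assignment on
  structural signatures (degree, hop distance to cell 1, neighbour-degree
  profile), verified to be a graph isomorphism with a deterministic
  backtracking fallback for cost ties. Exact pro-oocyte volume ties break
  toward the lower fragment id and are flagged.
* **Male mode** never attempts canonical labels: it reports the component
  census (fusome-connected cells = traversed rings + 1), and whether each
  component's topology embeds into the maximally branched 16-cell tree.

## What the synthetic generator emulates — and what it does not

`simulate_volume_table()` draws per-cell volumes
`T_k * f_i(alpha*, beta*) * exp(N(0, sigma))`; noise is multiplicative
lognormal because volumes are positive and the empirical scatter is
relative. Defaults state the measured world: `alpha* = 0.7`,
`beta* = 0.5`, ratio 2:1:1:1, 12 cysts per stage (the published 2- and
4-cell sample size; 8- and 16-cell samples were 6 and 11), `sigma = 0.05`.

`render_cyst()` builds a voxel world from a cyst tree: a seeded 3D
force-directed layout places cells ~3.6 µm apart; each cell's fusome is a
ball of prescribed relative volume (mean radius 0.95 µm), bridges are
250 nm cylinders, and each ring canal is a torus (major radius 550 nm,
minor 220 nm) centred on its bridge. Geometry defaults keep every
structure resolved at the default 100 x 100 x 200 nm rendering voxels and
keep bridges below ~5% of total fusome volume, so ground-truth fractions
track the prescribed ones within 0.02. Male-style fragmentation deletes
bridge mid-segments with probability `p_frag`. Every render carries a
machine-readable answer key (per-voxel owner labels, per-cell voxel
volumes, ring positions, the tree, deleted bridges), so every segmentation
operation can be scored without human input.

The generator does **not** emulate microscopy physics: no point-spread
function, photon noise, background staining, touching neighbouring cysts,
or segmentation-probability errors (a Gaussian blur option exists solely
to produce probability-map-like inputs). A green round-trip therefore
establishes the correctness of the geometric/topological pipeline — not
robustness to imaging artefacts, which only real stacks can test.

## Degenerate inputs and tie-breaks

* Zero detected rings: the cyst is treated as single-celled (warning).
* A cutting disk that fails to disconnect, or shatters, the fusome raises
  a named error for that ring; sub-2% debris shaved off the tube wall is
  folded into the cut set rather than failing the sample.
* `run_pipeline()` skips failing samples with a logged warning instead of
  crashing the batch.
* Equal canonical-form centroid rootings and equal-cost label assignments
  resolve deterministically (lexicographic / lowest-id), so identical
  inputs always give identical outputs.

## Known limitations

* The published per-cyst volume spreadsheet is not redistributable with
  the package, so the reproduction of the measured optimum
  (`alpha = 0.700`, `beta = 0.515`) runs only when its CSV export is
  placed at `inst/extdata/s1_volumes.csv`; the corresponding acceptance
  test fails (honestly) in its absence.
* Enumeration is limited to starts of at most 8 cells; the labelled
  product space beyond that is astronomically larger and not needed for
  the 16-cell question.
* The splitter assumes each ring canal's plane locally separates the two
  sister fragments — true for tube-and-ball geometry, untested for
  pathological shapes such as a fusome folding back through its own ring
  plane.
* Image I/O uses a plain-text voxel format rather than TIFF (no TIFF
  reader is available in this build); arrays in memory are first-class
  citizens throughout.
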