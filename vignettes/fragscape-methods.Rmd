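---
title: "Morphological segmentation and fragmentation statistics: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological segmentation and fragmentation statistics: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragscape)
```

This vignette is the package's account of its science: the models it
implements, the conventions it fixes where the literature is silent, and
the reasoning behind the design choices that were genuinely open.

## The binary landscape and its geometry

All spatial analysis operates on a `binary_landscape`: a rectangular grid
of foreground/background cells with a cell size in meters (default 30 m,
i.e. 0.09 ha per cell). Cells are addressed `(row, col)` with row 1 at the
top; every module shares this convention.

Two geometric conventions deserve emphasis, because everything downstream
inherits them:

* **The map exterior counts as background.** The Euclidean distance to
  background of a foreground cell is the distance to the nearest
  background cell *or* to the nearest virtual cell outside the border.
  This makes segmentation invariant under padding with background rings,
  keeps a solid 11×11 map equivalent to an 11×11 square pasted into a
  larger empty map, and leaves no undefined distances: an all-foreground
  map still has an edge zone along the border and core in its interior.
  The alternative (in-map background only, with an infinite sentinel)
  breaks padding invariance for any map whose border region is far from
  in-map background, so it was rejected.
* **The background uses the dual connectivity of the foreground.** With
  the default 8-neighbor foreground rule, background components are
  4-connected, and vice versa. Without duality a diagonal foreground ring
  and the background threading through its diagonal gaps could both be
  "connected", a classical topological paradox; with it, a hole (a
  background component that does not touch the border) is well defined.

Distances are center-to-center Euclidean distances in cell units,
computed by an exact distance transform (`EBImage::distmap`, checked
against brute force in the tests).

## MSPA: the seven-class decision order

`mspa_segment()` assigns each foreground cell exactly one class, with two
parameters: the edge width *D* (default 4 cells = 120 m at 30 m
resolution; *D* = √(a² + b²) for axis offsets *a*, *b*) and the
connectivity rule *R* (default 8). The decision order is:

1. **core** — distance to background strictly greater than *D* ("greater
   than", hence strict; the boundary classes use the complementary
   non-strict "≤ *D*").
2. **islet** — the cell's foreground component contains no core cell.
   Islets are decided at component level, so a thin closed ring without
   core is all islet even though it encloses background.
3. **bridge** — the cell lies on a minimal geodesic path through
   non-core foreground (connectivity *R*, step counting) joining two
   *distinct* core components. All cells on *any* minimal geodesic for
   some core pair are marked, so corridors keep their geodesic fan where
   they enter the squares they connect.
4. **loop** — see below.
5. **perforation** — within *D* (Euclidean) of core, and the nearest
   background is part of a hole. Nearest-background ties resolve to the
   outer background, i.e. to edge: perforation requires the hole to be
   strictly nearest.
6. **edge** — within *D* of core, facing the outer background.
7. **branch** — everything left.

Connectors precede the boundary classes deliberately: with the reverse
precedence a corridor shorter than 2*D* would be swallowed by the edge
zone of the cores it connects and the landscape's connecting structure
would become invisible exactly where it is most fragile. The reverse
precedence is still available (`boundary_over_connector = TRUE`) for
comparison with tools that carve connectors out of the residue beyond the
edge zone; under that option corridor cells within *D* of core become
edge and only the middle of a long corridor stays bridge.

A consequence of the strict Euclidean reading of "within *D* of core" is
that the corner cells of a convex patch — geodesically attached to the
edge band but Euclidean-farther than *D* from core — classify as branch.
This is the literal reading of the class definitions and is asserted in
the fixtures.

### The loop rule

The bridge rule extends naturally to paths that leave and re-enter the
*same* core component, but a literal per-pair version is degenerate on a
grid: any two adjacent core-contact cells are joined by a length-1
geodesic, so every cell of the edge band around any core would qualify.
The package therefore decides loops at the level of **link regions**
(connected components of non-core foreground): a region *L* adjacent to a
set *K* of core components is a loop region iff *L* ∪ *K* encloses
background that *K* alone does not (its hole count strictly increases).
This is exactly the topological statement "the region closes a cycle with
its cores": a handle that leaves a core and rejoins it encloses new
background; the inner and outer bands of a thick annulus do not (the
annulus' core ring already encloses the hole), and a corridor between two
cores does not. Within a gated region, loop cells are those beyond *D*
of core — the part of the handle outside the edge zone — and bridge takes
precedence where both apply. The marking is region-level: in a
cycle-closing region, outlying beyond-*D* cells (e.g. the corners of the
square carrying the handle) are also labeled loop rather than branch;
this coarseness is accepted and documented here.

### Verification

The segmentation is verified three ways in the test suite: an
independent brute-force classifier (flood fill, exhaustive pairwise
distances, queue BFS — no code shared with the package) must agree
cell-for-cell on hundreds of random landscapes at several *D* and both
connectivities; seven geometric fixtures (`generate_fixture()`) carry
expected label grids derived in closed form from rectangle distances and
Chebyshev geodesic fans; and the partition invariant (Σ class counts =
foreground count) is asserted on every case. Random-map checks run at
40×40, where the brute-force oracle is exact and fast; the implementation
itself is routinely used at 256×256 and larger.

## Landscape pattern indices

Conventions, fixed and documented rather than configurable where the
field's tools disagree:

* **Perimeter** counts 4-neighbor cell edges against background *or* the
  map border (the landscape-boundary-counts convention). Patch
  connectivity defaults to 8, matching the MSPA rule.
* **PD** = patches / area × 100 (patches per 100 ha; per km² available).
* **NLSI** = (e − e_min)/(e_max − e_min) with the integer-square closed
  form for e_min (4n, 4n+2 or 4n+4 for a = n² + m) and, under the
  border-counting convention, e_max = 4a while the class can be fully
  dispersed (a ≤ ⌈Z/2⌉), else 4(Z − a) + 2(R + C). Both closed forms are
  validated against exhaustive arrangement search for small areas in the
  tests. A class filling the landscape has e_max = e_min and NLSI is
  defined as 0.
* **COHESION** = [1 − Σpⱼ / Σpⱼ√aⱼ]·[1 − 1/√Z]⁻¹·100 in cell units; 0
  when all patches are single cells, 100 when one patch fills the
  landscape. Padding the landscape changes COHESION only through the Z
  correction term, and the tests pin that exact dependence.
* **MESH** = Σaⱼ²/A in hectares — the expected size of the patch
  containing a uniformly random cell; it never exceeds A, with equality
  iff one patch covers everything.
* **CONTAG** uses proportional class abundances and rook adjacencies
  with double counting: CONTAG = [1 + ΣΣ q·ln q / (2 ln m)]·100 with
  q_ik = P_i·g_ik/Σ_k g_ik. Note two properties that are easy to
  mis-state: a one-cell checkerboard of two classes gives exactly 50
  (only the two cross terms survive), and two solid half-planes approach
  50 — not 100 — as the grid grows, because the class-abundance entropy
  term remains at equal abundances. CONTAG → 100 requires single-class
  dominance; CONTAG → 0 is the independent random map. Observed values
  of 47–50 at foreground proportions near 0.55 therefore sit just below
  the equal-abundance ceiling (≈ 50.4 at F = 0.55) and indicate strongly
  aggregated, block-contiguous maps.

## The synthetic generator

`generate_mrc()` implements a modified-random-clusters neutral model:
Bernoulli marks at probability `cluster_p`, 4-neighbor clusters assigned
to the foreground in random order until the foreground share of marked
cells reaches `target_f`, remaining cells filled by the neighborhood
majority (seeded coin flips on ties), and finally a composition
adjustment that nibbles or grows random boundary cells until the
foreground count equals `round(target_f · n)` exactly. The adjustment is
part of the generator's definition: cluster granularity otherwise leaves
the realized composition a few percent off at coarse settings, and
composition is the one property the model promises to control.
`cluster_p = 0` degenerates to an independent random map. A single
integer seed drives all stochastic steps through one locally scoped RNG
state; the caller's RNG is untouched, and identical parameters + seed are
bit-reproducible.

Percolation clusters below the 4-neighbor threshold (~0.593) have
fractal boundaries, which caps the contagion of plain MRC maps near 31
at F = 0.55 (and majority smoothing only reaches ~36). Real regional
land-cover maps are far more aggregated — contagion 47–50 at these
compositions implies cross-class adjacencies on the order of 1% —
because their patches are contiguous at the kilometer scale. The
`coarse_factor` parameter reproduces this: the cluster map is generated
on a lattice coarsened by the factor and each coarse cell is replicated
as a block. The calibrated regime used in the tests and the acceptance
script is a 512×512 grid, `coarse_factor = 16`, `cluster_p = 0.55`,
`target_f = 0.55`, which lands contagion at ≈ 47.5–48.5 across seeds.

What the generator emulates: composition, aggregation level and
block-scale contiguity of classified regional maps. What it does not:
anisotropy (valleys, coastlines), road-network geometry, classification
noise, multi-class structure, spatially autocorrelated loss. Passing
tests on these landscapes therefore demonstrate correctness of the
*measures* and the expected *directional* responses to loss, not
numerical parity with any particular real landscape.

### Fixtures and change scenarios

`generate_fixture()` builds deterministic shapes whose class maps follow
in closed form from the definitions (solid square, scatter, thin ring,
thick annulus, dumbbell, dumbbell-with-stub, core-with-handle). The
expected grids are constructed from rectangle-distance formulas and
Chebyshev fan arithmetic — not by running any classifier — so they are a
third, independent route against which both the implementation and the
brute-force oracle are compared.

`apply_scenario()` provides loss-only edits (edge erosion, hole
punching, whole-patch removal, corridor carving); foreground never grows,
mirroring study systems where habitat gain is negligible. The seeded
three-date demo (`demo_scenario()`, 192×192 by default, 256×256 in the
acceptance script) generates a block-contiguous base at foreground
proportion 0.6456 and degrades it to 0.5909 and 0.4910 — the bundled
1985/2000/2010 farmland proportions — by punching and erosion. Loss is
spatially uniform, so (unlike field landscapes, where conversion
concentrates on scattered islet/branch farmland) the demo's losses come
mostly from the dominant core class; the conversion-source composition is
reported by the acceptance script but no real-data value is claimed
for it.

## Markov chains over class maps

`estimate_transitions()` cross-tabulates per-cell states (7 classes +
non-farmland) between two dates into counts **C** and row-normalizes to
**P**. States absent at the first date get an identity row with a
warning — the estimator refuses to invent flow. Diagnostics:

* **Stationary distribution** π: dominant left eigenvector, normalized;
  reducible chains warn and return one valid solution.
* **Convergence rate** ρ = 1/|λ₂|, taking λ₂ as the largest eigenvalue
  modulus *strictly below one*. For ergodic chains this is the classical
  subdominant eigenvalue. For chains estimated from loss-only sequences
  the non-farmland state is absorbing (and absent states contribute
  artificial unit eigenvalues), yet the approach to the absorbing set
  still has a well-defined geometric rate — which is what this
  convention returns, with a warning about reducibility. ρ > 1 means
  faster convergence; uniform rows give λ₂ = 0 and ρ = ∞.
* **Normalized entropy** H(**P**) = −Σᵢ πᵢ Σⱼ P_ij ln P_ij / ln s, with
  s the number of states carrying stationary mass and 0·ln 0 = 0. The
  π-weighting makes H the entropy *rate* of the chain, the standard
  normalization; but for an absorbing chain the stationary mass sits on
  one state and the rate is legitimately 0. Because the weighting
  convention is not uniquely fixed in the landscape-succession
  literature, `weights = "uniform"` computes the plain row-average
  variant, which stays informative for absorbing chains; both are
  reported by the pipeline and acceptance script.

The whole estimation-plus-diagnostics path is validated by parameter
recovery: 100,000 cells are simulated from a known 8-state chain and
re-estimated. The chain used has identical row patterns (persistence
0.9, one featured conversion at 0.07 — boundary-to-edge,
connector-to-bridge, islet/branch-to-non-farmland — and six rare moves
at 0.005), for two reasons: each of the eight states then receives
roughly 12,500 cells, putting every entry's sampling error well inside
the 0.01 check, and equal row entropies make H insensitive to the
conditioning of the estimated stationary vector, so the 2% tolerance on
H and ρ measures estimation error rather than spectral sensitivity.

## Trend and accuracy statistics

Change statistics define the average annual decrement over an interval
as (area₂ − area₁)/(t₂ − t₁) and its rate relative to the
**interval-start** area — the convention validated by the bundled
1985–2010 record, where 240.52/16397.31 reproduces the printed −1.47%/yr.
Losses are negative. Values are kept at full precision internally;
`rounded = TRUE` applies 2-decimal reporting with **half-toward-zero**
tie-breaking, the only rounding rule consistent with every printed cell
of the bundled record (the 2008–2010 decrement is an exact half,
−193.095 → −193.09, while −1.4668 → −1.47 rules out truncation).

Pearson correlations use `stats::cor.test` (two-tailed, t on n − 2 df)
with flags at 0.05/0.01; zero-variance pairs are undefined (`NA`), never
coerced to 0. Accuracy/kappa follow the standard confusion-matrix
definitions and are cross-checked against `e1071::classAgreement` in the
tests; a matrix whose chance agreement is 1 has no defined kappa and is
rejected.

## Numerical choices and degenerate inputs

* Eigen-solutions use LAPACK via `eigen()`; unit-eigenvalue detection at
  1e-10; complex eigenvalues handled by modulus; stationarity asserted
  at 1e-10 in tests.
* Component labeling is deterministic: components are numbered in
  raster-scan order of their first cell.
* All-background maps segment to all-background; all-foreground maps get
  border edge and interior core (exterior-as-background); empty
  foreground makes per-foreground proportions an error, not NaN.
* Nodata cells default to background with a message (conservative for
  fragmentation: unknown cells never add habitat); a strict policy
  errors instead.
* Rasters: ESRI ASCII grids carry the cell size natively and are the
  text format of choice; TIFF payloads are read/written via the `tiff`
  package with the cell size supplied by the user (geospatial tags are
  out of scope). Georeferencing, reprojection and multi-band imagery are
  out of scope entirely.

## Known limitations

* Bit-exact parity with GUIDOS/MSPA software output is not claimed: the
  class semantics follow the published definitions, but the connector
  precedence (above) and the region-level loop rule differ from
  implementations that carve connectors from the beyond-edge residue.
* The loop rule's region-level marking can label outlying beyond-*D*
  cells of a cycle-closing region as loop (see above).
* The π-weighted entropy of loss-only chains is 0 by construction; use
  the uniform-weighted variant for such sequences.
* The generator reproduces composition and contagion, not the full
  spatial structure of any real landscape; directional claims verified
  on it (core down, islet up, PD up, MESH/COHESION down under loss
  edits) are the intended scope.
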