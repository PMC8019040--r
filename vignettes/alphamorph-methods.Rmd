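---
title: "Alpha-shape complexity of anatomical surfaces: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alpha-shape complexity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`alphamorph` scores the complexity of a closed 3D surface by how refined
an alpha shape must be before it recovers the surface's enclosed volume.
An alpha shape of a point set, for alpha radius $\alpha$, is the union of
the Delaunay tetrahedra whose circumradius is at most $\alpha$: at large
$\alpha$ it is the convex hull, and as $\alpha$ shrinks the fit tightens
into concavities and eventually disintegrates. For a mesh with volume
$V$ we fill the interior with uniform random points, fit alpha shapes
across a grid of refinement coefficients $k$ with
$\alpha = k \cdot l_{\mathrm{ref}}$, and define

* the **characteristic curve**: alpha-shape volume as a percentage of
  $V$ against $k$ (non-decreasing in $k$ by construction);
* the **optimal refinement** $k^\*$: the smallest $k$ whose alpha volume
  reaches $V$;
* **alpha complexity** $= 1/k^\*$.

The reference length $l_{\mathrm{ref}}$ — the mean distance of each
down-sampled point to its 100 nearest neighbours — makes $k$
dimensionless. Because $l_{\mathrm{ref}}$ scales linearly with the
specimen, uniformly rescaling a mesh leaves the whole curve, and hence
the complexity score, unchanged up to sampling noise; the test suite
asserts agreement within 5% under a tenfold rescaling and under random
rigid motions.

Key assumptions: the input mesh is watertight and consistently wound
(validated, not repaired — a silently hole-filled surface would bias the
volume anchor); the interior point process is uniform (plain rejection
sampling in the bounding box, no stratification); and points are in
general position, which holds with probability one for continuous
sampling.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `fill_min` | 250,000 | accepted interior points before down-sampling |
| `downsample_target` | 100,000 | points used for Delaunay fitting |
| `n_neighbors` | 100 | neighbours defining $l_{\mathrm{ref}}$ |
| `k` grid | 200 values, log-spaced on [0.1, 10,000] | refinement sweep |
| `sampled_k` | 6 values, log-equal over the grid | multi-scale profile |
| `tol` | $10^{-3}$ | relative volume tolerance of the $k^\*$ search |
| `master_seed` | — | all stage seeds derive from it |

All quantities that matter downstream (volume fractions, $k$, alpha
complexity) are dimensionless, so mesh units are carried only as an
opaque tag.

The `l_ref` average is the mean of per-point means; since every point
has exactly `n_neighbors` neighbours this coincides with the pooled mean
over all point–neighbour pairs. Nearest-neighbour queries go through a
kd-tree and are checked against an exhaustive $O(n^2)$ oracle in the
tests.

## Numerical choices

**One Delaunay, many fits.** The tetrahedralization is computed once per
cloud (Qhull, via scipy's spatial module through reticulate — the one
geometric primitive the package does not implement itself). Each
tetrahedron's circumradius and volume are precomputed; a fit at any
$\alpha$ is then a threshold query on the radius-sorted cumulative
volume. Because a single cumulative sum serves the whole grid, the
characteristic curve is *exactly* non-decreasing, with no floating-point
wiggle.

**Inclusive threshold and the hull anchor.** A tetrahedron with
circumradius exactly $\alpha$ is kept. Near-coplanar sliver cells on the
hull can carry arbitrarily large finite circumradii, so no finite
$\alpha$ is guaranteed to reproduce the hull to machine precision; since
the family is defined as spanning shrink-wraps *through to the convex
hull*, the top grid point reports the full Delaunay volume, which equals
the hull volume and is asserted against an independent convex-hull
computation at $10^{-9}$ relative tolerance. Truly degenerate
tetrahedra (determinant below $10^{-14}$ of the edge-length scale) get
infinite radius and are never kept by a finite fit; their volume is
numerically zero.

**Optimal-k search.** The curve value is monotone in $k$, so the
crossing of 100% is bracketed on the grid and bisected in $\log_{10} k$
(fresh threshold queries, not interpolation) until the volume mismatch
is within `tol` or the bracket is narrower than $10^{-3}$ in
$\log_{10} k$. Bisection on a monotone objective is derivative-free,
deterministic, and cannot stall on the flat zero-volume region, which is
why it replaces a general-purpose simplex search here. Two boundary
regimes are flagged rather than hidden: a convex body whose interior
sample hull falls short of the mesh volume never crosses 100% and is
reported at the coarse grid boundary with a warning (the score floor
$10^{-4}$), and a crossing below the finest grid point is reported at
the fine boundary. Volume fractions above 100% at coarse $k$ are
expected for concave shapes (the hull exceeds the mesh volume); the
crossing from below defines $k^\*$.

**Containment tests.** Point-in-mesh queries ray-cast along $+z$ with a
2D grid over triangle footprints; rays that pass within tolerance of an
edge, vertex, or near-parallel triangle's plane are re-cast with random
directions against the full triangle list. The fallback directions come
from the stage seed, so results are reproducible; the test suite checks
1,000 random queries per mesh against a generalized winding-number
oracle.

**Heatmaps.** "The coarsest fit a point contributes to" is
operationalized as boundary membership: a triangle shared by tetrahedra
with radii $r_1 \le r_2$ is on the boundary exactly for
$r_1 \le \alpha < r_2$ (hull triangles from $r_1$ on), so each face's
coarsest qualifying grid $k$ is read directly off these intervals
without refitting, and each point takes the maximum over its incident
faces. Boundary membership is not monotone in $k$, hence the maximum
rather than an interval assumption. Points never on any boundary carry a
sentinel and are excluded from face averages; an all-sentinel face
inherits its edge-neighbours' mean. The colour ramp is applied to
$\log_{10} k$ and inverted so that low coarsest-$k$ (complex) regions
render warm, with anchors chosen so red-minus-blue decreases
monotonically along the ramp.

**Comparative statistics.** Pagel's $\lambda$ multiplies the
off-diagonal phylogenetic covariance; it is profiled by bounded scalar
ML on $[0, 1]$ (with the endpoints checked explicitly) and boundary
estimates are reported as-is. PGLS estimates $\lambda$ jointly with the
coefficients; standard errors use the unbiased residual variance with
$n - p$ degrees of freedom, $\lambda$ not counted, and $t$ is always
slope/SE. Ancestral states are the GLS conditional means given the
tip–ancestor Brownian covariance (the root equals the GLS grand mean).
The phylogenetic ANOVA and MANOVA reference the classical $F$ and
Wilks' $\Lambda$ to null distributions simulated under (multivariate)
Brownian motion with rates estimated from the data, using the
$(1 + \#\{\text{more extreme}\})/(n_{\mathrm{sim}} + 1)$ continuity
correction. The phylogenetic PCA normalizes the covariance matrix to
unit depth so scores stay in trait units and a star tree reproduces
ordinary PCA exactly up to sign; all five procedures are asserted to
collapse to their classical counterparts on a star phylogeny and are
cross-checked against independent reference implementations in the test
suite.

## What the synthetic generator emulates — and what it does not

`make_tube()` produces closed, watertight, endocast-like tubes with
separately controllable features:

* **folds** — raised-cosine grooves of given depth, angular width, and
  optional helical twist, mimicking wall protrusions seen from the
  lumen. The compact smooth bump guarantees watertightness at every
  depth below 1.
* **gross form** — linear taper and axis curvature (`bend_angle`, a
  circular arc). Axis curvature is the generator's whole-structure
  concavity: its hull void is bridged only by coarse fits, which is what
  makes the coarse end of the profile informative.
* **fine texture** — band-limited random harmonics on the radius, with
  default wavenumbers (16–32 angular, 10–24 axial) sitting well above
  the fold scales so that texture and gross form act at separable
  scales by construction.

Groove mouths are narrow voids and are therefore bridged at relatively
fine $\alpha$; wide grooves additionally pull the convex hull inward
(chords across the mouth), which can keep a shallowly grooved tube's
sample hull below the mesh volume. The monotone fold-depth ladder in
the acceptance tests therefore uses narrow grooves (width 0.6 rad),
where depth maps cleanly onto the crossing point.

The generator emulates topology and scale structure, not anatomy: no
real endocast's cross-sections, wall thickness variation, asymmetry, or
photogrammetric noise are modelled. Passing tests demonstrate that the
pipeline orders known geometric complexity correctly and separates
scales it was built to separate — not that it resolves every contrast
present in real specimens.

The comparative simulator (`simulate_tree_and_traits()`,
`make_cohort()`) draws pure-birth ultrametric trees, Brownian
predictors, and responses with known slopes and residual $\lambda$; the
default cohort mirrors a 40-specimen / 19-species study with
intraspecific replicates whose within-species jitter is kept below the
between-species spread.

## Multi-scale profiles and the morphospace

Profiles sample the characteristic curve at six log-equally spaced
coefficients (nearest grid points, no refitting). The package default
spans the full grid, $\{0.1, 1, 10, 100, 1000, 10^4\}$. At the sampling
density used here, $k = 0.1$ means $\alpha$ far below the minimum
Delaunay circumradius, so that column is structurally zero for every
specimen and carries no shape information; cohort-level ordinations
therefore sample the informative range $[1, 10^4]$ (configurable in
`run_config()` / `sample_profile()`). PCA inputs are scaled to zero
mean and unit variance; constant columns raise an error naming the
variable rather than silently dropping it.

On the scale-separation cohort (axis curvature crossed with texture
amplitude) the first component concentrates its squared loading mass on
the three coarsest sampled coefficients and the second on the three
finest — the acceptance suite asserts both masses above 60%.

## Problem sizes in the tests

The study-scale defaults (250k fill, 100k fit points) run in well under
a minute per specimen, but the suite works at desk scale so the whole
battery stays quick: geometry fixtures use 12k–20k fit points at mesh
resolutions of 64–72 angular vertices, the ladder and invariance checks
use 20k points, and the calibration studies use 500 replicates
(simulation-based p-values at $n_{\mathrm{sim}} = 199$ within each).
These sizes are the package's chosen trade-off between statistical
resolution and turnaround; the sampling-noise tolerances quoted in the
tests (e.g. 5% for rigid-motion invariance) reflect them.

## Known limitations

* Complexity has a floor of $10^{-4}$ (the coarse grid boundary) for
  convex or near-convex bodies; scores at the floor are ties and should
  be treated as "no measurable complexity", not compared further.
* The interior-sample hull underestimates the mesh volume by a
  density-dependent margin, so very shallow concavities (below roughly
  the hull deficit at the chosen point count) are indistinguishable
  from convex.
* Weighted alpha shapes, 2D analyses, and functional statistics over
  whole characteristic curves are out of scope, as are mesh repair and
  anatomical region segmentation of the heatmaps.
* $\lambda$ is constrained to $[0, 1]$; reference implementations that
  allow values outside this range can differ at the boundary.
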