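# alphamorph

Landmark-free quantification of 3D shape complexity for closed anatomical
surfaces, with phylogenetic comparative tests.

Many biological structures — vaginal lumina, bacula, endocasts of body
cavities — are too irregular to carry homologous landmarks, which rules
out classical geometric morphometrics. `alphamorph` instead measures how
hard a shape is to approximate with a family of alpha shapes: geometric
fits to a point set that range from a coarse convex hull down to tight
"shrink-wraps" as the alpha radius shrinks. A complex, invaginated
structure needs a very tight fit before the fitted volume matches the
true enclosed volume; a convex structure is matched by coarse fits.

## The method

For a watertight triangulated mesh:

1. The interior is filled with uniformly random points (rejection
   sampling in the bounding box, ≥ 250,000 accepted points) and
   down-sampled to 100,000 points.
2. A per-specimen reference length `l_ref` is computed as the mean
   distance of every point to its 100 nearest neighbours, and the alpha
   radius is scaled as `α = k · l_ref`, making the refinement
   coefficient `k` dimensionless and the analysis size-invariant.
3. Alpha shapes are fitted across 200 values of `k`, log-spaced on
   [0.1, 10,000] (a single Delaunay tetrahedralization is filtered by
   circumradius at every `k`), giving the **characteristic curve** of
   alpha-shape volume (as % of mesh volume) against `k`.
4. The **optimal k** is the refinement at which the alpha-shape volume
   equals the mesh volume, found by monotone bracketing and bisection,
   and **alpha complexity = 1 / optimal k** — higher values mean more
   complex shapes.
5. Per-vertex **complexity heatmaps**: each point is coloured by the
   coarsest `k` at which it appears on an alpha-shape boundary, painted
   onto the optimal fit (warm = resolved only by tight fits = complex).
6. **Morphospace**: alpha volumes sampled at six log-spaced `k` values
   per specimen enter ordinary and phylogenetic PCA.
7. **Comparative tests** (all re-implemented on plain linear algebra,
   with `ape` trees): Pagel's λ signal test, ML ancestral states, PGLS
   with a Pagel correlation structure, and simulation-based phylogenetic
   ANOVA / MANOVA.

A parametric generator of endocast-like tube meshes (invaginating folds,
helical twist, axis curvature, taper, band-limited surface texture) and
a simulator of trees and traits with known λ and slopes provide ground
truth for every stage.

## Worked example

```r
library(alphamorph)
mesh  <- make_tube(tube_spec(n_folds = 3, fold_depth = 0.6, fold_width = 0.6))
cloud <- fill_interior(mesh, n_min = 250000, seed = 1)
cloud <- downsample(cloud, 100000, seed = 2)
curve <- characteristic_curve(cloud, mesh)
optimal_refinement(curve)
#> complexity_result: optimal k 1.2387, alpha complexity 0.8073 (bisection)
```

The folded tube needs a tight fit (optimal k ≈ 1.24, complexity ≈ 0.81);
a sphere processed the same way never reaches its mesh volume before the
convex-hull limit and is flagged at the coarse boundary (complexity
10⁻⁴). The multi-scale profile shows where the complexity lives:

```r
sample_profile(curve, sampled_k_default(1, 10000, 6))$sampled_fractions
#> [1]  97.92 110.92 112.08 112.50 112.72 112.86
```

(the fold volume is bridged between k ≈ 1 and k ≈ 6; the plateau above
100% is the hull of a concave shape exceeding the mesh volume).

Comparative statistics on simulated ground truth:

```r
st <- simulate_tree_and_traits(n_species = 50, lambda = 0.8,
                               slopes = c(x1 = 0.5), resid_sd = 0.4, seed = 7)
d <- st$data; rownames(d) <- d$species
pgls(d, st$tree, "y", "x1")
#> PGLS: y ~ x1  (n = 50, lambda = 0.8671, logLik = -2.593)
#>    Predictor     Slope..SE    T     p
#>  (Intercept) 0.085 ± 0.195 0.44 0.665
#>           x1 0.566 ± 0.084 6.74 0.000
```

A command-line front end is installed with the package
(`system.file("exec/alphamorph", package = "alphamorph")`) with
`specimen`, `cohort`, and `synth` subcommands.

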