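test_that("alpha radius is k times the reference length, domain-checked", {
  expect_equal(alpha_radius(2, 0.5), 1.0)
  expect_equal(alpha_radius(0.1, 1), 0.1)
  expect_equal(alpha_radius(10000, 1), 10000)
  expect_error(alpha_radius(-1, 1), "positive")
  expect_error(alpha_radius(1, 0), "positive")
})

test_that("regular tetrahedron fit switches exactly at its circumradius", {
  pts <- make_primitive("regular_tetrahedron", 1)$vertices
  rc <- sqrt(3 / 8)
  fit_in <- fit_alpha_shape(pts, 0.7)
  expect_equal(fit_in$volume, sqrt(2) / 12, tolerance = 1e-12)
  expect_equal(nrow(fit_in$boundary_facets), 4)
  expect_equal(fit_alpha_shape(pts, 0.5)$volume, 0)
  # inclusive boundary convention: circumradius <= alpha keeps the cell
  expect_equal(fit_alpha_shape(pts, rc * (1 + 1e-9))$volume, sqrt(2) / 12,
               tolerance = 1e-12)
  expect_equal(fit_alpha_shape(pts, rc * (1 - 1e-9))$volume, 0)
})

test_that("degenerate coplanar clouds raise a geometry error", {
  pts <- cbind(runif(30), runif(30), 0)
  expect_error(alpha_complex(pts), "Delaunay|degenerate|coplanar")
})

test_that("large-alpha fit equals the convex hull of the cloud", {
  set.seed(21)
  pts <- matrix(runif(1500), ncol = 3)
  ac <- alpha_complex(pts)
  a_all <- max(ac$radius[is.finite(ac$radius)]) * 1.01
  fit <- fit_alpha_shape(ac, a_all)
  expect_equal(fit$volume, convex_hull_volume(pts), tolerance = 1e-9)
  # at alpha = 10 the fit is already within sliver-cell tolerance of it
  expect_equal(fit_alpha_shape(ac, 10)$volume, convex_hull_volume(pts),
               tolerance = 0.01)
})

test_that("kept tetrahedra match a first-principles circumradius filter", {
  set.seed(22)
  pts <- matrix(rnorm(3 * 40), ncol = 3)
  ac <- alpha_complex(pts)
  oracle_r <- brute_circumradii(pts, ac$tets)
  for (a in quantile(oracle_r, c(0.15, 0.5, 0.85)) * exp(runif(3, -0.01, 0.01))) {
    expect_identical(fit_alpha_shape(ac, a)$kept_tetrahedra,
                     which(oracle_r <= a))
  }
})

test_that("characteristic curve has the default grid and provenance", {
  tube <- fx("tube20k", tube_fixture)
  crv <- tube$curve
  expect_length(crv$k_grid, 200)
  expect_equal(range(crv$k_grid), c(0.1, 10000))
  expect_true(all(diff(crv$k_grid) > 0))
  expect_equal(crv$l_ref, reference_length(tube$cloud, 100),
               tolerance = 1e-12)
  # largest-k entry equals the hull fraction (convex-hull oracle)
  expect_equal(crv$volume_fractions[200],
               100 * convex_hull_volume(tube$cloud$points) / crv$mesh_volume,
               tolerance = 1e-9)
})

test_that("curve export round-trips through CSV", {
  tube <- fx("tube20k", tube_fixture)
  p <- file.path(withr::local_tempdir(), "curve.csv")
  write_curve(tube$curve, p)
  back <- read.csv(p)
  expect_identical(back$k, tube$curve$k_grid)
  expect_identical(back$volume_fraction, tube$curve$volume_fractions)
})

test_that("optimal refinement matches a dense-grid scan", {
  tube <- fx("tube20k", tube_fixture)
  opt <- tube$opt
  expect_true(opt$convergence$converged)
  # dense 2000-point scan oracle
  dense_k <- k_grid_default(n = 2000)
  dense_fr <- 100 * alphamorph:::alpha_volume_at(
    tube$complex, dense_k * tube$curve$l_ref) / tube$curve$mesh_volume
  k_oracle <- dense_k[which(dense_fr >= 100)[1]]
  # agreement to within one dense-grid step in log10 k
  expect_lt(abs(log10(opt$optimal_k) - log10(k_oracle)), 5 / 2000 + 1e-12)
  expect_identical(opt$alpha_complexity, 1 / opt$optimal_k)
})

test_that("a convex mesh is flagged out-of-range at the coarse boundary", {
  sph <- fx("sphere15k", sphere_fixture)
  expect_warning(optimal_refinement(sph$curve), "never reaches")
  expect_false(sph$opt$convergence$converged)
  expect_equal(sph$opt$optimal_k, 10000)
  expect_equal(sph$opt$alpha_complexity, 1e-4)
})

test_that("alpha volume is non-decreasing and fit volume consistent", {
  tube <- fx("tube20k", tube_fixture)
  fr <- tube$curve$volume_fractions
  expect_identical(fr, sort(fr))      # exact monotonicity
  a <- 2 * tube$curve$l_ref
  fit <- fit_alpha_shape(tube$complex, a)
  expect_equal(fit$volume, sum(tube$complex$volume[fit$kept_tetrahedra]),
               tolerance = 1e-9)
  # boundary facets belong to exactly one kept tetrahedron
  ac <- tube$complex
  on_b <- ac$face_r_lo <= a & ac$face_r_hi > a
  expect_identical(nrow(fit$boundary_facets), sum(on_b))
})

test_that("complexity result JSON is complete and numeric", {
  tube <- fx("tube20k", tube_fixture)
  p <- file.path(withr::local_tempdir(), "cx.json")
  write_complexity_json(tube$opt, p, id = "tube", seed = 101)
  j <- jsonlite::read_json(p)
  expect_equal(j$alpha_complexity, tube$opt$alpha_complexity)
  expect_equal(j$optimal_k, tube$opt$optimal_k)
  expect_equal(j$specimen, "tube")
})
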