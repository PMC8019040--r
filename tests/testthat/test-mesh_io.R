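test_that("analytic primitive volumes are recovered", {
  expect_equal(mesh_volume(make_primitive("cube", 2)), 8, tolerance = 1e-12)
  sph <- make_primitive("sphere", 2, 3)
  expect_equal(mesh_volume(sph), 4 / 3 * pi * 8, tolerance = 0.01)
  tor <- make_primitive("torus", c(2, 0.5), 64)
  expect_equal(mesh_volume(tor), 2 * pi^2 * 2 * 0.25, tolerance = 0.01)
  tet <- make_primitive("regular_tetrahedron", 1)
  expect_equal(mesh_volume(tet), sqrt(2) / 12, tolerance = 1e-12)
})

test_that("mesh volume is invariant to rigid motion and cubic in scale", {
  mesh <- make_tube(tube_spec(n_folds = 2, fold_depth = 0.4,
                              n_theta = 32, n_z = 48))
  v0 <- mesh_volume(mesh)
  expect_equal(mesh_volume(translate_mesh(mesh, c(11, -4, 3.7))), v0,
               tolerance = 1e-9)
  expect_equal(mesh_volume(rotate_mesh(mesh, random_rotation(4))), v0,
               tolerance = 1e-9)
  expect_equal(mesh_volume(scale_mesh(mesh, 10)), 1000 * v0,
               tolerance = 1e-9)
})

test_that("validation rejects open meshes, naming boundary edges", {
  cube <- make_primitive("cube", 1)
  open_faces <- cube$faces[-1, ]
  expect_error(surface_mesh(cube$vertices, open_faces), "not watertight")
  expect_error(surface_mesh(cube$vertices, open_faces), "edge")
  # volume-dependent operations refuse such input at construction
  expect_error(surface_mesh(cube$vertices, cube$faces[c(1:12, 3), ]),
               "winding|watertight")
})

test_that("validation rejects degenerate faces and bad indices", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.5, 0.5, 0))
  expect_error(surface_mesh(v, rbind(c(1, 2, 2), c(1, 2, 3), c(1, 3, 2))),
               "degenerate|watertight")
  cube <- make_primitive("cube", 1)
  f <- cube$faces
  f[1, 1] <- 99L
  expect_error(surface_mesh(cube$vertices, f), "out of range")
})

test_that("orientation is normalized so enclosed volume is positive", {
  cube <- make_primitive("cube", 2)
  flipped <- surface_mesh(cube$vertices, cube$faces[, c(1, 3, 2)])
  expect_equal(mesh_volume(flipped), 8, tolerance = 1e-12)
  expect_gt(alphamorph:::signed_volume(flipped$vertices, flipped$faces), 0)
})

test_that("PLY, OBJ round-trips preserve geometry (ascii and binary)", {
  sph <- make_primitive("sphere", 1.5, 2)
  td <- withr::local_tempdir()
  for (cfg in list(list(f = "ply", b = FALSE), list(f = "ply", b = TRUE),
                   list(f = "obj", b = FALSE))) {
    p <- file.path(td, paste0("m_", cfg$f, cfg$b, ".", cfg$f))
    write_mesh(sph, p, format = cfg$f, binary = cfg$b)
    back <- read_mesh(p)
    expect_equal(back$vertices, sph$vertices, ignore_attr = TRUE,
                 tolerance = 1e-12)
    expect_equal(mesh_volume(back), mesh_volume(sph), tolerance = 1e-12)
  }
})

test_that("icosphere OBJ at subdivision 3 reads back with 642 vertices", {
  # vertex count follows the subdivision recurrence 10 * 4^n + 2
  sph <- make_primitive("sphere", 1, 3)
  p <- file.path(withr::local_tempdir(), "ico.obj")
  write_mesh(sph, p, format = "obj")
  expect_equal(nrow(read_mesh(p)$vertices), 642)
})

test_that("ascii STL soup is merged into a watertight mesh", {
  tet <- make_primitive("regular_tetrahedron", 1)
  p <- file.path(withr::local_tempdir(), "t.stl")
  v <- tet$vertices
  con <- file(p, "w")
  writeLines("solid t", con)
  for (i in seq_len(nrow(tet$faces))) {
    writeLines(c(" facet normal 0 0 0", "  outer loop",
                 sprintf("   vertex %.17g %.17g %.17g",
                         v[tet$faces[i, ], 1], v[tet$faces[i, ], 2],
                         v[tet$faces[i, ], 3]),
                 "  endloop", " endfacet"), con)
  }
  writeLines("endsolid t", con)
  close(con)
  back <- read_mesh(p)
  expect_equal(nrow(back$vertices), 4)
  expect_equal(mesh_volume(back), sqrt(2) / 12, tolerance = 1e-12)
})

test_that("heatmap mesh export writes colors and bit-exact sidecars", {
  df <- fx("deepfold20k", deepfold_fixture)
  hm <- heatmap_of(df)$hm
  td <- withr::local_tempdir()
  p <- file.path(td, "hm.ply")
  paths <- write_heatmap_mesh(hm, p)
  vk <- read.csv(paths$vertex_csv)
  expect_identical(vk$coarsest_k, hm$vertex_k)    # bit-exact round trip
  fk <- read.csv(paths$face_csv)
  expect_identical(fk$face_k, hm$face_k)
  ply <- readLines(p)
  expect_true(any(grepl("property uchar red", ply)))
  # extreme values carry the extreme warm/cool colors
  cols <- alphamorph:::k_to_color(c(0.1, 10000), hm$k_grid)
  expect_gt(cols[1, 1], cols[1, 3])   # low k: red dominant (warm)
  expect_gt(cols[2, 3], cols[2, 1])   # high k: blue dominant (cool)
})

test_that("xyz point-cloud round trip is exact", {
  set.seed(5)
  pts <- matrix(rnorm(90), ncol = 3)
  p <- file.path(withr::local_tempdir(), "c.xyz")
  write_xyz(pts, p)
  expect_equal(read_xyz(p), pts, ignore_attr = TRUE, tolerance = 1e-15)
})
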