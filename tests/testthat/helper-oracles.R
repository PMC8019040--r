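# Independent oracles and shared fixtures. Oracles are deliberately naive
# (O(n^2) scans, per-element solves, generalized winding numbers) and never
# share code with the implementation paths they check.

fixture_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(fixture_cache[[name]])) fixture_cache[[name]] <- builder()
  fixture_cache[[name]]
}

# Generalized winding number containment (van Oosterom & Strackee solid
# angles): inside iff the summed solid angle is ~ 4*pi.
winding_inside <- function(mesh, pts) {
  v <- mesh$vertices
  f <- mesh$faces
  vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    a <- v[f[, 1], , drop = FALSE] - rep(p, each = nrow(f))
    b <- v[f[, 2], , drop = FALSE] - rep(p, each = nrow(f))
    cc <- v[f[, 3], , drop = FALSE] - rep(p, each = nrow(f))
    la <- sqrt(rowSums(a^2)); lb <- sqrt(rowSums(b^2)); lc <- sqrt(rowSums(cc^2))
    num <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
           a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
           a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
    den <- la * lb * lc + rowSums(a * b) * lc + rowSums(b * cc) * la +
           rowSums(cc * a) * lb
    abs(sum(2 * atan2(num, den))) > 2 * pi
  }, TRUE)
}

# Exhaustive nearest-neighbour reference length.
brute_lref <- function(pts, n_neighbors) {
  d <- as.matrix(dist(pts))
  mean(vapply(seq_len(nrow(d)), function(i)
    mean(sort(d[i, -i])[seq_len(n_neighbors)]), 0))
}

# Circumradius of each tetrahedron from first principles: solve the
# circumcentre linear system per tetrahedron.
brute_circumradii <- function(points, tets) {
  vapply(seq_len(nrow(tets)), function(i) {
    p <- points[tets[i, ], , drop = FALSE]
    A <- 2 * sweep(p[2:4, , drop = FALSE], 2, p[1, ])
    rhs <- rowSums(p[2:4, , drop = FALSE]^2) - sum(p[1, ]^2)
    ctr <- tryCatch(solve(A, rhs), error = function(e) rep(Inf, 3))
    sqrt(sum((ctr - p[1, ])^2))
  }, 0)
}

# Small deterministic interior-cloud pipeline used by many fixtures.
cloud_for <- function(mesh, n_fill, n_down, seed) {
  downsample(fill_interior(mesh, n_min = n_fill, seed = seed),
             n_target = n_down, seed = seed + 1)
}

specimen_fixture <- function(name, mesh, n_fill, n_down, seed) {
  fx(name, function() {
    cl <- cloud_for(mesh, n_fill, n_down, seed)
    ac <- alpha_complex(cl)
    crv <- characteristic_curve(cl, mesh, complex = ac)
    cl$l_ref <- crv$l_ref
    opt <- suppressWarnings(optimal_refinement(crv))
    list(mesh = mesh, cloud = cl, complex = ac, curve = crv, opt = opt)
  })
}

tube_fixture <- function() {
  specimen_fixture("tube20k",
                   make_tube(tube_spec(n_folds = 3, fold_depth = 0.5,
                                       fold_width = 0.6, n_theta = 64,
                                       n_z = 128)),
                   40000, 20000, seed = 101)
}

sphere_fixture <- function() {
  specimen_fixture("sphere15k", make_primitive("sphere", 2, 3),
                   30000, 15000, seed = 202)
}

deepfold_fixture <- function() {
  specimen_fixture("deepfold20k",
                   make_tube(tube_spec(n_folds = 4, fold_depth = 0.7,
                                       n_theta = 72, n_z = 144)),
                   40000, 20000, seed = 303)
}

# Fold-depth complexity ladder (shared between property and acceptance
# tests).
ladder_fixture <- function() {
  fx("ladder", function() {
    depths <- c(0, 0.2, 0.4, 0.6, 0.8)
    vapply(seq_along(depths), function(i) {
      mesh <- make_tube(tube_spec(n_folds = 3, fold_depth = depths[i],
                                  fold_width = 0.6, n_theta = 64, n_z = 128))
      cl <- cloud_for(mesh, 40000, 20000, seed = 400 + 7 * i)
      crv <- characteristic_curve(cl, mesh)
      suppressWarnings(optimal_refinement(crv))$alpha_complexity
    }, 0)
  })
}

# 4 x 4 cohort crossing gross axis curvature with fine surface texture.
scale_cohort_fixture <- function(master = 5150) {
  fx("scale_cohort", function() {
    grid <- expand.grid(bend = c(0.3, 1.0, 1.7, 2.4),
                        noise = c(0, 0.015, 0.03, 0.045))
    sk <- sampled_k_default(1, 10000, 6)
    profs <- lapply(seq_len(nrow(grid)), function(i) {
      mesh <- make_tube(tube_spec(n_folds = 2, fold_depth = 0.3,
                                  bend_angle = grid$bend[i],
                                  noise_amp = grid$noise[i],
                                  n_theta = 72, n_z = 144,
                                  seed = derive_seed(master, paste0("shape", i))))
      cl <- cloud_for(mesh, 25000, 12000,
                      seed = derive_seed(master, paste0("cloud", i)))
      sample_profile(characteristic_curve(cl, mesh), sk, id = paste0("s", i))
    })
    list(grid = grid, profiles = profs, matrix = profile_matrix(profs))
  })
}

# Heatmap of a specimen fixture at its optimal refinement.
heatmap_of <- function(fxt) {
  ac <- fxt$complex
  co <- coarsest_contribution(fxt$cloud, complex = ac)
  fit <- fit_alpha_shape(ac, fxt$opt$optimal_k * fxt$curve$l_ref,
                         k = fxt$opt$optimal_k)
  list(hm = build_heatmap(fit, co), coarsest = co)
}
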