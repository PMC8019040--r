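#' Analytic benchmark primitives
#'
#' Watertight meshes with known analytic volumes, used as oracles for the
#' volume and alpha-shape machinery: axis-aligned cube, icosphere, torus,
#' and regular tetrahedron.
#'
#' @param kind one of `"sphere"`, `"cube"`, `"torus"`,
#'   `"regular_tetrahedron"`.
#' @param size for the sphere the radius; for the cube the edge length;
#'   for the tetrahedron the edge length; for the torus a length-2 vector
#'   `c(R, r)` (ring radius, tube radius).
#' @param resolution sphere: icosphere subdivision level (vertex count
#'   `10 * 4^level + 2`); torus: number of segments around each circle.
#' @return a validated `surface_mesh`.
#' @export
make_primitive <- function(kind = c("sphere", "cube", "torus",
                                    "regular_tetrahedron"),
                           size = 1, resolution = 3) {
  kind <- match.arg(kind)
  raw <- switch(kind,
    cube = {
      a <- size / 2
      v <- as.matrix(expand.grid(x = c(-a, a), y = c(-a, a), z = c(-a, a)))
      # vertices ordered (x fastest): consistent outward triangulation
      f <- rbind(c(1, 3, 4), c(1, 4, 2),   # z = -a
                 c(5, 6, 8), c(5, 8, 7),   # z = +a
                 c(1, 2, 6), c(1, 6, 5),   # y = -a
                 c(3, 7, 8), c(3, 8, 4),   # y = +a
                 c(1, 5, 7), c(1, 7, 3),   # x = -a
                 c(2, 4, 8), c(2, 8, 6))   # x = +a
      list(vertices = v, faces = f)
    },
    sphere = icosphere(size, resolution),
    torus = torus_mesh(size[1], size[2], resolution),
    regular_tetrahedron = {
      v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) *
        (size / (2 * sqrt(2)))
      f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
      list(vertices = v, faces = f)
    })
  surface_mesh(raw$vertices, raw$faces)
}

icosphere <- function(radius = 1, subdiv = 3) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env(parent = emptyenv())
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      got <- mid_cache[[key]]
      if (!is.null(got)) return(got)
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1]] <<- m
      id <- nv + length(newv)
      mid_cache[[key]] <- id
      id
    }
    newf <- matrix(0L, nrow(f) * 4, 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[(4 * k - 3):(4 * k), ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                           c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  list(vertices = v * radius, faces = f)
}

torus_mesh <- function(R = 2, r = 0.5, resolution = 48) {
  nu <- resolution       # around the ring
  nv <- max(12, resolution %/% 2)  # around the tube
  iu <- rep(0:(nu - 1), each = nv)
  iv <- rep(0:(nv - 1), times = nu)
  u <- 2 * pi * iu / nu
  vv <- 2 * pi * iv / nv
  verts <- cbind((R + r * cos(vv)) * cos(u),
                 (R + r * cos(vv)) * sin(u),
                 r * sin(vv))
  idx <- function(i, j) ((i %% nu) * nv + (j %% nv)) + 1L
  i <- rep(0:(nu - 1), each = nv)
  j <- rep(0:(nv - 1), times = nu)
  f <- rbind(cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
             cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  list(vertices = verts, faces = f)
}

#' Specification for a parametric tube-like benchmark mesh
#'
#' Describes an endocast-like closed tube whose wall can carry
#' invaginations (longitudinal grooves), helical twist of the groove loci,
#' linear taper, and band-limited fine surface texture. The cross-section
#' radius is `r(theta, z) = R(z) * (1 - sum_i d_i * bump(theta - theta_i -
#' phi * z)) + noise(theta, z)` with `R(z)` the (possibly tapering) base
#' radius and `bump` a raised-cosine dent of compact angular support, so
#' the mesh stays watertight at every depth below 1.
#'
#' @param length axial length of the tube.
#' @param radius base cross-section radius.
#' @param taper fractional radius reduction from base to tip in `[0, 0.9]`.
#' @param n_folds number of wall invaginations (grooves).
#' @param fold_depth groove depth as a fraction of the radius in
#'   `[0, 0.9]`.
#' @param fold_width angular extent of each groove (radians); defaults to
#'   the widest non-overlapping value.
#' @param spiral_turns helical turns of the groove loci over the tube
#'   length.
#' @param bend_angle total turn of the tube axis (radians) along a
#'   circular arc: gross whole-structure concavity whose hull void is
#'   only bridged by coarse alpha fits. Must keep the bend radius above
#'   the tube radius (no self-intersection).
#' @param noise_amp RMS amplitude of the fine surface texture, as a
#'   fraction of the radius.
#' @param noise_waves number of random texture harmonics.
#' @param noise_band_theta,noise_band_z inclusive integer wavenumber
#'   bands of the texture harmonics (angular / axial); the defaults sit
#'   well above the fold scales so texture and gross form are separable.
#' @param n_theta,n_z angular and axial vertex resolution.
#' @param seed seed for the texture phases.
#' @return an object of class `tube_spec`.
#' @export
tube_spec <- function(length = 10, radius = 2, taper = 0, n_folds = 0,
                      fold_depth = 0, fold_width = NULL, spiral_turns = 0,
                      bend_angle = 0, noise_amp = 0, noise_waves = 6,
                      noise_band_theta = c(16L, 32L),
                      noise_band_z = c(10L, 24L),
                      n_theta = 128, n_z = 256, seed = 1L) {
  if (fold_depth < 0 || fold_depth >= 1)
    stop("fold_depth must lie in [0, 1): depth >= 1 self-intersects the axis")
  if (taper < 0 || taper > 0.9) stop("taper must lie in [0, 0.9]")
  if (bend_angle < 0 || (bend_angle > 0 && length / bend_angle <= radius))
    stop("bend_angle too large: bend radius must exceed the tube radius")
  if (is.null(fold_width))
    fold_width <- if (n_folds > 0) min(pi / 2, 0.9 * 2 * pi / n_folds) else pi / 2
  structure(list(length = length, radius = radius, taper = taper,
                 n_folds = n_folds, fold_depth = fold_depth,
                 fold_width = fold_width, spiral_turns = spiral_turns,
                 bend_angle = bend_angle,
                 noise_amp = noise_amp, noise_waves = noise_waves,
                 noise_band_theta = as.integer(noise_band_theta),
                 noise_band_z = as.integer(noise_band_z),
                 n_theta = as.integer(n_theta), n_z = as.integer(n_z),
                 seed = as.integer(seed)),
            class = "tube_spec")
}

#' Generate a parametric tube-like benchmark mesh
#'
#' Builds the closed surface described by a [tube_spec()]: ring vertices
#' on an `n_theta` x `(n_z + 1)` grid, quad sides split into triangles,
#' and triangle-fan end caps (the radius is strictly positive, so each cap
#' polygon is star-shaped about its centre). Deterministic per seed; the
#' groove-free, texture-free tube has the analytic volume
#' [tube_volume_analytic()].
#'
#' @param spec a `tube_spec`.
#' @return a validated `surface_mesh`.
#' @export
make_tube <- function(spec) {
  stopifnot(inherits(spec, "tube_spec"))
  nt <- spec$n_theta
  nz <- spec$n_z
  theta <- 2 * pi * (0:(nt - 1)) / nt
  z <- spec$length * (0:nz) / nz
  TH <- matrix(theta, nt, nz + 1)
  ZZ <- matrix(z, nt, nz + 1, byrow = TRUE)

  Rz <- spec$radius * (1 - spec$taper * ZZ / spec$length)
  dent <- matrix(0, nt, nz + 1)
  if (spec$n_folds > 0 && spec$fold_depth > 0) {
    phi <- 2 * pi * spec$spiral_turns / spec$length
    half <- spec$fold_width / 2
    for (i in seq_len(spec$n_folds)) {
      ctr <- 2 * pi * (i - 1) / spec$n_folds
      d <- (TH - ctr - phi * ZZ) %% (2 * pi)
      d <- pmin(d, 2 * pi - d)          # wrapped angular distance
      b <- ifelse(d <= half, 0.5 * (1 + cos(pi * d / half)), 0)
      dent <- dent + spec$fold_depth * b
    }
  }
  r <- Rz * (1 - dent)
  if (spec$noise_amp > 0) {
    bt <- spec$noise_band_theta
    bz <- spec$noise_band_z
    field <- with_seed(spec$seed, {
      p <- sample(bt[1]:bt[2], spec$noise_waves, replace = TRUE)  # angular
      q <- sample(bz[1]:bz[2], spec$noise_waves, replace = TRUE)  # axial
      ph <- runif(spec$noise_waves, 0, 2 * pi)
      out <- matrix(0, nt, nz + 1)
      for (m in seq_len(spec$noise_waves))
        out <- out + cos(p[m] * TH + q[m] * 2 * pi * ZZ / spec$length + ph[m])
      out / sqrt(spec$noise_waves / 2)   # unit RMS
    })
    r <- r + spec$noise_amp * spec$radius * field
  }
  if (any(r <= 0))
    stop("tube radius collapses to zero: reduce fold_depth or noise_amp")

  verts <- cbind(as.vector(r * cos(TH)), as.vector(r * sin(TH)), as.vector(ZZ))
  verts <- rbind(verts, c(0, 0, 0), c(0, 0, spec$length))
  if (spec$bend_angle > 0) {
    # wrap the straight tube onto a circular arc in the xz-plane
    rho <- spec$length / spec$bend_angle
    phi <- verts[, 3] / rho
    verts <- cbind(rho - (rho - verts[, 1]) * cos(phi),
                   verts[, 2],
                   (rho - verts[, 1]) * sin(phi))
  }
  c_bot <- nt * (nz + 1) + 1L
  c_top <- c_bot + 1L
  idx <- function(i, j) (j * nt + (i %% nt)) + 1L  # i angular 0-based, j ring

  i <- rep(0:(nt - 1), times = nz)
  j <- rep(0:(nz - 1), each = nt)
  side <- rbind(cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  i0 <- 0:(nt - 1)
  cap_bot <- cbind(rep(c_bot, nt), idx(i0 + 1, 0), idx(i0, 0))
  cap_top <- cbind(rep(c_top, nt), idx(i0, nz), idx(i0 + 1, nz))
  surface_mesh(verts, rbind(side, cap_bot, cap_top))
}

#' Analytic volume of the groove-free, texture-free tube
#'
#' `pi * integral of R(z)^2 dz` for the linearly tapering base radius; the
#' discrete mesh converges to this as the angular resolution grows (the
#' inscribed-polygon factor is `(n/2pi) * sin(2pi/n)`).
#'
#' @param spec a `tube_spec` (folds and noise are ignored).
#' @param polygon_corrected multiply by the inscribed-polygon area factor
#'   for the spec's angular resolution, giving the exact mesh volume.
#' @return volume (length units cubed).
#' @export
tube_volume_analytic <- function(spec, polygon_corrected = FALSE) {
  tpr <- spec$taper
  v <- pi * spec$radius^2 * spec$length * (1 - tpr + tpr^2 / 3)
  if (polygon_corrected) {
    n <- spec$n_theta
    v <- v * (n / (2 * pi)) * sin(2 * pi / n)
  }
  v
}

#' Simulate a phylogeny and comparative trait data with known parameters
#'
#' A pure-birth ultrametric tree plus traits simulated under Brownian
#' motion: predictors are BM with unit rate, the response is the linear
#' combination of predictors plus a residual whose covariance follows the
#' Pagel lambda transform with known `lambda`. Used to check that the
#' comparative re-implementations recover the generating parameters.
#'
#' @param n_species number of tips (>= 4).
#' @param birth speciation rate of the pure-birth tree.
#' @param lambda true Pagel's lambda of the residual in `[0, 1]`.
#' @param slopes named numeric vector of regression slopes; one BM
#'   predictor is simulated per entry (empty for a signal-only trait).
#' @param resid_sd residual Brownian rate (SD scale at unit depth).
#' @param seed integer seed.
#' @return list with `tree` (an `ape::phylo`) and `data` (data.frame with
#'   `species`, `y`, and one column per predictor).
#' @export
simulate_tree_and_traits <- function(n_species = 50, birth = 1, lambda = 1,
                                     slopes = c(), resid_sd = 1, seed = 1L) {
  stopifnot(n_species >= 4, lambda >= 0, lambda <= 1)
  with_seed(seed, {
    tree <- ape::rphylo(n_species, birth = birth, death = 0)
    tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
    C <- ape::vcv.phylo(tree)
    C <- C / max(diag(C))              # unit tree depth
    Lc <- chol(C)
    preds <- NULL
    y <- rep(0, n_species)
    if (length(slopes)) {
      preds <- sapply(seq_along(slopes), function(i)
        drop(crossprod(Lc, rnorm(n_species))))
      colnames(preds) <- names(slopes) %||% paste0("x", seq_along(slopes))
      y <- drop(preds %*% slopes)
    }
    V <- pagel_transform(C, lambda)
    y <- y + resid_sd * drop(crossprod(chol(V), rnorm(n_species)))
    d <- data.frame(species = tree$tip.label, y = y)
    if (!is.null(preds)) d <- cbind(d, as.data.frame(preds))
    rownames(d) <- NULL
    list(tree = tree, data = d)
  })
}

#' Generate a full synthetic cohort: meshes, tree, and trait table
#'
#' Emulates the structure of a marine-mammal endocast study: several
#' species with intraspecific replicates (default 19 species / 40
#' specimens split 14 cetacean-like species with 32 specimens, 4
#' pinniped-like with 7, and 1 sirenian-like with 1), per-species groove
#' depth and surface texture with within-species jitter smaller than the
#' between-species spread, a pure-birth ultrametric tree, and a trait
#' table with body-size, testes-mass, dimorphism, and penis-tip columns.
#'
#' @param n_species number of species.
#' @param n_specimens total specimens across species.
#' @param resolution `c(n_theta, n_z)` mesh resolution for all specimens.
#' @param within_sd within-species jitter SD on the complexity knobs, as a
#'   fraction of the knob value (kept well below the between-species
#'   spread).
#' @param seed master seed.
#' @param make_meshes generate the meshes (set `FALSE` to get only specs).
#' @return list with `specs` (per-specimen `tube_spec`s), `meshes` (or
#'   `NULL`), `manifest` (data.frame specimen/species/group), `tree`, and
#'   `traits` (species-level data.frame matching the comparative schema).
#' @export
make_cohort <- function(n_species = 19, n_specimens = 40,
                        resolution = c(128, 256), within_sd = 0.08,
                        seed = 1L, make_meshes = TRUE) {
  stopifnot(n_specimens >= n_species, n_species >= 4)
  with_seed(seed, {
    # group structure: ~74% of species cetacean-like, a pinniped-like
    # block, and one sirenian-like species (paper-scale default 14/4/1)
    n_cet <- max(2, round(0.74 * n_species))
    n_pin <- max(1, n_species - n_cet - 1)
    n_cet <- n_species - n_pin - 1
    group <- c(rep("cetacean", n_cet), rep("pinniped", n_pin), "sirenian")
    species <- sprintf("sp%03d", seq_len(n_species))

    # specimens per species: fill extras into the cetacean block first
    n_each <- rep(1L, n_species)
    extra <- n_specimens - n_species
    k <- 0
    while (extra > 0) {
      i <- (k %% n_cet) + 1
      n_each[i] <- n_each[i] + 1L
      extra <- extra - 1
      k <- k + 1
    }

    # species-level complexity knobs: cetaceans span the range, pinnipeds
    # simple, the sirenian complex
    depth_sp <- numeric(n_species)
    depth_sp[group == "cetacean"] <- seq(0.1, 0.8, length.out = n_cet)
    depth_sp[group == "pinniped"] <- runif(n_pin, 0.02, 0.12)
    depth_sp[group == "sirenian"] <- 0.65
    noise_sp <- runif(n_species, 0.005, 0.03)
    folds_sp <- ifelse(group == "pinniped", 1L, sample(1:4, n_species, TRUE))
    spiral_sp <- ifelse(group == "cetacean" & runif(n_species) < 0.3,
                        sample(1:3, n_species, TRUE), 0)
    tips <- sample(c("filiform", "tapered", "blunt-end"), n_species, TRUE)

    manifest <- data.frame(
      specimen = sprintf("%s_ind%02d", rep(species, n_each),
                         unlist(lapply(n_each, seq_len))),
      species = rep(species, n_each),
      group = rep(group, n_each),
      stringsAsFactors = FALSE)

    specs <- vector("list", n_specimens)
    for (s in seq_len(n_specimens)) {
      sp_i <- match(manifest$species[s], species)
      jit <- function(x, lo, hi)
        min(hi, max(lo, x * (1 + rnorm(1, 0, within_sd))))
      specs[[s]] <- tube_spec(
        length = 10, radius = 2,
        taper = 0.2,
        n_folds = folds_sp[sp_i],
        fold_depth = jit(depth_sp[sp_i], 0.01, 0.88),
        spiral_turns = spiral_sp[sp_i],
        noise_amp = jit(noise_sp[sp_i], 0.001, 0.05),
        n_theta = resolution[1], n_z = resolution[2],
        seed = derive_seed(seed, manifest$specimen[s]))
    }

    tree <- ape::rphylo(n_species, birth = 1, death = 0)
    tree$tip.label <- species
    C <- ape::vcv.phylo(tree)
    C <- C / max(diag(C))
    Lc <- chol(C)
    bm <- function(sdev) drop(crossprod(Lc, rnorm(n_species))) * sdev
    mother_length <- exp(1 + bm(0.3))
    traits <- data.frame(
      species = species,
      neonate_length = mother_length * exp(-1.2 + bm(0.15)),
      mother_length = mother_length,
      testes_mass = exp(0.5 + bm(0.5)),
      male_body_mass = exp(4 + bm(0.4)),
      ssd = exp(bm(0.1)),
      penis_tip = tips,
      stringsAsFactors = FALSE)

    meshes <- NULL
    if (make_meshes) meshes <- lapply(specs, make_tube)
    list(specs = specs, meshes = meshes, manifest = manifest,
         tree = tree, traits = traits)
  })
}
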