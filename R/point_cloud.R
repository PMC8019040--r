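#' Test whether points lie inside a watertight mesh
#'
#' Containment by ray casting: a point is inside iff a ray from it crosses
#' the surface an odd number of times. Rays that graze an edge, vertex, or
#' near-parallel triangle are re-cast with fresh random directions until a
#' clean crossing count is obtained, so the test is robust on the
#' degenerate configurations that arise with axis-aligned meshes.
#'
#' @param mesh a validated `surface_mesh`.
#' @param points a single 3D coordinate or an n x 3 matrix.
#' @param seed seed for the fallback ray directions (results are
#'   deterministic given the seed; generic points never consult it).
#' @return logical vector, one flag per query point.
#' @export
in_polyhedron <- function(mesh, points, seed = 1L) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  dirs <- with_seed(seed, {
    d <- matrix(rnorm(3 * 64), ncol = 3)
    d / sqrt(rowSums(d^2))
  })
  cpp_points_in_mesh(mesh$vertices, mesh$faces, points, dirs)
}

#' Fill a mesh interior with uniform random points
#'
#' Rejection sampling in the axis-aligned bounding box: candidate points
#' are drawn uniformly and kept iff they pass [in_polyhedron()], until at
#' least `n_min` points have accumulated (default 250,000). Deterministic
#' given the seed.
#'
#' @param mesh a watertight `surface_mesh` with positive volume.
#' @param n_min minimum number of accepted interior points.
#' @param seed integer seed.
#' @param batch candidate batch size (does not affect the result).
#' @return an `interior_cloud` with fields `points`, `n_raw`, `seed`,
#'   `bbox`, `acceptance_rate`, `source`.
#' @export
fill_interior <- function(mesh, n_min = 250000, seed = 1L, batch = 65536L) {
  stopifnot(inherits(mesh, "surface_mesh"), n_min >= 1)
  bb <- apply(mesh$vertices, 2, range)
  span <- bb[2, ] - bb[1, ]
  acc <- vector("list", 0)
  n_acc <- 0
  n_try <- 0
  with_seed(seed, {
    while (n_acc < n_min) {
      cand <- cbind(runif(batch, bb[1, 1], bb[2, 1]),
                    runif(batch, bb[1, 2], bb[2, 2]),
                    runif(batch, bb[1, 3], bb[2, 3]))
      keep <- in_polyhedron(mesh, cand, seed = seed)
      acc[[length(acc) + 1]] <- cand[keep, , drop = FALSE]
      n_acc <- n_acc + sum(keep)
      n_try <- n_try + batch
      if (n_try >= 10 * batch && n_acc / n_try < 1e-4)
        stop("interior fill acceptance rate below 1e-4 (", n_acc, "/", n_try,
             "): mesh is pathologically thin relative to its bounding box")
    }
  })
  pts <- do.call(rbind, acc)
  structure(list(points = pts, n_raw = nrow(pts), n_down = nrow(pts),
                 seed = seed, bbox = bb,
                 acceptance_rate = n_acc / n_try,
                 source = attr(mesh, "id") %||% "mesh"),
            class = "interior_cloud")
}

#' Down-sample an interior point cloud
#'
#' Uniform random subset without replacement, taken before alpha-shape
#' fitting (default 100,000 points). Deterministic given the seed.
#'
#' @param cloud an `interior_cloud`.
#' @param n_target points to keep.
#' @param seed integer seed.
#' @return the down-sampled `interior_cloud`.
#' @export
downsample <- function(cloud, n_target = 100000, seed = 1L) {
  stopifnot(inherits(cloud, "interior_cloud"))
  n <- nrow(cloud$points)
  if (n_target < 1 || n_target > n)
    stop("n_target must be in [1, ", n, "], got ", n_target)
  idx <- if (n_target == n) seq_len(n) else
    with_seed(seed, sample.int(n, n_target))
  cloud$points <- cloud$points[idx, , drop = FALSE]
  cloud$n_down <- n_target
  cloud$l_ref <- NULL
  cloud$family <- NULL
  cloud
}

#' Point-cloud reference length
#'
#' For each point, the mean Euclidean distance to its `n_neighbors`
#' nearest neighbours (excluding itself); the reference length is the
#' grand mean of those per-point means. It scales linearly with the cloud
#' and makes the refinement coefficient k dimensionless via
#' alpha = k * l_ref.
#'
#' @param cloud an `interior_cloud` or an n x 3 matrix.
#' @param n_neighbors neighbour count (default 100).
#' @return the reference length (scalar, length units).
#' @export
reference_length <- function(cloud, n_neighbors = 100) {
  pts <- if (inherits(cloud, "interior_cloud")) cloud$points else as.matrix(cloud)
  if (nrow(pts) <= n_neighbors)
    stop("need more than ", n_neighbors, " points, got ", nrow(pts))
  nn <- RANN::nn2(pts, pts, k = n_neighbors + 1)
  mean(rowMeans(nn$nn.dists[, -1, drop = FALSE]))
}

# Attach l_ref (and keep it cached on the cloud object).
ensure_l_ref <- function(cloud, n_neighbors = 100) {
  if (is.null(cloud$l_ref))
    cloud$l_ref <- reference_length(cloud, n_neighbors)
  cloud
}

#' @export
print.interior_cloud <- function(x, ...) {
  cat(sprintf("interior_cloud: %d points (raw %d), seed %d%s\n",
              nrow(x$points), x$n_raw, x$seed,
              if (!is.null(x$l_ref)) sprintf(", l_ref %.6g", x$l_ref) else ""))
  invisible(x)
}
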