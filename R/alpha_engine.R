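## Alpha-shape machinery. The alpha complex of a point cloud is the set of
## Delaunay tetrahedra with circumradius <= alpha; its volume as a function
## of the refinement coefficient k (alpha = k * l_ref) is the
## characteristic curve, and the k at which that volume matches the source
## mesh volume defines the complexity score 1/k.

# Python bridge: Qhull via scipy.spatial for the Delaunay tetrahedralization
# and the independent convex-hull volume. Imported once per session.
get_scipy_spatial <- function() {
  if (is.null(.alphamorph_state$scipy_spatial)) {
    if (!reticulate::py_available(initialize = FALSE)) {
      py <- Sys.which("python")
      if (nzchar(py))
        try(reticulate::use_python(py, required = TRUE), silent = TRUE)
    }
    .alphamorph_state$scipy_spatial <- reticulate::import("scipy.spatial")
  }
  .alphamorph_state$scipy_spatial
}

# Delaunay tetrahedralization (1-based vertex-index rows).
delaunay_tetrahedra <- function(points) {
  stopifnot(ncol(points) == 3, nrow(points) >= 4)
  sp <- get_scipy_spatial()
  tets <- sp$Delaunay(points)$simplices
  storage.mode(tets) <- "integer"
  tets + 1L
}

#' Convex-hull volume of a point cloud
#'
#' Qhull's convex-hull volume, used as the coarse (k to infinity) limit of
#' the alpha-shape family and as an independent check on the sum of
#' Delaunay tetrahedron volumes.
#'
#' @param points n x 3 coordinate matrix.
#' @return hull volume.
#' @export
convex_hull_volume <- function(points) {
  get_scipy_spatial()$ConvexHull(as.matrix(points))$volume
}

# Circumradii and volumes of tetrahedra, vectorized. Near-flat tetrahedra
# (determinant below 1e-14 of the edge-length scale) get infinite radius so
# they are never kept; their volume is numerically zero.
tet_circumradius_volume <- function(points, tets) {
  p1 <- points[tets[, 1], , drop = FALSE]
  a <- points[tets[, 2], , drop = FALSE] - p1
  b <- points[tets[, 3], , drop = FALSE] - p1
  c_ <- points[tets[, 4], , drop = FALSE] - p1
  bxc <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
               b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
               b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  cxa <- cbind(c_[, 2] * a[, 3] - c_[, 3] * a[, 2],
               c_[, 3] * a[, 1] - c_[, 1] * a[, 3],
               c_[, 1] * a[, 2] - c_[, 2] * a[, 1])
  axb <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  det <- rowSums(a * bxc)
  na2 <- rowSums(a^2); nb2 <- rowSums(b^2); nc2 <- rowSums(c_^2)
  scale <- sqrt(na2 * nb2 * nc2)
  u <- (na2 * bxc + nb2 * cxa + nc2 * axb) / (2 * det)
  radius <- sqrt(rowSums(u^2))
  degenerate <- abs(det) <= 1e-14 * scale | !is.finite(radius)
  radius[degenerate] <- Inf
  list(radius = radius, volume = abs(det) / 6)
}

#' Build the alpha complex of an interior point cloud
#'
#' Computes the Delaunay tetrahedralization once, with per-tetrahedron
#' circumradii and volumes, the radius-sorted cumulative volume (so any
#' alpha fit is a threshold lookup), and the unique-face table recording
#' for every triangle the circumradii of its one or two incident
#' tetrahedra. Every alpha-shape fit, the characteristic curve, the
#' optimal-k search, and the heatmap all reuse this one object.
#'
#' @param cloud an `interior_cloud` or n x 3 matrix (>= 4 non-coplanar
#'   points).
#' @return an object of class `alpha_complex`.
#' @export
alpha_complex <- function(cloud) {
  pts <- if (inherits(cloud, "interior_cloud")) cloud$points else as.matrix(cloud)
  if (nrow(pts) < 4) stop("need at least 4 points for an alpha complex")
  tets <- tryCatch(delaunay_tetrahedra(pts),
                   error = function(e)
                     stop("Delaunay tetrahedralization failed (degenerate/",
                          "coplanar cloud?): ", conditionMessage(e)))
  cv <- tet_circumradius_volume(pts, tets)
  ord <- order(cv$radius)
  r_sorted <- cv$radius[ord]
  cum_vol <- cumsum(cv$volume[ord])

  # unique faces with the radii of their incident tetrahedra
  fidx <- rbind(tets[, c(1, 2, 3)], tets[, c(1, 2, 4)],
                tets[, c(1, 3, 4)], tets[, c(2, 3, 4)])
  frad <- rep(cv$radius, 4)
  key <- encode_faces(fidx)
  o <- order(key, frad)
  key <- key[o]; fidx <- fidx[o, , drop = FALSE]; frad <- frad[o]
  first <- !duplicated(key)
  grp <- cumsum(first)
  n_face <- grp[length(grp)]
  r_lo <- frad[first]
  r_hi <- rep(Inf, n_face)
  second <- which(!first)
  r_hi[grp[second]] <- frad[second]   # radius-sorted within key: 2nd is max
  structure(list(points = pts, tets = tets, radius = cv$radius,
                 volume = cv$volume, radius_sorted = r_sorted,
                 cum_volume = cum_vol, total_volume = sum(cv$volume),
                 faces = fidx[first, , drop = FALSE],
                 face_r_lo = r_lo, face_r_hi = r_hi),
            class = "alpha_complex")
}

#' @export
print.alpha_complex <- function(x, ...) {
  cat(sprintf("alpha_complex: %d points, %d tetrahedra, %d faces, hull volume %.6g\n",
              nrow(x$points), nrow(x$tets), nrow(x$faces),
              x$cum_volume[length(x$cum_volume)]))
  invisible(x)
}

# Alpha-complex volume at a given alpha radius (threshold lookup on the
# radius-sorted cumulative volume; exactly non-decreasing in alpha).
alpha_volume_at <- function(ac, alpha) {
  i <- findInterval(alpha, ac$radius_sorted)
  ifelse(i == 0, 0, ac$cum_volume[pmax(i, 1)])
}

#' Fit a single alpha shape
#'
#' Keeps every Delaunay tetrahedron whose circumradius is at most `alpha`
#' (inclusive, so the limit at large alpha is exactly the convex hull) and
#' extracts the boundary: the triangles belonging to exactly one kept
#' tetrahedron.
#'
#' @param cloud an `interior_cloud`, point matrix, or prebuilt
#'   [alpha_complex()].
#' @param alpha alpha radius (length units).
#' @param k optional refinement coefficient that produced `alpha`
#'   (provenance only).
#' @param l_ref optional reference length (provenance only).
#' @param mesh_vol optional source-mesh volume; if given, the fit records
#'   its volume as a percentage of it.
#' @return an `alpha_fit` with fields `k`, `alpha_radius`,
#'   `kept_tetrahedra` (row indices), `boundary_facets` (vertex triples),
#'   `volume`, `volume_fraction`.
#' @export
fit_alpha_shape <- function(cloud, alpha, k = NULL, l_ref = NULL,
                            mesh_vol = NULL) {
  ac <- if (inherits(cloud, "alpha_complex")) cloud else alpha_complex(cloud)
  stopifnot(length(alpha) == 1, is.finite(alpha), alpha > 0)
  kept <- which(ac$radius <= alpha)
  vol <- sum(ac$volume[kept])
  on_b <- ac$face_r_lo <= alpha & ac$face_r_hi > alpha
  structure(list(k = k, alpha_radius = alpha, l_ref = l_ref,
                 kept_tetrahedra = kept,
                 boundary_facets = ac$faces[on_b, , drop = FALSE],
                 volume = vol,
                 volume_fraction = if (!is.null(mesh_vol)) 100 * vol / mesh_vol,
                 complex = ac),
            class = "alpha_fit")
}

#' @export
print.alpha_fit <- function(x, ...) {
  cat(sprintf("alpha_fit: alpha %.6g, %d tetrahedra kept, volume %.6g%s\n",
              x$alpha_radius, length(x$kept_tetrahedra), x$volume,
              if (!is.null(x$volume_fraction))
                sprintf(" (%.2f%% of mesh)", x$volume_fraction) else ""))
  invisible(x)
}

#' Characteristic curve of alpha-shape volume against refinement
#'
#' For each refinement coefficient k on the grid, the alpha-shape volume
#' at alpha = k * l_ref expressed as a percentage of the source-mesh
#' volume. A single Delaunay tetrahedralization is shared across the whole
#' grid, and all volumes come from one radius-sorted cumulative sum, so
#' the curve is exactly non-decreasing.
#'
#' The coarsest member of the family is the convex hull by construction
#' (the suite of fits spans tight shrink-wraps through to the hull), so
#' the top grid point reports the full Delaunay volume: near-coplanar
#' sliver cells on the hull can carry arbitrarily large circumradii, and
#' anchoring the coarse end to the hull keeps the limit exact instead of
#' dependent on those degenerate radii.
#'
#' @param cloud an `interior_cloud` (the down-sampled interior of `mesh`).
#' @param mesh the source `surface_mesh` whose volume anchors the
#'   percentages.
#' @param k_grid refinement grid (default 200 values log-spaced on
#'   `[0.1, 10000]`).
#' @param n_neighbors neighbour count for the reference length.
#' @param complex optional prebuilt [alpha_complex()] for the cloud.
#' @param hull_at_kmax anchor the last grid point to the convex hull
#'   (default `TRUE`).
#' @return a `characteristic_curve` with fields `k_grid`,
#'   `volume_fractions`, `l_ref`, `mesh_volume`.
#' @export
characteristic_curve <- function(cloud, mesh, k_grid = k_grid_default(),
                                 n_neighbors = 100, complex = NULL,
                                 hull_at_kmax = TRUE) {
  stopifnot(inherits(mesh, "surface_mesh"), all(diff(k_grid) > 0))
  cloud <- ensure_l_ref(cloud, n_neighbors)
  ac <- complex %||% alpha_complex(cloud)
  vmesh <- mesh_volume(mesh)
  fr <- 100 * alpha_volume_at(ac, k_grid * cloud$l_ref) / vmesh
  if (hull_at_kmax) fr[length(fr)] <- 100 * ac$total_volume / vmesh
  structure(list(k_grid = k_grid, volume_fractions = fr,
                 l_ref = cloud$l_ref, mesh_volume = vmesh,
                 complex = ac),
            class = "characteristic_curve")
}

#' @export
print.characteristic_curve <- function(x, ...) {
  cat(sprintf(
    "characteristic_curve: %d k values on [%.4g, %.4g], fractions %.3g%% .. %.3g%%, l_ref %.6g\n",
    length(x$k_grid), min(x$k_grid), max(x$k_grid),
    min(x$volume_fractions), max(x$volume_fractions), x$l_ref))
  invisible(x)
}

#' Export a characteristic curve as CSV
#'
#' @param curve a `characteristic_curve`.
#' @param path output path (columns `k,volume_fraction`).
#' @return the path, invisibly.
#' @export
write_curve <- function(curve, path) {
  writeLines(c("k,volume_fraction",
               sprintf("%.17g,%.17g", curve$k_grid, curve$volume_fractions)),
             path)
  invisible(path)
}

#' Optimal refinement coefficient and alpha complexity
#'
#' Locates the smallest refinement coefficient at which the alpha-shape
#' volume reaches the source-mesh volume (the curve crosses 100%) by
#' bracketing on the grid and bisecting in log10 k against fresh alpha
#' fits, then reports alpha complexity = 1 / optimal k. The alpha-shape
#' volume is monotone in k, so bisection cannot stall. When the curve
#' never reaches 100 * (1 - tol) percent (a convex body whose interior
#' samples' hull falls just short of the mesh) the coefficient is reported
#' at the grid boundary and flagged out-of-range with a warning.
#'
#' @param curve a `characteristic_curve`.
#' @param tol relative volume tolerance for convergence (default 1e-3).
#' @return a `complexity_result` with `optimal_k`, `alpha_complexity`
#'   (= 1/optimal_k), and `convergence` diagnostics.
#' @export
optimal_refinement <- function(curve, tol = 1e-3) {
  stopifnot(inherits(curve, "characteristic_curve"))
  kg <- curve$k_grid
  fr <- curve$volume_fractions
  ac <- curve$complex
  frac_at <- function(k) 100 * alpha_volume_at(ac, k * curve$l_ref) / curve$mesh_volume

  make_result <- function(k, conv) {
    structure(list(optimal_k = k, alpha_complexity = 1 / k,
                   l_ref = curve$l_ref, mesh_volume = curve$mesh_volume,
                   convergence = conv),
              class = "complexity_result")
  }

  if (max(fr) < 100 * (1 - tol)) {
    warning(sprintf(
      "alpha volume never reaches the mesh volume on the k grid (max %.3f%%); reporting the grid boundary k = %g",
      max(fr), max(kg)))
    return(make_result(max(kg), list(converged = FALSE,
                                     reason = "no_crossing_below_k_max",
                                     achieved_fraction = max(fr),
                                     iterations = 0L)))
  }
  hit <- which(fr >= 100)
  if (!length(hit)) {
    # within tolerance of 100% but never crossing: smallest k inside the band
    i <- which(fr >= 100 * (1 - tol))[1]
    return(make_result(kg[i], list(converged = TRUE,
                                   reason = "within_tolerance_below_100",
                                   achieved_fraction = fr[i],
                                   iterations = 0L)))
  }
  i <- hit[1]
  if (i == 1) {
    warning("alpha volume already exceeds the mesh volume at the smallest grid k; reporting the grid boundary k = ",
            kg[1])
    return(make_result(kg[1], list(converged = FALSE,
                                   reason = "crossing_below_k_min",
                                   achieved_fraction = fr[1],
                                   iterations = 0L)))
  }
  lo <- log10(kg[i - 1]); hi <- log10(kg[i])
  it <- 0L
  f_hi <- fr[i]
  while (hi - lo > 1e-3) {
    mid <- (lo + hi) / 2
    fm <- frac_at(10^mid)
    it <- it + 1L
    if (abs(fm - 100) <= 100 * tol) { lo <- mid; hi <- mid; f_hi <- fm; break }
    if (fm >= 100) { hi <- mid; f_hi <- fm } else lo <- mid
  }
  k_opt <- 10^hi
  make_result(k_opt, list(converged = TRUE, reason = "bisection",
                          achieved_fraction = f_hi, iterations = it,
                          bracket_log10 = c(lo, hi)))
}

#' @export
print.complexity_result <- function(x, ...) {
  cat(sprintf("complexity_result: optimal k %.6g, alpha complexity %.6g (%s)\n",
              x$optimal_k, x$alpha_complexity, x$convergence$reason))
  invisible(x)
}

#' Export a complexity result as JSON
#'
#' @param result a `complexity_result`.
#' @param path output path.
#' @param id specimen identifier recorded in the file.
#' @param seed master seed recorded in the file.
#' @return the path, invisibly.
#' @export
write_complexity_json <- function(result, path, id = "specimen", seed = NA) {
  jsonlite::write_json(
    list(specimen = id, seed = seed, l_ref = result$l_ref,
         mesh_volume = result$mesh_volume, optimal_k = result$optimal_k,
         alpha_complexity = result$alpha_complexity,
         convergence = result$convergence),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Alpha radius from a refinement coefficient
#'
#' `alpha = k * l_ref`: the dimensionless refinement coefficient times the
#' cloud's reference length.
#'
#' @param k refinement coefficient (> 0).
#' @param l_ref reference length (> 0).
#' @return the alpha radius.
#' @export
alpha_radius <- function(k, l_ref) {
  if (any(k <= 0) || any(l_ref <= 0))
    stop("k and l_ref must be positive")
  k * l_ref
}
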