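#' Coarsest contributing refinement coefficient per cloud point
#'
#' For each point of the cloud, the largest (coarsest) grid refinement
#' coefficient at which the point is a vertex of at least one boundary
#' facet of the alpha shape. "Contributing" is operationalized as boundary
#' membership: interior tetrahedron vertices are invisible in the fitted
#' surface. A triangle shared by two tetrahedra with circumradii
#' `r_lo <= r_hi` lies on the boundary exactly when
#' `r_lo <= alpha < r_hi`, and a hull triangle when `alpha >= r_lo`, so
#' the per-face coarsest qualifying grid value is read off those
#' intervals without refitting; the per-point value is the maximum over
#' incident faces. Points never on any boundary across the grid receive
#' `NA` (the sentinel) and are excluded from face averaging downstream.
#'
#' @param cloud an `interior_cloud` with reference length (computed if
#'   absent).
#' @param k_grid refinement grid (default 200 values on `[0.1, 10000]`).
#' @param complex optional prebuilt [alpha_complex()].
#' @param fits optional list of per-k boundary vertex index sets (aligned
#'   with `k_grid`); when supplied, the value is computed directly from
#'   them instead of from the face intervals (the two routes agree).
#' @return numeric vector, one coarsest grid k per cloud point (`NA`
#'   sentinel for never-boundary points).
#' @export
coarsest_contribution <- function(cloud, k_grid = k_grid_default(),
                                  complex = NULL, fits = NULL) {
  stopifnot(all(diff(k_grid) > 0))
  if (!is.null(fits)) {
    if (!length(fits)) stop("empty list of alpha-shape fits")
    n <- if (inherits(cloud, "interior_cloud")) nrow(cloud$points) else nrow(cloud)
    out <- rep(NA_real_, n)
    for (i in seq_along(k_grid)) {   # ascending: later (coarser) writes win
      vs <- fits[[i]]
      if (length(vs)) out[vs] <- k_grid[i]
    }
    return(out)
  }
  cloud <- ensure_l_ref(cloud)
  ac <- complex %||% alpha_complex(cloud)
  n <- nrow(ac$points)
  lo <- ac$face_r_lo / cloud$l_ref
  hi <- ac$face_r_hi / cloud$l_ref
  ng <- length(k_grid)

  # largest grid index with k < hi (strict: at k = hi both tetrahedra are
  # kept and the face is interior)
  ih <- findInterval(hi, k_grid)
  eq <- which(is.finite(hi) & ih >= 1 & ih <= ng)
  eq <- eq[k_grid[pmax(ih[eq], 1)] == hi[eq]]
  ih[eq] <- ih[eq] - 1L
  ih[!is.finite(hi)] <- ng
  # smallest grid index with k >= lo
  il <- findInterval(lo, k_grid)
  il <- ifelse(il >= 1 & k_grid[pmax(il, 1)] == lo, il, il + 1L)

  ok <- ih >= il & ih >= 1 & il <= ng
  if (!any(ok)) stop("no boundary facet at any grid refinement coefficient")
  fk <- k_grid[ih[ok]]
  fo <- ac$faces[ok, , drop = FALSE]
  out <- group_max(c(fo[, 1], fo[, 2], fo[, 3]), rep(fk, 3), n)
  out[!is.finite(out)] <- NA_real_
  out
}

#' Build a per-vertex complexity heatmap on the optimal alpha shape
#'
#' Restricts the per-point coarsest contributing refinement coefficients
#' to the vertices of the optimal-refinement alpha shape's boundary and
#' averages them over faces: each face value is the arithmetic mean of its
#' three vertices' values, with sentinel (never-boundary) vertices
#' excluded from the mean and all-sentinel faces inheriting the mean of
#' their edge neighbours. Warm rendering corresponds to low coarsest k
#' (regions resolved only by tight fits, i.e. complex), cool to high k.
#'
#' @param opt_fit the `alpha_fit` at the optimal refinement coefficient.
#' @param coarsest per-cloud-point coarsest grid k from
#'   [coarsest_contribution()].
#' @param k_grid the refinement grid the coarsest values came from.
#' @return a `heatmap_mesh` with fields `vertices`, `faces`, `vertex_k`,
#'   `face_k`, `k_grid`.
#' @export
build_heatmap <- function(opt_fit, coarsest, k_grid = k_grid_default()) {
  stopifnot(inherits(opt_fit, "alpha_fit"))
  bf <- opt_fit$boundary_facets
  if (!nrow(bf)) stop("optimal fit has an empty boundary")
  used <- sort(unique(as.vector(bf)))
  vk <- coarsest[used]
  if (all(is.na(vk)))
    stop("no boundary vertex carries a coarsest-k value")
  remap <- integer(max(used))
  remap[used] <- seq_along(used)
  faces <- matrix(remap[bf], ncol = 3)
  fk_mat <- matrix(vk[faces], ncol = 3)
  face_k <- rowMeans(fk_mat, na.rm = TRUE)
  face_k[is.nan(face_k)] <- NA_real_

  # all-sentinel faces inherit the mean of their edge neighbours
  if (anyNA(face_k)) {
    ekey <- function(a, b) pmin(a, b) * 131072 + pmax(a, b)
    edges <- rbind(cbind(ekey(faces[, 1], faces[, 2]), seq_len(nrow(faces))),
                   cbind(ekey(faces[, 2], faces[, 3]), seq_len(nrow(faces))),
                   cbind(ekey(faces[, 3], faces[, 1]), seq_len(nrow(faces))))
    o <- order(edges[, 1])
    e <- edges[o, , drop = FALSE]
    same <- which(e[-nrow(e), 1] == e[-1, 1])
    nb <- cbind(e[same, 2], e[same + 1, 2])
    for (pass in 1:10) {
      na_i <- which(is.na(face_k))
      if (!length(na_i)) break
      vals <- c(face_k[nb[, 2]], face_k[nb[, 1]])
      at <- c(nb[, 1], nb[, 2])
      keep <- at %in% na_i & !is.na(vals)
      if (!any(keep)) break
      filled <- tapply(vals[keep], at[keep], mean)
      face_k[as.integer(names(filled))] <- as.numeric(filled)
    }
  }
  pts <- opt_fit$complex$points
  structure(list(vertices = pts[used, , drop = FALSE], faces = faces,
                 vertex_k = vk, face_k = face_k, k_grid = k_grid,
                 optimal_k = opt_fit$k),
            class = "heatmap_mesh")
}

#' @export
print.heatmap_mesh <- function(x, ...) {
  cat(sprintf(
    "heatmap_mesh: %d vertices, %d faces, coarsest-k range [%.4g, %.4g] (%d sentinel)\n",
    nrow(x$vertices), nrow(x$faces),
    suppressWarnings(min(x$vertex_k, na.rm = TRUE)),
    suppressWarnings(max(x$vertex_k, na.rm = TRUE)), sum(is.na(x$vertex_k))))
  invisible(x)
}

# Position of k on the colour scale: 0 at the fine (warm) end, 1 at the
# coarse (cool) end; monotone increasing in log10(k).
heatmap_color_position <- function(k, k_grid) {
  lo <- log10(min(k_grid)); hi <- log10(max(k_grid))
  pmin(1, pmax(0, (log10(k) - lo) / (hi - lo)))
}

# Warm-to-cool diverging colours on log10(k): low k (complex) renders hot.
k_to_color <- function(k, k_grid) {
  # anchors chosen so red-minus-blue decreases monotonically along the ramp
  ramp <- grDevices::colorRamp(c("#b2182b", "#f6e8c3", "#2166ac"))
  pos <- heatmap_color_position(k, k_grid)
  out <- matrix(128L, length(k), 3)
  fin <- is.finite(pos)
  if (any(fin)) out[fin, ] <- round(ramp(pos[fin]))
  storage.mode(out) <- "integer"
  out
}
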