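#' Default sampled refinement coefficients for multi-scale profiles
#'
#' Six values equally spaced on the logarithmic scale spanning the full
#' refinement grid, from highly refined fits to convex hulls.
#'
#' @param k_min,k_max grid endpoints.
#' @param n number of sampled coefficients (default 6).
#' @return numeric vector of length `n`.
#' @export
sampled_k_default <- function(k_min = 0.1, k_max = 10000, n = 6) {
  10^seq(log10(k_min), log10(k_max), length.out = n)
}

#' Multi-scale alpha-volume profile of a specimen
#'
#' Extracts the alpha-shape volume fraction at a small set of refinement
#' coefficients (default six, log-equally spaced over the grid), read at
#' the grid points nearest in log k to each requested value — the shapes
#' are not refitted. The profile summarizes at which spatial scales a
#' specimen's complexity resides and is the raw input of the morphospace
#' ordinations.
#'
#' @param curve a `characteristic_curve`.
#' @param sampled_k requested refinement coefficients (default
#'   [sampled_k_default()]).
#' @param id optional specimen identifier.
#' @return a `multiscale_profile` with `sampled_k` (the grid values
#'   actually used), `requested_k`, `sampled_fractions`, `specimen_id`.
#' @export
sample_profile <- function(curve, sampled_k = sampled_k_default(), id = NULL) {
  stopifnot(inherits(curve, "characteristic_curve"), all(diff(sampled_k) > 0))
  kg <- curve$k_grid
  if (any(sampled_k < min(kg)) || any(sampled_k > max(kg)))
    stop("sampled_k outside the curve's grid range [", min(kg), ", ", max(kg), "]")
  idx <- vapply(log10(sampled_k),
                function(lk) which.min(abs(log10(kg) - lk)), 0L)
  structure(list(specimen_id = id, requested_k = sampled_k,
                 sampled_k = kg[idx],
                 sampled_fractions = curve$volume_fractions[idx]),
            class = "multiscale_profile")
}

#' Assemble profiles into a specimens-by-scales matrix
#'
#' @param profiles list of `multiscale_profile`s.
#' @return numeric matrix, one row per specimen, columns named `k_<value>`.
#' @export
profile_matrix <- function(profiles) {
  m <- do.call(rbind, lapply(profiles, `[[`, "sampled_fractions"))
  rownames(m) <- vapply(seq_along(profiles), function(i)
    profiles[[i]]$specimen_id %||% paste0("specimen", i), "")
  colnames(m) <- paste0("k_", signif(profiles[[1]]$sampled_k, 4))
  m
}

#' Complexity morphospace by principal component analysis
#'
#' Ordinary (phylogenetically uncorrected) PCA of the multi-scale volume
#' profiles, on the correlation matrix by default (variables scaled to
#' zero mean and unit variance). The sign of each component is fixed so
#' its largest-magnitude loading is positive.
#'
#' @param profiles specimens x scales numeric matrix (or the output of
#'   [profile_matrix()]).
#' @param scale. scale variables to unit variance (default `TRUE`).
#' @param mode label recorded on the result (`"raw"` or
#'   `"species_mean"`).
#' @return a `morphospace_result` with `scores`, `loadings`,
#'   `variance_explained` (percent), `mode`.
#' @export
complexity_pca <- function(profiles, scale. = TRUE, mode = "raw") {
  x <- as.matrix(profiles)
  if (nrow(x) < 3) stop("PCA needs at least 3 specimens")
  if (anyNA(x)) stop("profiles contain missing values")
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop("degenerate (constant) profile variable(s): ",
         paste(colnames(x)[sds == 0] %||% which(sds == 0), collapse = ", "))
  p <- prcomp(x, center = TRUE, scale. = scale.)
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(p$rotation, 2, flip, "*")
  sco <- sweep(p$x, 2, flip, "*")
  structure(list(scores = sco, loadings = rot,
                 variance_explained = 100 * p$sdev^2 / sum(p$sdev^2),
                 sdev = p$sdev * abs(flip), mode = mode),
            class = "morphospace_result")
}

#' @export
print.morphospace_result <- function(x, ...) {
  cat(sprintf("morphospace_result (%s): %d specimens, %d components\n",
              x$mode, nrow(x$scores), ncol(x$scores)))
  ve <- sprintf("PC%d %.1f%%", seq_along(x$variance_explained),
                x$variance_explained)
  cat(" variance explained:", paste(utils::head(ve, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Phylogenetic principal component analysis
#'
#' PCA on the evolutionary correlation (or covariance) matrix: Pagel's
#' lambda is estimated by maximum likelihood jointly with the evolutionary
#' covariance of the traits, the matrix is eigendecomposed, and scores are
#' the tip residuals from the phylogenetic (GLS) mean projected on the
#' eigenvectors. With lambda near zero, or on a star phylogeny, the
#' result coincides with ordinary PCA up to component sign.
#'
#' @param species_profiles species x variables matrix with species row
#'   names.
#' @param tree an `ape::phylo` whose tips cover the row names.
#' @param mode `"cor"` (default) or `"cov"`.
#' @param lambda `"ML"` (default) or a fixed value in `[0, 1]`.
#' @return a `morphospace_result` (mode `"phylogenetic"`) that also
#'   carries `lambda` and `logL`.
#' @export
phylo_pca <- function(species_profiles, tree, mode = c("cor", "cov"),
                      lambda = "ML") {
  mode <- match.arg(mode)
  x <- as.matrix(species_profiles)
  if (is.null(rownames(x))) stop("species_profiles needs species row names")
  miss <- setdiff(rownames(x), tree$tip.label)
  if (length(miss))
    stop("species absent from the tree: ", paste(miss, collapse = ", "))
  tree <- ape::keep.tip(tree, rownames(x))
  C <- ape::vcv.phylo(tree)[rownames(x), rownames(x)]
  C <- C / max(diag(C))   # unit depth: scores in trait units, not rate units
  n <- nrow(x); m <- ncol(x)

  evol_fit <- function(lam) {
    V <- pagel_transform(C, lam)
    L <- chol(V)
    xt <- backsolve(L, x, transpose = TRUE)
    ot <- backsolve(L, rep(1, n), transpose = TRUE)
    a <- drop(crossprod(ot, xt)) / sum(ot^2)
    res_t <- xt - outer(ot, a)
    Rml <- crossprod(res_t) / n
    logL <- -0.5 * (n * determinant(Rml)$modulus[1] +
                    m * 2 * sum(log(diag(L))) + n * m * (1 + log(2 * pi)))
    list(a = a, R = crossprod(res_t) / (n - 1), logL = as.numeric(logL),
         V = V)
  }
  if (identical(lambda, "ML")) {
    op <- optimize(function(l) evol_fit(l)$logL, c(0, 1), maximum = TRUE,
                   tol = 1e-8)
    cand <- c(0, op$maximum, 1)
    ll <- vapply(cand, function(l) evol_fit(l)$logL, 0)
    lambda <- cand[which.max(ll)]
  }
  fit <- evol_fit(lambda)
  R <- fit$R
  M <- if (mode == "cor") stats::cov2cor(R) else R
  eg <- eigen(M, symmetric = TRUE)
  rot <- eg$vectors
  xc <- sweep(x, 2, fit$a)
  if (mode == "cor") xc <- sweep(xc, 2, sqrt(diag(R)), "/")
  sco <- xc %*% rot
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(rot, 2, flip, "*")
  sco <- sweep(sco, 2, flip, "*")
  dimnames(rot) <- list(colnames(x), paste0("PC", seq_len(m)))
  dimnames(sco) <- list(rownames(x), paste0("PC", seq_len(m)))
  structure(list(scores = sco, loadings = rot,
                 variance_explained = 100 * eg$values / sum(eg$values),
                 sdev = sqrt(pmax(eg$values, 0)), mode = "phylogenetic",
                 lambda = lambda, logL = fit$logL),
            class = "morphospace_result")
}

#' Species means of a specimen-level matrix
#'
#' @param x specimens x variables matrix.
#' @param species character vector of species labels, one per row.
#' @return species x variables matrix of arithmetic means.
#' @export
species_means <- function(x, species) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(species))
  g <- rowsum(x, species) / as.vector(table(species)[sort(unique(species))])
  g[order(rownames(g)), , drop = FALSE]
}
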