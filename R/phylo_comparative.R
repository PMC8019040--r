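## Phylogenetic comparative statistics, re-implemented on plain
## linear-algebra primitives: Pagel's lambda signal test, ML (GLS)
## ancestral states, PGLS with a Pagel residual correlation, and
## simulation-based phylogenetic ANOVA / MANOVA. Trees are `ape::phylo`
## objects; trait vectors are matched to tips by name.

#' Pagel lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal (shared-history) covariances by lambda
#' while keeping the diagonal: lambda = 0 removes all phylogenetic
#' structure (a star tree), lambda = 1 is plain Brownian motion.
#'
#' @param C phylogenetic covariance matrix (`ape::vcv.phylo`).
#' @param lambda value in `[0, 1]`.
#' @return the transformed covariance matrix.
#' @export
pagel_transform <- function(C, lambda) {
  V <- lambda * C
  diag(V) <- diag(C)
  V
}

# Match a named trait vector (or data rows) against tree tips; returns the
# pruned tree and values in tip order.
match_to_tree <- function(tree, x) {
  nm <- if (is.null(dim(x))) names(x) else rownames(x)
  if (is.null(nm)) stop("trait values must be named by species")
  miss <- setdiff(nm, tree$tip.label)
  if (length(miss))
    stop("species absent from the tree: ", paste(miss, collapse = ", "))
  tree <- ape::keep.tip(tree, nm)
  ord <- tree$tip.label
  x <- if (is.null(dim(x))) x[ord] else x[ord, , drop = FALSE]
  if (!ape::is.ultrametric(tree, tol = 1e-6))
    warning("tree is not ultrametric within tolerance")
  list(tree = tree, x = x)
}

# Profile log-likelihood machinery for GLS under V(lambda). Returns
# coefficients, sigma2 (ML), RSS, logdet, logL.
gls_profile <- function(X, y, V) {
  n <- length(y)
  L <- chol(V)
  Xt <- backsolve(L, X, transpose = TRUE)
  yt <- backsolve(L, y, transpose = TRUE)
  qrX <- qr(Xt)
  beta <- qr.coef(qrX, yt)
  r <- yt - Xt %*% beta
  rss <- sum(r^2)
  logdet <- 2 * sum(log(diag(L)))
  sigma2 <- rss / n
  logL <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  list(beta = drop(beta), rss = rss, sigma2 = sigma2, logdet = logdet,
       logL = logL, XtX = crossprod(Xt))
}

#' Pagel's lambda phylogenetic signal test
#'
#' Maximum-likelihood estimate of Pagel's lambda on `[0, 1]` for a
#' continuous trait under Brownian motion, with a likelihood-ratio test
#' against lambda = 0 (chi-squared, 1 df). Boundary estimates are
#' reported as-is.
#'
#' @param tree an `ape::phylo`.
#' @param trait named numeric vector of per-species values.
#' @return list with `lambda`, `logL`, `logL0`, `p`.
#' @export
pagels_lambda <- function(tree, trait) {
  m <- match_to_tree(tree, trait)
  if (length(m$x) < 4) stop("need at least 4 species")
  if (anyNA(m$x)) stop("trait contains missing values")
  C <- ape::vcv.phylo(m$tree)
  X <- matrix(1, length(m$x))
  ll <- function(l) gls_profile(X, m$x, pagel_transform(C, l))$logL
  op <- optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-8)
  cand <- c(0, op$maximum, 1)
  lls <- vapply(cand, ll, 0)
  best <- which.max(lls)
  logL0 <- lls[1]
  list(lambda = cand[best], logL = lls[best], logL0 = logL0,
       p = pchisq(2 * max(0, lls[best] - logL0), df = 1, lower.tail = FALSE))
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' GLS estimates of the trait value at every internal node: the estimate
#' at a node is the phylogenetically weighted mean of the tips given the
#' between-node Brownian covariance, and the root estimate equals the GLS
#' grand mean.
#'
#' @param tree an `ape::phylo`.
#' @param trait named numeric vector of tip values.
#' @return named numeric vector of estimates for internal nodes (names
#'   are the `phylo` node numbers).
#' @export
ancestral_states <- function(tree, trait) {
  m <- match_to_tree(tree, trait)
  tree <- m$tree
  x <- m$x
  n <- length(tree$tip.label)
  n_node <- tree$Nnode
  depths <- ape::node.depth.edgelength(tree)   # distance from the root
  mr <- ape::mrca(tree, full = TRUE)
  tip_idx <- seq_len(n)
  anc_idx <- n + seq_len(n_node)
  C_tip <- matrix(depths[mr[tip_idx, tip_idx]], n, n)
  C_anc <- matrix(depths[mr[anc_idx, tip_idx, drop = FALSE]], n_node, n)
  Ci <- solve(C_tip)
  one <- rep(1, n)
  mu <- sum(Ci %*% x) / sum(Ci)
  est <- drop(mu + C_anc %*% (Ci %*% (x - mu)))
  names(est) <- as.character(anc_idx)
  est
}

#' Phylogenetic generalized least squares with a Pagel correlation
#'
#' GLS regression whose residual covariance is the Pagel transform of the
#' Brownian covariance, with lambda estimated by maximum likelihood on
#' `[0, 1]` jointly with the coefficients (or held fixed). Standard
#' errors use the unbiased residual variance with `n - p` degrees of
#' freedom (lambda is not counted), t = slope/SE, and two-sided p-values
#' from the t distribution.
#'
#' @param data data.frame with a `species` column (or species row names)
#'   and the model variables.
#' @param tree an `ape::phylo` covering the species.
#' @param response response variable name.
#' @param predictors character vector of predictor names.
#' @param lambda `"ML"` (default) or a fixed value in `[0, 1]`.
#' @return a `pgls_fit` with a per-coefficient table (slope, SE, t, p),
#'   `lambda`, `logL`, `n`, `df`.
#' @export
pgls <- function(data, tree, response, predictors, lambda = "ML") {
  if ("species" %in% names(data)) rownames(data) <- data$species
  vars <- c(response, predictors)
  stopifnot(all(vars %in% names(data)))
  d <- data[complete.cases(data[, vars, drop = FALSE]), vars, drop = FALSE]
  m <- match_to_tree(tree, d)
  d <- m$x
  n <- nrow(d)
  if (n <= length(predictors) + 1)
    stop("too few complete cases (", n, ") for ", length(predictors),
         " predictors")
  X <- cbind(`(Intercept)` = 1, as.matrix(d[, predictors, drop = FALSE]))
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design: predictors are collinear")
  y <- d[[response]]
  C <- ape::vcv.phylo(m$tree)

  fit_at <- function(l) gls_profile(X, y, pagel_transform(C, l))
  if (identical(lambda, "ML")) {
    op <- optimize(function(l) fit_at(l)$logL, c(0, 1), maximum = TRUE,
                   tol = 1e-8)
    cand <- c(0, op$maximum, 1)
    lls <- vapply(cand, function(l) fit_at(l)$logL, 0)
    lambda <- cand[which.max(lls)]
    boundary <- lambda %in% c(0, 1)
  } else boundary <- FALSE
  f <- fit_at(lambda)
  p_coef <- ncol(X)
  df <- n - p_coef
  sigma2 <- f$rss / df
  se <- sqrt(diag(sigma2 * solve(f$XtX)))
  tval <- f$beta / se
  pval <- 2 * pt(-abs(tval), df)
  tab <- data.frame(term = colnames(X), slope = f$beta, se = se, t = tval,
                    p = pval, row.names = NULL)
  structure(list(coefficients = tab, lambda = lambda,
                 lambda_boundary = boundary, logL = f$logL, n = n, df = df,
                 sigma2 = sigma2, response = response,
                 predictors = predictors),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS: %s ~ %s  (n = %d, lambda = %.4g%s, logLik = %.3f)\n",
              x$response, paste(x$predictors, collapse = " + "), x$n,
              x$lambda, if (x$lambda_boundary) " [boundary]" else "",
              x$logL))
  tab <- x$coefficients
  tab$slope_se <- sprintf("%.3f ± %.3f", tab$slope, tab$se)
  print(data.frame(Predictor = tab$term, `Slope..SE` = tab$slope_se,
                   T = round(tab$t, 2), p = round(tab$p, 3)),
        row.names = FALSE)
  invisible(x)
}

# One-way ANOVA F statistics for each column of a response matrix.
anova_F_matrix <- function(Y, g) {
  Y <- as.matrix(Y)
  g <- as.factor(g)
  n <- nrow(Y)
  k <- nlevels(g)
  G <- model.matrix(~ g - 1)
  cnt <- colSums(G)
  M <- crossprod(G, Y) / cnt
  grand <- colMeans(Y)
  ssb <- colSums(cnt * sweep(M, 2, grand)^2)
  sst <- colSums(Y^2) - n * grand^2
  ssw <- sst - ssb
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[sst <= 0] <- 0    # constant response: no variance to partition
  f
}

# ML Brownian rate of a trait on a tree (GLS residual quadratic form / n).
bm_rate <- function(C, x) {
  Ci <- solve(C)
  mu <- sum(Ci %*% x) / sum(Ci)
  drop(crossprod(x - mu, Ci %*% (x - mu))) / length(x)
}

#' Phylogenetic ANOVA by Brownian simulation
#'
#' The classical one-way F statistic on the observed data, referenced to
#' a null distribution of F statistics from traits simulated under
#' Brownian motion on the tree (rate estimated from the data), following
#' the simulation approach of Garland et al. The phylogenetic p-value
#' uses the +1 continuity correction.
#'
#' @param tree an `ape::phylo`.
#' @param trait named numeric vector of species values.
#' @param groups named factor/character of group labels per species.
#' @param n_sim number of Brownian null simulations.
#' @param seed integer seed.
#' @return list with `F`, `p_phylo`, `p_classical`, `n_sim`.
#' @export
phyl_anova <- function(tree, trait, groups, n_sim = 1000, seed = 1L) {
  m <- match_to_tree(tree, trait)
  g <- as.factor(groups[m$tree$tip.label])
  if (nlevels(droplevels(g)) < 2) stop("need at least 2 groups")
  g <- droplevels(g)
  n <- length(m$x)
  k <- nlevels(g)
  Fobs <- anova_F_matrix(matrix(m$x), g)
  C <- ape::vcv.phylo(m$tree)
  sig2 <- bm_rate(C, m$x)
  Lc <- chol(C)
  Fsim <- with_seed(seed, {
    Z <- matrix(rnorm(n * n_sim), n, n_sim)
    anova_F_matrix(crossprod(Lc, Z) * sqrt(sig2), g)
  })
  list(F = Fobs,
       p_phylo = (1 + sum(Fsim >= Fobs)) / (n_sim + 1),
       p_classical = pf(Fobs, k - 1, n - k, lower.tail = FALSE),
       n_sim = n_sim)
}

# Wilks' lambda and its Rao F approximation for a one-way design.
wilks_lambda <- function(Y, g) {
  Y <- as.matrix(Y)
  g <- as.factor(g)
  n <- nrow(Y); p <- ncol(Y); k <- nlevels(g)
  if (p > n - k) stop("more response dimensions (", p,
                      ") than residual df (", n - k, ")")
  G <- model.matrix(~ g - 1)
  M <- G %*% (crossprod(G, Y) / colSums(G))     # fitted group means
  W <- crossprod(Y - M)
  Tm <- crossprod(sweep(Y, 2, colMeans(Y)))
  lam <- det(W) / det(Tm)
  q <- k - 1
  s <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  mm <- n - 1 - (p + q + 1) / 2
  df1 <- p * q
  df2 <- mm * s - p * q / 2 + 1
  Fapprox <- (1 - lam^(1 / s)) / lam^(1 / s) * df2 / df1
  list(lambda = lam, F = Fapprox, df1 = df1, df2 = df2,
       p = pf(Fapprox, df1, df2, lower.tail = FALSE))
}

#' Phylogenetically corrected MANOVA by multivariate Brownian simulation
#'
#' Wilks' lambda (with its F approximation) on the observed multivariate
#' response, referenced to a null distribution from multivariate Brownian
#' simulations on the tree with the evolutionary covariance estimated
#' from the data. Smaller Wilks' lambda is more extreme; the phylogenetic
#' p-value uses the +1 continuity correction.
#'
#' @param tree an `ape::phylo`.
#' @param scores species x variables matrix (e.g. PC scores) with species
#'   row names.
#' @param groups named group labels per species.
#' @param n_sim number of simulations.
#' @param seed integer seed.
#' @return list with `wilks`, `F`, `df1`, `df2`, `p_phylo`,
#'   `p_classical`, `n_sim`.
#' @export
phyl_manova <- function(tree, scores, groups, n_sim = 1000, seed = 1L) {
  m <- match_to_tree(tree, as.matrix(scores))
  Y <- m$x
  g <- droplevels(as.factor(groups[m$tree$tip.label]))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  n <- nrow(Y); p <- ncol(Y)
  obs <- wilks_lambda(Y, g)
  C <- ape::vcv.phylo(m$tree)
  Ci <- solve(C)
  one <- rep(1, n)
  a <- drop(crossprod(one, Ci %*% Y)) / sum(Ci)
  Yc <- sweep(Y, 2, a)
  R <- crossprod(Yc, Ci %*% Yc) / (n - 1)
  Lc <- chol(C)
  Lr <- chol(R + diag(1e-12 * max(diag(R)), p))
  lam_sim <- with_seed(seed, vapply(seq_len(n_sim), function(i) {
    Ys <- crossprod(Lc, matrix(rnorm(n * p), n, p)) %*% Lr
    wilks_lambda(Ys, g)$lambda
  }, 0))
  list(wilks = obs$lambda, F = obs$F, df1 = obs$df1, df2 = obs$df2,
       p_phylo = (1 + sum(lam_sim <= obs$lambda)) / (n_sim + 1),
       p_classical = obs$p, n_sim = n_sim)
}

#' Star phylogeny
#'
#' All tips attach directly to the root with equal branch lengths; every
#' phylogenetic procedure reduces to its classical counterpart on this
#' tree.
#'
#' @param labels tip labels (or a single integer count).
#' @param depth common branch length.
#' @return an `ape::phylo`.
#' @export
star_tree <- function(labels, depth = 1) {
  if (length(labels) == 1 && is.numeric(labels))
    labels <- sprintf("sp%03d", seq_len(labels))
  tr <- ape::stree(length(labels), type = "star", tip.label = labels)
  tr$edge.length <- rep(depth, nrow(tr$edge))
  tr
}

#' Export a set of PGLS fits as a regression table
#'
#' CSV with columns Model, N, Predictor, Slope, SE, T, p (the intercept
#' row is omitted).
#'
#' @param fits named list of `pgls_fit`s.
#' @param path output CSV path.
#' @return the table, invisibly.
#' @export
write_pgls_table <- function(fits, path) {
  rows <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    tab <- f$coefficients[f$coefficients$term != "(Intercept)", ]
    data.frame(model = nm, n = f$n, predictor = tab$term,
               slope = tab$slope, se = tab$se, t = tab$t, p = tab$p)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}
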