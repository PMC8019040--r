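test_that("profiles sample six nearest-grid fractions, monotone", {
  tube <- fx("tube20k", tube_fixture)
  prof <- sample_profile(tube$curve)
  expect_length(prof$sampled_fractions, 6)
  expect_equal(prof$requested_k, c(0.1, 1, 10, 100, 1000, 10000))
  expect_true(all(prof$sampled_k %in% tube$curve$k_grid))
  expect_true(all(diff(prof$sampled_fractions) >= 0))
  expect_equal(prof$sampled_fractions[6], tube$curve$volume_fractions[200])
  expect_error(sample_profile(tube$curve, c(0.01, 1, 10, 100, 1000, 10000)),
               "outside")
})

test_that("PCA matches a from-scratch eigendecomposition oracle", {
  set.seed(51)
  x <- matrix(rnorm(10 * 6), 10, 6)
  x[, 2] <- 3 * x[, 1] + 1          # two perfectly correlated variables
  p2 <- complexity_pca(x[, 1:2])
  expect_equal(p2$variance_explained[1], 100, tolerance = 1e-9)
  p <- complexity_pca(x)
  expect_equal(sum(p$variance_explained), 100, tolerance = 1e-6)
  # oracle: eigenvectors of the correlation matrix, scores by projection
  z <- scale(x)
  eg <- eigen(crossprod(z) / (nrow(x) - 1), symmetric = TRUE)
  expect_equal(100 * eg$values / sum(eg$values), p$variance_explained,
               tolerance = 1e-9)
  for (j in 1:6)
    expect_equal(abs(drop(z %*% eg$vectors[, j])), abs(p$scores[, j]),
                 ignore_attr = TRUE, tolerance = 1e-9)
  # sign convention: dominant loading positive
  expect_true(all(apply(p$loadings, 2, function(v) v[which.max(abs(v))] > 0)))
})

test_that("constant profile variables raise a degenerate-variable error", {
  x <- cbind(a = rnorm(10), b = rep(2, 10), c = rnorm(10))
  expect_error(complexity_pca(x), "b")
  expect_error(complexity_pca(x[1:2, ]), "at least 3")
})

test_that("species-mean PCA equals individual PCA when n = 1 per species", {
  set.seed(52)
  x <- matrix(rnorm(8 * 4), 8, 4, dimnames = list(paste0("sp", 1:8), NULL))
  sm <- species_means(x, rownames(x))
  expect_equal(complexity_pca(sm)$variance_explained,
               complexity_pca(x[rownames(sm), ])$variance_explained,
               tolerance = 1e-12)
})

test_that("phylogenetic PCA collapses to ordinary PCA without signal", {
  set.seed(53)
  n <- 40
  tr <- star_tree(n, depth = 2)
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(tr$tip.label, NULL))
  pp <- phylo_pca(x, tr)
  po <- complexity_pca(x)
  for (j in 1:4)
    expect_equal(abs(pp$scores[, j]), abs(po$scores[, j]),
                 ignore_attr = TRUE, tolerance = 1e-6)
  # iid data on a real tree: ML lambda ~ 0 and the same collapse
  tr2 <- simulate_tree_and_traits(n_species = n, seed = 8)$tree
  x2 <- matrix(rnorm(n * 3), n, 3, dimnames = list(tr2$tip.label, NULL))
  pp2 <- phylo_pca(x2, tr2)
  expect_lt(pp2$lambda, 0.15)
  po2 <- complexity_pca(x2)
  if (pp2$lambda == 0)
    expect_equal(abs(pp2$scores[, 1]), abs(po2$scores[, 1]),
                 ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("phylogenetic PCA recovers strong signal and matches phytools", {
  skip_if_not_installed("phytools")
  lam <- vapply(1:8, function(r) {
    st <- simulate_tree_and_traits(n_species = 50, lambda = 1, seed = 600 + r)
    x <- cbind(st$data$y,
               simulate_tree_and_traits(n_species = 50, lambda = 1,
                                        seed = 700 + r)$data$y)
    # same tree shape is required: resimulate trait 2 on st's tree
    C <- ape::vcv.phylo(st$tree)
    x2 <- drop(crossprod(chol(C / max(diag(C))),
                         alphamorph:::with_seed(800 + r, rnorm(50))))
    X <- cbind(x1 = st$data$y, x2 = x2)
    rownames(X) <- st$tree$tip.label
    phylo_pca(X, st$tree)$lambda
  }, 0)
  expect_gte(mean(lam), 0.8)
  st <- simulate_tree_and_traits(n_species = 40, lambda = 0.8, seed = 55)
  X <- cbind(a = st$data$y, b = st$data$y * 0.4 + rnorm(40))
  rownames(X) <- st$tree$tip.label
  mine <- phylo_pca(X, st$tree)
  or <- phytools::phyl.pca(st$tree, X, method = "lambda", mode = "cor")
  expect_equal(mine$lambda, or$lambda, tolerance = 1e-3)
  expect_equal(abs(unclass(mine$loadings)), abs(unclass(or$Evec)),
               ignore_attr = TRUE, tolerance = 1e-4)
})

test_that("tip label mismatches are reported by name", {
  x <- matrix(rnorm(12), 4, 3,
              dimnames = list(c("a", "b", "c", "zz"), NULL))
  tr <- star_tree(c("a", "b", "c", "d"))
  expect_error(phylo_pca(x, tr), "zz")
})
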