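test_that("lambda likelihood reduces to iid normal at lambda = 0", {
  st <- simulate_tree_and_traits(n_species = 40, lambda = 1, seed = 61)
  y <- setNames(st$data$y, st$data$species)
  C <- ape::vcv.phylo(st$tree)
  V0 <- diag(diag(C))
  f <- alphamorph:::gls_profile(matrix(1, 40), y[st$tree$tip.label], V0)
  # equal terminal depths: weighted mean = plain mean, iid gaussian logL
  mu <- mean(y)
  s2 <- mean((y - mu)^2) / diag(C)[1]
  ll_iid <- sum(dnorm(y[st$tree$tip.label], mu,
                      sqrt(s2 * diag(C)), log = TRUE))
  expect_equal(f$logL, ll_iid, tolerance = 1e-8)
})

test_that("Pagel's lambda recovers signal and rejects its absence", {
  st <- simulate_tree_and_traits(n_species = 80, lambda = 1, seed = 62)
  y <- setNames(st$data$y, st$data$species)
  fit <- pagels_lambda(st$tree, y)
  expect_gt(fit$lambda, 0.7)
  expect_lt(fit$p, 0.05)
  # shuffling trait values across tips destroys the signal
  ysh <- setNames(alphamorph:::with_seed(1, sample(y)), names(y))
  fit0 <- pagels_lambda(st$tree, ysh)
  expect_lt(fit0$lambda, 0.3)
  expect_gt(fit0$p, 0.05)
  expect_error(pagels_lambda(ape::keep.tip(st$tree, st$tree$tip.label[1:3]),
                             y[1:3]), "at least 4")
})

test_that("lambda estimates match the phytools oracle", {
  skip_if_not_installed("phytools")
  st <- simulate_tree_and_traits(n_species = 60, lambda = 0.7, seed = 9)
  y <- setNames(st$data$y, st$data$species)
  mine <- pagels_lambda(st$tree, y)
  or <- phytools::phylosig(st$tree, y, method = "lambda", test = TRUE)
  expect_equal(mine$lambda, or$lambda, tolerance = 1e-4)
  expect_equal(mine$logL, or$logL, tolerance = 1e-6)
  expect_equal(mine$p, or$P, tolerance = 1e-6)
})

test_that("ancestral states obey closed forms and the GLS matrix oracle", {
  # symmetric 2-tip tree: root is the midpoint
  tr2 <- ape::read.tree(text = "(a:1,b:1);")
  est <- ancestral_states(tr2, c(a = 2, b = 4))
  expect_equal(unname(est), 3, tolerance = 1e-12)
  # a constant trait is constant everywhere
  st <- simulate_tree_and_traits(n_species = 8, seed = 63)
  cst <- setNames(rep(2.5, 8), st$tree$tip.label)
  expect_true(all(abs(ancestral_states(st$tree, cst) - 2.5) < 1e-10))
  # 8-tip fixture against re-rooted GLS means computed independently
  y <- setNames(st$data$y, st$data$species)
  est8 <- ancestral_states(st$tree, y)
  for (node in as.integer(names(est8))) {
    rr <- if (node == ape::Ntip(st$tree) + 1L) st$tree else
      ape::root(st$tree, node = node, resolve.root = TRUE)
    Cr <- ape::vcv.phylo(rr)[names(y), names(y)]
    Ci <- solve(Cr)
    expect_equal(unname(est8[as.character(node)]),
                 sum(Ci %*% y) / sum(Ci), tolerance = 1e-8)
  }
})

test_that("ancestral states match the phytools oracle", {
  skip_if_not_installed("phytools")
  st <- simulate_tree_and_traits(n_species = 30, lambda = 1, seed = 64)
  y <- setNames(st$data$y, st$data$species)
  mine <- ancestral_states(st$tree, y)
  or <- phytools::fastAnc(st$tree, y)
  expect_equal(unname(mine[names(or)]), unname(unclass(or)),
               tolerance = 1e-8)
})

test_that("PGLS at lambda 0 equals OLS; t always equals slope/SE", {
  st <- simulate_tree_and_traits(n_species = 40, slopes = c(x1 = 0.3),
                                 resid_sd = 1, seed = 65)
  d <- st$data
  rownames(d) <- d$species
  f0 <- pgls(d, st$tree, "y", "x1", lambda = 0)
  ols <- summary(lm(y ~ x1, d))$coefficients
  expect_equal(f0$coefficients$slope, unname(ols[, 1]), tolerance = 1e-8)
  expect_equal(f0$coefficients$se, unname(ols[, 2]), tolerance = 1e-8)
  f <- pgls(d, st$tree, "y", "x1")
  expect_equal(f$coefficients$t, f$coefficients$slope / f$coefficients$se,
               tolerance = 1e-12)
  expect_true(all(f$coefficients$p >= 0 & f$coefficients$p <= 1))
  expect_error(pgls(cbind(d, x2 = 2 * d$x1), st$tree, "y", c("x1", "x2")),
               "collinear")
})

test_that("PGLS matches the nlme corPagel oracle", {
  skip_if_not_installed("nlme")
  st <- simulate_tree_and_traits(n_species = 50, lambda = 0.6,
                                 slopes = c(x1 = 0.5), resid_sd = 0.4,
                                 seed = 3)
  d <- st$data
  rownames(d) <- d$species
  mine <- pgls(d, st$tree, "y", "x1")
  or <- nlme::gls(y ~ x1, data = d,
                  correlation = ape::corPagel(0.5, st$tree, form = ~species),
                  method = "ML")
  expect_equal(mine$lambda,
               unname(coef(or$modelStruct$corStruct)), tolerance = 1e-4)
  expect_equal(mine$coefficients$slope, unname(coef(or)), tolerance = 1e-6)
  expect_equal(mine$coefficients$se, unname(sqrt(diag(vcov(or)))),
               tolerance = 1e-5)
})

test_that("lambda and PGLS are invariant to branch-length rescaling", {
  st <- simulate_tree_and_traits(n_species = 30, lambda = 0.7,
                                 slopes = c(x1 = 0.4), seed = 66)
  d <- st$data
  rownames(d) <- d$species
  tr10 <- st$tree
  tr10$edge.length <- tr10$edge.length * 37
  y <- setNames(d$y, d$species)
  expect_equal(pagels_lambda(st$tree, y)$lambda,
               pagels_lambda(tr10, y)$lambda, tolerance = 1e-6)
  f1 <- pgls(d, st$tree, "y", "x1")
  f2 <- pgls(d, tr10, "y", "x1")
  expect_equal(f1$coefficients$slope, f2$coefficients$slope,
               tolerance = 1e-8)
  expect_equal(f1$lambda, f2$lambda, tolerance = 1e-6)
})

test_that("phylogenetic ANOVA: F matches classical, contracts hold", {
  st <- simulate_tree_and_traits(n_species = 45, lambda = 1, seed = 67)
  y <- setNames(st$data$y, st$data$species)
  g <- setNames(alphamorph:::with_seed(2,
                sample(c("u", "v", "w"), 45, TRUE)), names(y))
  res <- phyl_anova(st$tree, y, g, n_sim = 400, seed = 5)
  Flm <- anova(lm(y ~ g))[1, "F value"]
  expect_equal(res$F, Flm, tolerance = 1e-9)
  # constant trait: F = 0, p = 1
  cst <- setNames(rep(1, 45), names(y))
  res0 <- phyl_anova(st$tree, cst, g, n_sim = 100, seed = 5)
  expect_equal(res0$F, 0)
  expect_equal(res0$p_phylo, 1, tolerance = 0.02)
  # planted shift on a star tree is detected
  tr <- star_tree(names(y))
  ysh <- y + 3 * sd(y) * (g == "u")
  expect_lt(phyl_anova(tr, ysh, g, n_sim = 400, seed = 5)$p_phylo, 0.01)
  expect_error(phyl_anova(st$tree, y, setNames(rep("u", 45), names(y))),
               "2 groups")
})

test_that("phylogenetic ANOVA p agrees with the phytools oracle", {
  skip_if_not_installed("phytools")
  st <- simulate_tree_and_traits(n_species = 40, lambda = 1, seed = 68)
  y <- setNames(st$data$y, st$data$species)
  g <- setNames(alphamorph:::with_seed(3,
                sample(c("u", "v"), 40, TRUE)), names(y))
  mine <- phyl_anova(st$tree, y, g, n_sim = 1500, seed = 6)
  or <- phytools::phylANOVA(st$tree, factor(g[st$tree$tip.label]), y,
                            nsim = 1500)
  expect_equal(mine$F, or$F, tolerance = 1e-8)
  expect_lt(abs(mine$p_phylo - or$Pf), 0.06)
})

test_that("phylogenetic MANOVA invariances and univariate reduction", {
  st <- simulate_tree_and_traits(n_species = 40, lambda = 1, seed = 69)
  tips <- st$tree$tip.label
  Y <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(tips, NULL))
  g <- setNames(alphamorph:::with_seed(4, sample(c("u", "v"), 40, TRUE)),
                tips)
  res <- phyl_manova(st$tree, Y, g, n_sim = 300, seed = 7)
  # orthogonal rotation of the response leaves Wilks' lambda unchanged
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  res_rot <- phyl_manova(st$tree, Y %*% Q, g, n_sim = 300, seed = 7)
  expect_equal(res$wilks, res_rot$wilks, tolerance = 1e-9)
  # univariate response reduces to the ANOVA engine
  y1 <- Y[, 1, drop = FALSE]
  resu <- phyl_manova(st$tree, y1, g, n_sim = 2000, seed = 8)
  resa <- phyl_anova(st$tree, drop(y1), g, n_sim = 2000, seed = 9)
  expect_lt(abs(resu$p_phylo - resa$p_phylo), 0.06)
  Ybig <- matrix(rnorm(40 * 39), 40, dimnames = list(tips, NULL))
  expect_error(phyl_manova(st$tree, Ybig, n_sim = 10, seed = 1,
                           groups = g), "dimensions")
})
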