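#' Pipeline run configuration
#'
#' Bundles the study-level defaults: interior fill minimum (250,000
#' points), down-sample target (100,000), reference-length neighbour count
#' (100), the 200-value refinement grid on `[0.1, 10000]`, six sampled
#' refinement coefficients for the multi-scale profile, the optimal-k
#' volume tolerance, the master seed from which every stage seed is
#' derived, and the taxon subset switch.
#'
#' @param fill_min minimum accepted interior points.
#' @param downsample_target points kept for shape fitting.
#' @param n_neighbors neighbours for the reference length.
#' @param k_min,k_max,k_steps refinement grid.
#' @param sampled_count sampled refinement coefficients for profiles.
#' @param sampled_k explicit sampled coefficients (overrides
#'   `sampled_count`).
#' @param tol optimal-k relative volume tolerance.
#' @param master_seed integer master seed.
#' @param subset `"all"` or `"cetaceans"` (drop other groups from the
#'   comparative models).
#' @return a `run_config` with a stable `hash`.
#' @export
run_config <- function(fill_min = 250000, downsample_target = 100000,
                       n_neighbors = 100, k_min = 0.1, k_max = 10000,
                       k_steps = 200, sampled_count = 6, sampled_k = NULL,
                       tol = 1e-3, master_seed = 1L,
                       subset = c("all", "cetaceans")) {
  subset <- match.arg(subset)
  if (!(fill_min >= 1 && downsample_target >= 1 && n_neighbors >= 1 &&
        k_steps >= 2 && sampled_count >= 2))
    stop("all counts must be positive")
  if (!(k_min > 0 && k_max > k_min))
    stop("k range must be positive and increasing, got [", k_min, ", ",
         k_max, "]")
  if (downsample_target > fill_min)
    stop("downsample_target must not exceed fill_min")
  if (is.null(sampled_k))
    sampled_k <- sampled_k_default(k_min, k_max, sampled_count)
  cfg <- list(fill_min = fill_min, downsample_target = downsample_target,
              n_neighbors = n_neighbors, k_min = k_min, k_max = k_max,
              k_steps = k_steps, sampled_k = sampled_k, tol = tol,
              master_seed = as.integer(master_seed), subset = subset)
  cfg$k_grid <- k_grid_default(k_min, k_max, k_steps)
  cfg$hash <- sprintf("%08x", derive_seed(0, paste(deparse(
    cfg[c("fill_min", "downsample_target", "n_neighbors", "k_min", "k_max",
          "k_steps", "sampled_k", "tol", "master_seed", "subset")]),
    collapse = "")))
  structure(cfg, class = "run_config")
}

#' Run the complexity pipeline on one specimen
#'
#' Executes fill -> down-sample -> reference length -> alpha complex ->
#' characteristic curve -> optimal refinement -> alpha complexity ->
#' heatmap -> multi-scale profile on a single mesh, with stage seeds
#' derived from the master seed and the specimen id. Optionally writes
#' JSON/CSV/PLY outputs plus a provenance record.
#'
#' @param mesh a `surface_mesh` or a mesh file path.
#' @param config a [run_config()].
#' @param id specimen identifier (drives the derived seeds).
#' @param out_dir optional output directory.
#' @param heatmap compute the per-vertex heatmap (default `TRUE`).
#' @return list with `complexity`, `curve`, `profile`, `heatmap`, `cloud`,
#'   and `provenance`.
#' @export
run_specimen <- function(mesh, config = run_config(), id = "specimen",
                         out_dir = NULL, heatmap = TRUE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  if (is.character(mesh)) mesh <- read_mesh(mesh)
  seeds <- list(fill = derive_seed(config$master_seed, paste0(id, "/fill")),
                down = derive_seed(config$master_seed, paste0(id, "/down")))
  cloud <- fill_interior(mesh, n_min = config$fill_min, seed = seeds$fill)
  n_raw <- cloud$n_raw
  cloud <- downsample(cloud, n_target = config$downsample_target,
                      seed = seeds$down)
  cloud <- ensure_l_ref(cloud, config$n_neighbors)
  ac <- alpha_complex(cloud)
  curve <- characteristic_curve(cloud, mesh, k_grid = config$k_grid,
                                n_neighbors = config$n_neighbors,
                                complex = ac)
  cx <- optimal_refinement(curve, tol = config$tol)
  prof <- sample_profile(curve, config$sampled_k, id = id)
  hm <- NULL
  if (heatmap) {
    coarse <- coarsest_contribution(cloud, config$k_grid, complex = ac)
    opt_fit <- fit_alpha_shape(ac, alpha = cx$optimal_k * cloud$l_ref,
                               k = cx$optimal_k, l_ref = cloud$l_ref,
                               mesh_vol = curve$mesh_volume)
    hm <- build_heatmap(opt_fit, coarse, config$k_grid)
  }
  prov <- list(specimen = id, config_hash = config$hash,
               master_seed = config$master_seed, stage_seeds = seeds,
               n_raw = n_raw, n_down = nrow(cloud$points),
               acceptance_rate = cloud$acceptance_rate,
               l_ref = cloud$l_ref,
               solver_iterations = cx$convergence$iterations,
               elapsed_s = proc.time()[["elapsed"]] - t0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_complexity_json(cx, file.path(out_dir, paste0(id, "_complexity.json")),
                          id = id, seed = config$master_seed)
    write_curve(curve, file.path(out_dir, paste0(id, "_curve.csv")))
    writeLines(c("k,volume_fraction",
                 sprintf("%.17g,%.17g", prof$sampled_k,
                         prof$sampled_fractions)),
               file.path(out_dir, paste0(id, "_profile.csv")))
    if (!is.null(hm))
      write_heatmap_mesh(hm, file.path(out_dir, paste0(id, "_heatmap.ply")))
    jsonlite::write_json(prov, file.path(out_dir, paste0(id, "_provenance.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  list(complexity = cx, curve = curve, profile = prof, heatmap = hm,
       cloud = cloud, provenance = prov)
}

#' Run the full cohort analysis
#'
#' Per-specimen complexity, species means, all-individuals and
#' species-mean PCA, phylogenetic PCA, Pagel's lambda signal test and
#' ancestral states of (log10) alpha complexity, the three PGLS predictor
#' sets (neonate + mother length; testes mass + male body mass; sexual
#' size dimorphism), and phylogenetic ANOVA / MANOVA across penis-tip
#' categories. All quantitative traits and alpha complexity are log10
#' transformed before the comparative models. The `subset = "cetaceans"`
#' switch restricts the comparative models to the cetacean group.
#'
#' @param meshes named list of `surface_mesh`es (or mesh file paths);
#'   names are specimen ids.
#' @param manifest data.frame with columns `specimen`, `species`, and
#'   optionally `group` (needed for the cetacean subset).
#' @param tree an `ape::phylo` covering the manifest species.
#' @param traits species-level data.frame with columns `species`,
#'   `neonate_length`, `mother_length`, `testes_mass`, `male_body_mass`,
#'   `ssd`, `penis_tip`.
#' @param config a [run_config()].
#' @param out_dir optional output directory for CSV tables.
#' @param heatmaps compute per-specimen heatmaps (off by default at cohort
#'   scale).
#' @return list with per-specimen results and every cohort-level table.
#' @export
run_cohort <- function(meshes, manifest, tree, traits,
                       config = run_config(), out_dir = NULL,
                       heatmaps = FALSE) {
  stopifnot(all(c("specimen", "species") %in% names(manifest)),
            length(meshes) == nrow(manifest))
  bad <- setdiff(manifest$species, traits$species)
  if (length(bad)) stop("manifest species missing from traits: ",
                        paste(unique(bad), collapse = ", "))
  bad <- setdiff(traits$species, tree$tip.label)
  if (length(bad)) stop("trait species missing from tree: ",
                        paste(unique(bad), collapse = ", "))
  tree <- ape::keep.tip(tree, intersect(tree$tip.label, traits$species))

  runs <- lapply(seq_along(meshes), function(i)
    run_specimen(meshes[[i]], config, id = manifest$specimen[i],
                 heatmap = heatmaps))
  names(runs) <- manifest$specimen
  complexity <- vapply(runs, function(r) r$complexity$alpha_complexity, 0)
  profiles <- profile_matrix(lapply(runs, `[[`, "profile"))

  pca_raw <- complexity_pca(profiles, mode = "raw")
  sp_prof <- species_means(profiles, manifest$species)
  sp_cx <- drop(species_means(matrix(complexity, ncol = 1),
                              manifest$species))
  pca_sp <- complexity_pca(sp_prof, mode = "species_mean")
  ppca <- phylo_pca(sp_prof, tree)

  log_cx <- log10(sp_cx)
  sig <- pagels_lambda(tree, log_cx)
  anc <- ancestral_states(tree, log_cx)

  td <- traits
  rownames(td) <- td$species
  td <- td[names(sp_cx), ]
  model_data <- data.frame(
    species = td$species,
    alpha_complexity = log_cx,
    neonate_length = log10(td$neonate_length),
    mother_length = log10(td$mother_length),
    testes_mass = log10(td$testes_mass),
    male_body_mass = log10(td$male_body_mass),
    ssd = log10(td$ssd),
    penis_tip = td$penis_tip)
  if (config$subset == "cetaceans") {
    if (!"group" %in% names(manifest))
      stop("cetacean subset requested but manifest has no 'group' column")
    keep <- unique(manifest$species[manifest$group == "cetacean"])
    model_data <- model_data[model_data$species %in% keep, ]
  }
  mtree <- ape::keep.tip(tree, model_data$species)
  pgls_fits <- list(
    neonate = pgls(model_data, mtree, "alpha_complexity",
                   c("neonate_length", "mother_length")),
    testes = pgls(model_data, mtree, "alpha_complexity",
                  c("testes_mass", "male_body_mass")),
    ssd = pgls(model_data, mtree, "alpha_complexity", "ssd"))

  groups <- setNames(model_data$penis_tip, model_data$species)
  cx_named <- setNames(model_data$alpha_complexity, model_data$species)
  aov_res <- phyl_anova(mtree, cx_named, groups,
                        seed = derive_seed(config$master_seed, "phylANOVA"))
  sc <- ppca$scores[rownames(ppca$scores) %in% model_data$species, ,
                    drop = FALSE]
  n_pc <- min(ncol(sc), nrow(sc) - length(unique(groups)) - 1)
  man_res <- phyl_manova(mtree, sc[, seq_len(n_pc), drop = FALSE], groups,
                         seed = derive_seed(config$master_seed, "phylMANOVA"))

  out <- list(runs = runs, complexity = complexity,
              species_complexity = sp_cx, profiles = profiles,
              species_profiles = sp_prof, pca_raw = pca_raw,
              pca_species = pca_sp, ppca = ppca, lambda = sig,
              ancestral = anc, pgls = pgls_fits, anova = aov_res,
              manova = man_res, tree = tree, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(data.frame(specimen = manifest$specimen,
                         species = manifest$species,
                         alpha_complexity = complexity, profiles),
              file.path(out_dir, "specimens.csv"), row.names = FALSE)
    write.csv(data.frame(species = names(sp_cx), alpha_complexity = sp_cx,
                         sp_prof),
              file.path(out_dir, "species_means.csv"), row.names = FALSE)
    write.csv(data.frame(pca_raw$scores),
              file.path(out_dir, "pca_scores.csv"))
    write.csv(data.frame(pca_raw$loadings),
              file.path(out_dir, "pca_loadings.csv"))
    write_pgls_table(pgls_fits, file.path(out_dir, "pgls_models.csv"))
    jsonlite::write_json(
      list(config_hash = config$hash, master_seed = config$master_seed,
           lambda = sig, anova = aov_res, manova = man_res),
      file.path(out_dir, "comparative.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
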