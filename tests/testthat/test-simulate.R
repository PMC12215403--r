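test_that("simulated trees are ultrametric, unit depth, reproducible", {
  tr <- simulate_tree(3, seed = 1)
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(tr$Nnode, 2)
  expect_identical(ape::write.tree(simulate_tree(40, seed = 9)),
                   ape::write.tree(simulate_tree(40, seed = 9)))
  depths <- ape::node.depth.edgelength(simulate_tree(25, seed = 5))[1:25]
  expect_lt(diff(range(depths)), 1e-9)
  expect_equal(max(depths), 1)
  expect_error(simulate_tree(2), "at least 3")
})

test_that("frozen and loss-only copy-number processes behave analytically", {
  tree <- simulate_tree(12, seed = 2)
  frozen <- evolve_family_counts(
    tree, sim_config(n_species = 12, n_families = 30, n_causal = 1,
                     causal_weights = 1, lambda = 0, mu = 0, seed = 2))
  expect_equal(unname(apply(frozen, 2, function(col) length(unique(col)))),
               rep(1L, 30))  # every species inherits the root count

  dying <- evolve_family_counts(
    tree, sim_config(n_species = 12, n_families = 40, n_causal = 1,
                     causal_weights = 1, lambda = 0, mu = 60, seed = 2))
  expect_true(all(dying == 0L))
})

test_that("critical birth-death preserves the mean (martingale property)", {
  # lambda = mu: E[tip count] = E[root count] = (1 - p) / p
  tree <- simulate_tree(6, seed = 3)
  cfg <- sim_config(n_species = 6, n_families = 2000, n_causal = 1,
                    causal_weights = 1, lambda = 1, mu = 1, root_p = 0.5,
                    seed = 7)
  counts <- evolve_family_counts(tree, cfg)
  tip_mean <- mean(counts)
  expect_m <- (1 - cfg$root_p) / cfg$root_p
  # 3 standard errors of the Monte-Carlo mean over families
  se <- sd(colMeans(counts)) / sqrt(ncol(counts))
  expect_lt(abs(tip_mean - expect_m), 3 * se + 1e-12)
})

test_that("the liability model is null, monotone and recorded faithfully", {
  tree <- simulate_tree(30, seed = 4)
  cfg0 <- sim_config(n_species = 30, n_families = 50, n_causal = 2,
                     causal_weights = c(0, 0), sigma_phylo = 0,
                     sigma_iid = 0, seed = 4)
  counts <- evolve_family_counts(tree, cfg0)
  truth0 <- assign_trait(counts, tree, cfg0)
  expect_equal(unname(truth0$resistance), rep(0.5, 30))

  cfg1 <- sim_config(n_species = 30, n_families = 50, n_causal = 1,
                     causal_weights = 5, sigma_phylo = 0, sigma_iid = 0,
                     seed = 4)
  truth1 <- assign_trait(counts, tree, cfg1)
  fam <- truth1$causal_families
  ord <- order(counts[, fam])
  expect_true(all(diff(truth1$resistance[ord]) >= 0))

  # liability reproducible from counts, weights and recorded noise draws
  cfg2 <- sim_config(n_species = 30, n_families = 50, n_causal = 2,
                     causal_weights = c(2, -1), seed = 4)
  truth2 <- assign_trait(counts, tree, cfg2)
  rebuilt <- drop(counts[, truth2$causal_families] %*% truth2$weights) +
    truth2$bm_draw[rownames(counts)] + truth2$iid_draw[rownames(counts)]
  expect_equal(unname(truth2$liability), unname(rebuilt))

  # doubling the weights doubles the genetic liability exactly (sigma = 0)
  cfg3 <- sim_config(n_species = 30, n_families = 50, n_causal = 2,
                     causal_weights = c(2, -1), sigma_phylo = 0,
                     sigma_iid = 0, seed = 4)
  cfg4 <- sim_config(n_species = 30, n_families = 50, n_causal = 2,
                     causal_weights = c(4, -2), sigma_phylo = 0,
                     sigma_iid = 0, seed = 4)
  l3 <- assign_trait(counts, tree, cfg3)$liability
  l4 <- assign_trait(counts, tree, cfg4)$liability
  expect_equal(2 * l3, l4)
  expect_equal(var(l4), 4 * var(l3))
})

test_that("noise-free growth curves integrate to the logistic quadrature", {
  tree <- simulate_tree(4, seed = 6)
  cfg <- sim_config(n_species = 4, n_families = 10, n_causal = 1,
                    causal_weights = 2, od_noise_sd = 0, rate_jitter_sd = 0,
                    n_replicates = 1, seed = 6)
  counts <- evolve_family_counts(tree, cfg)
  truth <- assign_trait(counts, tree, cfg)
  curves <- emit_growth_curves(truth, cfg)
  ctl <- Filter(function(cv) cv$dose == 0, curves)[[1]]
  # closed-form logistic parameters at dose 0: K = k0, rho known per species
  # independent oracle: adaptive quadrature of the same logistic
  K <- cfg$k0; N0 <- cfg$n0
  od1 <- ctl$od[2]
  rho <- log((K / od1 - 1) / ((K - N0) / N0)) / -1  # invert OD(1)
  oracle <- integrate(function(t) K / (1 + ((K - N0) / N0) * exp(-rho * t)),
                      0, 168, rel.tol = 1e-10)$value
  expect_equal(eauc(ctl), oracle, tolerance = 1e-3)  # trapezoid error only
})

test_that("resistance extremes drive the treated/control EAUC ratio", {
  tree <- simulate_tree(4, seed = 8)
  cfg <- sim_config(n_species = 4, n_families = 30, n_causal = 1,
                    causal_weights = 2, root_p = 0.4, od_noise_sd = 0,
                    rate_jitter_sd = 0, n_replicates = 1, seed = 8)
  counts <- evolve_family_counts(tree, cfg)
  truth <- assign_trait(counts, tree, cfg)
  truth$resistance[] <- c(0.999, 0.001, 0.5, 0.5)
  curves <- emit_growth_curves(truth, cfg)
  ph <- phenotype_table(curves)
  resistant <- ph[ph$species == names(truth$resistance)[1], ]
  sensitive <- ph[ph$species == names(truth$resistance)[2], ]
  expect_gt(min(resistant$relative_growth), 0.85)
  expect_lt(max(sensitive$relative_growth), 0.15)
})

test_that("complete datasets are cross-consistent and seed-stable", {
  cfg <- sim_config(n_species = 20, n_families = 40, n_causal = 2,
                    causal_weights = c(2, -2), seed = 12)
  dir1 <- withr::local_tempdir()
  ds <- make_dataset(cfg, out_dir = dir1)
  # every emitted file loads through the package's own readers
  tree <- read_newick(ds$paths$tree)
  expect_setequal(tree$tip.label, rownames(ds$counts))
  counts <- read_orthogroup_counts(ds$paths$counts)
  expect_equal(counts, ds$counts)
  mem <- read_membership(ds$paths$membership)
  expect_equal(membership_counts(mem)[rownames(counts), colnames(counts)],
               counts, ignore_attr = TRUE)
  curves <- read_plate_table(ds$paths$plate, ds$paths$metadata)
  expect_length(curves, 20 * 3 * 3)
  ann <- data.table::fread(ds$paths$annotations)
  expect_true("causal_term" %in% ann$term_name)

  # byte-identical regeneration from the same seed
  dir2 <- withr::local_tempdir()
  make_dataset(cfg, out_dir = dir2)
  for (p in names(ds$paths)) {
    expect_identical(unname(tools::md5sum(ds$paths[[p]])),
                     unname(tools::md5sum(file.path(dir2,
                                                    basename(ds$paths[[p]])))),
                     label = p)
  }

  # a different seed changes the draws but not the shapes
  ds2 <- make_dataset(sim_config(n_species = 20, n_families = 40,
                                 n_causal = 2, causal_weights = c(2, -2),
                                 seed = 13))
  expect_equal(dim(ds2$counts), dim(ds$counts))
  expect_false(identical(ds2$counts, ds$counts))
})

test_that("the default design reproduces the 57/57/114 class arithmetic", {
  ds <- make_dataset(sim_config(seed = 19))
  ph <- phenotype_table(ds$curves)
  cl <- classify_tails(ph, 1, 2, 0.2)
  expect_equal(as.vector(table(cl$table$class_label)), c(57, 57))
  expect_equal(nrow(cl$table), 114)
  inst <- build_instance_table(cl, ds$counts)
  expect_equal(dim(inst$X), c(114, 2000))
})
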