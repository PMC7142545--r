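test_that("null planting yields an empty truth record", {
  ds <- generate_dataset(sim_config(n_genes = 30, n_replicates = 2,
                                    n_specific_genes = 0, n_modules = 0,
                                    n_markers_per_morph = 0,
                                    n_sex_genes = 0, seed = 1))
  expect_length(ds$truth$specific_genes, 0)
  expect_length(ds$truth$module_members, 0)
  expect_length(ds$truth$marker_genes, 0)
  expect_length(ds$truth$sex_genes, 0)
  expect_equal(dim(ds$expr$values), c(30L, 30L))
})

test_that("generation is a pure function of the seed", {
  cfg <- sim_config(n_genes = 80, n_replicates = 2, n_specific_genes = 6,
                    n_modules = 1, module_size = 8,
                    n_markers_per_morph = 2, n_sex_genes = 10, seed = 42)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$truth, b$truth)
  cfg2 <- sim_config(n_genes = 80, n_replicates = 2, n_specific_genes = 6,
                     n_modules = 1, module_size = 8,
                     n_markers_per_morph = 2, n_sex_genes = 10, seed = 43)
  expect_false(identical(generate_dataset(cfg2)$expr$values,
                         a$expr$values))
})

test_that("all 15 types are covered and gene roles are disjoint", {
  ds <- generate_dataset(sim_config(seed = 2))
  expect_equal(length(unique(ds$expr$samples$type)), 15L)
  expect_equal(table(ds$expr$samples$type)[[1]], 4L)
  roles <- list(names(ds$truth$specific_genes),
                unlist(lapply(ds$truth$module_members, `[[`, "genes")),
                unlist(ds$truth$marker_genes),
                unlist(ds$truth$sex_genes))
  expect_equal(sum(lengths(roles)), length(unique(unlist(roles))))
  expect_true(all(unlist(roles) %in% rownames(ds$expr$values)))
  hubs <- vapply(ds$truth$module_members, `[[`, "", "hub")
  expect_true(all(vapply(seq_along(hubs), function(k)
    hubs[k] %in% ds$truth$module_members[[k]]$genes, TRUE)))
})

test_that("infeasible configurations fail before generation", {
  expect_error(sim_config(n_genes = 50, n_specific_genes = 40,
                          n_modules = 2, module_size = 10,
                          n_markers_per_morph = 2, n_sex_genes = 0),
               "infeasible")
  expect_error(sim_config(specific_fold = 1), "specific_fold")
  expect_error(sim_config(module_rho = 1), "module_rho")
  expect_error(sim_config(noise_log2_sd = 0), "strictly positive")
})

test_that("module members reach the configured log-scale correlation", {
  ds <- generate_dataset(sim_config(n_genes = 100, n_replicates = 10,
                                    n_specific_genes = 0, n_modules = 1,
                                    module_size = 10, module_rho = 0.9,
                                    n_markers_per_morph = 0,
                                    n_sex_genes = 0, seed = 7))
  members <- ds$truth$module_members[[1]]$genes
  cm <- cor(t(log2(ds$expr$values[members, ])))
  mean_r <- mean(cm[upper.tri(cm)])
  expect_gt(mean_r, 0.8)
  expect_lt(mean_r, 0.95)
  # the hub tracks the latent factor more tightly than any member
  hub <- ds$truth$module_members[[1]]$hub
  hub_r <- mean(cm[hub, setdiff(members, hub)])
  expect_gt(hub_r, mean_r)
})

test_that("strongly planted specific genes peak in their target type", {
  ds <- generate_dataset(sim_config(n_genes = 200, n_replicates = 3,
                                    n_specific_genes = 30,
                                    specific_fold = 16, n_modules = 0,
                                    n_markers_per_morph = 0,
                                    n_sex_genes = 0,
                                    noise_log2_sd = 0.3, seed = 9))
  tm <- aggregate_types(ds$expr)
  peak <- colnames(tm$values)[apply(tm$values, 1, which.max)]
  names(peak) <- rownames(tm$values)
  tgt <- ds$truth$specific_genes
  expect_equal(unname(peak[names(tgt)]), unname(tgt))
})

test_that("background tau sits below planted-specific tau", {
  ds <- generate_dataset(sim_config(n_genes = 500, n_replicates = 2,
                                    n_specific_genes = 30, n_modules = 0,
                                    n_markers_per_morph = 0,
                                    n_sex_genes = 0, seed = 13))
  tau <- compute_tau(filter_expressed(aggregate_types(ds$expr), 0.5))
  planted <- tau$tau[tau$gene_id %in% names(ds$truth$specific_genes)]
  background <- tau$tau[!tau$gene_id %in% names(ds$truth$specific_genes)]
  expect_gt(min(planted), quantile(background, 0.95))
})
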