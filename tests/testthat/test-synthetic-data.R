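test_that("generation is deterministic and tables are internally consistent", {
  cfg <- sim_config(seed = 42)
  sim1 <- generate_dataset(cfg)
  sim2 <- generate_dataset(cfg)
  expect_identical(sim1, sim2)

  t <- sim1$tables
  expect_silent(validate_study_tables(t))
  expect_true(all(abs(rowSums(t$relabund_species) - 1) < 1e-9))
  expect_true(all(abs(rowSums(t$relabund_genus) - 1) < 1e-9))
  expect_true(all(t$counts_species >= 0))
  expect_identical(t$metadata$sample_id, rownames(t$metabolites))
  # genus tables aggregate the species tables through the taxonomy map
  agg <- rowsum(t(t$relabund_species), t$taxonomy$genus)
  expect_equal(unname(t(agg)[, colnames(t$relabund_genus)]),
               unname(t$relabund_genus), tolerance = 1e-12)
})

test_that("dominant taxon mean relative abundance is near its configured value", {
  sim <- generate_dataset(sim_config(seed = 7))
  expect_lt(abs(mean(sim$tables$relabund_species[, "sp001"]) - 0.59), 0.05)
  # and the detection floor creates genuine zeros for the CLR to handle
  expect_gt(sum(sim$tables$relabund_species == 0), 0)
})

test_that("a noiseless monotone effect preserves ranks exactly", {
  eff <- planted_effect("m001", "aging_year", "linear", 1)
  cfg <- sim_config(n_metabolites = 1, effect_table = eff, noise_sd = 0,
                    censor_quantile = 0, n_rare_metabolites = 0, seed = 3)
  sim <- generate_dataset(cfg)
  rho <- cor(sim$tables$metadata$aging_year, sim$tables$metabolites[, "m001"],
             method = "spearman")
  expect_equal(rho, 1)
})

test_that("planted age- and acid-associated taxa are present", {
  sim <- generate_dataset(sim_config(seed = 5))
  t <- sim$tables
  expect_gt(cor(t$metadata$aging_year, t$relabund_species[, "sp002"],
                method = "spearman"), 0.3)
  expect_gt(cor(t$physio$total_acid, t$relabund_species[, "sp003"],
                method = "spearman"), 0.3)
  # total acid and pH anticorrelated by design
  expect_lt(cor(t$physio$total_acid, t$physio$pH), 0)
})

test_that("ground-truth signs match Spearman signs of source vs target in the noiseless limit", {
  eff <- rbind(planted_effect("m001", "aging_year", "linear", 1.0),
               planted_effect("m002", "aging_year", "saturating", -0.8),
               planted_effect("m003", "index:total_acid", "linear", 0.9),
               planted_effect("m004", "index:pH", "linear", -1.1),
               planted_effect("m005", "taxon:sp005", "linear", 1.0))
  cfg <- sim_config(n_metabolites = 5, effect_table = eff, noise_sd = 0,
                    censor_quantile = 0, n_rare_metabolites = 0, seed = 9)
  sim <- generate_dataset(cfg)
  t <- sim$tables
  src <- list(m001 = t$metadata$aging_year, m002 = t$metadata$aging_year,
              m003 = t$physio$total_acid, m004 = t$physio$pH,
              m005 = t$relabund_species[, "sp005"])
  for (m in names(src)) {
    planted <- sim$ground_truth$sign[sim$ground_truth$metabolite == m]
    observed <- sign(cor(src[[m]], t$metabolites[, m], method = "spearman"))
    expect_equal(observed, planted, info = m)
  }
})

test_that("interaction effects carry an undefined (NA) monotone sign", {
  eff <- planted_effect("m001", "aging_year", "interaction", 1, "taxon:sp002")
  cfg <- sim_config(n_metabolites = 1, effect_table = eff,
                    n_rare_metabolites = 0, seed = 2)
  gt <- generate_dataset(cfg)$ground_truth
  expect_true(is.na(gt$sign[1]))
})

test_that("censoring removes exactly the lowest values", {
  set.seed(1)
  x <- matrix(rnorm(100, 10), 100, 1, dimnames = list(NULL, "m"))
  out <- inject_missingness(x, 0.2)
  expect_equal(sum(is.na(out)), 20)
  expect_true(max(x[is.na(out)]) <= min(out, na.rm = TRUE))
  # identity at zero
  expect_equal(inject_missingness(x, 0), x)
  # all-equal column: tie rule censors exactly floor(q*n), by row index
  xeq <- matrix(5, 100, 1)
  oeq <- inject_missingness(xeq, 0.2)
  expect_equal(which(is.na(oeq[, 1])), 1:20)
  expect_error(inject_missingness(x, 1), "censor_quantile")
})

test_that("config validation rejects inconsistent setups", {
  expect_error(sim_config(dominant_taxon_mean_fraction = 1.2), "dominant")
  expect_error(planted_effect("m1", "aging_year", "linear", 0), "nonzero")
  bad <- planted_effect("m001", "taxon:sp999", "linear", 1)
  expect_error(sim_config(n_taxa_species = 20, effect_table = bad),
               "beyond n_taxa_species")
  expect_error(sim_config(n_metabolites = 1,
                          effect_table = default_effect_table(80)),
               "n_metabolites")
})
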