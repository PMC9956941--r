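test_that("measurement filter keeps exactly the sufficiently measured metabolites", {
  m <- matrix(1, 100, 3, dimnames = list(NULL, c("A", "B", "C")))
  m[51:100, 2] <- NA          # B: 50 non-missing
  m[50:100, 3] <- NA          # C: 49 non-missing
  f <- filter_metabolites(m, 50)
  expect_equal(colnames(f$metabolites), c("A", "B"))
  expect_equal(f$dropped, "C")
  # threshold 0 is the identity
  expect_equal(filter_metabolites(m, 0)$metabolites, m)
  # an all-missing column never survives a threshold >= 1
  m[, 1] <- NA
  expect_true("A" %in% filter_metabolites(m, 1)$dropped)
  expect_error(filter_metabolites(matrix(NA_real_, 5, 1), 1), "no metabolites")
})

test_that("imputation uses the per-metabolite minimum and z-scores use sample sd", {
  m <- matrix(c(10, 100, 1000), 3, 1, dimnames = list(NULL, "A"))
  z <- impute_and_standardize(m)
  expect_equal(as.numeric(z), c(-1, 0, 1))  # log10 -> {1,2,3}, sample sd = 1
  m2 <- matrix(c(5, NA, 5000), 3, 1, dimnames = list(NULL, "A"))
  z2 <- impute_and_standardize(m2)
  # the missing value imputes to 5, so rows 1 and 2 standardize identically
  expect_equal(z2[1, 1], z2[2, 1])
  # columns come out centered and scaled
  sim <- generate_dataset(tiny_sim_config())
  z3 <- impute_and_standardize(sim$tables$metabolites)
  expect_true(all(abs(colMeans(z3)) < 1e-9))
  expect_true(all(abs(apply(z3, 2, sd) - 1) < 1e-9))
  # errors name the metabolite
  expect_error(impute_and_standardize(matrix(c(-1, 2), 2, 1,
                                             dimnames = list(NULL, "bad"))),
               "bad")
  expect_error(impute_and_standardize(matrix(c(7, 7, 7), 3, 1,
                                             dimnames = list(NULL, "flat"))),
               "constant")
})

test_that("storage-time residualization removes the time trend", {
  n <- 110
  set.seed(4)
  tm <- sample(c(3, 8, 10, 20, 25), n, replace = TRUE)
  lin <- .5 * tm + 2                     # exactly linear in storage time
  noisy <- as.numeric(scale(0.8 * tm + rnorm(n)))
  orth <- as.numeric(scale(residuals(lm(rnorm(n) ~ tm))))
  m <- cbind(lin = lin, noisy = noisy, orth = orth)
  r <- residualize_storage_time(m, tm)
  expect_equal(unname(r[, "lin"]), rep(0, n))
  expect_equal(attr(r, "constant_after_residualization"), "lin")
  expect_lt(abs(cor(r[, "noisy"], tm, method = "spearman")), 0.1)
  expect_equal(unname(r[, "orth"]), orth, tolerance = 1e-8)
  expect_error(residualize_storage_time(m, tm[-1]), "storage_time")
})

test_that("taxa filter applies both thresholds strictly and is idempotent", {
  n <- 100
  rel <- matrix(0, n, 3, dimnames = list(NULL, c("t1", "t2", "t3")))
  rel[1:20, 1] <- 0.01    # mean 0.002, 20 nonzero samples -> kept
  rel[1:10, 2] <- 0.02    # mean 0.002, 10 nonzero samples -> dropped (> 10 strict)
  rel[, 3] <- 1 - rowSums(rel[, 1:2])
  f <- filter_taxa(rel, 0.001, 10)
  expect_equal(colnames(f$relabund), c("t1", "t3"))
  expect_equal(f$dropped, "t2")
  # zero thresholds keep every taxon seen at least once
  expect_equal(ncol(filter_taxa(rel, 0, 0)$relabund), 3)
  # idempotence
  f2 <- filter_taxa(f$relabund, 0.001, 10)
  expect_equal(f2$relabund, f$relabund)
})

test_that("clr matches its closed forms and definitional identities", {
  expect_equal(as.numeric(clr_transform(matrix(1 / 4, 1, 4))), rep(0, 4))
  got <- as.numeric(clr_transform(matrix(c(0.5, 0.25, 0.25), 1, 3)))
  expect_equal(got, c(2 * log(2) / 3, -log(2) / 3, -log(2) / 3),
               tolerance = 1e-12)
  set.seed(2)
  rel <- matrix(runif(50), 10, 5)
  rel <- rel / rowSums(rel)
  rel[1, 2] <- 0
  rel[1, ] <- rel[1, ] / sum(rel[1, ])
  z <- clr_transform(rel)
  expect_true(all(abs(rowSums(z)) < 1e-9))
  # scale invariance clr(c * x) = clr(x) on positive compositions (replaced
  # zeros are pinned at the replacement value, so rows with zeros are exempt)
  pos <- rel[-1, , drop = FALSE]
  expect_equal(clr_transform(3.7 * pos), clr_transform(pos), tolerance = 1e-9)
  expect_error(clr_transform(matrix(-1, 1, 2)), "nonnegative")
})

test_that("alpha diversity matches closed forms", {
  one <- matrix(c(100), 1, 1)
  d1 <- alpha_diversity(one)
  expect_equal(unlist(d1), c(chao1 = 1, shannon = 0, simpson = 0))
  unif <- matrix(25, 1, 4)
  d4 <- alpha_diversity(unif)
  expect_equal(d4$shannon, 2)        # 2 bits
  expect_equal(d4$simpson, 0.75)
  expect_equal(d4$chao1, 4)
  mix <- matrix(c(1, 1, 2, 5), 1, 4)
  expect_equal(alpha_diversity(mix)$chao1, 4.5)  # 4 + 2*1/(2*(1+1))
  expect_equal(alpha_diversity(mix, chao1_bias_corrected = FALSE)$chao1, 6)
  # chao1 >= observed richness; shannon maximal for the uniform profile
  set.seed(8)
  cts <- matrix(rpois(60, 3), 10, 6)
  cts[rowSums(cts) == 0, 1] <- 1
  d <- alpha_diversity(cts)
  expect_true(all(d$chao1 >= rowSums(cts > 0)))
  expect_true(all(d$shannon <= log2(6) + 1e-12))
  expect_true(all(d$simpson >= 0 & d$simpson <= 1))
  expect_error(alpha_diversity(matrix(0, 1, 3)), "positive count")
})

test_that("preprocess_tables wires the stages together and logs drops", {
  sim <- generate_dataset(sim_config(seed = 13))
  prep <- suppressMessages(preprocess_tables(sim$tables))
  expect_s3_class(prep, "preprocessed_tables")
  expect_equal(length(prep$log$metabolites_dropped), 3)  # the rare metabolites
  expect_true(all(abs(rowSums(prep$clr_species)) < 1e-9))
  expect_true(all(abs(colMeans(prep$metabolites)) < 1e-9))
  expect_lt(ncol(prep$clr_species), ncol(sim$tables$relabund_species))
})
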