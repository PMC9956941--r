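test_that("explained variance and R-squared match their closed forms", {
  y <- c(1, 2, 3)
  expect_equal(explained_variance(y, y), 1)
  expect_equal(explained_variance(y, rep(mean(y), 3)), 0)
  expect_equal(explained_variance(y, c(1, 2, 4)), 2 / 3)  # sample variance
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(y, c(2, 2, 2)), 0)
  expect_error(explained_variance(c(1, 1), c(1, 2)), "constant")
  expect_error(r_squared(c(1, 1), c(1, 2)), "undefined")
  # the two scores coincide when the residual has zero mean
  set.seed(1)
  yy <- rnorm(50)
  resid <- rnorm(50)
  resid <- resid - mean(resid)
  expect_equal(explained_variance(yy, yy - resid),
               r_squared(yy, yy - resid), tolerance = 1e-9)
})

test_that("cross-validation partitions every sample exactly once and is deterministic", {
  set.seed(5)
  X <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- X[, 1] + rnorm(60, 0, 0.3)
  cv1 <- cross_validated_predict(X, y, learner_spec("random_forest"), seed = 9)
  cv2 <- cross_validated_predict(X, y, learner_spec("random_forest"), seed = 9)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$oof, cv2$oof)
  expect_equal(sort(unique(cv1$folds)), 1:5)
  expect_equal(tabulate(cv1$folds), rep(12, 5))
  expect_error(cross_validated_predict(X[1:8, ], y[1:8],
                                       learner_spec("lasso"), k = 5),
               "2k samples")
  expect_error(cross_validated_predict(X, rep(1, 60), learner_spec("lasso")),
               "zero variance")
})

test_that("lasso recovers a noiseless linear signal through the search", {
  set.seed(2)
  X <- matrix(rnorm(110 * 6), 110, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- 1.5 * X[, 3]
  cv <- cross_validated_predict(X, y, learner_spec("lasso"), seed = 3,
                                keep_models = FALSE)
  expect_gte(cv$ev, 0.99)
})

test_that("pure-noise metabolites score near zero out of fold", {
  set.seed(6)
  X <- matrix(rnorm(110 * 6), 110, 6, dimnames = list(NULL, paste0("f", 1:6)))
  evs <- vapply(1:8, function(i) {
    y <- rnorm(110)
    cross_validated_predict(X, y, learner_spec("random_forest"), seed = i,
                            keep_models = FALSE)$ev
  }, numeric(1))
  expect_true(mean(evs <= 0.1) >= 7 / 8)
})

test_that("learner comparison tabulates predicted counts and deltas", {
  sim <- generate_dataset(tiny_sim_config())
  prep <- suppressMessages(preprocess_tables(sim$tables,
    preprocess_config(metabolite_min_measurements = 10, taxa_min_measurements = 3)))
  X <- assemble_features("PI", prep)
  mets <- prep$metabolites[, c("m001", "m003"), drop = FALSE]
  learners <- list(rf = learner_spec("random_forest"), lasso = learner_spec("lasso"))
  cmp <- compare_learners(mets, X, learners, runs = 2, seed = 4)
  expect_equal(nrow(cmp$counts), 4)                     # 2 learners x 2 runs
  expect_true(all(cmp$counts$n_predicted_r2 %in% 0:2))
  expect_equal(sort(unique(cmp$deltas$metabolite)), c("m001", "m003"))
  expect_equal(nrow(cmp$per_metabolite), 8)
  # same seed, same output
  cmp2 <- compare_learners(mets, X, learners, runs = 2, seed = 4)
  expect_identical(cmp$counts, cmp2$counts)
  # single metabolite, single learner: one count per run, in {0, 1}
  cmp1 <- compare_learners(mets[, 1, drop = FALSE], X,
                           learners["rf"], runs = 1, seed = 4)
  expect_equal(nrow(cmp1$counts), 1)
  expect_true(cmp1$counts$n_predicted_r2 %in% 0:1)
})

test_that("nested feature groups do not lose explained variance for microbial metabolites", {
  # FM contains the taxa features PI lacks; over seeds, the median EV of a
  # taxon-driven metabolite under FM must be at least that under PI
  evs <- vapply(1:6, function(s) {
    sim <- generate_dataset(tiny_sim_config(seed = 200 + s))
    prep <- suppressMessages(preprocess_tables(sim$tables,
      preprocess_config(metabolite_min_measurements = 10, taxa_min_measurements = 3)))
    y <- prep$metabolites[, "m002"]  # planted on taxon sp005
    c(fm = cross_validated_predict(assemble_features("FM", prep), y,
                                   learner_spec("random_forest"), seed = s,
                                   keep_models = FALSE)$ev,
      pi = cross_validated_predict(assemble_features("PI", prep), y,
                                   learner_spec("random_forest"), seed = s,
                                   keep_models = FALSE)$ev)
  }, numeric(2))
  expect_gte(median(evs["fm", ]), median(evs["pi", ]))
})
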