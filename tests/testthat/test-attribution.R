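test_that("a single-node tree attributes nothing and its base is the constant", {
  tr <- make_tree(left = -1, right = -1, var = -1, split = 0,
                  value = 4.2, cover = 10)
  phi <- huangjiuML:::treeshap_cpp(list(tr), matrix(rnorm(6), 3, 2))
  expect_equal(unname(phi), matrix(0, 3, 2))
})

test_that("TreeSHAP equals brute-force Shapley enumeration on a hand-built tree", {
  # depth-2 tree on 2 of 4 features: root splits f1 at 0, children split f2
  tr <- make_tree(left = c(1, 3, 5, -1, -1, -1, -1),
                  right = c(2, 4, 6, -1, -1, -1, -1),
                  var = c(0, 1, 1, -1, -1, -1, -1),
                  split = c(0, -0.5, 0.5, 0, 0, 0, 0),
                  value = c(0, 0, 0, 1, 2, 5, 9),
                  cover = c(100, 60, 40, 20, 40, 25, 15))
  set.seed(3)
  X <- matrix(rnorm(4 * 4), 4, 4)
  phi <- huangjiuML:::treeshap_cpp(list(tr), X)
  for (s in 1:4)
    expect_equal(unname(phi[s, ]), oracle_shap(list(tr), X[s, ], 4),
                 tolerance = 1e-10)
})

test_that("TreeSHAP matches the brute-force oracle on fitted shallow ensembles", {
  set.seed(7)
  n <- 80
  p <- 5
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- X[, 1] * (X[, 2] > 0) + 0.5 * X[, 3] + rnorm(n, 0, 0.1)

  rf <- fit_learner(learner_spec("random_forest", params = list(
    num.trees = 5, max.depth = 2, mtry = 3)), X, y, seed = 1)
  gb <- fit_learner(learner_spec("gradient_boosting", search = FALSE,
                                 params = list(nrounds = 4, max_depth = 2,
                                               eta = 0.5)), X, y, seed = 1)
  for (model in list(rf, gb)) {
    ens <- huangjiuML:::.as_ensemble(model)
    got <- tree_shap(model, X[1:6, ])
    for (s in 1:6)
      expect_equal(unname(got$shap[s, ]),
                   oracle_shap(ens$trees, X[s, ], p), tolerance = 1e-6)
  }
})

test_that("local accuracy holds for every sample of full-size fitted models", {
  set.seed(8)
  X <- matrix(rnorm(100 * 8), 100, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- X[, 1] - 0.7 * X[, 2] + 0.3 * X[, 3] * X[, 4] + rnorm(100, 0, 0.2)

  rf <- fit_learner(learner_spec("random_forest"), X, y, seed = 2)
  ts <- tree_shap(rf, X)
  expect_lt(max(abs(ts$base + rowSums(ts$shap) - predict_learner(rf, X))), 1e-6)

  gb <- fit_learner(learner_spec("gradient_boosting", search = FALSE), X, y,
                    seed = 2)
  tsb <- tree_shap(gb, X)
  ens <- huangjiuML:::.as_ensemble(gb)
  fx <- huangjiuML:::tree_predict_cpp(ens$trees, X) + ens$offset
  # exact against the ensemble function; float32 storage limits agreement
  # with the library's own prediction path
  expect_lt(max(abs(tsb$base + rowSums(tsb$shap) - fx)), 1e-6)
  expect_lt(max(abs(fx - predict_learner(gb, X))), 5e-6)
})

test_that("TreeSHAP agrees with the xgboost reference implementation", {
  set.seed(9)
  X <- matrix(rnorm(90 * 6), 90, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- X[, 1] + X[, 2]^2 + rnorm(90, 0, 0.3)
  gb <- fit_learner(learner_spec("gradient_boosting", search = FALSE,
                                 params = list(nrounds = 60)), X, y, seed = 3)
  ts <- tree_shap(gb, X)
  ref <- predict(gb$fit, xgboost::xgb.DMatrix(X, nthread = 1),
                 predcontrib = TRUE)
  expect_lt(max(abs(ref[, 1:6] - ts$shap)), 1e-5)
  expect_lt(abs(ref[1, 7] - ts$base), 1e-5)
})

test_that("lasso models are rejected for SHAP attribution", {
  set.seed(10)
  X <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, paste0("f", 1:3)))
  m <- fit_learner(learner_spec("lasso"), X, X[, 1], seed = 1)
  expect_error(tree_shap(m, X), "unsupported model")
})

test_that("directional attribution recovers a planted positive driver", {
  set.seed(11)
  n <- 110
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- as.numeric(scale(X[, 4]))          # single positive noiseless driver
  cv <- cross_validated_predict(X, y, learner_spec("gradient_boosting",
                                                   search = FALSE), seed = 5)
  att <- directional_attribution(cv, X, y)
  expect_equal(att$feature[which.max(att$directional_mean_abs_shap)], "f4")
  expect_gt(att$directional_mean_abs_shap[4], 0)
  # irrelevant features carry only residual attribution (held-out-fold SHAP
  # picks up a little approximation noise at n = 110), an order of magnitude
  # below the driver
  expect_true(all(att$mean_abs_shap[-4] < 0.05))
  expect_gt(att$mean_abs_shap[4], 10 * max(att$mean_abs_shap[-4]))
  # |directional| = mean_abs wherever the sign is nonzero
  nz <- att$spearman_sign != 0
  expect_equal(abs(att$directional_mean_abs_shap[nz]), att$mean_abs_shap[nz])
})

test_that("attribution is invariant to the raw concentration scale", {
  sim <- generate_dataset(tiny_sim_config())
  raw <- sim$tables$metabolites[, "m002", drop = FALSE]
  y1 <- impute_and_standardize(raw)[, 1]
  y2 <- impute_and_standardize(raw * 1000)[, 1]
  expect_equal(y1, y2, tolerance = 1e-12)  # log10 shift removed by z-scoring
  prep <- tiny_prep()
  X <- assemble_features("AMS", prep)
  cv1 <- cross_validated_predict(X, y1, learner_spec("random_forest"), seed = 3)
  cv2 <- cross_validated_predict(X, y2, learner_spec("random_forest"), seed = 3)
  a1 <- directional_attribution(cv1, X, y1)
  a2 <- directional_attribution(cv2, X, y2)
  # identical up to floating-point-induced split flips in the forests
  expect_identical(a1$spearman_sign, a2$spearman_sign)
  expect_lt(max(abs(a1$mean_abs_shap - a2$mean_abs_shap)), 5e-3)
})

test_that("constant features get Spearman sign zero with a warning", {
  set.seed(12)
  X <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(NULL, c("a", "b", "cst")))
  X[, "cst"] <- 1
  y <- X[, 1]
  cv <- cross_validated_predict(X, y, learner_spec("random_forest"), seed = 1)
  expect_warning(att <- directional_attribution(cv, X, y), "cst")
  expect_equal(att$spearman_sign[att$feature == "cst"], 0L)
  expect_equal(att$directional_mean_abs_shap[att$feature == "cst"], 0)
})
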