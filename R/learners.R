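#' Learner specification
#'
#' Declares one of the supported per-metabolite regression learners together
#' with its fixed parameters and (optionally) a random hyperparameter search.
#'
#' \describe{
#'   \item{lasso}{L1-regularized linear regression (glmnet); the search draws
#'     the regularization strength log-uniformly from \[1e-4, 10\].}
#'   \item{random_forest}{ranger with the fixed defaults 100 trees, max depth
#'     5, min samples per leaf 5, min samples to split 2, mtry 10 (capped at
#'     the number of columns); variance splitting. Search disabled by default
#'     since the parameters are fixed; when enabled it draws mtry, leaf size
#'     and depth.}
#'   \item{gradient_boosting}{xgboost with 100 rounds; the search draws
#'     learning rate (log-uniform \[0.01, 0.3\]), tree depth 2-6, minimum
#'     child weight and subsampling rate.}
#' }
#'
#' @param kind `"lasso"`, `"random_forest"` or `"gradient_boosting"`.
#' @param search run the random hyperparameter search? Defaults to `TRUE`
#'   except for the fixed-parameter random forest.
#' @param n_search number of random draws in the search (default 10).
#' @param params named list overriding individual fixed parameters.
#' @return object of class `learner_spec`.
#' @export
learner_spec <- function(kind = c("lasso", "random_forest", "gradient_boosting"),
                         search = NULL, n_search = 10, params = list()) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    lasso = list(lambda = 0.01),
    random_forest = list(num.trees = 100, max.depth = 5, min.bucket = 5,
                         min.node.size = 2, mtry = 10),
    gradient_boosting = list(nrounds = 100, eta = 0.1, max_depth = 3,
                             min_child_weight = 5, subsample = 1))
  defaults[names(params)] <- params
  if (is.null(search)) search <- kind != "random_forest"
  structure(list(kind = kind, search = search, n_search = n_search,
                 params = defaults), class = "learner_spec")
}

# one random draw from the learner's hyperparameter space (RNG state is
# assumed to be seeded by the caller)
.draw_params <- function(spec) {
  p <- spec$params
  switch(spec$kind,
    lasso = {
      p$lambda <- 10^runif(1, -4, 1)
      p
    },
    random_forest = {
      p$mtry <- sample(2:15, 1)
      p$min.bucket <- sample(c(2, 5, 10), 1)
      p$max.depth <- sample(c(3, 5, 7), 1)
      p
    },
    gradient_boosting = {
      p$eta <- 10^runif(1, -2, log10(0.3))
      p$max_depth <- sample(2:6, 1)
      p$min_child_weight <- sample(c(1, 3, 5, 10), 1)
      p$subsample <- runif(1, 0.7, 1)
      p
    })
}

#' Fit a learner on a feature matrix
#'
#' @param spec a [learner_spec()].
#' @param X numeric feature matrix.
#' @param y numeric response.
#' @param params parameter list (defaults to `spec$params`).
#' @param seed integer seed for the stochastic learners.
#' @return object of class `hj_model`.
#' @export
fit_learner <- function(spec, X, y, params = spec$params, seed = 1L) {
  X <- as.matrix(X)
  fit <- switch(spec$kind,
    lasso = glmnet::glmnet(X, y, alpha = 1, lambda = params$lambda),
    random_forest = ranger::ranger(
      x = X, y = y,
      num.trees = params$num.trees,
      max.depth = params$max.depth,
      min.bucket = params$min.bucket,
      min.node.size = params$min.node.size,
      mtry = min(params$mtry, ncol(X)),
      num.threads = 1, seed = seed, keep.inbag = TRUE),
    gradient_boosting = {
      xp <- list(eta = params$eta, max_depth = params$max_depth,
                 min_child_weight = params$min_child_weight,
                 subsample = params$subsample,
                 base_score = mean(y), nthread = 1, seed = seed)
      xgboost::xgb.train(params = xp,
                         data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
                         nrounds = params$nrounds, verbose = 0)
    })
  structure(list(kind = spec$kind, fit = fit,
                 feature_names = colnames(X),
                 train_X = if (spec$kind == "random_forest") X else NULL,
                 base_score = if (spec$kind == "gradient_boosting") mean(y) else NULL,
                 params = params),
            class = "hj_model")
}

#' Predict from a fitted learner
#'
#' @param model an `hj_model` from [fit_learner()].
#' @param X feature matrix with the training columns.
#' @return numeric vector of predictions.
#' @export
predict_learner <- function(model, X) {
  X <- as.matrix(X)[, model$feature_names, drop = FALSE]
  switch(model$kind,
    lasso = as.numeric(predict(model$fit, X)),
    random_forest = as.numeric(
      predict(model$fit, data = X, num.threads = 1)$predictions),
    gradient_boosting = as.numeric(
      predict(model$fit, xgboost::xgb.DMatrix(X, nthread = 1))))
}
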