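# --- extraction of fitted ensembles into the flat tree representation ------

# ranger forest: prediction is the mean over trees, so leaf values are
# rescaled by 1/T and trees are summed. Covers are the in-bag training
# weights routed through each tree.
.ensemble_ranger <- function(model) {
  fit <- model$fit
  ntree <- fit$num.trees
  X <- model$train_X
  trees <- vector("list", ntree)
  for (t in seq_len(ntree)) {
    ti <- ranger::treeInfo(fit, t)
    left <- as.integer(ifelse(is.na(ti$leftChild), -1L, ti$leftChild))
    right <- as.integer(ifelse(is.na(ti$rightChild), -1L, ti$rightChild))
    var <- as.integer(ifelse(is.na(ti$splitvarID), -1L, ti$splitvarID))
    split <- as.numeric(ifelse(is.na(ti$splitval), 0, ti$splitval))
    value <- as.numeric(ifelse(is.na(ti$prediction), 0, ti$prediction)) / ntree
    cover <- tree_covers_cpp(left, right, var, split, TRUE, X,
                             as.numeric(fit$inbag.counts[[t]]))
    trees[[t]] <- list(left = left, right = right, var = var, split = split,
                       value = value, cover = as.numeric(cover), le = TRUE,
                       f32 = FALSE)
  }
  list(trees = trees, offset = 0)
}

# xgboost booster: prediction is base_score + sum of tree outputs; covers are
# exported by xgboost itself.
.ensemble_xgb <- function(model) {
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = model$fit))
  valcol <- if ("Gain" %in% names(dt)) "Gain" else "Quality"
  trees <- lapply(split(dt, dt$Tree), function(d) {
    d <- d[order(d$Node), ]
    is_leaf <- d$Feature == "Leaf"
    list(left = as.integer(ifelse(is_leaf, -1L, match(d$Yes, d$ID) - 1L)),
         right = as.integer(ifelse(is_leaf, -1L, match(d$No, d$ID) - 1L)),
         var = as.integer(ifelse(is_leaf, -1L,
                                 match(d$Feature, model$feature_names) - 1L)),
         split = as.numeric(ifelse(is_leaf, 0, d$Split)),
         value = as.numeric(ifelse(is_leaf, d[[valcol]], 0)),
         cover = as.numeric(d$Cover), le = FALSE, f32 = TRUE)
  })
  list(trees = unname(trees), offset = model$base_score)
}

.as_ensemble <- function(model) {
  switch(model$kind,
         random_forest = .ensemble_ranger(model),
         gradient_boosting = .ensemble_xgb(model),
         stop("unsupported model for SHAP attribution: '", model$kind,
              "' (tree ensembles only)"))
}

#' SHAP values of a fitted tree ensemble
#'
#' Computes per-sample, per-feature Shapley values of a fitted random-forest
#' or gradient-boosting model with the polynomial-time tree-path algorithm
#' under the path-dependent (cover-weighted conditional expectation) value
#' function. Local accuracy holds: for every sample,
#' `base + sum(shap) = model prediction` (within numerical tolerance).
#'
#' @param model an `hj_model` from [fit_learner()]; must be a tree ensemble
#'   (lasso attribution is out of scope).
#' @param X feature matrix to explain (rows are explained independently).
#' @return list with `shap` (samples x features matrix) and `base` (scalar
#'   expected prediction over the training distribution).
#' @export
tree_shap <- function(model, X) {
  stopifnot(inherits(model, "hj_model"))
  ens <- .as_ensemble(model)
  X <- as.matrix(X)[, model$feature_names, drop = FALSE]
  phi <- treeshap_cpp(ens$trees, X)
  dimnames(phi) <- list(rownames(X), model$feature_names)
  base <- ens$offset + sum(vapply(ens$trees, function(tr) {
    leaf <- tr$left < 0
    sum(tr$cover[leaf] * tr$value[leaf]) / tr$cover[1]
  }, numeric(1)))
  list(shap = phi, base = base)
}

#' Directional mean-absolute SHAP attribution
#'
#' The pipeline's per-(metabolite, feature) summary statistic: SHAP values
#' are computed on the held-out fold of every cross-validation fold (so the
#' attribution reflects generalizable structure), pooled over folds, the mean
#' absolute value is taken per feature and averaged over runs, and the result
#' is signed by the Spearman correlation between the raw feature column and
#' the metabolite over all samples. Positive directional values push the
#' metabolite up, negative ones down; a zero or undefined correlation maps to
#' sign 0.
#'
#' @param cv_results a `cv_result` (or list of them, one per run) fitted with
#'   `keep_models = TRUE` and a tree-ensemble learner.
#' @param X the feature matrix used for the fits.
#' @param y the standardized metabolite.
#' @param on `"test"` (default) computes SHAP on held-out folds;
#'   `"train"` on the training folds (diagnostic switch).
#' @return object of class `attribution_result`: data.frame with columns
#'   `feature`, `mean_abs_shap`, `spearman_sign`,
#'   `directional_mean_abs_shap`.
#' @export
directional_attribution <- function(cv_results, X, y, on = c("test", "train")) {
  on <- match.arg(on)
  if (inherits(cv_results, "cv_result")) cv_results <- list(cv_results)
  X <- as.matrix(X)
  p <- ncol(X)
  run_mean_abs <- matrix(NA_real_, length(cv_results), p)
  for (r in seq_along(cv_results)) {
    cv <- cv_results[[r]]
    if (is.null(cv$models)) stop("cv_result was built with keep_models = FALSE")
    pooled <- list()
    for (f in seq_along(cv$models)) {
      rows <- if (on == "test") which(cv$folds == f) else which(cv$folds != f)
      pooled[[f]] <- tree_shap(cv$models[[f]], X[rows, , drop = FALSE])$shap
    }
    run_mean_abs[r, ] <- colMeans(abs(do.call(rbind, pooled)))
  }
  mean_abs <- colMeans(run_mean_abs)

  sgn <- vapply(seq_len(p), function(j) {
    if (sd(X[, j]) == 0) {
      warning("constant feature '", colnames(X)[j], "': Spearman sign set to 0")
      return(0)
    }
    sign(cor(X[, j], y, method = "spearman"))
  }, numeric(1))

  structure(data.frame(feature = colnames(X),
                       mean_abs_shap = mean_abs,
                       spearman_sign = as.integer(sgn),
                       directional_mean_abs_shap = mean_abs * sgn,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("attribution_result", "data.frame"))
}
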