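#' Explained variance of predictions
#'
#' `1 - Var(y - yhat) / Var(y)`, with the sample-variance (n-1) convention
#' used throughout the package. Equals 1 for perfect prediction and 0 for the
#' constant mean predictor; differs from [r_squared()] only through
#' prediction bias.
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @return a single number (can be negative).
#' @export
explained_variance <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), !anyNA(y), !anyNA(yhat))
  v <- var(y)
  if (v == 0) stop("explained variance undefined for constant y")
  1 - var(y - yhat) / v
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`; negative for
#' predictors worse than the mean.
#'
#' @inheritParams explained_variance
#' @return a single number.
#' @export
r_squared <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), !anyNA(y), !anyNA(yhat))
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("R^2 undefined for constant y")
  1 - sum((y - yhat)^2) / tss
}

#' Cross-validated out-of-fold prediction of one metabolite
#'
#' Random seeded k-fold partition; within each training fold an optional
#' random hyperparameter search (`spec$n_search` draws scored by inner 3-fold
#' cross-validated explained variance) selects the configuration, the model
#' is refit on the full training fold, and the held-out fold is predicted.
#' Every sample is predicted exactly once; scoring uses the pooled
#' out-of-fold predictions.
#'
#' @param X samples x features matrix (no missing values).
#' @param y standardized metabolite vector (no missing values).
#' @param spec a [learner_spec()].
#' @param k number of folds (default 5).
#' @param seed integer seed controlling the fold assignment, the search and
#'   the learners; identical seeds give identical results.
#' @param keep_models retain the per-fold fitted models (needed for
#'   attribution).
#' @return object of class `cv_result`: list with `oof` (out-of-fold
#'   predictions aligned to samples), `ev`, `r2`, `folds` (fold id per
#'   sample), `models` (per-fold `hj_model`s or `NULL`), `chosen_params`,
#'   `learner`, `seed`.
#' @export
cross_validated_predict <- function(X, y, spec, k = 5, seed = 1L,
                                    keep_models = TRUE) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, !anyNA(y), !anyNA(X))
  if (n < 2 * k) stop("need at least 2k samples for k-fold cross-validation")
  if (var(y) == 0) stop("degenerate metabolite: zero variance")

  set.seed(child_seed(seed, 101))
  folds <- sample(rep_len(seq_len(k), n))
  oof <- numeric(n)
  models <- vector("list", k)
  chosen <- vector("list", k)

  for (f in seq_len(k)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    params <- spec$params
    if (spec$search && spec$n_search > 0) {
      set.seed(child_seed(seed, 102, f))
      cand <- replicate(spec$n_search, .draw_params(spec), simplify = FALSE)
      inner <- sample(rep_len(1:3, length(tr)))
      score <- vapply(seq_along(cand), function(ci) {
        pin <- numeric(length(tr))
        for (g in 1:3) {
          itr <- tr[inner != g]
          ite <- tr[inner == g]
          m <- fit_learner(spec, X[itr, , drop = FALSE], y[itr],
                           params = cand[[ci]],
                           seed = child_seed(seed, 103, f, g, ci))
          pin[inner == g] <- predict_learner(m, X[ite, , drop = FALSE])
        }
        explained_variance(y[tr], pin)
      }, numeric(1))
      params <- cand[[which.max(score)]]
    }
    m <- fit_learner(spec, X[tr, , drop = FALSE], y[tr], params = params,
                     seed = child_seed(seed, 104, f))
    oof[te] <- predict_learner(m, X[te, , drop = FALSE])
    if (keep_models) models[[f]] <- m
    chosen[[f]] <- params
  }
  structure(list(oof = oof, ev = explained_variance(y, oof),
                 r2 = r_squared(y, oof), folds = folds,
                 models = if (keep_models) models,
                 chosen_params = chosen, learner = spec$kind, seed = seed),
            class = "cv_result")
}

#' Compare learners across metabolites
#'
#' Runs repeated cross-validated prediction of every metabolite with each
#' learner and tabulates, per learner and run, the number of metabolites
#' predicted above the threshold (on R-squared and on explained variance),
#' plus per-metabolite explained-variance deltas between learner pairs. Fold
#' assignments are seeded per (metabolite, run) and shared across learners so
#' learners are compared on identical partitions.
#'
#' @param metabolites standardized samples x metabolites matrix.
#' @param X feature matrix shared by all learners.
#' @param learners named list of [learner_spec()]s (>= 2 for deltas).
#' @param runs number of repeated runs (default 10).
#' @param k folds.
#' @param r2_threshold "well predicted" threshold (default 0.3).
#' @param seed global seed.
#' @return list with `counts` (learner, run, n_predicted_r2,
#'   n_predicted_ev), `summary` (mean and sd of counts per learner),
#'   `per_metabolite` (long data.frame of metabolite, learner, run, ev, r2),
#'   and `deltas` (mean EV difference per metabolite for every learner pair).
#' @export
compare_learners <- function(metabolites, X, learners, runs = 10, k = 5,
                             r2_threshold = 0.3, seed = 1L) {
  stopifnot(length(learners) >= 1, !is.null(names(learners)))
  mets <- colnames(metabolites)
  rows <- list()
  for (r in seq_len(runs)) {
    for (j in seq_along(mets)) {
      cv_seed <- child_seed(seed, 200, r, j)
      for (ln in names(learners)) {
        cv <- cross_validated_predict(X, metabolites[, j], learners[[ln]],
                                      k = k, seed = cv_seed,
                                      keep_models = FALSE)
        rows[[length(rows) + 1]] <- data.frame(
          metabolite = mets[j], learner = ln, run = r,
          ev = cv$ev, r2 = cv$r2, stringsAsFactors = FALSE)
      }
    }
  }
  per_met <- do.call(rbind, rows)
  counts <- do.call(rbind, lapply(split(per_met, per_met[c("learner", "run")]),
    function(d) data.frame(learner = d$learner[1], run = d$run[1],
                           n_predicted_r2 = sum(d$r2 > r2_threshold),
                           n_predicted_ev = sum(d$ev > r2_threshold))))
  rownames(counts) <- NULL
  summary <- do.call(rbind, lapply(split(counts, counts$learner), function(d)
    data.frame(learner = d$learner[1],
               mean_n_r2 = mean(d$n_predicted_r2), sd_n_r2 = sd(d$n_predicted_r2),
               mean_n_ev = mean(d$n_predicted_ev), sd_n_ev = sd(d$n_predicted_ev))))
  rownames(summary) <- NULL

  deltas <- NULL
  lns <- names(learners)
  if (length(lns) >= 2) {
    ev_mean <- tapply(per_met$ev, per_met[c("metabolite", "learner")], mean)
    pairs <- utils::combn(lns, 2, simplify = FALSE)
    deltas <- do.call(rbind, lapply(pairs, function(p)
      data.frame(metabolite = rownames(ev_mean), learner_a = p[1],
                 learner_b = p[2],
                 delta_ev = ev_mean[, p[1]] - ev_mean[, p[2]],
                 stringsAsFactors = FALSE)))
    rownames(deltas) <- NULL
  }
  list(counts = counts, summary = summary, per_metabolite = per_met,
       deltas = deltas, r2_threshold = r2_threshold)
}
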