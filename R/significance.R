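#' Bootstrap significance of explained variance
#'
#' Tests whether a feature group explains a metabolite better than chance. In
#' each bootstrap iteration a fresh random k-fold cross-validation is drawn;
#' within each fold the training set is resampled with replacement to its
#' original size (held-out folds are never resampled), the learner is
#' trained on the resample and scored on the untouched held-out fold, and the
#' pooled out-of-fold explained variance of the iteration is recorded. The
#' 95% confidence interval is the 2.5/97.5 percentile of the iteration EVs
#' and the one-sided p-value against the "no explanation" null is
#' `(1 + #\{EV_b <= 0\}) / (B + 1)`.
#'
#' The learner is trained at its fixed parameters (no hyperparameter search
#' inside the bootstrap); the point estimate comes from an ordinary
#' cross-validated fit under the same seed family.
#'
#' @param X feature matrix.
#' @param y standardized metabolite.
#' @param spec a [learner_spec()].
#' @param iterations number of bootstrap iterations B (default 100; a warning
#'   is issued below 20 because percentile CIs become unstable).
#' @param k folds.
#' @param alpha significance level for the `significant` flag.
#' @param seed integer seed.
#' @return object of class `bootstrap_result`: list with `ev` (point
#'   estimate), `boot_ev` (length-B vector), `ci_low`, `ci_high`, `p_value`,
#'   `significant`, `degenerate_ci` (TRUE when B == 1), `iterations`,
#'   `alpha`.
#' @export
bootstrap_significance <- function(X, y, spec, iterations = 100, k = 5,
                                   alpha = 0.05, seed = 1L) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, iterations >= 1)
  if (iterations < 20)
    warning("fewer than 20 bootstrap iterations: confidence interval unstable")
  fixed <- spec
  fixed$search <- FALSE

  point <- cross_validated_predict(X, y, fixed, k = k,
                                   seed = child_seed(seed, 300),
                                   keep_models = FALSE)

  boot_ev <- numeric(iterations)
  for (b in seq_len(iterations)) {
    set.seed(child_seed(seed, 301, b))
    folds <- sample(rep_len(seq_len(k), n))
    oof <- numeric(n)
    for (f in seq_len(k)) {
      tr <- which(folds != f)
      te <- which(folds == f)
      res <- sample(tr, length(tr), replace = TRUE)
      m <- fit_learner(fixed, X[res, , drop = FALSE], y[res],
                       seed = child_seed(seed, 302, b, f))
      oof[te] <- predict_learner(m, X[te, , drop = FALSE])
    }
    boot_ev[b] <- explained_variance(y, oof)
  }
  ci <- quantile(boot_ev, c(0.025, 0.975), names = FALSE)
  p <- (1 + sum(boot_ev <= 0)) / (iterations + 1)
  structure(list(ev = point$ev, boot_ev = boot_ev,
                 ci_low = ci[1], ci_high = ci[2],
                 p_value = p, significant = p < alpha,
                 degenerate_ci = iterations == 1,
                 iterations = iterations, alpha = alpha,
                 learner = spec$kind, seed = seed),
            class = "bootstrap_result")
}

#' Benjamini-Hochberg adjustment for a set of bootstrap results
#'
#' Optional multiple-testing correction across metabolites (off in the main
#' pipeline, which reports raw bootstrap p-values).
#'
#' @param results list of `bootstrap_result` objects.
#' @param alpha FDR level.
#' @return data.frame with `p_value`, `p_adjusted`, `significant_adjusted`.
#' @export
adjust_bootstrap_results <- function(results, alpha = 0.05) {
  p <- vapply(results, `[[`, numeric(1), "p_value")
  padj <- stats::p.adjust(p, method = "BH")
  data.frame(metabolite = names(results) %||% seq_along(results),
             p_value = p, p_adjusted = padj,
             significant_adjusted = padj < alpha)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
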