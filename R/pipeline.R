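#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run. Defaults are the pipeline's
#' standard values: measurement filter 50, taxa filters 0.1% / 10, CLR zero
#' replacement 1e-10, 5 folds, 10 search iterations, 10 runs, 100 bootstrap
#' iterations, EV threshold 0.3.
#'
#' @param input_dir directory of study tables ([read_study_tables()]); leave
#'   `NULL` to simulate.
#' @param simulate a [sim_config()] used when `input_dir` is `NULL`.
#' @param preprocess a [preprocess_config()].
#' @param feature_groups character vector of groups to run.
#' @param learner a [learner_spec()] for the per-group models (default: the
#'   fixed-parameter random forest).
#' @param runs repeated CV runs per metabolite.
#' @param k folds.
#' @param bootstrap_iterations bootstrap iterations per metabolite.
#' @param alpha significance level.
#' @param ev_threshold well-predicted threshold for the cluster map.
#' @param attribution compute directional SHAP attribution (tree learners
#'   only).
#' @param seed global seed, recorded in every output artifact.
#' @param output_dir where results are written.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL,
                            simulate = sim_config(),
                            preprocess = preprocess_config(),
                            feature_groups = c("FM", "PI", "AFS", "AMS",
                                               "AFG", "AMG"),
                            learner = learner_spec("random_forest"),
                            runs = 10,
                            k = 5,
                            bootstrap_iterations = 100,
                            alpha = 0.05,
                            ev_threshold = 0.3,
                            attribution = TRUE,
                            seed = 1L,
                            output_dir = "results") {
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input_dir does not exist: ", input_dir)
  feature_groups <- match.arg(feature_groups, feature_group_names(),
                              several.ok = TRUE)
  structure(list(input_dir = input_dir, simulate = simulate,
                 preprocess = preprocess, feature_groups = feature_groups,
                 learner = learner, runs = runs, k = k,
                 bootstrap_iterations = bootstrap_iterations, alpha = alpha,
                 ev_threshold = ev_threshold, attribution = attribution,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; `simulate`,
#' `preprocess` and `learner` may be given as nested key/value maps.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    y$simulate$effect_table <- NULL  # not expressible in flat YAML; use default
    y$simulate <- do.call(sim_config, y$simulate)
  }
  if (!is.null(y$preprocess)) y$preprocess <- do.call(preprocess_config, y$preprocess)
  if (!is.null(y$learner)) y$learner <- do.call(learner_spec, y$learner)
  do.call(pipeline_config, y)
}

#' Run the full pipeline
#'
#' Loads (or simulates) the study tables, preprocesses them, and for every
#' requested feature group fits repeated cross-validated models per
#' metabolite, runs the bootstrap significance test, and (for tree learners)
#' the directional SHAP attribution. Finally builds the descriptive layer:
#' Spearman associations of the physiochemical indexes with the metabolites,
#' the cluster map of well-predicted metabolites, and the one-way ANOVA of
#' total acid across sample clusters. All result tables and a manifest JSON
#' are written under `config$output_dir`; the run is deterministic given the
#' seed (byte-identical outputs on re-run).
#'
#' @param config a [pipeline_config()].
#' @return invisibly a list with the in-memory results (`prep`, `groups`,
#'   `reporting`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  tables <- if (is.null(config$input_dir)) {
    sim <- generate_dataset(config$simulate)
    write_study_tables(sim$tables, file.path(out, "simulated_input"),
                       ground_truth = sim$ground_truth)
    sim$tables
  } else {
    read_study_tables(config$input_dir)
  }

  prep <- preprocess_tables(tables, config$preprocess)
  mets <- colnames(prep$metabolites)

  groups <- list()
  for (g in config$feature_groups) {
    X <- assemble_features(g, prep)
    ev_rows <- list()
    boot_rows <- list()
    attr_rows <- list()
    cv_first <- list()
    for (j in seq_along(mets)) {
      y <- prep$metabolites[, j]
      cvs <- lapply(seq_len(config$runs), function(r)
        cross_validated_predict(X, y, config$learner, k = config$k,
                                seed = child_seed(config$seed, match(g, feature_group_names()), r, j),
                                keep_models = config$attribution && r == 1))
      for (r in seq_along(cvs))
        ev_rows[[length(ev_rows) + 1]] <- data.frame(
          metabolite = mets[j], group = g, learner = config$learner$kind,
          run = r, ev = cvs[[r]]$ev, r2 = cvs[[r]]$r2)
      bs <- bootstrap_significance(X, y, config$learner,
                                   iterations = config$bootstrap_iterations,
                                   k = config$k, alpha = config$alpha,
                                   seed = child_seed(config$seed, 400 + match(g, feature_group_names()), j))
      boot_rows[[j]] <- data.frame(metabolite = mets[j], group = g,
                                   ev = bs$ev, ci_low = bs$ci_low,
                                   ci_high = bs$ci_high, p_value = bs$p_value,
                                   significant = bs$significant)
      if (config$attribution &&
          config$learner$kind %in% c("random_forest", "gradient_boosting")) {
        att <- directional_attribution(cvs[[1]], X, y)
        att$metabolite <- mets[j]
        att$group <- g
        attr_rows[[length(attr_rows) + 1]] <- att
      }
      cv_first[[j]] <- cvs[[1]]$ev
    }
    ev_tab <- do.call(rbind, ev_rows)
    boot_tab <- do.call(rbind, boot_rows)
    attr_tab <- if (length(attr_rows)) do.call(rbind, attr_rows)
    gdir <- file.path(out, g)
    dir.create(gdir, showWarnings = FALSE)
    write.table(ev_tab, file.path(gdir, "ev_r2.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(boot_tab, file.path(gdir, "bootstrap.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(attr_tab)) {
      write.table(attr_tab, file.path(gdir, "attribution.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      wide <- tapply(attr_tab$directional_mean_abs_shap,
                     attr_tab[c("feature", "metabolite")], identity)
      .write_matrix_tsv(t(wide), file.path(gdir, "attribution_directional_matrix.tsv"))
    }
    mean_ev <- tapply(ev_tab$ev, ev_tab$metabolite, mean)[mets]
    groups[[g]] <- list(features = X, ev = ev_tab, bootstrap = boot_tab,
                        attribution = attr_tab, mean_ev = mean_ev)
  }

  ## descriptive layer: associations, cluster map, ANOVA across clusters
  ref_group <- if ("PI" %in% names(groups)) "PI" else names(groups)[1]
  mean_ev <- groups[[ref_group]]$mean_ev
  assoc <- spearman_association(
    cbind(prep$physio[, c("total_acid", "amino_nitrogen", "reducing_sugar",
                          "pH", "conductivity")],
          aging_year = prep$metadata$aging_year),
    prep$metabolites)
  rep_dir <- file.path(out, "reporting")
  dir.create(rep_dir, showWarnings = FALSE)
  .write_matrix_tsv(assoc$rho, file.path(rep_dir, "spearman_rho.tsv"))
  .write_matrix_tsv(assoc$p, file.path(rep_dir, "spearman_p.tsv"))
  cm <- NULL
  anova_res <- NULL
  if (sum(mean_ev > config$ev_threshold, na.rm = TRUE) >= 2) {
    cm <- cluster_metabolite_map(prep$metabolites, mean_ev,
                                 threshold = config$ev_threshold)
    write_cluster_map(cm, rep_dir)
    anova_res <- anova_by_cluster(prep$physio$total_acid, cm$sample_clusters)
    write.table(data.frame(index = "total_acid", f = anova_res$f,
                           p = anova_res$p),
                file.path(rep_dir, "anova_total_acid.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("huangjiuML")),
    input = if (is.null(config$input_dir)) "simulated" else config$input_dir,
    feature_groups = config$feature_groups,
    learner = config$learner$kind,
    runs = config$runs, k = config$k,
    bootstrap_iterations = config$bootstrap_iterations,
    alpha = config$alpha, ev_threshold = config$ev_threshold,
    stages = c("load", "preprocess",
               paste0("model:", config$feature_groups),
               "bootstrap", if (config$attribution) "attribution",
               "reporting"),
    dropped = prep$log)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(prep = prep, groups = groups,
                 reporting = list(association = assoc, cluster_map = cm,
                                  anova_total_acid = anova_res),
                 manifest = manifest))
}
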