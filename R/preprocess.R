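#' Preprocessing configuration
#'
#' Thresholds and switches for metabolite/taxa quality control. Defaults are
#' the conventional ones for this kind of cohort: metabolites kept when
#' measured in at least 50 samples; taxa kept above 0.1% mean relative
#' abundance and more than 10 nonzero measurements (both strict); CLR zeros
#' replaced by 1e-10.
#'
#' @param metabolite_min_measurements minimum non-missing values per
#'   metabolite (kept when `>=` this count).
#' @param taxa_min_mean_abundance mean relative-abundance threshold (strict
#'   `>`).
#' @param taxa_min_measurements nonzero-sample threshold (strict `>`).
#' @param clr_zero_replacement value substituted for zeros before the CLR.
#' @param residualize_on_storage_time if `TRUE`, metabolites are replaced by
#'   OLS residuals on storage time after standardization (off by default:
#'   aging year is itself a predictor downstream).
#' @param shannon_base logarithm base for the Shannon index (2 = bits).
#' @param chao1_bias_corrected use the small-sample (F2+1) form of Chao1.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(metabolite_min_measurements = 50,
                              taxa_min_mean_abundance = 0.001,
                              taxa_min_measurements = 10,
                              clr_zero_replacement = 1e-10,
                              residualize_on_storage_time = FALSE,
                              shannon_base = 2,
                              chao1_bias_corrected = TRUE) {
  stopifnot(metabolite_min_measurements >= 0, taxa_min_mean_abundance >= 0,
            taxa_min_measurements >= 0, clr_zero_replacement > 0)
  structure(as.list(environment()), class = "preprocess_config")
}

#' Filter metabolites by measurement count
#'
#' Keeps exactly the metabolites with at least `min_measurements` non-missing
#' values ("metabolites with less than N measurements are removed"); column
#' order is preserved.
#'
#' @param metabolites samples x metabolites matrix, NAs allowed.
#' @param min_measurements minimum number of non-missing values.
#' @return list with `metabolites` (filtered matrix) and `dropped` (character
#'   vector of removed metabolite IDs, for logging).
#' @export
filter_metabolites <- function(metabolites, min_measurements = 50) {
  m <- as.matrix(metabolites)
  keep <- colSums(!is.na(m)) >= min_measurements
  if (!any(keep)) stop("no metabolites survive the measurement filter")
  list(metabolites = m[, keep, drop = FALSE],
       dropped = colnames(m)[!keep])
}

#' Impute missing metabolite values and standardize
#'
#' Missing values are imputed as the per-metabolite minimum of the observed
#' values (the detection-limit convention), levels are log10-transformed, and
#' each metabolite is z-scored (sample sd, n-1 denominator). Output columns
#' have mean 0 and sd 1.
#'
#' @param metabolites samples x metabolites matrix of positive values, NAs
#'   allowed.
#' @return standardized matrix of the same shape.
#' @export
impute_and_standardize <- function(metabolites) {
  m <- as.matrix(metabolites)
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    obs <- x[!is.na(x)]
    if (!length(obs)) stop("metabolite '", colnames(m)[j], "' has no observed values")
    if (any(obs <= 0))
      stop("metabolite '", colnames(m)[j], "' has nonpositive values; log10 undefined")
    x[is.na(x)] <- min(obs)
    x <- log10(x)
    s <- sd(x)
    if (s == 0)
      stop("metabolite '", colnames(m)[j], "' is constant after log transform")
    out[, j] <- (x - mean(x)) / s
  }
  out
}

#' Residualize metabolites on storage time
#'
#' Replaces each (standardized) metabolite by the residuals of an OLS fit on
#' storage time, then re-standardizes. Metabolites that are exactly linear in
#' storage time become all-zero columns and are flagged in the
#' `"constant_after_residualization"` attribute rather than erroring.
#'
#' @param metabolites standardized samples x metabolites matrix, no NAs.
#' @param storage_time numeric vector, one value per sample (aging years).
#' @return matrix of re-standardized residuals.
#' @export
residualize_storage_time <- function(metabolites, storage_time) {
  m <- as.matrix(metabolites)
  if (length(storage_time) != nrow(m) || anyNA(storage_time))
    stop("storage_time must be complete and match the number of samples")
  flat <- character()
  out <- m
  for (j in seq_len(ncol(m))) {
    r <- residuals(lm(m[, j] ~ storage_time))
    s <- sd(r)
    if (s < 1e-12) {
      out[, j] <- 0
      flat <- c(flat, colnames(m)[j])
    } else {
      out[, j] <- (r - mean(r)) / s
    }
  }
  attr(out, "constant_after_residualization") <- flat
  out
}

#' Filter taxa by mean abundance and prevalence
#'
#' Keeps taxa with mean relative abundance strictly greater than
#' `min_mean_abundance` and strictly more than `min_measurements` samples with
#' nonzero abundance. Rows are not renormalized afterwards: the downstream CLR
#' is scale-invariant, so renormalization would not change the result.
#'
#' @param relabund samples x taxa relative-abundance matrix (rows on the
#'   simplex).
#' @param min_mean_abundance strict mean-abundance threshold.
#' @param min_measurements strict nonzero-sample threshold.
#' @return list with `relabund` (filtered matrix) and `dropped` (character
#'   vector of removed taxa).
#' @export
filter_taxa <- function(relabund, min_mean_abundance = 0.001,
                        min_measurements = 10) {
  m <- as.matrix(relabund)
  keep <- colMeans(m) > min_mean_abundance & colSums(m > 0) > min_measurements
  list(relabund = m[, keep, drop = FALSE], dropped = colnames(m)[!keep])
}

#' Centered log-ratio transform
#'
#' Per sample, zeros are replaced by `zero_replacement` and
#' `clr_i = ln(x_i) - mean_j ln(x_j)` is computed over the retained taxa of
#' that row. Rows of the output sum to 0; the transform is invariant to
#' rescaling of a row.
#'
#' @param relabund samples x taxa matrix of nonnegative values.
#' @param zero_replacement positive value substituted for zeros.
#' @return CLR-transformed matrix of the same shape.
#' @export
clr_transform <- function(relabund, zero_replacement = 1e-10) {
  m <- as.matrix(relabund)
  if (any(m < 0)) stop("relative abundances must be nonnegative")
  stopifnot(zero_replacement > 0)
  m <- pmax(m, zero_replacement)
  lg <- log(m)
  sweep(lg, 1, rowMeans(lg), `-`)
}

#' Alpha-diversity indices per sample
#'
#' Chao1 richness (bias-corrected small-sample form by default:
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, with F1/F2 the singleton/doubleton
#' counts; classical form `S_obs + F1^2 / (2 F2)` available), Shannon entropy
#' (base 2 by default, i.e. bits) and the Gini-Simpson index
#' `1 - sum p_i^2`, all computed from a count table.
#'
#' @param counts samples x taxa matrix of nonnegative integer counts; every
#'   sample must have at least one positive count.
#' @param shannon_base logarithm base for Shannon.
#' @param chao1_bias_corrected if `FALSE`, the classical Chao1 form is used
#'   (with `F1^2 / (2 F2)` taken as 0 when no doubletons exist).
#' @return data.frame with columns `chao1`, `shannon`, `simpson`, one row per
#'   sample.
#' @export
alpha_diversity <- function(counts, shannon_base = 2,
                            chao1_bias_corrected = TRUE) {
  m <- as.matrix(counts)
  if (any(m < 0)) stop("counts must be nonnegative")
  if (any(rowSums(m) == 0)) stop("every sample needs at least one positive count")
  shannon <- vegan::diversity(m, index = "shannon", base = shannon_base)
  simpson <- vegan::diversity(m, index = "simpson")
  f1 <- rowSums(m == 1)
  f2 <- rowSums(m == 2)
  s_obs <- rowSums(m > 0)
  chao1 <- if (chao1_bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    s_obs + ifelse(f2 > 0, f1^2 / (2 * f2), 0)
  }
  data.frame(chao1 = chao1, shannon = as.numeric(shannon),
             simpson = as.numeric(simpson), row.names = rownames(m))
}

#' Run the full preprocessing stage on a study-table bundle
#'
#' Applies, in order: the metabolite measurement filter, minimum imputation +
#' log10 z-scoring (+ optional storage-time residualization), the taxa
#' abundance/prevalence filters at both annotation levels, the CLR transform,
#' and alpha diversity on species- and genus-level counts.
#'
#' @param tables a `study_tables` bundle (see [generate_dataset()]).
#' @param config a [preprocess_config()].
#' @return list of class `preprocessed_tables` with elements `metabolites`
#'   (standardized matrix), `clr_species`, `clr_genus`, `diversity_species`,
#'   `diversity_genus`, `physio`, `metadata`, and `log` (dropped IDs per
#'   filter).
#' @export
preprocess_tables <- function(tables, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  validate_study_tables(tables)
  fm <- filter_metabolites(tables$metabolites, config$metabolite_min_measurements)
  met <- impute_and_standardize(fm$metabolites)
  if (config$residualize_on_storage_time)
    met <- residualize_storage_time(met, tables$metadata$aging_year)
  ft_s <- filter_taxa(tables$relabund_species, config$taxa_min_mean_abundance,
                      config$taxa_min_measurements)
  ft_g <- filter_taxa(tables$relabund_genus, config$taxa_min_mean_abundance,
                      config$taxa_min_measurements)
  structure(list(
    metabolites = met,
    clr_species = clr_transform(ft_s$relabund, config$clr_zero_replacement),
    clr_genus = clr_transform(ft_g$relabund, config$clr_zero_replacement),
    diversity_species = alpha_diversity(tables$counts_species,
                                        config$shannon_base,
                                        config$chao1_bias_corrected),
    diversity_genus = alpha_diversity(tables$counts_genus,
                                      config$shannon_base,
                                      config$chao1_bias_corrected),
    physio = tables$physio,
    metadata = tables$metadata,
    log = list(metabolites_dropped = fm$dropped,
               species_dropped = ft_s$dropped,
               genera_dropped = ft_g$dropped)
  ), class = "preprocessed_tables")
}
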