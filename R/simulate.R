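#' Planted feature-to-metabolite effect
#'
#' Describes one ground-truth driver of a synthetic metabolite: the source
#' variable (aging year, a taxon, or a physiochemical index), the functional
#' form on the standardized scale, and a signed coefficient.
#'
#' @param target_metabolite metabolite identifier, e.g. `"m007"`.
#' @param source one of `"aging_year"`, `"taxon:<species id>"`,
#'   `"index:<physio column>"`.
#' @param form `"linear"`, `"saturating"` (x/(1+|x|)), `"threshold"`
#'   (indicator x > median), or `"interaction"` (product with `source2`).
#' @param coefficient signed effect size on the standardized scale; nonzero.
#' @param source2 second source, required for `form = "interaction"`.
#' @return a one-row data.frame usable in `sim_config()$effect_table`.
#' @export
planted_effect <- function(target_metabolite, source, form, coefficient,
                           source2 = NA_character_) {
  stopifnot(is.character(target_metabolite), length(target_metabolite) == 1)
  form <- match.arg(form, c("linear", "saturating", "threshold", "interaction"))
  if (coefficient == 0) stop("planted effect coefficient must be nonzero")
  if (form == "interaction" && is.na(source2))
    stop("interaction effects need a second source")
  data.frame(metabolite = target_metabolite, source = source, source2 = source2,
             form = form, coefficient = coefficient, stringsAsFactors = FALSE)
}

#' Default planted-effect table
#'
#' A fixed mixture of drivers emulating the structure of an aged-huangjiu
#' cohort: metabolites driven by aging year alone (time-related chemistry such
#' as esterification products), by single taxa (microbially produced
#' compounds such as lactic acid), by physiochemical indexes, plus a few
#' nonlinear (saturating, threshold) and interaction effects that separate
#' tree learners from linear ones. All remaining metabolites are pure noise.
#'
#' @param n_metabolites total number of metabolites in the configuration.
#' @return data.frame of planted effects.
#' @export
default_effect_table <- function(n_metabolites = 80) {
  sp <- function(i) sprintf("taxon:sp%03d", i)
  met <- function(i) sprintf("m%03d", i)
  fx <- list()
  # 10 linear aging-year metabolites, alternating sign
  for (i in 1:10)
    fx[[length(fx) + 1]] <- planted_effect(met(i), "aging_year", "linear",
                                           ifelse(i %% 2 == 0, -1, 1) * (0.8 + 0.07 * i))
  # 10 linear single-taxon metabolites over species 2..11
  for (i in 1:10)
    fx[[length(fx) + 1]] <- planted_effect(met(10 + i), sp(1 + i), "linear",
                                           ifelse(i %% 3 == 0, -1, 1) * (0.8 + 0.05 * i))
  # 6 index-driven metabolites (total acid is the dominant index in aged wine)
  idx <- c("index:total_acid", "index:total_acid", "index:total_acid",
           "index:pH", "index:reducing_sugar", "index:conductivity")
  for (i in 1:6)
    fx[[length(fx) + 1]] <- planted_effect(met(20 + i), idx[i], "linear",
                                           ifelse(i %% 2 == 0, -1, 1) * 1.0)
  # nonlinear forms: saturating and threshold, on year and on taxa
  fx[[length(fx) + 1]] <- planted_effect(met(27), "aging_year", "saturating", 1.2)
  fx[[length(fx) + 1]] <- planted_effect(met(28), "aging_year", "saturating", -1.0)
  fx[[length(fx) + 1]] <- planted_effect(met(29), sp(12), "saturating", 1.1)
  fx[[length(fx) + 1]] <- planted_effect(met(30), sp(13), "saturating", -0.9)
  fx[[length(fx) + 1]] <- planted_effect(met(31), "aging_year", "threshold", 1.2)
  fx[[length(fx) + 1]] <- planted_effect(met(32), sp(14), "threshold", -1.1)
  fx[[length(fx) + 1]] <- planted_effect(met(33), sp(15), "threshold", 1.0)
  fx[[length(fx) + 1]] <- planted_effect(met(34), "aging_year", "threshold", -1.0)
  # interactions: year x taxon, acid x taxon
  fx[[length(fx) + 1]] <- planted_effect(met(35), "aging_year", "interaction", 1.2,
                                         source2 = sp(16))
  fx[[length(fx) + 1]] <- planted_effect(met(36), "index:total_acid", "interaction", 1.0,
                                         source2 = sp(17))
  eff <- do.call(rbind, fx)
  if (max(as.integer(sub("^m", "", eff$metabolite))) > n_metabolites)
    stop("n_metabolites too small for the default effect table")
  eff
}

#' Simulation configuration
#'
#' Defines the synthetic cohort: sample size and aging-year design, the
#' compositional taxa model with one dominant taxon, the planted
#' metabolite effects, noise and censoring levels.
#'
#' Defaults emulate the study conditions of an aged-huangjiu cohort:
#' 110 samples over aging years 3/8/10/20/25, a species table dominated by
#' one taxon at ~59% mean relative abundance, one taxon monotone in aging
#' year and one in total acid, and 80 metabolites of which 36 carry planted
#' effects and 3 are heavily censored (to exercise the measurement filter).
#'
#' @param n_samples number of samples.
#' @param aging_years distinct aging years sampled.
#' @param aging_weights positive sampling weights, one per aging year.
#' @param n_taxa_species,n_taxa_genus numbers of species / genera.
#' @param dominant_taxon_mean_fraction target mean relative abundance of the
#'   dominant species (`sp001`), in (0, 1).
#' @param detection_floor relative abundances below this are recorded as zero
#'   (then rows renormalized); creates the zeros that exercise CLR
#'   zero-replacement.
#' @param read_depth multinomial sequencing depth for the count tables.
#' @param n_metabolites number of metabolites.
#' @param effect_table data.frame of planted effects (see [planted_effect()]).
#' @param noise_sd per-metabolite Gaussian noise sd on the log scale
#'   (scalar, recycled).
#' @param censor_quantile proportion of low values per metabolite set missing,
#'   in [0, 1).
#' @param n_rare_metabolites number of trailing metabolites censored at
#'   `rare_censor_quantile` instead (dropped later by the measurement filter).
#' @param rare_censor_quantile censoring quantile for the rare metabolites.
#' @param seed global integer seed; fans out to per-stage child seeds.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 110,
                       aging_years = c(3, 8, 10, 20, 25),
                       aging_weights = rep(1, length(aging_years)),
                       n_taxa_species = 60,
                       n_taxa_genus = 20,
                       dominant_taxon_mean_fraction = 0.59,
                       detection_floor = 1e-4,
                       read_depth = 10000,
                       n_metabolites = 80,
                       effect_table = default_effect_table(n_metabolites),
                       noise_sd = 0.5,
                       censor_quantile = 0.1,
                       n_rare_metabolites = 3,
                       rare_censor_quantile = 0.6,
                       seed = 1L) {
  stopifnot(n_samples >= 10,
            length(aging_years) == length(aging_weights),
            all(aging_weights > 0),
            dominant_taxon_mean_fraction > 0, dominant_taxon_mean_fraction < 1,
            n_taxa_species >= 2, n_taxa_genus >= 2,
            n_taxa_genus <= n_taxa_species,
            censor_quantile >= 0, censor_quantile < 1,
            noise_sd >= 0)
  if (!is.null(effect_table) && nrow(effect_table) > 0) {
    tm <- unique(effect_table$metabolite)
    if (n_metabolites < length(tm))
      stop("n_metabolites must be >= number of distinct planted targets")
    srcs <- c(effect_table$source, stats::na.omit(effect_table$source2))
    sp_ids <- grep("^taxon:", srcs, value = TRUE)
    sp_num <- as.integer(sub("^taxon:sp", "", sp_ids))
    if (length(sp_num) && max(sp_num) > n_taxa_species)
      stop("effect table references species beyond n_taxa_species")
    idx_ids <- sub("^index:", "", grep("^index:", srcs, value = TRUE))
    bad <- setdiff(idx_ids, c("total_acid", "amino_nitrogen", "reducing_sugar",
                              "pH", "conductivity"))
    if (length(bad)) stop("unknown index source(s): ", paste(bad, collapse = ", "))
  }
  structure(list(n_samples = n_samples, aging_years = aging_years,
                 aging_weights = aging_weights,
                 n_taxa_species = n_taxa_species, n_taxa_genus = n_taxa_genus,
                 dominant_taxon_mean_fraction = dominant_taxon_mean_fraction,
                 detection_floor = detection_floor, read_depth = read_depth,
                 n_metabolites = n_metabolites, effect_table = effect_table,
                 noise_sd = noise_sd, censor_quantile = censor_quantile,
                 n_rare_metabolites = n_rare_metabolites,
                 rare_censor_quantile = rare_censor_quantile,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# standardize a numeric vector (sample sd); constant vectors map to zeros
.zs <- function(x) {
  s <- sd(x)
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Generate a paired microbiome / physiochemistry / metabolome dataset
#'
#' Draws a synthetic cohort under `config` and returns the aligned study
#' tables together with the machine-readable ground truth of planted effects.
#' Deterministic given `config$seed`.
#'
#' The taxa composition is log-normal renormalized to the simplex, with the
#' dominant species' fraction controlled on the logit scale around the
#' configured mean; species 2 is monotone (in expectation) in aging year and
#' species 3 in total acid. Counts are multinomial at `read_depth`.
#' Metabolites are standardized sums of the planted effects plus Gaussian
#' noise, exponentiated to positive concentrations, then censored below the
#' per-metabolite `censor_quantile`.
#'
#' @param config a [sim_config()].
#' @return list with elements `tables` (class `study_tables`: `metadata`,
#'   `physio`, `metabolites`, `relabund_species`, `relabund_genus`,
#'   `counts_species`, `counts_genus`, `taxonomy`) and `ground_truth`
#'   (data.frame of planted effects with their monotone sign, `NA` for
#'   interactions).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  sample_id <- sprintf("S%03d", seq_len(n))

  ## --- metadata: deterministic proportional allocation of aging years ---
  w <- config$aging_weights / sum(config$aging_weights)
  cnt <- floor(w * n)
  rem <- n - sum(cnt)
  if (rem > 0) {
    frac <- w * n - cnt
    cnt[order(frac, decreasing = TRUE)[seq_len(rem)]] <- cnt[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  year <- rep(config$aging_years, times = cnt)
  metadata <- data.frame(sample_id = sample_id, aging_year = year,
                         stringsAsFactors = FALSE)

  ## --- physiochemical indexes ---
  set.seed(child_seed(config$seed, 1))
  total_acid <- 4.5 + 0.08 * year + rnorm(n, 0, 0.45)          # g/L, rises with age
  pH <- 4.55 - 0.12 * total_acid + rnorm(n, 0, 0.05)           # acid pushes pH down
  amino_nitrogen <- 0.45 + 0.012 * year + rnorm(n, 0, 0.07)    # g/L
  reducing_sugar <- 15 + 0.30 * year + rnorm(n, 0, 3)          # g/L
  conductivity <- 1.6 + 0.02 * year + rnorm(n, 0, 0.2)         # mS/cm
  physio <- data.frame(sample_id = sample_id, total_acid = total_acid,
                       amino_nitrogen = amino_nitrogen,
                       reducing_sugar = reducing_sugar, pH = pH,
                       conductivity = conductivity, stringsAsFactors = FALSE)

  ## --- taxa: log-normal latent abundances on the simplex ---
  set.seed(child_seed(config$seed, 2))
  S <- config$n_taxa_species
  sp_id <- sprintf("sp%03d", seq_len(S))
  year_z <- .zs(year)
  acid_z <- .zs(total_acid)
  mu <- rnorm(S, 0, 1.5)
  # species carrying planted effects are kept clear of the detection floor:
  # an effect planted on an undetectable taxon would be unrecoverable by design
  eff_sp <- unique(sub("^taxon:", "",
                       grep("^taxon:", c(config$effect_table$source,
                                         config$effect_table$source2),
                            value = TRUE)))
  mu[match(eff_sp, sp_id)] <- pmax(mu[match(eff_sp, sp_id)], 0.5)
  beta_age <- numeric(S)
  beta_acid <- numeric(S)
  beta_age[2] <- 1.2    # rises with aging year (Methyloversatilis-like)
  beta_age[4] <- -0.8   # fades during long-term storage
  beta_acid[3] <- 1.2   # rises with total acid (LAB-like)
  latent <- matrix(rnorm(n * S, 0, 1), n, S)
  latent <- sweep(latent, 2, mu, `+`) +
    outer(year_z, beta_age) + outer(acid_z, beta_acid)
  A <- exp(latent)
  # dominant species: fraction controlled on the logit scale
  f0 <- config$dominant_taxon_mean_fraction
  lf <- log(f0 / (1 - f0)) + rnorm(n, 0, 0.25)
  fdom <- 1 / (1 + exp(-lf))
  A[, 1] <- fdom / (1 - fdom) * rowSums(A[, -1, drop = FALSE])
  latent[, 1] <- log(A[, 1])
  rel <- A / rowSums(A)
  rel[rel < config$detection_floor] <- 0
  rel <- rel / rowSums(rel)
  dimnames(rel) <- list(sample_id, sp_id)

  counts <- t(apply(rel, 1, function(p) rmultinom(1, config$read_depth, p)[, 1]))
  dimnames(counts) <- dimnames(rel)

  # taxonomy: dominant species is its own genus; the rest in contiguous blocks
  G <- config$n_taxa_genus
  g_id <- sprintf("g%02d", seq_len(G))
  genus_of <- c(1, 1 + sort(rep_len(seq_len(G - 1), S - 1)))
  taxonomy <- data.frame(species = sp_id, genus = g_id[genus_of],
                         stringsAsFactors = FALSE)
  agg <- function(m) {
    out <- t(rowsum(t(m), group = taxonomy$genus))
    out[, g_id[g_id %in% colnames(out)], drop = FALSE]
  }
  rel_g <- agg(rel)
  counts_g <- agg(counts)

  ## --- metabolites: standardized planted effects + noise, exponentiated ---
  set.seed(child_seed(config$seed, 3))
  M <- config$n_metabolites
  met_id <- sprintf("m%03d", seq_len(M))
  src_vec <- function(src) {
    if (src == "aging_year") return(year_z)
    if (startsWith(src, "index:")) return(.zs(physio[[sub("^index:", "", src)]]))
    if (startsWith(src, "taxon:")) {
      j <- match(sub("^taxon:", "", src), sp_id)
      return(.zs(latent[, j]))
    }
    stop("unknown effect source: ", src)
  }
  apply_form <- function(x, form) {
    switch(form,
           linear = x,
           saturating = x / (1 + abs(x)),
           threshold = as.numeric(x > median(x)),
           stop("unhandled form"))
  }
  z <- matrix(0, n, M, dimnames = list(sample_id, met_id))
  eff <- config$effect_table
  if (!is.null(eff) && nrow(eff)) {
    for (r in seq_len(nrow(eff))) {
      j <- match(eff$metabolite[r], met_id)
      if (is.na(j)) stop("effect targets unknown metabolite: ", eff$metabolite[r])
      x1 <- src_vec(eff$source[r])
      contrib <- if (eff$form[r] == "interaction") {
        x1 * src_vec(eff$source2[r])
      } else {
        apply_form(x1, eff$form[r])
      }
      z[, j] <- z[, j] + eff$coefficient[r] * contrib
    }
  }
  noise_sd <- rep_len(config$noise_sd, M)
  z <- z + sweep(matrix(rnorm(n * M), n, M), 2, noise_sd, `*`)
  base_level <- rnorm(M, mean = log(50), sd = 1)  # spread of concentration scales
  conc <- exp(sweep(z, 2, base_level, `+`))

  ## --- censoring ---
  cq <- rep_len(config$censor_quantile, M)
  if (config$n_rare_metabolites > 0) {
    rare <- seq.int(M - config$n_rare_metabolites + 1, M)
    cq[rare] <- config$rare_censor_quantile
  }
  metabolites <- conc
  for (j in seq_len(M))
    metabolites[, j] <- inject_missingness(conc[, j, drop = FALSE], cq[j])[, 1]

  tables <- structure(list(metadata = metadata, physio = physio,
                           metabolites = metabolites,
                           relabund_species = rel, relabund_genus = rel_g,
                           counts_species = counts, counts_genus = counts_g,
                           taxonomy = taxonomy),
                      class = "study_tables")
  validate_study_tables(tables)

  gt <- if (is.null(eff) || !nrow(eff)) {
    data.frame(metabolite = character(), source = character(),
               source2 = character(), form = character(),
               coefficient = numeric(), sign = integer())
  } else {
    transform(eff, sign = ifelse(form == "interaction", NA_integer_,
                                 as.integer(sign(coefficient))))
  }
  list(tables = tables, ground_truth = gt)
}

#' Censor low values of a metabolite table
#'
#' Per metabolite, the `censor_quantile` fraction of lowest observed values is
#' set to missing (left-censoring, the mechanism behind detection limits).
#' For a column with `n` non-missing values, exactly `floor(censor_quantile *
#' n)` values are censored — the smallest ones, ties broken by row index — so
#' every censored value is less than or equal to every surviving value. No
#' column is ever fully censored.
#'
#' @param metabolites numeric matrix (samples x metabolites), NAs allowed.
#' @param censor_quantile proportion in [0, 1).
#' @return the matrix with additional NAs.
#' @export
inject_missingness <- function(metabolites, censor_quantile) {
  if (censor_quantile < 0 || censor_quantile >= 1)
    stop("censor_quantile must be in [0, 1)")
  m <- as.matrix(metabolites)
  if (censor_quantile == 0) return(m)
  for (j in seq_len(ncol(m))) {
    obs <- which(!is.na(m[, j]))
    k <- floor(censor_quantile * length(obs))
    if (k >= 1) {
      # order() is stable: ties resolved by original row index
      m[obs[order(m[obs, j])[seq_len(k)]], j] <- NA
    }
  }
  m
}

#' Validate an aligned study-table bundle
#'
#' Checks that all tables share an identical ordered sample-ID set, that
#' relative-abundance rows sum to 1 (within 1e-9), and that counts are
#' nonnegative. Errors list the offending samples.
#'
#' @param tables a `study_tables` list.
#' @return invisibly `TRUE`.
#' @export
validate_study_tables <- function(tables) {
  ids <- tables$metadata$sample_id
  for (nm in c("physio")) {
    if (!identical(tables[[nm]]$sample_id, ids))
      stop("sample IDs of '", nm, "' differ from metadata: ",
           paste(union(setdiff(tables[[nm]]$sample_id, ids),
                       setdiff(ids, tables[[nm]]$sample_id)), collapse = ", "))
  }
  for (nm in c("metabolites", "relabund_species", "relabund_genus",
               "counts_species", "counts_genus")) {
    if (is.null(tables[[nm]])) next
    if (!identical(rownames(tables[[nm]]), ids))
      stop("sample IDs of '", nm, "' differ from metadata: ",
           paste(union(setdiff(rownames(tables[[nm]]), ids),
                       setdiff(ids, rownames(tables[[nm]]))), collapse = ", "))
  }
  for (nm in c("relabund_species", "relabund_genus")) {
    rs <- rowSums(tables[[nm]])
    if (any(abs(rs - 1) > 1e-9))
      stop("rows of '", nm, "' do not sum to 1")
  }
  for (nm in c("counts_species", "counts_genus")) {
    if (any(tables[[nm]] < 0)) stop("negative counts in '", nm, "'")
  }
  invisible(TRUE)
}
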