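# Small simulation fixtures shared across test files. Everything is built in
# code at test time; sizes are kept small so the default run stays fast.

tiny_sim_config <- function(seed = 101, n_metabolites = 6,
                            effect_table = tiny_effects(), ...) {
  sim_config(n_samples = 40, aging_years = c(3, 8, 10, 20, 25),
             n_taxa_species = 12, n_taxa_genus = 5,
             n_metabolites = n_metabolites, effect_table = effect_table,
             noise_sd = 0.4, censor_quantile = 0.05, n_rare_metabolites = 0,
             seed = seed, ...)
}

tiny_effects <- function() {
  rbind(planted_effect("m001", "aging_year", "linear", 1.2),
        planted_effect("m002", "taxon:sp005", "linear", 1.0),
        planted_effect("m003", "index:total_acid", "linear", -1.0))
}

tiny_prep <- function(seed = 101) {
  sim <- generate_dataset(tiny_sim_config(seed))
  suppressMessages(preprocess_tables(sim$tables,
                                     preprocess_config(metabolite_min_measurements = 10,
                                                       taxa_min_measurements = 3)))
}
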