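#!/usr/bin/env Rscript
# Stage 2 — quality control and transforms.
#
# Metabolites measured in fewer than 50 samples are dropped, the rest are
# imputed at the per-metabolite minimum, log10-transformed and z-scored.
# Taxa below 0.1% mean relative abundance or with at most 10 nonzero
# measurements are dropped, the rest CLR-transformed (zeros -> 1e-10);
# Chao1 / Shannon / Simpson are computed from the count tables.

library(huangjiuML)

tables <- read_study_tables("results/data")
prep <- preprocess_tables(tables, preprocess_config())

dir.create("results/prep", showWarnings = FALSE, recursive = TRUE)
huangjiuML:::.write_matrix_tsv(prep$metabolites,
                               "results/prep/metabolites_standardized.tsv")
huangjiuML:::.write_matrix_tsv(prep$clr_species, "results/prep/clr_species.tsv")
huangjiuML:::.write_matrix_tsv(prep$clr_genus, "results/prep/clr_genus.tsv")
write.table(cbind(sample_id = rownames(prep$diversity_species),
                  prep$diversity_species),
            "results/prep/diversity_species.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("metabolites kept:", ncol(prep$metabolites), "— dropped:",
    paste(prep$log$metabolites_dropped, collapse = ", "), "\n")
cat("species kept:", ncol(prep$clr_species), "of",
    ncol(tables$relabund_species), "\n")
cat("genera kept: ", ncol(prep$clr_genus), "of",
    ncol(tables$relabund_genus), "\n")
cat("alpha diversity (species level): Chao1",
    round(mean(prep$diversity_species$chao1), 1), "| Shannon",
    round(mean(prep$diversity_species$shannon), 2), "bits | Simpson",
    round(mean(prep$diversity_species$simpson), 3), "on average\n")
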