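#!/usr/bin/env Rscript
# Stage 7 — descriptive association layer.
#
# Spearman associations of the physiochemical indexes with the standardized
# metabolites, the two-way cluster map of well-predicted metabolites
# (EV > 0.3 under the PI model), and the one-way ANOVA of total acid across
# the sample clusters.

library(huangjiuML)

tables <- read_study_tables("results/data")
prep <- preprocess_tables(tables, preprocess_config())

ev_tab <- read.delim("results/models/bootstrap_PI.tsv")
ev <- setNames(ev_tab$ev, ev_tab$metabolite)

assoc <- spearman_association(
  cbind(prep$physio[, c("total_acid", "amino_nitrogen", "reducing_sugar",
                        "pH", "conductivity")],
        aging_year = prep$metadata$aging_year),
  prep$metabolites)

dir.create("results/reporting", showWarnings = FALSE, recursive = TRUE)
huangjiuML:::.write_matrix_tsv(assoc$rho, "results/reporting/spearman_rho.tsv")
huangjiuML:::.write_matrix_tsv(assoc$p, "results/reporting/spearman_p.tsv")

cm <- cluster_metabolite_map(prep$metabolites, ev, threshold = 0.3)
write_cluster_map(cm, "results/reporting")
an <- anova_by_cluster(prep$physio$total_acid, cm$sample_clusters)

cat("well-predicted metabolites (EV > 0.3):", length(cm$retained), "\n")
cat("metabolite clusters:", table(cm$metabolite_clusters), "\n")
cat("sample clusters:    ", table(cm$sample_clusters), "\n")
cat("total acid across sample clusters: F =", round(an$f, 2),
    ", p =", signif(an$p, 3), "\n")
n_assoc <- sum(assoc$flagged["total_acid", ], na.rm = TRUE)
cat(n_assoc, "metabolites associated with total acid",
    "(|rho| > 0.3, p < 0.01)\n")
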