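#' Spearman association matrix between two tables
#'
#' Spearman rho (average ranks for ties) between every column of `tableA` and
#' every column of `tableB`, with two-sided p-values from the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on the
#' pairwise-complete sample size. Pairs with fewer than 3 complete
#' observations are reported as `NA`.
#'
#' @param tableA,tableB numeric matrices/data.frames with aligned rows;
#'   `tableB` defaults to `tableA`.
#' @param rho_screen,p_screen thresholds for the `flagged` matrix
#'   (`|rho| > rho_screen & p < p_screen`).
#' @return list of matrices `rho`, `p`, `n` (pairwise-complete counts) and
#'   `flagged`.
#' @export
spearman_association <- function(tableA, tableB = tableA,
                                 rho_screen = 0.3, p_screen = 0.01) {
  A <- as.matrix(tableA)
  B <- as.matrix(tableB)
  stopifnot(nrow(A) == nrow(B))
  rho <- matrix(NA_real_, ncol(A), ncol(B),
                dimnames = list(colnames(A), colnames(B)))
  p <- rho
  nmat <- rho
  for (i in seq_len(ncol(A))) {
    for (j in seq_len(ncol(B))) {
      ok <- complete.cases(A[, i], B[, j])
      n <- sum(ok)
      nmat[i, j] <- n
      if (n < 3) next
      r <- suppressWarnings(cor(A[ok, i], B[ok, j], method = "spearman"))
      if (is.na(r)) next
      rho[i, j] <- r
      if (abs(r) >= 1) {
        p[i, j] <- 0
      } else {
        tstat <- r * sqrt((n - 2) / (1 - r^2))
        p[i, j] <- 2 * pt(-abs(tstat), df = n - 2)
      }
    }
  }
  list(rho = rho, p = p, n = nmat,
       flagged = !is.na(rho) & abs(rho) > rho_screen & !is.na(p) & p < p_screen)
}

#' Two-way cluster map of well-predicted metabolites
#'
#' Retains the metabolites whose explained variance exceeds `threshold`,
#' hierarchically clusters metabolites and samples (Euclidean distance on the
#' standardized values, average linkage by default) and cuts both trees into
#' a configurable number of clusters (default 3 metabolite clusters MC and 3
#' sample clusters SC). Metabolite columns are sorted by name before
#' clustering so the result is invariant to input order; cluster labels are
#' assigned in order of first appearance over the sorted data.
#'
#' @param metabolites standardized samples x metabolites matrix.
#' @param ev named vector of explained variance per metabolite.
#' @param threshold EV retention threshold (default 0.3).
#' @param k_metabolites,k_samples number of clusters on each axis.
#' @param method linkage method for [hclust()].
#' @return object of class `cluster_map_result`: list with
#'   `metabolite_clusters` and `sample_clusters` (named integer vectors),
#'   `metabolite_tree` / `sample_tree` (hclust objects), `retained`,
#'   `threshold`.
#' @export
cluster_metabolite_map <- function(metabolites, ev, threshold = 0.3,
                                   k_metabolites = 3, k_samples = 3,
                                   method = "average") {
  m <- as.matrix(metabolites)
  keep <- names(ev)[!is.na(ev) & ev > threshold]
  keep <- intersect(colnames(m), keep)
  if (length(keep) == 0)
    stop("no metabolites exceed the explained-variance threshold ", threshold)
  if (length(keep) < 2)
    stop("fewer than 2 metabolites survive the threshold; nothing to cluster")
  m <- m[, sort(keep), drop = FALSE]
  ht_met <- hclust(dist(t(m)), method = method)
  ht_sam <- hclust(dist(m), method = method)
  relabel <- function(cl) {
    lv <- unique(cl)
    out <- match(cl, lv)
    names(out) <- names(cl)
    out
  }
  mc <- relabel(cutree(ht_met, k = min(k_metabolites, length(keep))))
  sc <- relabel(cutree(ht_sam, k = min(k_samples, nrow(m))))
  structure(list(metabolite_clusters = mc, sample_clusters = sc,
                 metabolite_tree = ht_met, sample_tree = ht_sam,
                 retained = sort(keep), threshold = threshold),
            class = "cluster_map_result")
}

#' One-way ANOVA of an index across sample clusters
#'
#' Fixed-effects one-way ANOVA of `values` across the groups in `labels`.
#' With zero within-group variance and nonzero between-group variance the F
#' statistic is reported as `Inf` with p = 0.
#'
#' @param values numeric vector (e.g. total acid per sample).
#' @param labels cluster label per sample (>= 2 clusters, each with >= 2
#'   samples).
#' @return list with `f` and `p`.
#' @export
anova_by_cluster <- function(values, labels) {
  labels <- as.factor(labels)
  stopifnot(length(values) == length(labels))
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 clusters")
  if (any(tab < 2)) stop("singleton cluster(s): ",
                         paste(names(tab)[tab < 2], collapse = ", "))
  grand <- mean(values)
  ssb <- sum(tapply(values, labels, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(values, labels, function(v) sum((v - mean(v))^2)))
  df1 <- length(tab) - 1
  df2 <- length(values) - length(tab)
  if (ssw == 0) {
    if (ssb == 0) stop("all values identical; ANOVA undefined")
    return(list(f = Inf, p = 0))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, p = pf(f, df1, df2, lower.tail = FALSE))
}

#' Export a cluster map result
#'
#' Writes cluster assignments as TSV and both dendrograms as Newick trees.
#'
#' @param cm a `cluster_map_result`.
#' @param dir output directory (created if missing).
#' @return invisibly the vector of written paths.
#' @export
write_cluster_map <- function(cm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    metab = file.path(dir, "metabolite_clusters.tsv"),
    sampl = file.path(dir, "sample_clusters.tsv"),
    tmet = file.path(dir, "metabolite_dendrogram.nwk"),
    tsam = file.path(dir, "sample_dendrogram.nwk"))
  write.table(data.frame(metabolite = names(cm$metabolite_clusters),
                         cluster = paste0("MC-", cm$metabolite_clusters)),
              paths["metab"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = names(cm$sample_clusters),
                         cluster = paste0("SC-", cm$sample_clusters)),
              paths["sampl"], sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(ape::as.phylo(cm$metabolite_tree), paths["tmet"])
  ape::write.tree(ape::as.phylo(cm$sample_tree), paths["tsam"])
  invisible(paths)
}
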