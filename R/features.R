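#' Names of the six feature groups
#' @return character vector `c("FM","PI","AFS","AMS","AFG","AMG")`.
#' @export
feature_group_names <- function() c("FM", "PI", "AFS", "AMS", "AFG", "AMG")

#' Assemble a named feature group
#'
#' Builds the samples x features matrix for one of the six named groups:
#' \describe{
#'   \item{PI}{physiochemical indexes: total acid, amino nitrogen, reducing
#'     sugar, pH, conductivity, and aging year.}
#'   \item{AMS}{aging microbiome at species level: CLR species abundances plus
#'     the three alpha-diversity indices computed on species counts.}
#'   \item{AFS}{aging-related factors at species level: AMS plus aging year.}
#'   \item{AMG / AFG}{the genus-level analogues.}
#'   \item{FM}{full model: the union of all blocks; aging year appears once,
#'     diversity indices are kept at both annotation levels under
#'     level-tagged names.}
#' }
#' Columns are ordered block-wise (physio, year, CLR, diversity), taxa
#' alphabetical within their block; constant columns are dropped with a
#' message. Every column carries a provenance tag.
#'
#' @param name one of [feature_group_names()].
#' @param prep a `preprocessed_tables` list from [preprocess_tables()].
#' @return numeric matrix with attribute `provenance` (character vector with
#'   one of `"physio"`, `"year"`, `"clr-species"`, `"clr-genus"`,
#'   `"diversity"` per column) and attribute `group`.
#' @export
assemble_features <- function(name, prep) {
  name <- match.arg(name, feature_group_names())
  n <- nrow(prep$metabolites)
  ids <- rownames(prep$metabolites)

  physio_block <- function() {
    m <- as.matrix(prep$physio[, c("total_acid", "amino_nitrogen",
                                   "reducing_sugar", "pH", "conductivity")])
    rownames(m) <- ids
    list(m = m, prov = rep("physio", ncol(m)))
  }
  year_block <- function() {
    m <- matrix(prep$metadata$aging_year, ncol = 1,
                dimnames = list(ids, "aging_year"))
    list(m = m, prov = "year")
  }
  clr_block <- function(level) {
    clr <- if (level == "species") prep$clr_species else prep$clr_genus
    clr <- clr[, order(colnames(clr)), drop = FALSE]
    list(m = clr, prov = rep(paste0("clr-", level), ncol(clr)))
  }
  div_block <- function(level, tag_level = FALSE) {
    d <- if (level == "species") prep$diversity_species else prep$diversity_genus
    m <- as.matrix(d)
    if (tag_level) colnames(m) <- paste(colnames(m), level, sep = "_")
    rownames(m) <- ids
    list(m = m, prov = rep("diversity", ncol(m)))
  }

  blocks <- switch(name,
    PI  = list(physio_block(), year_block()),
    AMS = list(clr_block("species"), div_block("species")),
    AFS = list(year_block(), clr_block("species"), div_block("species")),
    AMG = list(clr_block("genus"), div_block("genus")),
    AFG = list(year_block(), clr_block("genus"), div_block("genus")),
    FM  = list(physio_block(), year_block(),
               clr_block("species"), div_block("species", tag_level = TRUE),
               clr_block("genus"), div_block("genus", tag_level = TRUE))
  )
  if (name %in% c("AFS", "AMS") && ncol(prep$clr_species) == 0)
    stop("feature group ", name, " requires species-level taxa")
  if (name %in% c("AFG", "AMG") && ncol(prep$clr_genus) == 0)
    stop("feature group ", name, " requires genus-level taxa")

  X <- do.call(cbind, lapply(blocks, `[[`, "m"))
  prov <- unlist(lapply(blocks, `[[`, "prov"))
  const <- apply(X, 2, function(v) sd(v) == 0)
  if (any(const)) {
    message("dropping constant feature column(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
    prov <- prov[!const]
  }
  stopifnot(nrow(X) == n)
  structure(X, provenance = prov, group = name)
}

#' Export a feature matrix as TSV with a provenance header row
#'
#' The first data row is the provenance tag of each column; sample IDs go in
#' the first column.
#'
#' @param X feature matrix from [assemble_features()].
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_feature_matrix <- function(X, path) {
  prov <- attr(X, "provenance")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample_id", colnames(X)), collapse = "\t"), con)
  writeLines(paste(c("#provenance", prov), collapse = "\t"), con)
  utils::write.table(data.frame(sample_id = rownames(X), X,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
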