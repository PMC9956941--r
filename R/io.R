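# Readers and writers for the study-table bundle. Everything is plain TSV
# (matrices with a sample_id first column) plus a ground-truth JSON; taxa
# counts can optionally come from a BIOM file.

.write_matrix_tsv <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), as.data.frame(m),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1] != "sample_id")
    stop("expected first column 'sample_id' in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2,
                                              as.numeric))) &
                   !is.na(as.matrix(df[, -1, drop = FALSE])), arr.ind = TRUE)
    if (nrow(bad))
      stop("malformed numeric cell in ", path, " at row ", bad[1, 1] + 1,
           ", column '", colnames(df)[bad[1, 2] + 1], "'")
    m <- apply(df[, -1, drop = FALSE], 2, as.numeric)
  }
  rownames(m) <- df$sample_id
  m
}

#' Write a study-table bundle to a directory
#'
#' Writes `metadata.tsv`, `physio.tsv`, `metabolites.tsv`, the four taxa
#' tables, `taxonomy.tsv`, and (when given) `ground_truth.json`. All files
#' round-trip through [read_study_tables()].
#'
#' @param tables a `study_tables` bundle.
#' @param dir output directory (created if missing).
#' @param ground_truth optional planted-effect data.frame.
#' @return invisibly `dir`.
#' @export
write_study_tables <- function(tables, dir, ground_truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(tables$metadata, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(tables$physio, file.path(dir, "physio.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (nm in c("metabolites", "relabund_species", "relabund_genus",
               "counts_species", "counts_genus"))
    .write_matrix_tsv(tables[[nm]], file.path(dir, paste0(nm, ".tsv")))
  write.table(tables$taxonomy, file.path(dir, "taxonomy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(ground_truth))
    jsonlite::write_json(ground_truth, file.path(dir, "ground_truth.json"),
                         dataframe = "rows", na = "null", digits = NA)
  invisible(dir)
}

#' Read a study-table bundle from a directory
#'
#' Inverse of [write_study_tables()]; validates sample-ID alignment and
#' reports malformed numeric cells with their position.
#'
#' @param dir directory containing the TSV files.
#' @return a `study_tables` bundle.
#' @export
read_study_tables <- function(dir) {
  need <- c("metadata.tsv", "physio.tsv", "metabolites.tsv",
            "relabund_species.tsv", "relabund_genus.tsv",
            "counts_species.tsv", "counts_genus.tsv", "taxonomy.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  tables <- structure(list(
    metadata = read.delim(file.path(dir, "metadata.tsv"),
                          stringsAsFactors = FALSE),
    physio = read.delim(file.path(dir, "physio.tsv"),
                        stringsAsFactors = FALSE),
    metabolites = .read_matrix_tsv(file.path(dir, "metabolites.tsv")),
    relabund_species = .read_matrix_tsv(file.path(dir, "relabund_species.tsv")),
    relabund_genus = .read_matrix_tsv(file.path(dir, "relabund_genus.tsv")),
    counts_species = .read_matrix_tsv(file.path(dir, "counts_species.tsv")),
    counts_genus = .read_matrix_tsv(file.path(dir, "counts_genus.tsv")),
    taxonomy = read.delim(file.path(dir, "taxonomy.tsv"),
                          stringsAsFactors = FALSE)),
    class = "study_tables")
  validate_study_tables(tables)
  tables
}

#' Read the planted ground truth written by [write_study_tables()]
#' @param path path to `ground_truth.json`.
#' @return data.frame of planted effects.
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::fromJSON(path)
  as.data.frame(gt, stringsAsFactors = FALSE)
}

#' Read a taxa count table from a BIOM file
#'
#' Optional entry point for taxa tables produced by standard amplicon
#' pipelines. Requires the `biomformat` package; returns samples x taxa
#' counts (BIOM stores taxa x samples).
#'
#' @param path BIOM file (JSON or HDF5 dialect).
#' @return numeric matrix, samples in rows.
#' @export
read_taxa_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("reading BIOM files requires the 'biomformat' package")
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")
  t(m)
}
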