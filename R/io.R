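#' Read and write the package's tabular formats
#'
#' Matrices are tab-separated with sample ids in the first column and feature
#' ids in the header; a missing metabolite value is an empty cell. Sample
#' metadata is a TSV with columns `sample_id`, `patient_id`, `day`, `type`
#' and optionally `nf_day`. The taxonomy map is a two-column TSV
#' (`asv_id`, `genus`).
#'
#' @param mat numeric matrix, samples x features.
#' @param path file path.
#' @name nfomics-io
NULL

#' @rdname nfomics-io
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' @rdname nfomics-io
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Read a count table from TSV or BIOM format
#'
#' TSV tables use the [read_matrix_tsv()] dialect. BIOM files (".biom")
#' require the `biomformat` package and are transposed to samples x taxa.
#'
#' @param path file path.
#' @return an integer matrix, samples x taxa.
#' @export
read_count_table <- function(path) {
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      .nf_stop("reading BIOM files requires the 'biomformat' package")
    m <- t(as(biomformat::biom_data(biomformat::read_biom(path)), "matrix"))
  } else {
    m <- read_matrix_tsv(path)
  }
  storage.mode(m) <- "integer"
  m
}

#' @rdname nfomics-io
#' @export
write_sample_metadata <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' @rdname nfomics-io
#' @export
read_sample_metadata <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname nfomics-io
#' @export
read_genus_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  setNames(df[[2]], df[[1]])
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Emits `metabolome.tsv` (missing = empty cell), `counts.tsv`,
#' `samples.tsv`, `patients.tsv`, `genus_map.tsv` and `truth.yaml` (the
#' generator configuration and the planted association matrix).
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(cohort$metabolome, file.path(dir, "metabolome.tsv"))
  if (!is.null(cohort$counts))
    write_matrix_tsv(cohort$counts, file.path(dir, "counts.tsv"))
  write_sample_metadata(cohort$samples, file.path(dir, "samples.tsv"))
  write.table(cohort$patients, file.path(dir, "patients.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  if (!is.null(cohort$genus_map))
    write.table(data.frame(asv_id = names(cohort$genus_map),
                           genus = unname(cohort$genus_map)),
                file.path(dir, "genus_map.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  tr <- cohort$truth
  truth <- list(
    config = unclass(tr$config),
    metabolome = unclass(tr$metabolome),
    microbiome = if (!is.null(tr$microbiome)) {
      mt <- unclass(tr$microbiome)
      if (!is.null(mt$association)) {
        mt$association_metabolites <- colnames(tr$microbiome$association)
        mt$association <- apply(tr$microbiome$association, 2, as.numeric,
                                simplify = FALSE)
      }
      mt
    })
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}
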