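#' Read a genes x samples expression matrix from TSV/CSV
#'
#' The file must have gene ids in the first column and one header row of
#' sample ids. Values must parse as non-negative finite numbers; any cell
#' that does not (including literal `NA`) is a parse error that names the
#' offending gene and sample. Duplicated gene ids are collapsed by row-wise
#' mean, with a message.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return Numeric matrix, genes in rows, samples in columns, with a
#'   `platform_tag` attribute (empty string by default).
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop_("empty expression matrix in ", path)
  genes <- raw[[1L]]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body),
                                 dimnames = dimnames(body)))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_(sprintf("non-numeric value '%s' at gene '%s', sample '%s' in %s",
                  body[bad[1L, 1L], bad[1L, 2L]], genes[bad[1L, 1L]],
                  colnames(body)[bad[1L, 2L]], path))
  }
  if (any(vals < 0))
    stop_("negative expression values in ", path,
          "; input must be linear-scale intensities or TPM")
  if (anyDuplicated(genes)) {
    n_dup <- sum(duplicated(genes))
    sums <- rowsum(vals, genes, reorder = FALSE)
    counts <- as.vector(table(factor(genes, levels = rownames(sums))))
    vals <- sums / counts
    message(sprintf("collapsed %d duplicated gene id(s) by row-wise mean", n_dup))
  } else {
    rownames(vals) <- genes
  }
  message(sprintf("read %d genes x %d samples from %s",
                  nrow(vals), ncol(vals), path))
  attr(vals, "platform_tag") <- ""
  vals
}

#' Write an expression matrix to TSV/CSV
#'
#' Inverse of [read_expression_matrix()]: first column `gene_id`, one column
#' per sample.
#'
#' @param mat Numeric genes x samples matrix with dimnames.
#' @param path Output path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(mat, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  assert_expression_matrix(mat, "mat")
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample -> cell type annotation table
#'
#' @param path Two-column TSV with header columns `sample_id` and `cell_type`.
#' @return data.frame with character columns `sample_id` and `cell_type`.
#' @export
read_sample_annotation <- function(path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  assert_annotation(ann)
  ann[, c("sample_id", "cell_type")]
}

#' Read a cell-type group structure from YAML or JSON
#'
#' @param path File mapping group id -> list of member cell types; format is
#'   chosen by extension (`.yaml`/`.yml` or `.json`).
#' @return Named list of character vectors.
#' @export
read_cell_groups <- function(path) {
  ext <- tolower(tools::file_ext(path))
  groups <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop_("unsupported group file extension '.", ext, "' (use yaml or json)"))
  groups <- lapply(groups, as.character)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop_("every group must be named")
  groups
}

#' Transcripts-per-million normalization of raw RNA-seq counts
#'
#' Per sample, each gene's count is divided by its length (length-rate),
#' and rates are rescaled so every column sums to one million:
#' `TPM_i = (count_i / length_i) / sum_j(count_j / length_j) * 1e6`.
#'
#' @param counts Genes x samples matrix of raw counts (non-negative).
#' @param gene_lengths Named numeric vector of gene lengths in bases; must
#'   cover every gene in `counts` with positive lengths.
#' @return Genes x samples TPM matrix; columns sum to 1e6.
#' @export
tpm_transform <- function(counts, gene_lengths) {
  assert_expression_matrix(counts, "counts")
  missing <- setdiff(rownames(counts), names(gene_lengths))
  if (length(missing))
    stop_("genes missing from length table: ",
          paste(utils::head(missing, 10L), collapse = ", "),
          if (length(missing) > 10L) sprintf(" (and %d more)", length(missing) - 10L))
  len <- gene_lengths[rownames(counts)]
  if (any(!is.finite(len)) || any(len <= 0))
    stop_("gene lengths must be positive and finite")
  rate <- counts / len
  tot <- colSums(rate)
  if (any(tot == 0))
    stop_("all-zero sample(s): ",
          paste(colnames(counts)[tot == 0], collapse = ", "))
  out <- sweep(rate, 2L, tot, "/") * 1e6
  attr(out, "platform_tag") <- "rnaseq-tpm"
  out
}

#' Quantile normalization of an expression matrix
#'
#' Forces every sample (column) onto a common distribution: the mean of the
#' cross-sample order statistics. Within-column rank order is preserved and
#' tied values receive the mean of the reference values over their rank span.
#'
#' @param mat Genes x samples matrix with at least 2 samples. A single-column
#'   matrix is returned unchanged with a warning.
#' @return Quantile-normalized matrix with the same dimnames.
#' @export
quantile_normalize <- function(mat) {
  assert_expression_matrix(mat, "mat")
  if (ncol(mat) < 2L) {
    warning("quantile normalization needs >= 2 samples; returning input unchanged")
    return(mat)
  }
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  attr(out, "platform_tag") <- attr(mat, "platform_tag")
  out
}

#' Cross-platform scale adjustment
#'
#' Rescales a query matrix by a single global linear factor so that its
#' maximum matches a reference maximum (e.g., matching TPM-scale RNA-seq data
#' to the intensity range of the microarray data a signature was built from).
#' Ratios between entries, and hence all sample-sample correlations, are
#' preserved exactly.
#'
#' @param query Genes x samples matrix with a positive maximum.
#' @param reference_max Positive target maximum.
#' @return Rescaled matrix with `max(out) == reference_max`.
#' @export
cross_platform_scale <- function(query, reference_max) {
  assert_expression_matrix(query, "query")
  assert_scalar_number(reference_max, "reference_max", positive = TRUE)
  m <- max(query)
  if (m <= 0) stop_("query matrix is all zero; cannot rescale")
  out <- query * (reference_max / m)
  attr(out, "platform_tag") <- attr(query, "platform_tag")
  out
}
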