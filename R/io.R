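#' Validate a gene-by-sample count matrix
#'
#' Checks the container invariants every downstream computation relies on:
#' a numeric matrix of non-negative integers with unique, non-empty gene
#' rownames and sample colnames. Violations raise an error naming the
#' offending gene/sample so a bad input file is diagnosable.
#'
#' @param counts numeric matrix, genes in rows, samples in columns.
#' @return the matrix, invisibly, with storage mode coerced where needed.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stopf("counts must be a numeric matrix (genes x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate gene id: '%s'",
          rownames(counts)[anyDuplicated(rownames(counts))])
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate sample id: '%s'",
          colnames(counts)[anyDuplicated(colnames(counts))])
  if (anyNA(counts)) {
    idx <- which(is.na(counts), arr.ind = TRUE)[1L, ]
    stopf("missing count for gene '%s', sample '%s'",
          rownames(counts)[idx[1L]], colnames(counts)[idx[2L]])
  }
  bad <- counts < 0 | counts != round(counts)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stopf("count for gene '%s', sample '%s' is %s; counts must be non-negative integers",
          rownames(counts)[idx[1L]], colnames(counts)[idx[2L]],
          format(counts[idx[1L], idx[2L]]))
  }
  invisible(counts)
}

#' Read a count matrix from TSV or MatrixMarket
#'
#' TSV layout: tab-separated, UTF-8, header row of sample ids, first column
#' `gene_id`, no quoting. MatrixMarket (`mtx`) layout: coordinate integer
#' matrix plus two sidecar files with one gene id / one sample id per line.
#'
#' @param path path to the matrix file.
#' @param format `"tsv"` or `"mtx"`.
#' @param genes_file,samples_file id sidecars for `mtx`; default
#'   `<path>.genes` / `<path>.samples`.
#' @return validated integer matrix, genes in rows, samples in columns.
#' @seealso [write_count_matrix()]
#' @export
read_count_matrix <- function(path, format = c("tsv", "mtx"),
                              genes_file = paste0(path, ".genes"),
                              samples_file = paste0(path, ".samples")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "tsv") {
    df <- read.delim(path, check.names = FALSE, quote = "",
                     stringsAsFactors = FALSE)
    if (ncol(df) < 2L || names(df)[1L] != "gene_id")
      stopf("count TSV must have a 'gene_id' first column and >= 1 sample column")
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) {
      j <- which(!vapply(df[-1L], is.numeric, logical(1L)))[1L]
      stopf("non-numeric counts in sample column '%s'", names(df)[-1L][j])
    }
    rownames(m) <- as.character(df[[1L]])
  } else {
    for (f in c(genes_file, samples_file))
      if (!file.exists(f)) stopf("sidecar file not found: %s", f)
    mm <- Matrix::readMM(path)
    m <- as.matrix(mm)
    gid <- readLines(genes_file)
    sid <- readLines(samples_file)
    if (length(gid) != nrow(m) || length(sid) != ncol(m))
      stopf("sidecar id counts (%d genes, %d samples) do not match matrix dim %d x %d",
            length(gid), length(sid), nrow(m), ncol(m))
    dimnames(m) <- list(gid, sid)
  }
  validate_counts(m)
  storage.mode(m) <- "double"
  m
}

#' Write a count matrix to TSV or MatrixMarket
#'
#' Inverse of [read_count_matrix()]; a write/read round trip is exact.
#'
#' @inheritParams read_count_matrix
#' @param counts validated count matrix.
#' @export
write_count_matrix <- function(counts, path, format = c("tsv", "mtx"),
                               genes_file = paste0(path, ".genes"),
                               samples_file = paste0(path, ".samples")) {
  format <- match.arg(format)
  validate_counts(counts)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(rownames(counts), genes_file)
    writeLines(colnames(counts), samples_file)
  }
  invisible(path)
}

#' Read a gene annotation table
#'
#' TSV with columns `gene_id`, `effective_length` (bp, cumulative exonic
#' length), `gc_fraction` (in \[0, 1\]).
#'
#' @param path path to the annotation TSV.
#' @return data.frame with the three validated columns.
#' @export
read_annotation <- function(path) {
  df <- read_required_tsv(path, c("gene_id", "effective_length", "gc_fraction"))
  df$gene_id <- as.character(df$gene_id)
  if (anyDuplicated(df$gene_id))
    stopf("duplicate gene id in annotation: '%s'",
          df$gene_id[anyDuplicated(df$gene_id)])
  bad <- !is.finite(df$effective_length) | df$effective_length < 1
  if (any(bad))
    stopf("effective_length must be >= 1 bp (gene '%s')", df$gene_id[bad][1L])
  bad <- !is.finite(df$gc_fraction) | df$gc_fraction < 0 | df$gc_fraction > 1
  if (any(bad))
    stopf("gc_fraction must lie in [0, 1] (gene '%s')", df$gene_id[bad][1L])
  df
}

#' Read a sample metadata table
#'
#' TSV with a `sample_id` column plus arbitrary covariates. Empty fields in
#' numeric columns become `NA`; ids must be unique.
#'
#' @param path path to the metadata TSV.
#' @return data.frame keyed by `sample_id`.
#' @export
read_samples <- function(path) {
  df <- read_required_tsv(path, "sample_id")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stopf("duplicate sample id in metadata: '%s'",
          df$sample_id[anyDuplicated(df$sample_id)])
  df
}

#' Read a latent-factor table
#'
#' TSV with `sample_id` plus one numeric column per factor (e.g. externally
#' computed PEER covariates). When `sample_ids` is given the factor table
#' must cover exactly that sample set; a mismatch error lists the symmetric
#' difference.
#'
#' @param path path to the factor TSV.
#' @param sample_ids optional character vector to check and order against.
#' @return numeric matrix, samples in rows (named), factors in columns, with
#'   attribute `provenance = "external-file"`.
#' @export
read_factors <- function(path, sample_ids = NULL) {
  df <- read_required_tsv(path, "sample_id")
  ids <- as.character(df$sample_id)
  if (anyDuplicated(ids))
    stopf("duplicate sample id in factor table: '%s'", ids[anyDuplicated(ids)])
  f <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  if (ncol(f) == 0L) stopf("factor table has no factor columns")
  if (!is.numeric(f)) stopf("factor columns must all be numeric")
  rownames(f) <- ids
  if (!is.null(sample_ids)) {
    extra <- setdiff(ids, sample_ids)
    missing <- setdiff(sample_ids, ids)
    if (length(extra) || length(missing))
      stopf("factor table sample set differs from matrix: extra {%s}; missing {%s}",
            paste(extra, collapse = ", "), paste(missing, collapse = ", "))
    f <- f[sample_ids, , drop = FALSE]
  }
  attr(f, "provenance") <- "external-file"
  f
}

#' Write a latent-factor table
#' @param factors samples-by-factors numeric matrix with sample rownames.
#' @param path output TSV path.
#' @export
write_factors <- function(factors, path) {
  df <- data.frame(sample_id = rownames(factors), factors,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_required_tsv <- function(path, required) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.delim(path, check.names = FALSE, quote = "",
                   stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stopf("%s: missing required column(s): %s", path,
          paste(miss, collapse = ", "))
  df
}

# report gene/sample set agreement between a matrix and side tables
check_ids_match <- function(matrix_ids, table_ids, what) {
  extra <- setdiff(table_ids, matrix_ids)
  missing <- setdiff(matrix_ids, table_ids)
  if (length(extra) || length(missing))
    stopf("%s ids do not match the matrix: extra {%s}; missing {%s}", what,
          paste(extra, collapse = ", "), paste(missing, collapse = ", "))
  invisible(TRUE)
}
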