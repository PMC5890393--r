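#' Read a counts table
#'
#' Two on-disk layouts are supported: a TSV with gene ids in the first column
#' and one column per sample, and MatrixMarket (\code{.mtx}) with sibling
#' \code{<stem>.rownames.txt} / \code{<stem>.colnames.txt} files holding gene
#' and sample ids. Both round-trip integer counts losslessly through
#' \code{\link{write_counts}}.
#'
#' @param path file path (\code{.tsv}/\code{.txt} or \code{.mtx}).
#' @param biotype optional named biotype vector passed to
#'   \code{\link{expression_matrix}}; defaults to \code{"coding"} for all.
#' @return \code{ExpressionMatrix}.
#' @export
read_counts <- function(path, biotype = "coding") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rn <- readLines(paste0(stem, ".rownames.txt"))
    cn <- readLines(paste0(stem, ".colnames.txt"))
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop("MTX dimension mismatch with rownames/colnames sidecar files")
    dimnames(m) <- list(rn, cn)
    return(expression_matrix(m, biotype))
  }
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first)) stop("empty counts file: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("counts TSV needs a gene-id column plus >=1 sample column")
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in counts TSV (ragged rows?): ", path)
  rownames(m) <- as.character(tab[[1]])
  expression_matrix(m, biotype)
}

#' Write a counts table
#'
#' @param mat \code{ExpressionMatrix}.
#' @param path destination; \code{.mtx} selects MatrixMarket with id sidecars,
#'   anything else a TSV with a leading \code{gene} column.
#' @export
write_counts <- function(mat, path) {
  counts <- mat$counts
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(rownames(counts), paste0(stem, ".rownames.txt"))
    writeLines(colnames(counts), paste0(stem, ".colnames.txt"))
  } else {
    df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname read_counts
#' @export
read_sample_metadata <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("sample", "group", "total_reads")
  if (!all(need %in% names(tab)))
    stop("metadata TSV must have columns: ", paste(need, collapse = ", "))
  sample_metadata(tab$sample, tab$group, tab$total_reads)
}

#' @rdname write_counts
#' @param meta metadata data.frame.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
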