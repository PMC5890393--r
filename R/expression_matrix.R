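#' Expression matrix container
#'
#' Bundles a genes x samples matrix of raw integer counts with a per-gene
#' biotype (\code{"coding"} or \code{"lncRNA"}) and, after
#' \code{\link{normalize_median_of_ratios}}, per-sample size factors and
#' normalized counts.
#'
#' @param counts integer matrix, genes in rows, samples in columns; rownames
#'   are gene ids, colnames sample ids. No duplicates, no negatives.
#' @param biotype named character vector (\code{coding}/\code{lncRNA}) covering
#'   every gene, or a single value recycled to all genes.
#' @return An object of class \code{ExpressionMatrix}: a list with elements
#'   \code{counts}, \code{biotype}, and (once normalized) \code{size_factors}
#'   and \code{normalized}.
#' @export
expression_matrix <- function(counts, biotype = "coding") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "double"  # keeps > .Machine$integer.max totals safe
  if (length(biotype) == 1L) biotype <- stats::setNames(rep(biotype, nrow(counts)), rownames(counts))
  if (!all(rownames(counts) %in% names(biotype)))
    stop("biotype missing for some genes")
  biotype <- biotype[rownames(counts)]
  if (!all(biotype %in% c("coding", "lncRNA")))
    stop("biotype values must be 'coding' or 'lncRNA'")
  structure(list(counts = counts, biotype = biotype,
                 size_factors = NULL, normalized = NULL),
            class = "ExpressionMatrix")
}

#' @method print ExpressionMatrix
#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%d coding, %d lncRNA)%s\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$biotype == "coding"), sum(x$biotype == "lncRNA"),
              if (is.null(x$normalized)) "" else ", normalized"))
  invisible(x)
}

#' @method dim ExpressionMatrix
#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' Sample metadata table
#'
#' @param sample,group,total_reads equal-length vectors; one row per sample.
#' @return data.frame with columns \code{sample}, \code{group},
#'   \code{total_reads}.
#' @export
sample_metadata <- function(sample, group, total_reads) {
  stopifnot(length(sample) == length(group), length(sample) == length(total_reads))
  if (anyDuplicated(sample)) stop("duplicate sample ids in metadata")
  if (any(total_reads < 0)) stop("total_reads must be >= 0")
  data.frame(sample = as.character(sample), group = as.character(group),
             total_reads = as.numeric(total_reads), stringsAsFactors = FALSE)
}

check_meta_covers <- function(mat, meta) {
  missing <- setdiff(colnames(mat$counts), meta$sample)
  if (length(missing))
    stop("metadata missing for samples: ", paste(missing, collapse = ", "))
  meta[match(colnames(mat$counts), meta$sample), , drop = FALSE]
}

#' Discard low-depth samples
#'
#' Removes every sample whose total mapped reads fall below \code{min_reads}
#' (strictly less than; a sample with exactly \code{min_reads} reads is kept).
#' Column order of the retained samples is preserved.
#'
#' @param mat \code{ExpressionMatrix}.
#' @param meta metadata data.frame from \code{\link{sample_metadata}} covering
#'   all samples in \code{mat}.
#' @param min_reads depth threshold, default 1e6.
#' @return Filtered \code{ExpressionMatrix}; errors if no sample survives.
#' @export
filter_samples <- function(mat, meta, min_reads = 1e6) {
  meta <- check_meta_covers(mat, meta)
  keep <- meta$total_reads >= min_reads
  if (!any(keep))
    stop("no samples pass the read-depth filter; discarded: ",
         paste(meta$sample[!keep], collapse = ", "))
  out <- mat
  out$counts <- mat$counts[, keep, drop = FALSE]
  out$size_factors <- NULL
  out$normalized <- NULL
  out
}

#' Median-of-ratios normalization
#'
#' Computes per-sample size factors as the exponentiated median, over
#' reference genes with nonzero counts in every sample, of the log-ratio of
#' the gene's count to its geometric mean across samples (the convention of
#' the standard count-based DE tools); normalized counts are raw counts
#' divided by the sample's size factor. When no gene is nonzero in all samples the
#' function falls back to library-size factors (column totals scaled to
#' geometric mean 1) with a warning.
#'
#' @param mat \code{ExpressionMatrix} with >= 2 samples.
#' @return \code{ExpressionMatrix} with \code{size_factors} and
#'   \code{normalized} filled in.
#' @export
normalize_median_of_ratios <- function(mat) {
  counts <- mat$counts
  if (ncol(counts) < 2) stop("need at least 2 samples to normalize")
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    warning("no gene nonzero in all samples; falling back to library-size factors")
    totals <- colSums(counts)
    if (any(totals == 0)) stop("sample with zero total counts cannot be normalized")
    sf <- totals / exp(mean(log(totals)))
  } else {
    loggeo <- rowMeans(log(counts[ref, , drop = FALSE]))
    sf <- apply(counts[ref, , drop = FALSE], 2, function(col)
      exp(stats::median(log(col) - loggeo)))
  }
  out <- mat
  out$size_factors <- stats::setNames(sf, colnames(counts))
  out$normalized <- sweep(counts, 2, sf, "/")
  out
}
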