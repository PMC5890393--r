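#' Gene annotation set
#'
#' Holds gene models (coding and lncRNA) with their exon structure. All
#' internal coordinates are 0-based half-open; conversion from the 1-based
#' closed GFF3 convention happens only at the I/O boundary
#' (\code{\link{read_annotation}} / \code{\link{write_annotation_gff3}}).
#' Exons are merged (overlaps collapsed) and sorted at construction; the gene
#' span and derived features (exonic length in nt, exon count) are recomputed
#' from the merged exons.
#'
#' @param genes data.frame with columns \code{gene_id}, \code{biotype}
#'   (\code{coding}/\code{lncRNA}), \code{contig}, \code{strand} (+/-).
#' @param exons data.frame with columns \code{gene_id}, \code{start},
#'   \code{end} (0-based half-open); every gene must have >= 1 exon.
#' @return Object of class \code{GeneAnnotation}: list with merged
#'   \code{genes} (plus \code{start}, \code{end}, \code{length},
#'   \code{n_exons}) and \code{exons} data.frames.
#' @export
gene_annotation <- function(genes, exons) {
  need_g <- c("gene_id", "biotype", "contig", "strand")
  if (!all(need_g %in% names(genes))) stop("genes needs columns: ", paste(need_g, collapse = ", "))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids in annotation")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be + or -")
  if (!all(genes$biotype %in% c("coding", "lncRNA")))
    stop("biotype must be coding or lncRNA")
  if (!all(c("gene_id", "start", "end") %in% names(exons)))
    stop("exons needs columns gene_id, start, end")
  if (any(exons$end <= exons$start)) stop("exon end must be > start (0-based half-open)")
  orphan <- setdiff(exons$gene_id, genes$gene_id)
  if (length(orphan)) stop("exons for unknown genes: ", paste(orphan, collapse = ", "))
  noex <- setdiff(genes$gene_id, exons$gene_id)
  if (length(noex)) stop("genes without exons: ", paste(noex, collapse = ", "))

  # merge overlapping exons per gene, half-open
  merged <- do.call(rbind, lapply(split(exons, exons$gene_id), function(ex) {
    ir <- IRanges::reduce(IRanges::IRanges(start = ex$start + 1L, end = ex$end))
    data.frame(gene_id = ex$gene_id[1], start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  }))
  rownames(merged) <- NULL
  merged <- merged[order(match(merged$gene_id, genes$gene_id), merged$start), ]

  spl <- split(merged, merged$gene_id)[genes$gene_id]
  genes$start <- vapply(spl, function(e) min(e$start), numeric(1))
  genes$end <- vapply(spl, function(e) max(e$end), numeric(1))
  genes$length <- vapply(spl, function(e) sum(e$end - e$start), numeric(1))
  genes$n_exons <- vapply(spl, nrow, integer(1))
  rownames(genes) <- NULL
  structure(list(genes = genes, exons = merged), class = "GeneAnnotation")
}

#' @method print GeneAnnotation
#' @export
print.GeneAnnotation <- function(x, ...) {
  cat(sprintf("GeneAnnotation: %d genes (%d coding, %d lncRNA), %d merged exons\n",
              nrow(x$genes), sum(x$genes$biotype == "coding"),
              sum(x$genes$biotype == "lncRNA"), nrow(x$exons)))
  invisible(x)
}

#' Subset an annotation by gene id
#' @param ann \code{GeneAnnotation}; \code{ids} gene ids to keep.
#' @param ids character vector of gene ids.
#' @export
annotation_subset <- function(ann, ids) {
  gene_annotation(ann$genes[ann$genes$gene_id %in% ids,
                            c("gene_id", "biotype", "contig", "strand")],
                  ann$exons[ann$exons$gene_id %in% ids, ])
}

ann_granges <- function(ann, what = c("exons", "genes")) {
  what <- match.arg(what)
  if (what == "exons") {
    g <- ann$exons
    meta <- ann$genes[match(g$gene_id, ann$genes$gene_id), ]
    GenomicRanges::GRanges(seqnames = meta$contig,
                           ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
                           strand = meta$strand, gene_id = g$gene_id,
                           biotype = meta$biotype)
  } else {
    g <- ann$genes
    GenomicRanges::GRanges(seqnames = g$contig,
                           ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
                           strand = g$strand, gene_id = g$gene_id, biotype = g$biotype)
  }
}

#' Read a gene annotation
#'
#' GFF3 (gene + exon features with a \code{biotype} attribute on genes) or
#' BED12. GFF3 1-based closed coordinates are converted to the internal
#' 0-based half-open convention; BED12 is already 0-based half-open and reads
#' natively, with the biotype supplied via the \code{biotype} argument since
#' BED carries no attributes.
#'
#' @param path GFF3 (\code{.gff}/\code{.gff3}) or BED (\code{.bed}) file.
#' @param biotype for BED input: a single biotype or a named vector by gene
#'   id. Ignored for GFF3 (taken from the attribute; missing attribute is an
#'   error).
#' @return \code{GeneAnnotation}.
#' @export
read_annotation <- function(path, biotype = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.bed$", path)) {
    gr <- rtracklayer::import(path, format = "bed")
    ids <- as.character(gr$name)
    if (is.null(biotype)) stop("biotype must be supplied for BED input")
    bt <- if (length(biotype) == 1L) stats::setNames(rep(biotype, length(ids)), ids) else biotype
    genes <- data.frame(gene_id = ids, biotype = unname(bt[ids]),
                        contig = as.character(GenomicRanges::seqnames(gr)),
                        strand = as.character(GenomicRanges::strand(gr)),
                        stringsAsFactors = FALSE)
    blocks <- gr$blocks  # block ranges, 1-based relative to feature start
    exons <- do.call(rbind, lapply(seq_along(gr), function(i) {
      b <- blocks[[i]]
      off <- GenomicRanges::start(gr)[i] - 1L  # 0-based feature start
      data.frame(gene_id = ids[i],
                 start = off + IRanges::start(b) - 1L,
                 end = off + IRanges::end(b), stringsAsFactors = FALSE)
    }))
    return(gene_annotation(genes, exons))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gtype <- tolower(as.character(gr$type))
  gg <- gr[gtype == "gene"]
  ge <- gr[gtype == "exon"]
  if (!length(gg)) stop("no gene features in GFF3: ", path)
  if (is.null(gg$biotype) || anyNA(gg$biotype))
    stop("gene feature(s) missing the biotype attribute in ", path)
  gid <- as.character(gg$ID)
  parent <- vapply(as.list(ge$Parent), function(p) as.character(p)[1], "")
  genes <- data.frame(gene_id = gid, biotype = as.character(gg$biotype),
                      contig = as.character(GenomicRanges::seqnames(gg)),
                      strand = as.character(GenomicRanges::strand(gg)),
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = parent,
                      start = GenomicRanges::start(ge) - 1L,
                      end = GenomicRanges::end(ge), stringsAsFactors = FALSE)
  gene_annotation(genes, exons)
}

#' Write an annotation as GFF3
#'
#' Emits gene features (with \code{ID} and \code{biotype} attributes) and
#' their exons (with \code{Parent}), converting internal 0-based half-open
#' coordinates back to GFF3's 1-based closed convention.
#'
#' @param ann \code{GeneAnnotation}.
#' @param path output file.
#' @export
write_annotation_gff3 <- function(ann, path) {
  g <- ann$genes
  e <- ann$exons
  em <- g[match(e$gene_id, g$gene_id), ]
  gene_gr <- GenomicRanges::GRanges(g$contig,
                                    IRanges::IRanges(g$start + 1L, g$end),
                                    strand = g$strand)
  S4Vectors::mcols(gene_gr) <- S4Vectors::DataFrame(
    type = "gene", ID = g$gene_id, biotype = g$biotype)
  exon_gr <- GenomicRanges::GRanges(em$contig,
                                    IRanges::IRanges(e$start + 1L, e$end),
                                    strand = em$strand)
  S4Vectors::mcols(exon_gr) <- S4Vectors::DataFrame(
    type = "exon", Parent = as.character(e$gene_id))
  rtracklayer::export(c(gene_gr, exon_gr), path, format = "gff3")
  invisible(path)
}
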