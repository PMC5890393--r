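#' Classify lncRNAs by genomic position
#'
#' Each lncRNA gets exactly one of three mutually exclusive classes, in
#' priority order:
#' \describe{
#'   \item{antisense_exon_overlap}{>= 1 lncRNA exon overlaps >= 1 coding exon
#'     on the opposite strand (the cis-antisense class).}
#'   \item{intergenic}{the lncRNA gene span overlaps no coding gene span on
#'     either strand (the lincRNA class).}
#'   \item{genic_other}{everything else, e.g. an lncRNA inside a coding
#'     intron or overlapping on the same strand.}
#' }
#' Overlap arithmetic is on the internal 0-based half-open coordinates.
#'
#' @param ann \code{GeneAnnotation} holding both the lncRNAs and the coding
#'   genes (classification is of each lncRNA against all coding genes).
#' @return data.frame \code{gene_id}, \code{class}, \code{supporting}
#'   (comma-joined coding gene ids driving the call; empty for intergenic).
#' @export
classify_lncrna_position <- function(ann) {
  lnc_ids <- ann$genes$gene_id[ann$genes$biotype == "lncRNA"]
  cod_ids <- ann$genes$gene_id[ann$genes$biotype == "coding"]
  if (!length(lnc_ids))
    return(data.frame(gene_id = character(), class = character(),
                      supporting = character(), stringsAsFactors = FALSE))

  exon_gr <- ann_granges(ann, "exons")
  gene_gr <- ann_granges(ann, "genes")
  lnc_ex <- exon_gr[exon_gr$gene_id %in% lnc_ids]
  cod_ex <- exon_gr[exon_gr$gene_id %in% cod_ids]
  lnc_g <- gene_gr[gene_gr$gene_id %in% lnc_ids]
  cod_g <- gene_gr[gene_gr$gene_id %in% cod_ids]

  # exon-exon overlaps on the opposite strand
  hits <- GenomicRanges::findOverlaps(lnc_ex, cod_ex, ignore.strand = TRUE)
  opp <- as.character(GenomicRanges::strand(lnc_ex))[S4Vectors::queryHits(hits)] !=
    as.character(GenomicRanges::strand(cod_ex))[S4Vectors::subjectHits(hits)]
  anti <- split(cod_ex$gene_id[S4Vectors::subjectHits(hits)[opp]],
                lnc_ex$gene_id[S4Vectors::queryHits(hits)[opp]])

  # gene-span overlaps, strand-blind (the intergenic test)
  shits <- GenomicRanges::findOverlaps(lnc_g, cod_g, ignore.strand = TRUE)
  span <- split(cod_g$gene_id[S4Vectors::subjectHits(shits)],
                lnc_g$gene_id[S4Vectors::queryHits(shits)])

  cls <- vapply(lnc_ids, function(id) {
    if (!is.null(anti[[id]])) "antisense_exon_overlap"
    else if (is.null(span[[id]])) "intergenic"
    else "genic_other"
  }, "")
  sup <- vapply(lnc_ids, function(id) {
    s <- if (!is.null(anti[[id]])) anti[[id]] else if (!is.null(span[[id]])) span[[id]] else character()
    paste(sort(unique(s)), collapse = ",")
  }, "")
  data.frame(gene_id = lnc_ids, class = unname(cls), supporting = unname(sup),
             stringsAsFactors = FALSE)
}

#' Compare structural features of two lncRNA sets
#'
#' Reproduces the standard two-group structural comparison: per feature
#' (exonic gene length in nt, exon count) the mean, SEM (sd with the n-1
#' formula over sqrt(n)) and a Mann-Whitney p-value; and, when a coding
#' annotation is supplied, per positional class the counts, proportions and a
#' Fisher exact p-value on the 2x2 table (in class vs not, set A vs set B).
#'
#' @param lnc_a,lnc_b \code{GeneAnnotation} sets of lncRNAs (set A e.g. the
#'   cell-type-enriched lncRNAs, set B the remainder).
#' @param coding optional \code{GeneAnnotation} of coding genes for the
#'   positional comparison.
#' @return list with data.frames \code{features} and (if \code{coding} given)
#'   \code{classes}.
#' @export
compare_structural_features <- function(lnc_a, lnc_b, coding = NULL) {
  fa <- lnc_a$genes[lnc_a$genes$biotype == "lncRNA", ]
  fb <- lnc_b$genes[lnc_b$genes$biotype == "lncRNA", ]
  if (!nrow(fa) || !nrow(fb)) stop("both lncRNA sets must be non-empty")
  feat <- do.call(rbind, lapply(c(length = "length", n_exons = "n_exons"), function(f) {
    data.frame(feature = f,
               mean_a = mean(fa[[f]]), sem_a = sem(fa[[f]]),
               mean_b = mean(fb[[f]]), sem_b = sem(fb[[f]]),
               p = mann_whitney_u(fa[[f]], fb[[f]])$p,
               stringsAsFactors = FALSE)
  }))
  rownames(feat) <- NULL
  out <- list(features = feat)
  if (!is.null(coding)) {
    cls_of <- function(lnc) {
      both <- gene_annotation(
        rbind(lnc$genes[, c("gene_id", "biotype", "contig", "strand")],
              coding$genes[, c("gene_id", "biotype", "contig", "strand")]),
        rbind(lnc$exons, coding$exons))
      classify_lncrna_position(both)
    }
    ca <- cls_of(lnc_a); cb <- cls_of(lnc_b)
    classes <- c("intergenic", "antisense_exon_overlap", "genic_other")
    out$classes <- do.call(rbind, lapply(classes, function(k) {
      na_in <- sum(ca$class == k); nb_in <- sum(cb$class == k)
      tab <- matrix(c(na_in, nrow(ca) - na_in, nb_in, nrow(cb) - nb_in), 2)
      p <- if (any(rowSums(tab) == 0)) 1 else fisher_exact(tab)$p
      data.frame(class = k, count_a = na_in, prop_a = na_in / nrow(ca),
                 count_b = nb_in, prop_b = nb_in / nrow(cb),
                 p = p, stringsAsFactors = FALSE)
    }))
    rownames(out$classes) <- NULL
  }
  out
}
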