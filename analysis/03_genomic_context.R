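#!/usr/bin/env Rscript
# Genomic-context classification of species-A lncRNAs (intergenic /
# cis-antisense exon overlap / genic-other) and the structural comparison of
# cell-type-enriched vs remaining lncRNAs: exonic length and exon count
# (Mann-Whitney), positional class proportions (Fisher exact).

suppressMessages(library(lncnet))

ann <- read_annotation("results/bundle/annotation_A.gff3")
cls <- classify_lncrna_position(ann)
write.table(cls, "results/lncrna_position.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("positional classes:\n")
print(table(cls$class))

enrich <- read.delim("results/enrichment.tsv", stringsAsFactors = FALSE)
lnc_ids <- ann$genes$gene_id[ann$genes$biotype == "lncRNA"]
enriched <- intersect(lnc_ids, enrich$gene)
rest <- setdiff(lnc_ids, enriched)
cat(sprintf("enriched lncRNAs: %d, remaining: %d\n",
            length(enriched), length(rest)))

if (length(enriched) >= 2 && length(rest) >= 2) {
  cod <- annotation_subset(ann, ann$genes$gene_id[ann$genes$biotype == "coding"])
  rep <- compare_structural_features(
    annotation_subset(ann, enriched), annotation_subset(ann, rest), cod)
  write.table(rep$features, "results/structural_features.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(rep$classes, "results/positional_comparison.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat("structural comparison (mean +/- SEM, Mann-Whitney p):\n")
  print(rep$features, digits = 4)
  cat("positional comparison (Fisher exact p):\n")
  print(rep$classes, digits = 4)
}
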