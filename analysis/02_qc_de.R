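#!/usr/bin/env Rscript
# Cell-type expression analysis for species A: discard samples under 1M
# mapped reads, normalize by median-of-ratios, run the three pairwise NB
# Wald contrasts at 5% FDR, assign Venn enrichment categories, and bin
# lncRNA expression into global quartiles.

suppressMessages(library(lncnet))

ann <- read_annotation("results/bundle/annotation_A.gff3")
biotype <- setNames(ann$genes$biotype, ann$genes$gene_id)
mat <- read_counts("results/bundle/counts_celltype_A.tsv", biotype)
meta <- read_sample_metadata("results/bundle/meta_celltype_A.tsv")

kept <- filter_samples(mat, meta, 1e6)
cat(sprintf("sample filter: %d of %d samples retained\n",
            ncol(kept$counts), nrow(meta)))
meta <- meta[meta$sample %in% colnames(kept$counts), ]
norm <- normalize_median_of_ratios(kept)

groups <- sort(unique(meta$group))
de_list <- apply(utils::combn(groups, 2), 2, function(gp)
  de_test_pairwise(norm, meta, gp[1], gp[2]))
de <- do.call(rbind, de_list)
write.table(de, "results/de_results.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sig <- unique(de$gene[!is.na(de$q) & de$q < 0.05])
sig_lnc <- sig[biotype[sig] == "lncRNA"]
expressed_lnc <- sum(rowSums(norm$normalized[biotype[rownames(norm$normalized)] ==
                                               "lncRNA", ] > 0) > 0)
cat(sprintf("detectably expressed lncRNAs: %d; differentially expressed: %d (%.0f%%)\n",
            expressed_lnc, length(sig_lnc),
            100 * length(sig_lnc) / max(1, expressed_lnc)))

enrich <- call_enrichment(de_list, norm, meta, 0.05)
write.table(enrich, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
enr_lnc <- enrich[biotype[enrich$gene] == "lncRNA", ]
cat("lncRNA enrichment categories:\n")
print(table(enr_lnc$category))

quart <- quartile_bins(norm, meta)
write.table(quart, "results/quartiles.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("quartile occupancy by cell type (lncRNAs):\n")
print(table(quart$group[biotype[quart$gene] == "lncRNA"],
            quart$quartile[biotype[quart$gene] == "lncRNA"]))
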