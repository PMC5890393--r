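#' Pipeline configuration
#'
#' Collects every input and threshold of the end-to-end run. Inputs may be
#' given as file paths (read with the package readers) or as in-memory
#' objects. Thresholds default to the conventional values of this analysis:
#' 1M-read sample filter, 5% FDR, co-expression |r| >= 0.95 at nominal
#' p < 0.05, homology E-value < 1e-5.
#'
#' @param counts_celltype,meta_celltype species-A cell-type counts and
#'   metadata (path or object).
#' @param counts_dev_a,counts_dev_b developmental stage counts per species.
#' @param annotation_a optional annotation for the positional
#'   classification stage.
#' @param homology optional homology table (path or data.frame).
#' @param de_genes_a,de_genes_b optional gene sets to network over; when
#'   \code{NULL}, species A falls back to the union of its cell-type DE
#'   genes present in the developmental matrix, species B to all its genes.
#' @param min_reads,fdr,r_pos,r_neg,edge_p,evalue thresholds.
#' @param cor_method \code{"pearson"} or \code{"spearman"}.
#' @param seed seed recorded in the manifest and used for any permutation.
#' @param outdir output directory.
#' @return list of class \code{PipelineConfig}.
#' @export
pipeline_config <- function(counts_celltype, meta_celltype,
                            counts_dev_a, counts_dev_b,
                            annotation_a = NULL, homology = NULL,
                            de_genes_a = NULL, de_genes_b = NULL,
                            min_reads = 1e6, fdr = 0.05,
                            r_pos = 0.95, r_neg = -0.95, edge_p = 0.05,
                            evalue = 1e-5,
                            cor_method = c("pearson", "spearman"),
                            seed = 1, outdir = tempfile("lncnet_run_")) {
  stopifnot(fdr > 0, fdr <= 1, r_pos > 0, r_pos <= 1, r_neg >= -1, r_neg < 0,
            edge_p > 0, edge_p <= 1, evalue > 0, min_reads >= 0)
  structure(list(counts_celltype = counts_celltype,
                 meta_celltype = meta_celltype,
                 counts_dev_a = counts_dev_a, counts_dev_b = counts_dev_b,
                 annotation_a = annotation_a, homology = homology,
                 de_genes_a = de_genes_a, de_genes_b = de_genes_b,
                 min_reads = min_reads, fdr = fdr, r_pos = r_pos,
                 r_neg = r_neg, edge_p = edge_p, evalue = evalue,
                 cor_method = match.arg(cor_method), seed = as.integer(seed),
                 outdir = outdir),
            class = "PipelineConfig")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE))
}

load_input <- function(x, reader, ...) {
  if (is.character(x) && length(x) == 1L) reader(x, ...) else x
}

#' Run the full analysis pipeline
#'
#' Executes, in order: sample filtering, normalization, the three pairwise
#' cell-type DE contrasts, enrichment calls, quartile binning, optional
#' positional classification, per-species co-expression networks with hub
#' module extraction, and cross-species conserved-module matching. All
#' tables are written under \code{config$outdir} together with a JSON run
#' manifest (thresholds, seed, package version, warning count); any stage
#' failure aborts with a stage-named error.
#'
#' @param config \code{PipelineConfig}.
#' @return invisibly, a list with all intermediate and final results.
#' @export
run_pipeline <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  n_warn <- 0L
  wh <- function(w) { n_warn <<- n_warn + 1L; invokeRestart("muffleWarning") }

  ct <- run_stage("load", load_input(config$counts_celltype, read_counts))
  meta <- run_stage("load", load_input(config$meta_celltype, read_sample_metadata))
  dev_a <- run_stage("load", load_input(config$counts_dev_a, read_counts))
  dev_b <- run_stage("load", load_input(config$counts_dev_b, read_counts))

  ct <- run_stage("filter", filter_samples(ct, meta, config$min_reads))
  meta_f <- meta[meta$sample %in% colnames(ct$counts), ]
  ct <- run_stage("normalize", withCallingHandlers(
    normalize_median_of_ratios(ct), warning = wh))

  groups <- sort(unique(meta_f$group))
  if (length(groups) != 3) stop("stage de: expected 3 cell types, got ",
                                length(groups))
  combos <- utils::combn(groups, 2)
  de_list <- run_stage("de", apply(combos, 2, function(gp)
    de_test_pairwise(ct, meta_f, gp[1], gp[2])))
  de_all <- do.call(rbind, de_list)

  enrich <- run_stage("enrichment", call_enrichment(de_list, ct, meta_f, config$fdr))
  quart <- run_stage("quartiles", quartile_bins(ct, meta_f))

  context <- NULL
  if (!is.null(config$annotation_a)) {
    ann <- run_stage("context", load_input(config$annotation_a, read_annotation))
    context <- run_stage("context", classify_lncrna_position(ann))
  }

  de_sig <- unique(de_all$gene[!is.na(de_all$q) & de_all$q < config$fdr])
  de_a <- config$de_genes_a
  if (is.null(de_a)) de_a <- intersect(de_sig, rownames(dev_a$counts))
  if (length(de_a) < 2) de_a <- rownames(dev_a$counts)
  de_b <- config$de_genes_b
  if (is.null(de_b)) de_b <- rownames(dev_b$counts)

  net_a <- run_stage("network_A", withCallingHandlers(
    build_network(dev_a, de_a, config$r_pos, config$r_neg, config$edge_p,
                  config$cor_method), warning = wh))
  net_b <- run_stage("network_B", withCallingHandlers(
    build_network(dev_b, de_b, config$r_pos, config$r_neg, config$edge_p,
                  config$cor_method), warning = wh))
  mods_a <- run_stage("modules_A", extract_modules(net_a, dev_a$biotype, "A"))
  mods_b <- run_stage("modules_B", extract_modules(net_b, dev_b$biotype, "B"))

  matches <- NULL
  if (!is.null(config$homology)) {
    hom <- run_stage("conserve", load_homology(config$homology, config$evalue))
    matches <- run_stage("conserve", match_modules(mods_a, mods_b, hom))
  }

  out <- config$outdir
  utils::write.table(de_all, file.path(out, "de_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(enrich, file.path(out, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(quart, file.path(out, "quartiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(context))
    utils::write.table(context, file.path(out, "lncrna_position.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  write_edges_tsv(net_a, file.path(out, "network_A_edges.tsv"))
  write_edges_tsv(net_b, file.path(out, "network_B_edges.tsv"))
  write_sif(net_a, file.path(out, "network_A.sif"))
  write_sif(net_b, file.path(out, "network_B.sif"))
  if (nrow(net_a)) write_graphml(net_a, dev_a$biotype, file.path(out, "network_A.graphml"))
  if (nrow(net_b)) write_graphml(net_b, dev_b$biotype, file.path(out, "network_B.graphml"))
  if (!is.null(matches))
    report_conserved(matches, file.path(out, "conserved_modules.tsv"),
                     file.path(out, "conserved_summary.json"))

  manifest <- list(
    package = "lncnet",
    version = as.character(utils::packageVersion("lncnet")),
    seed = config$seed,
    thresholds = config[c("min_reads", "fdr", "r_pos", "r_neg", "edge_p", "evalue")],
    cor_method = config$cor_method,
    n_samples_retained = ncol(ct$counts),
    n_de_genes = length(de_sig),
    n_edges_a = nrow(net_a), n_edges_b = nrow(net_b),
    n_modules_a = length(mods_a), n_modules_b = length(mods_b),
    n_conserved = if (is.null(matches)) NA else length(matches),
    n_warnings = n_warn)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  invisible(list(matrix = ct, meta = meta_f, de = de_all, de_list = de_list,
                 enrichment = enrich, quartiles = quart, context = context,
                 network_a = net_a, network_b = net_b,
                 modules_a = mods_a, modules_b = mods_b,
                 conserved = matches, manifest = manifest))
}
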