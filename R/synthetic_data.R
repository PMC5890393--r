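#' Default planted-module specification
#'
#' Five planted lncRNA-hub modules: two conserved across species (linked by
#' orthologous members), one present in both species but with unrelated
#' member genes (the "independently evolved" case), and one private to each
#' species. Sizes are coding-gene member counts; \code{n_negative} members
#' get a sign-flipped latent loading so the network contains negative edges.
#'
#' @param latent_cor within-module latent correlation (0-1) applied to every
#'   module, default 0.99.
#' @return list of module specs (\code{name}, \code{size_a}, \code{size_b},
#'   \code{latent_cor}, \code{conserved}, \code{n_negative_a},
#'   \code{n_negative_b}).
#' @export
default_module_spec <- function(latent_cor = 0.99) {
  list(
    list(name = "M1", size_a = 6, size_b = 6, latent_cor = latent_cor,
         conserved = TRUE, n_negative_a = 1, n_negative_b = 1),
    list(name = "M2", size_a = 5, size_b = 7, latent_cor = latent_cor,
         conserved = TRUE, n_negative_a = 0, n_negative_b = 1),
    list(name = "M3", size_a = 6, size_b = 6, latent_cor = latent_cor,
         conserved = FALSE, n_negative_a = 1, n_negative_b = 0),
    list(name = "M4", size_a = 5, size_b = 0, latent_cor = latent_cor,
         conserved = FALSE, n_negative_a = 0, n_negative_b = 0),
    list(name = "M5", size_a = 0, size_b = 5, latent_cor = latent_cor,
         conserved = FALSE, n_negative_a = 0, n_negative_b = 0)
  )
}

#' Simulation configuration
#'
#' All tunables of the two-species synthetic data generator. Defaults mirror
#' the cell-type study design this package emulates: three sponge cell types
#' with unbalanced replicate counts whose retained samples number
#' archeocyte 15 / choanocyte 10 / pinacocyte 6, a 16-stage developmental
#' series per species, negative-binomial counts (gamma-Poisson), planted
#' co-expression modules with an lncRNA hub, and a many-to-many homology map
#' with a configurable spurious-pair rate.
#'
#' @param seed RNG seed; every draw in the generator flows from it.
#' @param n_coding_a,n_lnc_a,n_coding_b,n_lnc_b gene counts per species.
#' @param n_stages developmental time points, default 16.
#' @param celltype_replicates named vector, cell type -> generated replicate
#'   count (species A only carries the cell-type experiment).
#' @param below_qc named vector, how many of each type's replicates are
#'   planted below the read-depth QC threshold. Use
#'   \code{celltype_replicates = c(archeocyte = 15, choanocyte = 15,
#'   pinacocyte = 9)} with \code{below_qc = c(archeocyte = 0, choanocyte = 5,
#'   pinacocyte = 3)} to emulate a 39-sample experiment in which 31 survive
#'   the 1M-read filter.
#' @param nb_dispersion global NB dispersion alpha (variance =
#'   mu + alpha mu^2), or a per-gene named vector.
#' @param module_spec list of planted modules, see
#'   \code{\link{default_module_spec}}.
#' @param homology_noise spurious homology pairs as a fraction of the real
#'   ortholog pairs.
#' @param library_size_range min/max total reads per retained sample.
#' @param below_qc_range min/max total reads for planted sub-threshold
#'   samples (must stay below 1e6).
#' @param de_fraction fraction of species-A genes planted as cell-type DE
#'   (split equally across the three types).
#' @param de_log2fc planted log2 fold change for DE genes in their type.
#' @param latent_amplitude scale of the latent stage profile on the natural
#'   log mean (1.5 spans ~4.5 log2-units peak-to-trough, a strong
#'   developmental signal).
#' @param base_log_mean,base_log_sd log-normal baseline expression strength.
#' @param frac_intergenic,frac_antisense planted positional-class fractions
#'   for lncRNAs (remainder genic_other); defaults 0.5 / 0.2.
#' @param background_ortholog_frac fraction of non-module coding genes given
#'   a 1:1 ortholog in the other species.
#' @return validated config list of class \code{SimulationConfig}.
#' @export
simulation_config <- function(seed = 1,
                              n_coding_a = 120, n_lnc_a = 30,
                              n_coding_b = 120, n_lnc_b = 30,
                              n_stages = 16,
                              celltype_replicates = c(archeocyte = 15,
                                                      choanocyte = 10,
                                                      pinacocyte = 6),
                              below_qc = NULL,
                              nb_dispersion = 0.05,
                              module_spec = default_module_spec(),
                              homology_noise = 0.005,
                              library_size_range = c(2e6, 8e6),
                              below_qc_range = c(2e5, 9e5),
                              de_fraction = 0.1, de_log2fc = 2,
                              latent_amplitude = 1.5,
                              base_log_mean = log(50), base_log_sd = 1,
                              frac_intergenic = 0.5, frac_antisense = 0.2,
                              background_ortholog_frac = 0.3) {
  if (is.null(below_qc))
    below_qc <- stats::setNames(rep(0L, length(celltype_replicates)),
                                names(celltype_replicates))
  cfg <- list(seed = as.integer(seed), n_coding_a = n_coding_a,
              n_lnc_a = n_lnc_a, n_coding_b = n_coding_b, n_lnc_b = n_lnc_b,
              n_stages = n_stages, celltype_replicates = celltype_replicates,
              below_qc = below_qc, nb_dispersion = nb_dispersion,
              module_spec = module_spec, homology_noise = homology_noise,
              library_size_range = library_size_range,
              below_qc_range = below_qc_range,
              de_fraction = de_fraction, de_log2fc = de_log2fc,
              latent_amplitude = latent_amplitude,
              base_log_mean = base_log_mean, base_log_sd = base_log_sd,
              frac_intergenic = frac_intergenic,
              frac_antisense = frac_antisense,
              background_ortholog_frac = background_ortholog_frac)
  validate_config(cfg)
  structure(cfg, class = "SimulationConfig")
}

validate_config <- function(cfg) {
  with(cfg, {
    if (any(c(n_coding_a, n_lnc_a, n_coding_b, n_lnc_b, n_stages) <= 0))
      stop("all gene counts and n_stages must be > 0")
    if (any(celltype_replicates <= 0)) stop("replicate counts must be > 0")
    if (is.null(names(celltype_replicates)))
      stop("celltype_replicates must be named")
    if (!all(names(below_qc) %in% names(celltype_replicates)) ||
        any(below_qc > celltype_replicates))
      stop("below_qc must name a subset of replicates, <= their counts")
    if (any(nb_dispersion < 0)) stop("nb_dispersion must be >= 0")
    if (homology_noise < 0) stop("homology_noise must be >= 0")
    if (frac_intergenic + frac_antisense > 1 ||
        min(frac_intergenic, frac_antisense) < 0)
      stop("positional fractions must be >= 0 and sum to <= 1")
    for (m in module_spec) {
      if (m$latent_cor < 0 || m$latent_cor > 1)
        stop("module latent correlation must lie in [0, 1]")
      if (m$n_negative_a > m$size_a || m$n_negative_b > m$size_b)
        stop("n_negative exceeds module size")
    }
    for (sp in c("a", "b")) {
      need_cod <- sum(vapply(module_spec, function(m) m[[paste0("size_", sp)]], 0))
      need_lnc <- sum(vapply(module_spec, function(m) m[[paste0("size_", sp)]] > 0, TRUE))
      if (need_cod > get(paste0("n_coding_", sp)) ||
          need_lnc > get(paste0("n_lnc_", sp)))
        stop("module members exceed configured gene counts for species ", toupper(sp))
    }
  })
  invisible(cfg)
}

gene_ids <- function(cfg, species) {
  sp <- toupper(species)
  n_cod <- cfg[[paste0("n_coding_", tolower(species))]]
  n_lnc <- cfg[[paste0("n_lnc_", tolower(species))]]
  list(coding = sprintf("cod%s_%04d", sp, seq_len(n_cod)),
       lnc = sprintf("lnc%s_%04d", sp, seq_len(n_lnc)))
}

# Allocate planted structure: module membership per species, hub lncRNAs,
# cell-type DE genes, positional classes, below-QC sample labels.
plan_truth <- function(cfg) {
  ids_a <- gene_ids(cfg, "a"); ids_b <- gene_ids(cfg, "b")
  alloc <- function(ids, sizes) {
    # sequential disjoint allocation from the pool
    ends <- cumsum(sizes)
    starts <- c(1, utils::head(ends, -1) + 1)
    lapply(seq_along(sizes), function(i)
      if (sizes[i] > 0) ids[starts[i]:ends[i]] else character())
  }
  sizes_a <- vapply(cfg$module_spec, `[[`, 0, "size_a")
  sizes_b <- vapply(cfg$module_spec, `[[`, 0, "size_b")
  mem_a <- alloc(ids_a$coding, sizes_a)
  mem_b <- alloc(ids_b$coding, sizes_b)
  hub_a <- alloc(ids_a$lnc, as.integer(sizes_a > 0))
  hub_b <- alloc(ids_b$lnc, as.integer(sizes_b > 0))
  modules <- lapply(seq_along(cfg$module_spec), function(i) {
    m <- cfg$module_spec[[i]]
    list(name = m$name, latent_cor = m$latent_cor, conserved = isTRUE(m$conserved),
         hub_a = if (length(hub_a[[i]])) hub_a[[i]] else NA_character_,
         hub_b = if (length(hub_b[[i]])) hub_b[[i]] else NA_character_,
         members_a = mem_a[[i]], members_b = mem_b[[i]],
         negative_a = utils::head(mem_a[[i]], m$n_negative_a),
         negative_b = utils::head(mem_b[[i]], m$n_negative_b))
  })
  names(modules) <- vapply(modules, `[[`, "", "name")

  all_a <- c(ids_a$coding, ids_a$lnc)
  types <- names(cfg$celltype_replicates)
  n_de <- round(cfg$de_fraction * length(all_a) / length(types))
  de_pool <- sample(all_a, n_de * length(types))
  de_genes <- data.frame(gene = de_pool,
                         celltype = rep(types, each = n_de),
                         log2fc = rep(cfg$de_log2fc, length(de_pool)),
                         stringsAsFactors = FALSE)

  plant_classes <- function(lnc) {
    n <- length(lnc)
    n_int <- round(cfg$frac_intergenic * n)
    n_anti <- round(cfg$frac_antisense * n)
    cls <- c(rep("intergenic", n_int), rep("antisense_exon_overlap", n_anti),
             rep("genic_other", n - n_int - n_anti))
    data.frame(gene_id = sample(lnc), class = cls, stringsAsFactors = FALSE)
  }

  below <- unlist(lapply(types, function(tp) {
    k <- cfg$below_qc[[tp]]
    if (is.null(k) || k == 0) return(character())
    idx <- sample(cfg$celltype_replicates[[tp]], k)
    sprintf("%s_%02d", tp, sort(idx))
  }))

  list(modules = modules,
       de_genes = de_genes,
       classes_a = plant_classes(ids_a$lnc),
       classes_b = plant_classes(ids_b$lnc),
       below_qc_samples = as.character(below))
}

rnb <- function(n, mu, alpha) {
  if (all(alpha < 1e-12)) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / pmax(alpha, 1e-12))
}

gene_dispersion <- function(cfg, ids) {
  a <- cfg$nb_dispersion
  if (length(a) == 1L) stats::setNames(rep(a, length(ids)), ids) else a[ids]
}

# Latent stage profiles: module members/hubs load sqrt(rho) on a shared
# per-module stage factor (sign-flipped for negative members), background
# genes are pure independent noise. The module factor is standardized and
# each member's idiosyncratic noise is orthogonalized against it, so the
# realized (not just expected) pairwise latent correlation between two
# positive members is rho up to O(1/n) noise-noise covariance.
latent_profiles <- function(cfg, truth, species) {
  ids <- gene_ids(cfg, species)
  genes <- c(ids$coding, ids$lnc)
  lat <- matrix(stats::rnorm(length(genes) * cfg$n_stages),
                nrow = length(genes), dimnames = list(genes, NULL))
  std <- function(v) as.numeric(scale(v))
  for (m in truth$modules) {
    mem <- m[[paste0("members_", tolower(species))]]
    hub <- m[[paste0("hub_", tolower(species))]]
    if (!length(mem) || is.na(hub)) next
    z <- std(stats::rnorm(cfg$n_stages))
    rho <- m$latent_cor
    for (g in c(hub, mem)) {
      s <- if (g %in% m[[paste0("negative_", tolower(species))]]) -1 else 1
      e <- lat[g, ]
      e <- std(e - z * sum(e * z) / sum(z * z))
      lat[g, ] <- s * sqrt(rho) * z + sqrt(1 - rho) * e
    }
  }
  lat
}

#' Simulate a developmental stage-course count matrix
#'
#' One sample per stage; gene means follow exp(baseline + amplitude x latent
#' profile) rescaled per stage to the drawn library size, with NB
#' (gamma-Poisson) sampling on top.
#'
#' @param cfg \code{SimulationConfig}.
#' @param truth planted structure from the bundle (\code{NULL} to re-plan).
#' @param species \code{"A"} or \code{"B"}.
#' @param seed optional seed (set it when calling outside
#'   \code{\link{simulate_bundle}}).
#' @return \code{ExpressionMatrix} with stage columns \code{stage_01}, ...
#' @export
simulate_dev_counts <- function(cfg, truth = NULL, species = "A", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(truth)) truth <- plan_truth(cfg)
  ids <- gene_ids(cfg, species)
  genes <- c(ids$coding, ids$lnc)
  base <- stats::rnorm(length(genes), cfg$base_log_mean, cfg$base_log_sd)
  lat <- latent_profiles(cfg, truth, species)
  mu <- exp(base + cfg$latent_amplitude * lat)
  lib <- stats::runif(cfg$n_stages, cfg$library_size_range[1], cfg$library_size_range[2])
  mu <- sweep(mu, 2, colSums(mu), "/")
  mu <- sweep(mu, 2, lib, "*")
  alpha <- gene_dispersion(cfg, genes)
  counts <- matrix(0, nrow = length(genes), ncol = cfg$n_stages,
                   dimnames = list(genes, sprintf("stage_%02d", seq_len(cfg$n_stages))))
  for (i in seq_along(genes)) counts[i, ] <- rnb(cfg$n_stages, mu[i, ], alpha[i])
  biotype <- stats::setNames(rep(c("coding", "lncRNA"),
                                 c(length(ids$coding), length(ids$lnc))), genes)
  expression_matrix(counts, biotype)
}

#' Simulate the cell-type count matrix (species A)
#'
#' NB counts with a planted mean shift of \code{de_log2fc} log2 units for
#' each gene in its planted cell type; per-sample library sizes are drawn
#' within \code{library_size_range}, except for samples planted below the QC
#' threshold which draw from \code{below_qc_range}. Returns the matrix plus
#' the sample metadata (sample, group, total_reads).
#'
#' @inheritParams simulate_dev_counts
#' @return list with \code{matrix} (\code{ExpressionMatrix}) and \code{meta}.
#' @export
simulate_celltype_counts <- function(cfg, truth = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(truth)) truth <- plan_truth(cfg)
  ids <- gene_ids(cfg, "a")
  genes <- c(ids$coding, ids$lnc)
  base <- exp(stats::rnorm(length(genes), cfg$base_log_mean, cfg$base_log_sd))
  types <- names(cfg$celltype_replicates)
  samples <- unlist(lapply(types, function(tp)
    sprintf("%s_%02d", tp, seq_len(cfg$celltype_replicates[[tp]]))))
  group <- rep(types, times = unlist(cfg$celltype_replicates))
  below <- samples %in% truth$below_qc_samples
  lib <- ifelse(below,
                stats::runif(length(samples), cfg$below_qc_range[1], cfg$below_qc_range[2]),
                stats::runif(length(samples), cfg$library_size_range[1], cfg$library_size_range[2]))
  shift <- matrix(1, nrow = length(genes), ncol = length(types),
                  dimnames = list(genes, types))
  for (i in seq_len(nrow(truth$de_genes)))
    shift[truth$de_genes$gene[i], truth$de_genes$celltype[i]] <-
      2^truth$de_genes$log2fc[i]
  alpha <- gene_dispersion(cfg, genes)
  counts <- matrix(0, nrow = length(genes), ncol = length(samples),
                   dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    mu <- base * shift[, group[j]]
    mu <- mu / sum(mu) * lib[j]
    counts[, j] <- rnb(length(genes), mu, alpha)
  }
  biotype <- stats::setNames(rep(c("coding", "lncRNA"),
                                 c(length(ids$coding), length(ids$lnc))), genes)
  list(matrix = expression_matrix(counts, biotype),
       meta = sample_metadata(samples, group, round(lib)))
}

#' Simulate a gene annotation with controlled lncRNA placement
#'
#' Coding genes (2-4 exons) are laid out along synthetic contigs, 10 per
#' contig, with intergenic gaps of 3-6 kb and introns of 400-800 nt. Each
#' lncRNA is then placed according to its planted positional class:
#' intergenic lncRNAs go into coding-free space past the last coding gene of
#' a contig, cis-antisense lncRNAs get one exon overlapping a coding exon on
#' the opposite strand, and genic_other lncRNAs sit inside a coding intron
#' on the same strand.
#'
#' @inheritParams simulate_dev_counts
#' @return \code{GeneAnnotation} for the species.
#' @export
simulate_annotation <- function(cfg, truth = NULL, species = "A", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(truth)) truth <- plan_truth(cfg)
  ids <- gene_ids(cfg, species)
  classes <- truth[[paste0("classes_", tolower(species))]]

  genes <- list(); exons <- list()
  cursor <- stats::setNames(numeric(0), character(0))
  per_contig <- 10L
  gene_meta <- list()
  for (i in seq_along(ids$coding)) {
    contig <- sprintf("ctg%s_%02d", toupper(species), (i - 1) %/% per_contig + 1)
    if (is.na(cursor[contig])) cursor[contig] <- 0
    start <- cursor[[contig]] + sample(3000:6000, 1)
    n_ex <- sample(2:4, 1)
    ex_len <- sample(150:400, n_ex, replace = TRUE)
    in_len <- sample(400:800, max(n_ex - 1, 0), replace = TRUE)
    ex_start <- start + c(0, cumsum(ex_len[-n_ex] + in_len))
    strand <- sample(c("+", "-"), 1)
    genes[[length(genes) + 1]] <- data.frame(
      gene_id = ids$coding[i], biotype = "coding", contig = contig,
      strand = strand, stringsAsFactors = FALSE)
    exons[[length(exons) + 1]] <- data.frame(
      gene_id = ids$coding[i], start = ex_start, end = ex_start + ex_len,
      stringsAsFactors = FALSE)
    cursor[contig] <- max(ex_start + ex_len)
    gene_meta[[i]] <- list(contig = contig, strand = strand,
                           ex_start = ex_start, ex_len = ex_len)
  }

  n_anti <- sum(classes$class == "antisense_exon_overlap")
  n_other <- sum(classes$class == "genic_other")
  if (n_anti + n_other > length(ids$coding))
    stop("not enough coding genes to host the planted genic lncRNA classes")
  hosts <- sample(length(ids$coding), n_anti + n_other)
  host_anti <- hosts[seq_len(n_anti)]
  host_other <- hosts[n_anti + seq_len(n_other)]
  ai <- 0L; oi <- 0L
  contigs <- unique(vapply(gene_meta, `[[`, "", "contig"))
  ci <- 0L
  for (k in seq_len(nrow(classes))) {
    id <- classes$gene_id[k]
    cls <- classes$class[k]
    if (cls == "intergenic") {
      ci <- ci + 1L
      contig <- contigs[(ci - 1) %% length(contigs) + 1]
      start <- cursor[[contig]] + sample(2000:4000, 1)
      len <- sample(300:800, 1)
      genes[[length(genes) + 1]] <- data.frame(
        gene_id = id, biotype = "lncRNA", contig = contig,
        strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
      exons[[length(exons) + 1]] <- data.frame(
        gene_id = id, start = start, end = start + len, stringsAsFactors = FALSE)
      cursor[contig] <- start + len
    } else if (cls == "antisense_exon_overlap") {
      ai <- ai + 1L
      h <- gene_meta[[host_anti[ai]]]
      len <- min(250, h$ex_len[1] - 50)
      start <- h$ex_start[1] + 25
      genes[[length(genes) + 1]] <- data.frame(
        gene_id = id, biotype = "lncRNA", contig = h$contig,
        strand = if (h$strand == "+") "-" else "+", stringsAsFactors = FALSE)
      exons[[length(exons) + 1]] <- data.frame(
        gene_id = id, start = start, end = start + len, stringsAsFactors = FALSE)
    } else {
      oi <- oi + 1L
      h <- gene_meta[[host_other[oi]]]
      intron_start <- h$ex_start[1] + h$ex_len[1]
      genes[[length(genes) + 1]] <- data.frame(
        gene_id = id, biotype = "lncRNA", contig = h$contig,
        strand = h$strand, stringsAsFactors = FALSE)
      exons[[length(exons) + 1]] <- data.frame(
        gene_id = id, start = intron_start + 20, end = intron_start + 170,
        stringsAsFactors = FALSE)
    }
  }
  gene_annotation(do.call(rbind, genes), do.call(rbind, exons))
}

#' Simulate the cross-species homology map
#'
#' Real ortholog pairs link conserved modules member-to-member and a
#' configured fraction of background coding genes 1:1; spurious pairs are
#' added uniformly at random at rate \code{homology_noise} (relative to the
#' real pair count). All E-values are drawn below the conventional 1e-5
#' cutoff so the map survives loading; the map may be many-to-many.
#'
#' @inheritParams simulate_dev_counts
#' @return data.frame \code{gene_a}, \code{gene_b}, \code{evalue},
#'   \code{description}, \code{spurious}.
#' @export
simulate_homology <- function(cfg, truth = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(truth)) truth <- plan_truth(cfg)
  ids_a <- gene_ids(cfg, "a"); ids_b <- gene_ids(cfg, "b")
  pa <- character(); pb <- character()
  for (m in truth$modules) {
    if (!m$conserved || !length(m$members_a) || !length(m$members_b)) next
    k <- min(length(m$members_a), length(m$members_b))
    pa <- c(pa, m$members_a[seq_len(k)])
    pb <- c(pb, m$members_b[seq_len(k)])
  }
  mod_a <- unlist(lapply(truth$modules, `[[`, "members_a"))
  mod_b <- unlist(lapply(truth$modules, `[[`, "members_b"))
  bg_a <- setdiff(ids_a$coding, mod_a)
  bg_b <- setdiff(ids_b$coding, mod_b)
  n_bg <- round(cfg$background_ortholog_frac * min(length(bg_a), length(bg_b)))
  if (n_bg > 0) {
    pa <- c(pa, sample(bg_a, n_bg))
    pb <- c(pb, sample(bg_b, n_bg))
  }
  n_real <- length(pa)
  spurious <- rep(FALSE, n_real)
  n_noise <- round(cfg$homology_noise * n_real)
  while (n_noise > 0) {
    ca <- sample(ids_a$coding, 1); cb <- sample(ids_b$coding, 1)
    if (!any(pa == ca & pb == cb)) {
      pa <- c(pa, ca); pb <- c(pb, cb); spurious <- c(spurious, TRUE)
      n_noise <- n_noise - 1L
    }
  }
  data.frame(gene_a = pa, gene_b = pb,
             evalue = 10^-stats::runif(length(pa), 6.5, 50),
             description = "", spurious = spurious, stringsAsFactors = FALSE)
}

#' Simulate a full two-species bundle
#'
#' Runs the whole generator under one seed: planted truth, annotations and
#' developmental count matrices for both species, the species-A cell-type
#' experiment with metadata, and the homology map. Deterministic given the
#' config (identical seed + config gives byte-identical bundles).
#'
#' @param cfg \code{SimulationConfig}.
#' @return list of class \code{SimulatedBundle} with elements
#'   \code{counts_celltype_a}, \code{meta_celltype_a}, \code{counts_dev_a},
#'   \code{counts_dev_b}, \code{annotation_a}, \code{annotation_b},
#'   \code{homology}, \code{truth}, \code{config}.
#' @export
simulate_bundle <- function(cfg) {
  validate_config(cfg)
  set.seed(cfg$seed)
  truth <- plan_truth(cfg)
  ann_a <- simulate_annotation(cfg, truth, "A")
  ann_b <- simulate_annotation(cfg, truth, "B")
  ct <- simulate_celltype_counts(cfg, truth)
  dev_a <- simulate_dev_counts(cfg, truth, "A")
  dev_b <- simulate_dev_counts(cfg, truth, "B")
  hom <- simulate_homology(cfg, truth)
  structure(list(counts_celltype_a = ct$matrix, meta_celltype_a = ct$meta,
                 counts_dev_a = dev_a, counts_dev_b = dev_b,
                 annotation_a = ann_a, annotation_b = ann_b,
                 homology = hom, truth = truth, config = cfg),
            class = "SimulatedBundle")
}

#' Write a simulated bundle to disk
#'
#' Emits counts TSVs, sample metadata TSV, GFF3 annotations, the homology
#' TSV and the planted truth as JSON under \code{dir}.
#'
#' @param bundle \code{SimulatedBundle}; \code{dir} output directory.
#' @param dir output directory (created if needed).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(bundle$counts_celltype_a, file.path(dir, "counts_celltype_A.tsv"))
  write_sample_metadata(bundle$meta_celltype_a, file.path(dir, "meta_celltype_A.tsv"))
  write_counts(bundle$counts_dev_a, file.path(dir, "counts_dev_A.tsv"))
  write_counts(bundle$counts_dev_b, file.path(dir, "counts_dev_B.tsv"))
  write_annotation_gff3(bundle$annotation_a, file.path(dir, "annotation_A.gff3"))
  write_annotation_gff3(bundle$annotation_b, file.path(dir, "annotation_B.gff3"))
  utils::write.table(bundle$homology, file.path(dir, "homology.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(dir)
}
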