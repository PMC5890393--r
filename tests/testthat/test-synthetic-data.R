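test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_coding_a = 0), "> 0")
  expect_error(simulation_config(module_spec = list(
    list(name = "M", size_a = 3, size_b = 3, latent_cor = 1.2,
         conserved = TRUE, n_negative_a = 0, n_negative_b = 0))),
    "latent correlation")
  # module demand beyond the configured coding pool is a configuration error
  expect_error(simulation_config(n_coding_a = 10, module_spec = list(
    list(name = "M", size_a = 11, size_b = 3, latent_cor = 0.9,
         conserved = TRUE, n_negative_a = 0, n_negative_b = 0))),
    "exceed")
  expect_error(simulation_config(frac_intergenic = 0.8, frac_antisense = 0.4),
               "fractions")
})

test_that("the generator is deterministic given seed and config", {
  cfg <- simulation_config(seed = 99)
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(b1, b2)
  b3 <- simulate_bundle(simulation_config(seed = 100))
  expect_false(identical(b1$counts_dev_a$counts, b3$counts_dev_a$counts))
})

test_that("planted truth is structurally consistent with the bundle", {
  b <- planted_bundle(seed = 19)
  # every counted gene annotated exactly once, and vice versa
  expect_setequal(rownames(b$counts_dev_a$counts), b$annotation_a$genes$gene_id)
  expect_setequal(rownames(b$counts_dev_b$counts), b$annotation_b$genes$gene_id)
  # module members exist in their count matrices; disjoint within species
  mem_a <- unlist(lapply(b$truth$modules, `[[`, "members_a"))
  expect_true(all(mem_a %in% rownames(b$counts_dev_a$counts)))
  expect_false(anyDuplicated(mem_a) > 0)
  # every conserved module pair shares >= 1 homology pair
  for (m in Filter(function(m) m$conserved, b$truth$modules)) {
    n <- sum(b$homology$gene_a %in% m$members_a &
               b$homology$gene_b %in% m$members_b)
    expect_gte(n, 1)
  }
  # counts are non-negative integers
  expect_true(all(b$counts_celltype_a$counts >= 0))
  expect_true(all(b$counts_celltype_a$counts == round(b$counts_celltype_a$counts)))
})

test_that("realized within-module latent correlations sit at the configured rho", {
  cfg <- simulation_config(seed = 47, nb_dispersion = 0.005)
  set.seed(cfg$seed)
  truth <- lncnet:::plan_truth(cfg)
  lat <- lncnet:::latent_profiles(cfg, truth, "A")
  for (m in truth$modules) {
    if (is.na(m$hub_a) || !length(m$members_a)) next
    for (g in m$members_a) {
      sgn <- if (g %in% m$negative_a) -1 else 1
      expect_equal(sgn * cor(lat[m$hub_a, ], lat[g, ]), m$latent_cor,
                   tolerance = 0.02)
    }
  }
  # background genes stay uncorrelated on average
  bg <- setdiff(rownames(lat), unlist(lapply(truth$modules, function(m)
    c(m$hub_a, m$members_a))))
  cm <- cor(t(lat[bg[1:40], ]))
  expect_lt(mean(abs(cm[upper.tri(cm)])), 0.3)
})

test_that("NB sampling matches the gamma-Poisson moments", {
  set.seed(1)
  mu <- 100; alpha <- 0.1
  draws <- lncnet:::rnb(4000, mu, alpha)
  expect_equal(var(draws), mu + alpha * mu^2, tolerance = 0.1)
  # dispersion -> 0 collapses to Poisson around the mean
  draws0 <- lncnet:::rnb(1000, 500, 0)
  expect_equal(mean(draws0), 500, tolerance = 0.05)
})

test_that("planted sub-threshold samples reproduce the 39-to-31 design", {
  cfg <- simulation_config(
    seed = 23,
    celltype_replicates = c(archeocyte = 15, choanocyte = 15, pinacocyte = 9),
    below_qc = c(archeocyte = 0, choanocyte = 5, pinacocyte = 3))
  b <- simulate_bundle(cfg)
  expect_equal(nrow(b$meta_celltype_a), 39)
  kept <- filter_samples(b$counts_celltype_a, b$meta_celltype_a, 1e6)
  expect_equal(ncol(kept$counts), 31)
  meta_kept <- b$meta_celltype_a[b$meta_celltype_a$sample %in% colnames(kept$counts), ]
  expect_equal(as.integer(table(meta_kept$group)[c("archeocyte", "choanocyte", "pinacocyte")]),
               c(15L, 10L, 6L))
  # exactly the planted samples fall below the threshold
  expect_setequal(setdiff(b$meta_celltype_a$sample, colnames(kept$counts)),
                  b$truth$below_qc_samples)
})

test_that("null cell-type simulation rejects near the nominal rate", {
  cfg <- simulation_config(seed = 29, n_coding_a = 500, n_lnc_a = 100,
                           de_fraction = 0)
  b <- simulate_bundle(cfg)
  m <- normalize_median_of_ratios(
    filter_samples(b$counts_celltype_a, b$meta_celltype_a))
  de <- de_test_pairwise(m, b$meta_celltype_a, "archeocyte", "choanocyte")
  rej <- mean(de$p < 0.05, na.rm = TRUE)
  # generous sanity band; the calibrated check lives in the acceptance suite
  expect_lt(rej, 0.09)
})

test_that("count matrices round-trip losslessly through the TSV writer", {
  b <- planted_bundle(seed = 31)
  f <- tempfile(fileext = ".tsv")
  write_counts(b$counts_dev_a, f)
  back <- read_counts(f, b$counts_dev_a$biotype)
  expect_equal(back$counts, b$counts_dev_a$counts)
})

test_that("bundle export writes all artifacts including valid GFF3", {
  b <- planted_bundle(seed = 37)
  d <- tempfile("bundle_")
  write_bundle(b, d)
  expect_true(all(file.exists(file.path(d, c(
    "counts_celltype_A.tsv", "meta_celltype_A.tsv", "counts_dev_A.tsv",
    "counts_dev_B.tsv", "annotation_A.gff3", "annotation_B.gff3",
    "homology.tsv", "truth.json")))))
  back <- read_annotation(file.path(d, "annotation_A.gff3"))
  expect_equal(back$genes[order(back$genes$gene_id), ]$length,
               b$annotation_a$genes[order(b$annotation_a$genes$gene_id), ]$length)
})
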