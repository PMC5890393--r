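test_that("sample filter applies a strict less-than rule and preserves order", {
  counts <- named_matrix(matrix(5, 4, 3))
  m <- expression_matrix(counts)
  meta <- sample_metadata(colnames(counts), rep("A", 3), c(2e6, 1e6, 999999))
  f <- filter_samples(m, meta)
  expect_identical(colnames(f$counts), c("s01", "s02"))

  # all above threshold: identity
  meta2 <- sample_metadata(colnames(counts), rep("A", 3), c(2e6, 3e6, 4e6))
  expect_identical(filter_samples(m, meta2)$counts, m$counts)

  # everything discarded: hard error naming the samples
  meta3 <- sample_metadata(colnames(counts), rep("A", 3), c(1, 2, 3))
  expect_error(filter_samples(m, meta3), "s01.*s02.*s03")
})

test_that("median-of-ratios size factors match hand computation and symmetry", {
  # identical columns -> all size factors 1
  m <- expression_matrix(named_matrix(matrix(c(4, 8, 12), 3, 3)))
  expect_equal(unname(normalize_median_of_ratios(m)$size_factors), rep(1, 3))

  # doubled column -> doubled size factor
  base <- c(10, 20, 30)
  m2 <- expression_matrix(named_matrix(cbind(base, 2 * base)))
  sf <- normalize_median_of_ratios(m2)$size_factors
  expect_equal(unname(sf[2] / sf[1]), 2)

  # 3x3 hand-computed case: factors proportional to (1, 2, 1)
  m3 <- expression_matrix(named_matrix(rbind(c(10, 20, 10), c(20, 40, 20), c(30, 60, 30))))
  sf3 <- unname(normalize_median_of_ratios(m3)$size_factors)
  expect_equal(sf3 / sf3[1], c(1, 2, 1))

  # normalized = raw / size factor
  n3 <- normalize_median_of_ratios(m3)
  expect_equal(n3$normalized, sweep(n3$counts, 2, n3$size_factors, "/"))
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(31)
  counts <- named_matrix(matrix(rnbinom(600, mu = 80, size = 5), 100, 6))
  sf <- normalize_median_of_ratios(expression_matrix(counts))$size_factors
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(sf), unname(ref), tolerance = 1e-10)
})

test_that("all-zero reference falls back to library-size factors with warning", {
  counts <- named_matrix(rbind(c(10, 0), c(0, 10), c(5, 0)))
  m <- expression_matrix(counts)
  expect_warning(n <- normalize_median_of_ratios(m), "library-size")
  expect_equal(unname(n$size_factors[1] / n$size_factors[2]), 1.5)
})

test_that("BH adjustment matches hand step-up and stats::p.adjust", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(1)
  for (i in 1:5) {
    p <- runif(50)^2
    p[sample(50, 5)] <- NA
    q <- bh_adjust(p)
    expect_equal(q, stats::p.adjust(p, method = "BH"))
    expect_true(all(q >= p, na.rm = TRUE))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("DE test handles all-zero genes, is antisymmetric in the contrast", {
  set.seed(5)
  counts <- named_matrix(rbind(matrix(rnbinom(5 * 10, mu = 50, size = 10), 5),
                               rep(0, 10)))
  m <- expression_matrix(counts)
  meta <- sample_metadata(colnames(counts), rep(c("A", "B"), each = 5), rep(2e6, 10))
  ab <- de_test_pairwise(m, meta, "A", "B")
  ba <- de_test_pairwise(m, meta, "B", "A")
  expect_true(is.na(ab$p[6]))          # zero everywhere: no information
  expect_true(is.na(ab$q[6]))
  expect_equal(ab$p, ba$p)
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_error(de_test_pairwise(m, meta, "A", "C"), "group not present")
})

test_that("DE pipeline is invariant to sample column order", {
  set.seed(9)
  counts <- named_matrix(matrix(rnbinom(40 * 8, mu = 60, size = 8), 40, 8))
  meta <- sample_metadata(colnames(counts), rep(c("A", "B"), each = 4),
                          rep(2e6, 8))
  perm <- sample(8)
  de1 <- de_test_pairwise(expression_matrix(counts), meta, "A", "B")
  de2 <- de_test_pairwise(expression_matrix(counts[, perm]), meta, "A", "B")
  expect_equal(de1[order(de1$gene), ], de2[order(de2$gene), ])
})

test_that("planted fold changes are detected with high power", {
  set.seed(13)
  ng <- 300
  mu <- exp(rnorm(ng, log(50), 1))
  fc <- rep(1, ng); fc[1:30] <- 4
  counts <- named_matrix(cbind(matrix(rnbinom(ng * 5, mu = mu * fc, size = 1 / 0.05), ng),
                               matrix(rnbinom(ng * 5, mu = mu, size = 1 / 0.05), ng)))
  meta <- sample_metadata(colnames(counts), rep(c("A", "B"), each = 5), rep(2e6, 10))
  de <- de_test_pairwise(expression_matrix(counts), meta, "A", "B")
  power <- mean(de$q[1:30] < 0.05)
  expect_gte(power, 0.9)  # regression floor from the first calibration run
  expect_true(all(de$log2fc[1:30] > 0))
})

test_that("enrichment categories follow the highest-mean-among-significant rule", {
  genes <- c("g1", "g2")
  norm <- named_matrix(rbind(c(10, 10, 100, 100, 10, 10),
                             c(5, 5, 5, 5, 5, 5)), genes,
                       sprintf("s%02d", 1:6))
  m <- mat_with_normalized(norm)
  meta <- sample_metadata(colnames(norm),
                          rep(c("archeocyte", "choanocyte", "pinacocyte"), each = 2),
                          rep(2e6, 6))
  mk <- function(ga, gb, q) data.frame(gene = genes,
                                       contrast = paste0(ga, "_vs_", gb),
                                       base_mean_a = 0, base_mean_b = 0,
                                       log2fc = 0, p = q, q = q,
                                       stringsAsFactors = FALSE)
  de_list <- list(mk("archeocyte", "choanocyte", c(0.001, 0.9)),
                  mk("archeocyte", "pinacocyte", c(0.9, 0.9)),
                  mk("choanocyte", "pinacocyte", c(0.001, 0.9)))
  calls <- call_enrichment(de_list, m, meta)
  # g1 significant in cho-vs-arch and cho-vs-pin with top mean in choanocyte
  expect_equal(calls$category[calls$gene == "g1"], "choanocyte")
  # g2 never significant: no call
  expect_false("g2" %in% calls$gene)
})

test_that("planted cell-type genes recover their enrichment category", {
  b <- planted_bundle(seed = 21)
  m <- filter_samples(b$counts_celltype_a, b$meta_celltype_a)
  meta <- b$meta_celltype_a[b$meta_celltype_a$sample %in% colnames(m$counts), ]
  m <- normalize_median_of_ratios(m)
  groups <- sort(unique(meta$group))
  de_list <- apply(utils::combn(groups, 2), 2, function(gp)
    de_test_pairwise(m, meta, gp[1], gp[2]))
  calls <- call_enrichment(de_list, m, meta)
  truth <- b$truth$de_genes
  hit <- merge(truth, calls, by = "gene")
  acc <- mean(hit$category == hit$celltype)
  expect_gte(nrow(hit) / nrow(truth), 0.95)  # nearly all planted genes called
  expect_gte(acc, 0.95)                      # and in the planted category
})

test_that("quartile bins partition genes evenly and skip all-zero genes", {
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 0)
  norm <- named_matrix(matrix(vals, ncol = 1))
  m <- mat_with_normalized(norm)
  meta <- sample_metadata("s01", "A", 2e6)
  qb <- quartile_bins(m, meta)
  expect_equal(nrow(qb), 8)                       # the all-zero gene is unassigned
  expect_equal(as.integer(table(qb$quartile)), rep(2L, 4))
  expect_false("g009" %in% qb$gene)
  # ordering is low -> high
  expect_equal(qb$quartile[match(c("g001", "g008"), qb$gene)], c("Q1", "Q4"))
  # group mean above the 75th-percentile breakpoint lands in Q4
  expect_equal(qb$quartile[qb$gene == "g007"], "Q4")
})
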