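test_that("correlation handles affine, negated and constant profiles", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(correlation_with_p(x, 2 * x + 1)$r, 1)
  expect_equal(correlation_with_p(x, -x)$r, -1)
  expect_warning(r <- correlation_with_p(x, rep(2, 5)), "constant")
  expect_true(is.na(r$r))
  expect_error(correlation_with_p(x, 1:4), "equal length")

  # spearman is rank-based
  expect_equal(correlation_with_p(x, exp(x), method = "spearman")$r, 1)
})

test_that("t-based p tracks the full permutation p for edge-strength profiles", {
  # at edge-relevant correlation strengths (|r| near the 0.95 threshold) the
  # t transform approximates the exhaustive 5!-permutation null closely
  set.seed(3)
  for (i in 1:4) {
    x <- rnorm(5); y <- x + rnorm(5, sd = 0.05)
    robs <- abs(cor(x, y))
    rperm <- apply(all_perms(5), 1, function(id) abs(cor(x, y[id])))
    p_perm <- mean(rperm >= robs - 1e-12)
    p_t <- correlation_with_p(x, y)$p
    expect_lt(abs(p_t - p_perm), 0.02)
  }
})

test_that("edge thresholds are inclusive for r and strict for p", {
  m95 <- correlated_profile_matrix(0.95)
  r_obs <- cor(log2(m95$normalized[1, ] + 1), log2(m95$normalized[2, ] + 1))
  expect_equal(r_obs, 0.95, tolerance = 1e-12)
  # inclusive at the threshold: an edge exactly at r_pos is retained
  expect_equal(nrow(build_network(m95, c("g001", "g002"), r_pos = r_obs)), 1)
  # and dropped as soon as the threshold exceeds it
  expect_equal(nrow(build_network(m95, c("g001", "g002"),
                                  r_pos = r_obs + 1e-9)), 0)

  # r = 0.949 never reaches a 0.95 threshold
  m949 <- correlated_profile_matrix(0.949)
  expect_equal(nrow(build_network(m949, c("g001", "g002"), r_pos = 0.95)), 0)

  # strongly negative correlation enters through the r_neg side
  mneg <- correlated_profile_matrix(-0.99)
  net <- build_network(mneg, c("g001", "g002"))
  expect_equal(net$sign, "negative")
})

test_that("network is invariant to relabeling and stage permutation", {
  b <- planted_bundle(seed = 8)
  genes <- planted_network_genes(b$truth, "a")
  net1 <- build_network(b$counts_dev_a, genes)

  # permute stages (applied to all genes consistently)
  m2 <- b$counts_dev_a
  perm <- sample(ncol(m2$counts))
  m2$counts <- m2$counts[, perm]
  net2 <- build_network(m2, genes)
  expect_equal(net1, net2)

  # canonical ordering: no duplicate unordered pairs, gene_a < gene_b
  expect_true(all(net1$gene_a < net1$gene_b))
  expect_false(anyDuplicated(paste(net1$gene_a, net1$gene_b)) > 0)
})

test_that("planted modules are recovered as hub ego networks", {
  b <- planted_bundle(seed = 7)
  for (sp in c("a", "b")) {
    mat <- b[[paste0("counts_dev_", sp)]]
    genes <- planted_network_genes(b$truth, sp)
    net <- build_network(mat, genes)
    mods <- extract_modules(net, mat$biotype, toupper(sp))
    for (m in b$truth$modules) {
      hub <- m[[paste0("hub_", sp)]]
      mem <- m[[paste0("members_", sp)]]
      if (is.na(hub) || !length(mem)) next
      expect_true(hub %in% names(mods))
      jac <- length(intersect(mods[[hub]]$members, mem)) /
        length(union(mods[[hub]]$members, mem))
      expect_gte(jac, 0.8)
    }
  }
})

test_that("module extraction honors biotypes and star topologies", {
  edges <- data.frame(gene_a = c("cod1", "cod2", "cod3", "lnc1"),
                      gene_b = c("lnc1", "lnc1", "lnc1", "lnc2"),
                      r = 0.99, p = 1e-6, sign = "positive",
                      stringsAsFactors = FALSE)
  bt <- c(cod1 = "coding", cod2 = "coding", cod3 = "coding",
          lnc1 = "lncRNA", lnc2 = "lncRNA")
  mods <- extract_modules(edges, bt)
  # lnc1: star of three coding genes; lnc2 has only a lncRNA edge -> no module
  expect_equal(names(mods), "lnc1")
  expect_equal(mods$lnc1$members, c("cod1", "cod2", "cod3"))
  expect_equal(nrow(mods$lnc1$lnc_edges), 1)

  # two hubs may share coding members
  edges2 <- rbind(edges[1:3, ],
                  data.frame(gene_a = c("cod1", "cod2"), gene_b = "lnc2",
                             r = 0.99, p = 1e-6, sign = "positive",
                             stringsAsFactors = FALSE))
  mods2 <- extract_modules(edges2, bt)
  expect_setequal(names(mods2), c("lnc1", "lnc2"))
  expect_setequal(intersect(mods2$lnc1$members, mods2$lnc2$members),
                  c("cod1", "cod2"))
})

test_that("background-only simulations produce almost no strong correlations", {
  cfg <- simulation_config(seed = 17, n_coding_a = 170, n_lnc_a = 30,
                           module_spec = list())
  mat <- simulate_dev_counts(cfg, species = "A", seed = 17)
  mat <- normalize_median_of_ratios(mat)
  prof <- log2(mat$normalized + 1)
  cm <- cor(t(prof))
  frac <- mean(abs(cm[upper.tri(cm)]) >= 0.95)
  expect_lt(frac, 0.01)
})

test_that("network export formats carry the edges and node attributes", {
  edges <- data.frame(gene_a = "cod1", gene_b = "lnc1", r = 0.99, p = 1e-6,
                      sign = "positive", stringsAsFactors = FALSE)
  bt <- c(cod1 = "coding", lnc1 = "lncRNA")
  sif <- tempfile(fileext = ".sif"); gml <- tempfile(fileext = ".graphml")
  write_sif(edges, sif)
  expect_equal(readLines(sif), "cod1\tcoexpressed\tlnc1")
  write_graphml(edges, bt, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(g)$name, c("cod1", "lnc1"))
  expect_equal(sum(igraph::V(g)$hub == "true" | igraph::V(g)$hub == TRUE), 1)
})
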