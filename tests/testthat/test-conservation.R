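hom_df <- function(a, b, ev = 1e-20) data.frame(gene_a = a, gene_b = b,
                                                evalue = rep(ev, length(a)),
                                                stringsAsFactors = FALSE)

test_that("homology loading enforces the strict E-value cutoff and dedups", {
  tab <- data.frame(gene_a = c("a1", "a2", "a3", "a1", "a1"),
                    gene_b = c("b1", "b2", "b3", "b1", "b4"),
                    evalue = c(1e-10, 1e-5, 9.99e-6, 1e-10, 1e-3),
                    stringsAsFactors = FALSE)
  h <- load_homology(tab)
  # exactly-at-cutoff and above-cutoff rows dropped; duplicate collapsed
  expect_setequal(paste(h$gene_a, h$gene_b), c("a1 b1", "a3 b3"))

  # unicode minus in scientific notation parses
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b\tevalue", "a1\tb1\t1×10−6" , "a2\tb2\t1e-9"), f)
  # the "1x10-6" form is not numeric even after minus mapping: row errors
  expect_error(load_homology(f), "malformed.*line 2")
  writeLines(c("gene_a\tgene_b\tevalue", "a1\tb1\t1e−6", "a2\tb2\t1e-9"), f)
  h2 <- load_homology(f)
  expect_equal(nrow(h2), 2)
  expect_equal(h2$evalue[h2$gene_a == "a1"], 1e-6)
})

test_that("module matching needs at least one shared homologous pair", {
  mods_a <- list(ma = c("a1", "a2"))
  mods_b <- list(mb = c("b1", "b2"))
  expect_length(match_modules(mods_a, mods_b, hom_df(character(), character())), 0)

  m <- match_modules(list(ma = "a1"), list(mb = "b1"), hom_df("a1", "b1"))
  expect_length(m, 1)
  expect_equal(m[[1]]$n_shared, 1)

  # monotonicity: adding pairs never removes a match
  h2 <- hom_df(c("a1", "a2"), c("b1", "b2"))
  m2 <- match_modules(mods_a, mods_b, h2)
  expect_equal(m2[[1]]$n_shared, 2)
})

test_that("matching is symmetric under species transposition", {
  mods_a <- list(m1 = c("a1", "a2"), m2 = c("a3"))
  mods_b <- list(n1 = c("b1"), n2 = c("b2", "b3"))
  h <- hom_df(c("a1", "a3", "a2"), c("b1", "b2", "b3"))
  fwd <- conservation_summary(match_modules(mods_a, mods_b, h))
  ht <- data.frame(gene_a = h$gene_b, gene_b = h$gene_a, evalue = h$evalue,
                   stringsAsFactors = FALSE)
  rev <- conservation_summary(match_modules(mods_b, mods_a, ht))
  expect_setequal(paste(fwd$module_a, fwd$module_b),
                  paste(rev$module_b, rev$module_a))
})

test_that("permutation overlap p behaves at the degenerate extremes", {
  h <- hom_df("a1", "b1")
  # observed sharing 0 -> p = 1
  r0 <- overlap_permutation_p("a2", "b2", c("b1", "b2", "b3"), h,
                              n_perm = 200, seed = 1)
  expect_equal(r0$observed, 0)
  expect_equal(r0$p, 1)
  # module B = whole universe -> every permutation ties -> p = 1
  r1 <- overlap_permutation_p("a1", c("b1", "b2", "b3"), c("b1", "b2", "b3"),
                              h, n_perm = 200, seed = 1)
  expect_equal(r1$p, 1)
})

test_that("permutation p agrees with exact enumeration on a 3-gene universe", {
  # universe {b1,b2,b3}, module size 1, one homologous partner: exact p = 1/3
  h <- hom_df("a1", "b1")
  r <- overlap_permutation_p("a1", "b1", c("b1", "b2", "b3"), h,
                             n_perm = 3000, seed = 42)
  expect_equal(r$observed, 1)
  expect_lt(abs(r$p - 1 / 3), 0.03)
})

test_that("reports are byte-stable and list planted conserved modules only", {
  b <- planted_bundle(seed = 12)
  net_a <- build_network(b$counts_dev_a, planted_network_genes(b$truth, "a"))
  net_b <- build_network(b$counts_dev_b, planted_network_genes(b$truth, "b"))
  mods_a <- extract_modules(net_a, b$counts_dev_a$biotype, "A")
  mods_b <- extract_modules(net_b, b$counts_dev_b$biotype, "B")
  hom <- load_homology(b$homology)
  matches <- match_modules(mods_a, mods_b, hom)
  got <- conservation_summary(matches)
  planted <- Filter(function(m) m$conserved, b$truth$modules)
  expect_setequal(paste(got$module_a, got$module_b),
                  vapply(planted, function(m) paste(m$hub_a, m$hub_b), ""))

  f1 <- tempfile(); f2 <- tempfile()
  report_conserved(matches, f1)
  report_conserved(matches, f2)
  expect_identical(readLines(f1), readLines(f2))

  # empty matches: header-only table
  f3 <- tempfile()
  report_conserved(list(), f3)
  expect_match(readLines(f3)[1], "module_a")
  expect_length(readLines(f3), 1)
})
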