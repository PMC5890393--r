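# Shared fixture builders; everything is generated in code.

# tiny ExpressionMatrix with injected normalized values (bypasses the
# >=2-sample requirement of the normalizer where a test needs it)
mat_with_normalized <- function(norm, biotype = "coding") {
  m <- expression_matrix(round(norm), biotype)
  m$normalized <- norm
  m$size_factors <- stats::setNames(rep(1, ncol(norm)), colnames(norm))
  m
}

named_matrix <- function(x, genes = NULL, samples = NULL) {
  x <- as.matrix(x)
  rownames(x) <- if (is.null(genes)) sprintf("g%03d", seq_len(nrow(x))) else genes
  colnames(x) <- if (is.null(samples)) sprintf("s%02d", seq_len(ncol(x))) else samples
  x
}

# two-gene toy annotation: one coding gene with two exons and one lncRNA
# placed per `where` (intron same strand / overlapping exon opposite strand /
# far away)
toy_annotation <- function(where = c("intron", "antisense", "intergenic")) {
  where <- match.arg(where)
  lnc <- switch(where,
    intron = list(start = 250, end = 350, strand = "+"),
    antisense = list(start = 150, end = 250, strand = "-"),
    intergenic = list(start = 5000, end = 5200, strand = "+"))
  gene_annotation(
    genes = data.frame(gene_id = c("cod1", "lnc1"), biotype = c("coding", "lncRNA"),
                       contig = "ctg1", strand = c("+", lnc$strand),
                       stringsAsFactors = FALSE),
    exons = data.frame(gene_id = c("cod1", "cod1", "lnc1"),
                       start = c(100, 400, lnc$start),
                       end = c(200, 500, lnc$end), stringsAsFactors = FALSE))
}

# profiles with an exact target sample correlation, embedded in an
# ExpressionMatrix via the normalized slot (counts are placeholders)
correlated_profile_matrix <- function(r_target, n = 16, seed = 5) {
  set.seed(seed)
  x <- as.numeric(scale(rnorm(n)))
  z <- rnorm(n)
  z <- as.numeric(scale(residuals(lm(z ~ x))))
  y <- r_target * x + sqrt(1 - r_target^2) * z
  prof <- rbind(x, y) + 10  # keep normalized counts positive
  norm <- 2^prof - 1
  dimnames(norm) <- list(c("g001", "g002"), sprintf("t%02d", seq_len(n)))
  mat_with_normalized(norm)
}

# low-dispersion planted-truth bundle used by several suites
planted_bundle <- function(seed = 7) {
  simulate_bundle(simulation_config(seed = seed, nb_dispersion = 0.005,
                                    homology_noise = 0.01))
}

# all permutations of seq_len(n), one per row (n! x n matrix)
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

planted_network_genes <- function(truth, species = "a") {
  ids <- unique(unlist(lapply(truth$modules, function(m)
    c(m[[paste0("hub_", species)]], m[[paste0("members_", species)]]))))
  ids[!is.na(ids)]
}
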