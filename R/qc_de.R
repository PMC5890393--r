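#' Benjamini-Hochberg adjustment
#'
#' Step-up adjustment with monotonicity enforcement. \code{NA} p-values are
#' passed through unchanged and do not count toward the number of tests.
#'
#' @param p numeric vector of p-values in [0, 1] (NAs allowed).
#' @return Q-values, same length and order as \code{p}.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m) {
    o <- order(pv, decreasing = TRUE)
    ro <- order(o)
    q[ok] <- pmin(1, cummin(m / seq(m, 1) * pv[o]))[ro]
  }
  q
}

# Per-gene method-of-moments NB dispersion pooled across the two groups,
# floored at `floor`: alpha = (pooled within-group variance - mean)/mean^2.
mom_dispersion <- function(xa, xb, floor = 1e-8) {
  na <- length(xa); nb <- length(xb)
  s2 <- ((na - 1) * stats::var(xa) + (nb - 1) * stats::var(xb)) / (na + nb - 2)
  mu <- (mean(xa) + mean(xb)) / 2
  if (!is.finite(s2) || mu <= 0) return(floor)
  max((s2 - mu) / mu^2, floor)
}

#' Pairwise negative-binomial differential expression
#'
#' Wald test on normalized group means under an NB model: per gene, the
#' dispersion is estimated by pooled method of moments (floored at 1e-8), the
#' statistic is the log mean ratio over its delta-method standard error, and
#' the p-value is taken from a t reference distribution with
#' \eqn{n_A + n_B - 2} degrees of freedom (small replicate counts make the
#' normal reference anticonservative). Genes with zero raw counts in every
#' sample of both groups get \code{p = NA} and are excluded from the BH
#' adjustment, which is applied within the contrast.
#'
#' @param mat \code{ExpressionMatrix}; normalized on the fly if needed.
#' @param meta sample metadata covering \code{mat}'s samples.
#' @param group_a,group_b group labels to contrast (log2 fold change is
#'   A over B).
#' @param pseudocount added to group means for the fold change and Wald
#'   denominator so all-zero groups stay finite; default 0.5.
#' @return data.frame with one row per gene: \code{gene}, \code{contrast},
#'   \code{base_mean_a}, \code{base_mean_b}, \code{log2fc}, \code{p}, \code{q}.
#' @export
de_test_pairwise <- function(mat, meta, group_a, group_b, pseudocount = 0.5) {
  meta <- check_meta_covers(mat, meta)
  for (g in c(group_a, group_b))
    if (!g %in% meta$group) stop("group not present in metadata: ", g)
  sa <- meta$sample[meta$group == group_a]
  sb <- meta$sample[meta$group == group_b]
  if (length(sa) < 2 || length(sb) < 2)
    stop("both groups need >= 2 samples")
  if (is.null(mat$normalized)) mat <- normalize_median_of_ratios(mat)
  xa <- mat$normalized[, sa, drop = FALSE]
  xb <- mat$normalized[, sb, drop = FALSE]
  ra <- mat$counts[, sa, drop = FALSE]
  rb <- mat$counts[, sb, drop = FALSE]
  na <- length(sa); nb <- length(sb)

  mu_a <- rowMeans(xa); mu_b <- rowMeans(xb)
  allzero <- rowSums(ra) == 0 & rowSums(rb) == 0
  p <- lfc <- rep(NA_real_, nrow(xa))
  for (i in which(!allzero)) {
    alpha <- mom_dispersion(xa[i, ], xb[i, ])
    va <- (mu_a[i] + alpha * mu_a[i]^2) / na
    vb <- (mu_b[i] + alpha * mu_b[i]^2) / nb
    ma <- mu_a[i] + pseudocount
    mb <- mu_b[i] + pseudocount
    se <- sqrt(va / ma^2 + vb / mb^2)
    w <- (log(ma) - log(mb)) / se
    p[i] <- 2 * stats::pt(-abs(w), df = na + nb - 2)
    lfc[i] <- log2(ma / mb)
  }
  data.frame(gene = rownames(xa),
             contrast = paste0(group_a, "_vs_", group_b),
             base_mean_a = mu_a, base_mean_b = mu_b,
             log2fc = lfc, p = p, q = bh_adjust(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cell-type enrichment (Venn) assignment
#'
#' A gene is differentially expressed if \code{q < q_threshold} in at least
#' one pairwise contrast. Its Venn category is the set of cell types whose
#' normalized group mean exceeds that of every cell type they were
#' significantly compared against; cell types involved in no significant
#' contrast for the gene remain in the set (the gene is not distinguishable
#' from them). Singleton sets are the "X-enriched" calls. Genes with no
#' significant contrast get no call.
#'
#' @param de_list list of the three pairwise \code{\link{de_test_pairwise}}
#'   results.
#' @param mat normalized \code{ExpressionMatrix}.
#' @param meta sample metadata.
#' @param q_threshold FDR cutoff, default 0.05.
#' @return data.frame \code{gene}, \code{category} ("+"-joined sorted cell
#'   types), one row per DE gene.
#' @export
call_enrichment <- function(de_list, mat, meta, q_threshold = 0.05) {
  de <- do.call(rbind, de_list)
  groups <- sort(unique(meta$group))
  if (length(groups) != 3) stop("expected exactly 3 cell types")
  pairs <- unique(de$contrast)
  if (length(pairs) != 3) stop("expected all 3 pairwise contrasts")
  if (is.null(mat$normalized)) mat <- normalize_median_of_ratios(mat)
  meta <- check_meta_covers(mat, meta)
  gmean <- sapply(groups, function(g)
    rowMeans(mat$normalized[, meta$sample[meta$group == g], drop = FALSE]))

  sig <- de[!is.na(de$q) & de$q < q_threshold, ]
  if (!nrow(sig))
    return(data.frame(gene = character(), category = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(sig$contrast, "_vs_", fixed = TRUE)
  sig$ga <- vapply(parts, `[`, "", 1)
  sig$gb <- vapply(parts, `[`, "", 2)
  out <- lapply(split(sig, sig$gene), function(d) {
    keep <- groups
    for (k in seq_len(nrow(d))) {
      lo <- if (gmean[d$gene[1], d$ga[k]] >= gmean[d$gene[1], d$gb[k]]) d$gb[k] else d$ga[k]
      keep <- setdiff(keep, lo)
    }
    data.frame(gene = d$gene[1], category = paste(sort(keep), collapse = "+"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Expression quartile binning
#'
#' Summarizes each gene as the median of its nonzero normalized counts across
#' all samples (all groups pooled); the 25/50/75th percentiles of these
#' summaries are the global quartile breakpoints. Within each group, a gene's
#' quartile is the bin of its normalized group mean against those global
#' breakpoints (Q1 low to Q4 high). Genes with zero counts everywhere are
#' left unassigned.
#'
#' @param mat normalized \code{ExpressionMatrix}.
#' @param meta sample metadata.
#' @return data.frame \code{gene}, \code{group}, \code{quartile}.
#' @export
quartile_bins <- function(mat, meta) {
  if (is.null(mat$normalized)) mat <- normalize_median_of_ratios(mat)
  meta <- check_meta_covers(mat, meta)
  norm <- mat$normalized
  nz <- rowSums(norm > 0) > 0
  if (sum(nz) < 4) stop("need >= 4 genes with nonzero expression for quartiles")
  summ <- apply(norm[nz, , drop = FALSE], 1, function(v) stats::median(v[v > 0]))
  brk <- stats::quantile(summ, c(0.25, 0.5, 0.75), names = FALSE)
  groups <- sort(unique(meta$group))
  out <- do.call(rbind, lapply(groups, function(g) {
    gm <- rowMeans(norm[nz, meta$sample[meta$group == g], drop = FALSE])
    data.frame(gene = names(summ), group = g,
               quartile = paste0("Q", findInterval(gm, brk, left.open = TRUE) + 1L),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
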