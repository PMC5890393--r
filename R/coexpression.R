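#' Correlation with p-value
#'
#' Pearson (default) or Spearman correlation between two equal-length
#' profiles with a two-sided p-value from the t transform
#' \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on n-2 degrees of freedom. A constant
#' profile has no defined correlation: \code{r = NA} is returned with a
#' warning and the pair should be skipped.
#'
#' @param x,y numeric profiles, equal length >= 3, finite.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return list with \code{r} and \code{p}.
#' @export
correlation_with_p <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("profiles must have equal length")
  if (length(x) < 3) stop("need >= 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("profiles must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant profile: correlation undefined, pair skipped")
    return(list(r = NA_real_, p = NA_real_))
  }
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r <- stats::cor(x, y)
  n <- length(x)
  r_c <- max(min(r, 1 - 1e-15), -1 + 1e-15)
  tstat <- r_c * sqrt(n - 2) / sqrt(1 - r_c^2)
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Build a thresholded co-expression network
#'
#' Evaluates every unordered pair of the supplied differentially expressed
#' genes on log2(normalized + 1) profiles across stages and keeps an edge
#' when the correlation passes the inclusive magnitude thresholds
#' (\code{r >= r_pos} or \code{r <= r_neg}) at a nominal (uncorrected)
#' \code{p < p_max}; \code{adjust = "BH"} switches the p filter to
#' BH-adjusted values. Constant-profile genes are skipped with one warning.
#'
#' @param mat \code{ExpressionMatrix} over developmental stages (>= 3);
#'   normalized on the fly if needed.
#' @param de_genes character vector of differentially expressed gene ids
#'   (must be a subset of the matrix genes).
#' @param r_pos,r_neg inclusive positive/negative correlation thresholds
#'   (defaults 0.95 / -0.95).
#' @param p_max strict p-value threshold (default 0.05).
#' @param method correlation method, \code{"pearson"} (default) or
#'   \code{"spearman"}.
#' @param adjust \code{"none"} (default, nominal p) or \code{"BH"}.
#' @return data.frame of edges in canonical a < b order: \code{gene_a},
#'   \code{gene_b}, \code{r}, \code{p}, \code{sign}.
#' @export
build_network <- function(mat, de_genes, r_pos = 0.95, r_neg = -0.95,
                          p_max = 0.05, method = c("pearson", "spearman"),
                          adjust = c("none", "BH")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  if (ncol(mat$counts) < 3) stop("need >= 3 stages to build a network")
  missing <- setdiff(de_genes, rownames(mat$counts))
  if (length(missing)) stop("de_genes absent from matrix: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  if (is.null(mat$normalized)) mat <- normalize_median_of_ratios(mat)
  prof <- log2(mat$normalized[de_genes, , drop = FALSE] + 1)
  if (method == "spearman") prof <- t(apply(prof, 1, rank))
  keep <- apply(prof, 1, stats::sd) > 0
  if (any(!keep))
    warning(sum(!keep), " constant profile(s) skipped")
  prof <- prof[keep, , drop = FALSE]
  g <- rownames(prof)
  if (length(g) < 2)
    return(data.frame(gene_a = character(), gene_b = character(),
                      r = numeric(), p = numeric(), sign = character(),
                      stringsAsFactors = FALSE))
  n <- ncol(prof)
  cm <- stats::cor(t(prof))
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  r <- cm[ut]
  r_c <- pmax(pmin(r, 1 - 1e-15), -1 + 1e-15)
  p <- 2 * stats::pt(-abs(r_c * sqrt(n - 2) / sqrt(1 - r_c^2)), df = n - 2)
  if (adjust == "BH") p <- bh_adjust(p)
  sel <- (r >= r_pos | r <= r_neg) & p < p_max
  a <- g[ut[sel, 1]]; b <- g[ut[sel, 2]]
  swap <- a > b
  edges <- data.frame(gene_a = ifelse(swap, b, a), gene_b = ifelse(swap, a, b),
                      r = r[sel], p = p[sel],
                      sign = ifelse(r[sel] >= 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
}

#' Extract lncRNA hub modules
#'
#' One module per lncRNA that has at least one significant edge to a coding
#' gene: the module is the hub's ego network restricted to its coding
#' neighbors. lncRNA-lncRNA edges are recorded on the module but do not
#' create members, and two hubs may share members.
#'
#' @param edges edge data.frame from \code{\link{build_network}}.
#' @param biotype named biotype vector (or \code{GeneAnnotation}) covering
#'   all edge genes.
#' @param species optional species label stored on each module.
#' @return named list of modules; each module is a list with \code{hub},
#'   \code{members} (coding gene ids), \code{edges} (hub-member records),
#'   \code{lnc_edges} (hub-lncRNA records) and \code{species}.
#' @export
extract_modules <- function(edges, biotype, species = NA_character_) {
  if (inherits(biotype, "GeneAnnotation"))
    biotype <- stats::setNames(biotype$genes$biotype, biotype$genes$gene_id)
  genes <- union(edges$gene_a, edges$gene_b)
  unk <- setdiff(genes, names(biotype))
  if (length(unk)) stop("edge genes without biotype: ",
                        paste(utils::head(unk, 5), collapse = ", "))
  hubs <- genes[biotype[genes] == "lncRNA"]
  mods <- lapply(hubs, function(h) {
    inc <- edges[edges$gene_a == h | edges$gene_b == h, , drop = FALSE]
    other <- ifelse(inc$gene_a == h, inc$gene_b, inc$gene_a)
    coding <- biotype[other] == "coding"
    if (!any(coding)) return(NULL)
    structure(list(hub = h, members = sort(other[coding]),
                   edges = inc[coding, , drop = FALSE],
                   lnc_edges = inc[!coding, , drop = FALSE],
                   species = species),
              class = "CoexpressionModule")
  })
  names(mods) <- hubs
  Filter(Negate(is.null), mods)
}

#' @method print CoexpressionModule
#' @export
print.CoexpressionModule <- function(x, ...) {
  cat(sprintf("CoexpressionModule: hub %s (%s), %d coding members\n",
              x$hub, x$species, length(x$members)))
  invisible(x)
}

#' Write network exchange formats
#'
#' \code{write_edges_tsv} writes the edge table; \code{write_sif} the simple
#' interaction format (\code{a coexpressed b}); \code{write_graphml} a
#' GraphML file with biotype and hub-flag node attributes (via igraph);
#' \code{write_node_attributes} the matching node table.
#'
#' @param edges edge data.frame; \code{biotype} named vector.
#' @param path output file.
#' @name network_export
#' @export
write_edges_tsv <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname network_export
#' @export
write_sif <- function(edges, path) {
  writeLines(sprintf("%s\tcoexpressed\t%s", edges$gene_a, edges$gene_b), path)
  invisible(path)
}

#' @rdname network_export
#' @param biotype named biotype vector covering the edge genes.
#' @export
write_graphml <- function(edges, biotype, path) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  nodes <- igraph::V(g)$name
  igraph::V(g)$biotype <- unname(biotype[nodes])
  igraph::V(g)$hub <- unname(biotype[nodes] == "lncRNA")
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname network_export
#' @export
write_node_attributes <- function(edges, biotype, path) {
  nodes <- sort(union(edges$gene_a, edges$gene_b))
  df <- data.frame(gene = nodes, biotype = unname(biotype[nodes]),
                   hub = unname(biotype[nodes] == "lncRNA"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
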