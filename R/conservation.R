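#' Load a homology-pair table
#'
#' Reads a TSV of candidate homologous coding-gene pairs between species A
#' and species B (columns \code{gene_a}, \code{gene_b}, optional
#' \code{evalue}, optional \code{description}) and applies the strict E-value
#' cutoff: only rows with \code{evalue < evalue_max} are retained, so a pair
#' at exactly the cutoff is dropped. Exact and orientation-swapped duplicates
#' collapse to a single record (the smaller E-value wins). Scientific
#' notation tolerates a unicode minus sign.
#'
#' @param table path to a TSV, or a data.frame with the same columns.
#' @param evalue_max strict cutoff, default 1e-5.
#' @return data.frame \code{gene_a}, \code{gene_b}, \code{evalue},
#'   \code{description}.
#' @export
load_homology <- function(table, evalue_max = 1e-5) {
  if (is.character(table)) {
    tab <- utils::read.delim(table, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, colClasses = "character")
  } else tab <- as.data.frame(table, stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(tab)))
    stop("homology table needs columns gene_a, gene_b")
  if (is.null(tab$evalue)) tab$evalue <- 0
  if (is.null(tab$description)) tab$description <- ""
  if (is.character(tab$evalue)) {
    ev <- suppressWarnings(as.numeric(gsub("−", "-", tab$evalue)))
    ev[tab$evalue == ""] <- 0
  } else ev <- as.numeric(tab$evalue)
  bad <- which(is.na(ev) | !nzchar(tab$gene_a) | !nzchar(tab$gene_b) |
                 is.na(tab$gene_a) | is.na(tab$gene_b))
  if (length(bad))
    stop("malformed homology row(s) at line ", paste(bad + 1L, collapse = ", "))
  if (any(ev < 0)) stop("negative E-value")
  tab$evalue <- ev
  tab <- tab[tab$evalue < evalue_max, , drop = FALSE]
  # collapse duplicates, including swapped orientation, keeping min E-value
  key <- ifelse(tab$gene_a <= tab$gene_b,
                paste(tab$gene_a, tab$gene_b, sep = "\r"),
                paste(tab$gene_b, tab$gene_a, sep = "\r"))
  o <- order(key, tab$evalue)
  tab <- tab[o, , drop = FALSE]
  tab <- tab[!duplicated(key[o]), , drop = FALSE]
  rownames(tab) <- NULL
  tab[, c("gene_a", "gene_b", "evalue", "description")]
}

module_members <- function(m) if (inherits(m, "CoexpressionModule")) m$members else as.character(m)

shared_pairs <- function(members_a, members_b, homology) {
  fwd <- homology$gene_a %in% members_a & homology$gene_b %in% members_b
  rev <- homology$gene_a %in% members_b & homology$gene_b %in% members_a
  homology[fwd | rev, , drop = FALSE]
}

#' Match modules across species
#'
#' For every (species A module, species B module) pair, collects the
#' homology pairs with one member in each module and calls the pair a
#' putative evolutionarily conserved module match when at least
#' \code{min_shared} such pairs exist (default 1: a single shared homologue
#' suffices). Matches are sorted by shared-pair count, descending.
#'
#' @param modules_a,modules_b named lists of modules
#'   (\code{\link{extract_modules}} output, or plain character vectors of
#'   member ids).
#' @param homology homology data.frame from \code{\link{load_homology}}.
#' @param min_shared minimum number of shared homologous pairs, default 1.
#' @return list of matches, each a list \code{module_a}, \code{module_b},
#'   \code{n_shared}, \code{shared} (the homology rows); also summarized by
#'   \code{\link{conservation_summary}}.
#' @export
match_modules <- function(modules_a, modules_b, homology, min_shared = 1) {
  out <- list()
  for (na in names(modules_a)) for (nb in names(modules_b)) {
    sp <- shared_pairs(module_members(modules_a[[na]]),
                       module_members(modules_b[[nb]]), homology)
    if (nrow(sp) >= min_shared)
      out[[length(out) + 1L]] <- list(module_a = na, module_b = nb,
                                      n_shared = nrow(sp), shared = sp)
  }
  out[order(vapply(out, `[[`, 0, "n_shared"), decreasing = TRUE)]
}

#' Summarize conserved-module matches
#' @param matches output of \code{\link{match_modules}}.
#' @return data.frame \code{module_a}, \code{module_b}, \code{n_shared}.
#' @export
conservation_summary <- function(matches) {
  if (!length(matches))
    return(data.frame(module_a = character(), module_b = character(),
                      n_shared = integer(), stringsAsFactors = FALSE))
  data.frame(module_a = vapply(matches, `[[`, "", "module_a"),
             module_b = vapply(matches, `[[`, "", "module_b"),
             n_shared = vapply(matches, `[[`, 0, "n_shared"),
             stringsAsFactors = FALSE)
}

#' Permutation p-value for a module overlap
#'
#' How often does a random species-B module of the same size share at least
#' as many homologous pairs with the species-A module as observed? Species-B
#' membership labels are reshuffled (drawn without replacement from
#' \code{universe_b}) \code{n_perm} times; the p-value uses add-one
#' smoothing, \eqn{(1 + \#\{perm \ge obs\}) / (1 + n_{perm})}.
#'
#' @param members_a,members_b module member id vectors (or modules).
#' @param universe_b all candidate species-B gene ids.
#' @param homology homology data.frame.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed; the result is deterministic given it.
#' @return list with \code{p}, \code{observed} shared-pair count.
#' @export
overlap_permutation_p <- function(members_a, members_b, universe_b, homology,
                                  n_perm = 1000, seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  members_a <- module_members(members_a)
  members_b <- module_members(members_b)
  if (!all(members_b %in% universe_b)) stop("members_b must lie in universe_b")
  obs <- nrow(shared_pairs(members_a, members_b, homology))
  set.seed(seed)
  k <- length(members_b)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    mb <- sample(universe_b, k)
    if (nrow(shared_pairs(members_a, mb, homology)) >= obs) hits <- hits + 1L
  }
  list(p = (1 + hits) / (1 + n_perm), observed = obs)
}

#' Report conserved modules
#'
#' Writes the per-module-pair list of shared homologous gene pairs with
#' their description text in a deterministic order (matches by descending
#' shared count, then pairs by gene id), plus an optional JSON summary with
#' counts and permutation p-values.
#'
#' @param matches \code{\link{match_modules}} output.
#' @param path optional TSV destination; \code{json_path} optional JSON
#'   summary destination.
#' @param json_path optional path for the JSON summary.
#' @param perm_p optional named numeric vector of permutation p-values keyed
#'   by \code{module_a|module_b}.
#' @return the report data.frame, invisibly if written.
#' @export
report_conserved <- function(matches, path = NULL, json_path = NULL,
                             perm_p = NULL) {
  rows <- lapply(matches, function(m) {
    sp <- m$shared[order(m$shared$gene_a, m$shared$gene_b), , drop = FALSE]
    data.frame(module_a = m$module_a, module_b = m$module_b,
               gene_a = sp$gene_a, gene_b = sp$gene_b,
               evalue = sp$evalue, description = sp$description,
               stringsAsFactors = FALSE)
  })
  rep <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module_a = character(), module_b = character(),
               gene_a = character(), gene_b = character(),
               evalue = numeric(), description = character(),
               stringsAsFactors = FALSE)
  rownames(rep) <- NULL
  if (!is.null(path))
    utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    summ <- conservation_summary(matches)
    if (!is.null(perm_p))
      summ$perm_p <- unname(perm_p[paste(summ$module_a, summ$module_b, sep = "|")])
    jsonlite::write_json(list(n_conserved = nrow(summ), matches = summ),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  if (is.null(path)) rep else invisible(rep)
}

#' Published sponge conserved-module example
#'
#' Loads the bundled worked example: the published list of homologous
#' coding-gene pairs shared between co-expression modules of the demosponge
#' Amphimedon queenslandica (Aqu2.1 gene ids) and the calcisponge Sycon
#' ciliatum (scigt ids), grouped under three Amphimedon lncRNA hub headings.
#' Module memberships are reconstructed from the pair lists (species A =
#' Amphimedon, species B = Sycon) and the homology table is the printed pair
#' list itself.
#'
#' @return list with \code{modules_a}, \code{modules_b} (member id lists
#'   keyed by hub heading), \code{homology}, and the raw \code{pairs} table.
#' @export
conserved_module_example <- function() {
  path <- system.file("extdata", "sponge_conserved_module_pairs.tsv",
                      package = "lncnet", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  modules_a <- lapply(split(tab$gene_a, tab$module), unique)
  modules_b <- lapply(split(tab$gene_b, tab$module), unique)
  names(modules_b) <- paste0("Sycon_counterpart_of_", names(modules_b))
  homology <- load_homology(tab[, c("gene_a", "gene_b", "description")])
  list(modules_a = modules_a, modules_b = modules_b,
       homology = homology, pairs = tab)
}
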