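#' Format an enrichment overlap ratio
#'
#' Renders the overlap of a subnetwork with a pathway as
#' `"k/K (r)"`, where r = k/K rounded to two decimals — e.g. 6 of 26 genes
#' gives `"6/26 (0.23)"`.
#'
#' @param n_overlap Number of subnetwork genes in the set.
#' @param n_set Set size (within the universe).
#' @return Character scalar.
#' @export
format_ratio <- function(n_overlap, n_set) {
  sprintf("%d/%d (%.2f)", n_overlap, n_set, round(n_overlap / n_set, 2))
}

#' Pathway enrichment of a gene subnetwork
#'
#' Hypergeometric over-representation test of the subnetwork genes in each
#' gene set: with a universe of N genes of which K belong to the set, and
#' n subnetwork genes drawn, the p-value is the upper tail
#' `P(X >= n_overlap)`. Sets are first intersected with the universe; sets
#' with fewer than `min_set_size` genes after intersection are skipped
#' (reported). Adjusted values (`q`) are Benjamini-Hochberg across the
#' tested sets; significance is conventionally claimed at `q < 0.05`.
#'
#' The universe should be the population the subnetwork was drawn from —
#' in this pipeline, all scored genes present in the PPI graph.
#'
#' @param subnetwork_genes Character vector of subnetwork gene IDs (must
#'   be contained in `universe`).
#' @param sets A `gene_set_collection` (see [read_gene_sets()]).
#' @param universe Character vector of background gene IDs.
#' @param min_set_size Minimum within-universe set size to test (default 3).
#' @return `data.frame` with `set_name`, `n_overlap`, `n_set`, `ratio`,
#'   `ratio_label` (`"k/K (r)"`), `p`, `q`, and semicolon-joined
#'   `overlap_genes`, sorted by p.
#' @export
enrich <- function(subnetwork_genes, sets, universe, min_set_size = 3) {
  universe <- unique(universe)
  subnetwork_genes <- unique(subnetwork_genes)
  if (!length(universe)) abort("empty universe")
  if (!length(subnetwork_genes)) abort("empty subnetwork")
  outside <- setdiff(subnetwork_genes, universe)
  if (length(outside))
    abort("subnetwork gene(s) outside the universe: '%s'", outside[1])
  if (!length(sets)) abort("empty gene-set collection")

  trimmed <- lapply(sets, intersect, universe)
  small <- lengths(trimmed) < min_set_size
  if (any(small))
    message(sprintf("%d set(s) below min_set_size after universe intersection; skipped",
                    sum(small)))
  trimmed <- trimmed[!small]
  if (!length(trimmed)) abort("no testable gene sets after filtering")

  N <- length(universe)
  n_draw <- length(subnetwork_genes)
  rows <- lapply(names(trimmed), function(nm) {
    members <- trimmed[[nm]]
    ov <- intersect(subnetwork_genes, members)
    K <- length(members)
    k <- length(ov)
    data.frame(set_name = nm, n_overlap = k, n_set = K, ratio = k / K,
               ratio_label = format_ratio(k, K),
               p = stats::phyper(k - 1, K, N - K, n_draw,
                                 lower.tail = FALSE),
               overlap_genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bh_fdr(res$p)
  res <- res[order(res$p, res$set_name),
             c("set_name", "n_overlap", "n_set", "ratio", "ratio_label",
               "p", "q", "overlap_genes")]
  rownames(res) <- NULL
  res
}
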