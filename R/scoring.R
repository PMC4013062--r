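#' Inverse-normal gene score from an association p-value
#'
#' Converts a (two-sided) association p-value to a gene score: the
#' upper-tail standard-normal quantile, `z = qnorm(1 - p)`, so smaller
#' p-values give larger scores and `z(0.5) = 0`. To keep scores finite, p
#' is clipped into `[1e-16, 1 - 1e-16]` before the transform. The
#' functional form follows the dense-module-search tradition of scoring
#' genes by the probit of their evidence.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Numeric vector of finite gene scores.
#' @export
p_to_z <- function(p) {
  if (!is.numeric(p) || length(p) == 0)
    abort("p must be a non-empty numeric vector")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    abort("p-values must lie in (0, 1]")
  p <- pmin(pmax(p, 1e-16), 1 - 1e-16)
  stats::qnorm(p, lower.tail = FALSE)
}

#' Build the gene score map over a PPI network
#'
#' Restricts association evidence to the genes present in the network and
#' converts it to scores via [p_to_z()]. When several expression features
#' map to one gene (probesets, transcript clusters, exons), the gene is
#' scored from its minimum p-value. Network nodes without any scored
#' feature are dropped from the search graph; the count is reported.
#'
#' @param results Association results (`data.frame` with `feature_id` and
#'   `p`; `effect` is required when `signed = TRUE`). Rows with missing p
#'   (flagged model failures) are ignored.
#' @param network The PPI `igraph`.
#' @param mapping Optional feature-to-gene map (`data.frame` with
#'   `feature_id`, `gene_id`; see [read_feature_map()]). Without it,
#'   feature IDs are taken to be gene IDs.
#' @param signed If `TRUE`, scores carry the sign of the collapsed
#'   feature's effect (a directional variant); default is the
#'   direction-agnostic score used for module search.
#' @return Named numeric vector of gene scores (class `gene_scores`), one
#'   per network gene with evidence.
#' @export
build_score_map <- function(results, network, mapping = NULL,
                            signed = FALSE) {
  stopifnot(is.data.frame(results), all(c("feature_id", "p") %in%
                                          colnames(results)))
  res <- results[is.finite(results$p), , drop = FALSE]
  if (!nrow(res)) abort("no usable p-values in results")
  gene <- if (is.null(mapping)) {
    res$feature_id
  } else {
    mapping$gene_id[match(res$feature_id, mapping$feature_id)]
  }
  keep <- !is.na(gene)
  res <- res[keep, , drop = FALSE]
  gene <- gene[keep]
  ## collapse multiple features per gene: keep the smallest p
  ord <- order(gene, res$p)
  first <- !duplicated(gene[ord])
  collapsed <- res[ord, , drop = FALSE][first, , drop = FALSE]
  collapsed_gene <- gene[ord][first]

  nodes <- igraph::V(network)$name
  in_net <- collapsed_gene %in% nodes
  if (!any(in_net))
    abort("no overlap between scored genes and network nodes")
  z <- p_to_z(collapsed$p[in_net])
  if (signed) z <- z * sign(collapsed$effect[in_net])
  names(z) <- collapsed_gene[in_net]
  dropped <- length(nodes) - length(z)
  message(sprintf(
    "score map: %d scored network genes; %d unscored node(s) dropped; %d scored gene(s) not in network",
    length(z), dropped, sum(!in_net)))
  z <- z[order(names(z))]
  class(z) <- c("gene_scores", class(z))
  z
}
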