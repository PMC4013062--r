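#' Aggregate score of a gene module
#'
#' The module score of a gene set of size k is `Z_m = sum(z_i) / sqrt(k)`,
#' the normalized sum of its members' gene scores. This is the quantity the
#' greedy search maximizes.
#'
#' @param members Character vector of member gene IDs (non-empty).
#' @param scores Gene score map (named numeric; see [build_score_map()]).
#' @return The module score, a single number.
#' @export
module_score <- function(members, scores) {
  if (!length(members)) abort("module has no members")
  miss <- setdiff(members, names(scores))
  if (length(miss)) abort("unscored member gene: '%s'", miss[1])
  sum(scores[members]) / sqrt(length(members))
}

# Adjacency list over the scored node set; used so search_all builds it once.
scored_adjacency <- function(graph, scores) {
  nodes <- intersect(igraph::V(graph)$name, names(scores))
  if (!length(nodes)) abort("no scored nodes in the graph")
  sub <- igraph::induced_subgraph(graph, nodes)
  adj <- igraph::as_adj_list(sub)
  out <- lapply(adj, function(v) igraph::V(sub)$name[as.integer(v)])
  names(out) <- igraph::V(sub)$name
  out
}

grow_from_adjacency <- function(seed, adj, scores) {
  members <- seed
  total <- scores[[seed]]
  score <- total
  trajectory <- score
  cand <- setdiff(adj[[seed]], members)
  repeat {
    if (!length(cand)) break
    cand <- sort(cand)
    k <- length(members)
    gain <- (total + unname(scores[cand])) / sqrt(k + 1)
    best <- which.max(gain)  # first max = lexicographically smallest tie
    if (gain[best] > score) {
      add <- cand[best]
      members <- c(members, add)
      total <- total + scores[[add]]
      score <- gain[best]
      trajectory <- c(trajectory, score)
      cand <- setdiff(unique(c(cand, adj[[add]])), members)
    } else {
      break
    }
  }
  structure(list(seed = seed, members = sort(members),
                 k = length(members), score = score,
                 trajectory = trajectory),
            class = "af_module")
}

#' Grow one dense module from a seed gene
#'
#' Greedy steepest-ascent growth of the module score: starting from the
#' seed, the neighbor of the current module whose addition maximizes the
#' new score is added, but only if the score strictly increases; ties are
#' broken by lexicographic gene ID. The search stops when no neighboring
#' gene can be added. Only scored genes participate (the graph is
#' restricted to the nodes of `scores`), so every module is a connected
#' subgraph of scored genes and its trajectory of scores is strictly
#' increasing.
#'
#' @param seed Seed gene ID (must be a scored node of `graph`).
#' @param graph PPI `igraph`.
#' @param scores Gene score map.
#' @return An `af_module`: list with `seed`, `members` (sorted), `k`,
#'   `score`, and the growth `trajectory` of scores.
#' @export
grow_module <- function(seed, graph, scores) {
  if (!seed %in% names(scores)) abort("unscored seed gene: '%s'", seed)
  if (!seed %in% igraph::V(graph)$name)
    abort("seed gene '%s' not in the network", seed)
  grow_from_adjacency(seed, scored_adjacency(graph, scores), scores)
}

#' @export
print.af_module <- function(x, ...) {
  cat(sprintf("af_module: seed %s, k = %d, score = %.4f\n", x$seed, x$k,
              x$score))
  invisible(x)
}

#' Run the dense-module search from every scored gene
#'
#' Every scored network gene serves as the seed of one greedy search (see
#' [grow_module()]), yielding exactly one module per seed, in lexicographic
#' seed order. Identical member sets reached from different seeds are
#' retained, one per seed.
#'
#' @param graph PPI `igraph`.
#' @param scores Gene score map.
#' @return Named list of `af_module` objects (names = seed genes).
#' @export
search_all <- function(graph, scores) {
  adj <- scored_adjacency(graph, scores)
  seeds <- sort(names(adj))
  out <- lapply(seeds, grow_from_adjacency, adj = adj, scores = scores)
  names(out) <- seeds
  out
}

#' Tabulate a module list
#'
#' @param modules List of `af_module` objects (see [search_all()]).
#' @return `data.frame` with `seed`, `k`, `score`, and semicolon-joined
#'   `members`, sorted by score descending (ties by seed ID).
#' @export
modules_to_df <- function(modules) {
  df <- data.frame(
    seed = vapply(modules, `[[`, "", "seed"),
    k = vapply(modules, `[[`, 0L, "k"),
    score = vapply(modules, `[[`, 0, "score"),
    members = vapply(modules, function(m) paste(m$members, collapse = ";"),
                     ""),
    stringsAsFactors = FALSE, row.names = NULL)
  df[order(-df$score, df$seed), , drop = FALSE]
}

#' Merge the top-scoring modules into a disease subnetwork
#'
#' Selects the `ceiling(top_fraction * M)` modules with the highest scores
#' (ties at the cutoff broken by lexicographic seed ID, so exactly that
#' count is kept) and returns the union of their members together with the
#' PPI edges induced on that union.
#'
#' @param modules List of `af_module` objects.
#' @param top_fraction Fraction of modules to merge, in (0, 1]; default
#'   0.01 ("top 1%").
#' @param graph The PPI `igraph` the modules were grown on.
#' @return An `af_subnetwork`: list with `nodes` (sorted gene IDs),
#'   `graph` (induced `igraph`), `edges` (two-column matrix),
#'   `selected_seeds`, and `n_modules` (number merged).
#' @export
select_and_merge <- function(modules, top_fraction = 0.01, graph) {
  if (!length(modules)) abort("empty module list")
  if (!is_prop(top_fraction, closed_right = TRUE))
    abort("top_fraction must lie in (0, 1]")
  score <- vapply(modules, `[[`, 0, "score")
  seed <- vapply(modules, `[[`, "", "seed")
  n_sel <- ceiling(top_fraction * length(modules))
  sel <- order(-score, seed)[seq_len(n_sel)]
  nodes <- sort(unique(unlist(lapply(modules[sel], `[[`, "members"))))
  sub <- igraph::induced_subgraph(graph, nodes)
  structure(list(nodes = nodes, graph = sub,
                 edges = igraph::as_edgelist(sub),
                 selected_seeds = seed[sel], n_modules = n_sel),
            class = "af_subnetwork")
}

#' @export
print.af_subnetwork <- function(x, ...) {
  cat(sprintf("af_subnetwork: %d nodes, %d edges (union of %d modules)\n",
              length(x$nodes), nrow(x$edges), x$n_modules))
  invisible(x)
}
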