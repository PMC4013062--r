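# Shared fixtures and independent oracles.

# A small, fast simulation configuration for unit tests.
tiny_config <- function(seed = 1, ...) {
  args <- list(n_samples = 300, n_families = 90, n_genes = 80,
               n_signal_genes = 10, planted_module_size = 5,
               signal_effect = 0.5, n_gene_sets = 15,
               gene_set_size_range = c(5L, 15L), seed = seed)
  over <- list(...)
  args[names(over)] <- over
  args$gene_set_size_range <-
    pmin(args$gene_set_size_range, as.integer(args$n_genes))
  do.call(simulation_config, args)
}

# Brute-force Benjamini-Hochberg step-up oracle: for each rank i,
# q_(i) = min_{j >= i} p_(j) * m / j, capped at 1, mapped to input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(ps[i:m] * m / (i:m)))
  }, 0)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Step-by-step reference implementation of the greedy module-growth rule,
# written against an explicit edge table: at each step, evaluate every
# neighboring scored gene by recomputing the full module score from
# scratch, take the best strictly improving candidate (lexicographic
# tie-break), stop when none improves.
oracle_grow <- function(seed, edges, z) {
  members <- seed
  repeat {
    nbrs <- unique(c(edges$b[edges$a %in% members],
                     edges$a[edges$b %in% members]))
    cand <- sort(setdiff(intersect(nbrs, names(z)), members))
    current <- sum(z[members]) / sqrt(length(members))
    best <- NULL
    best_score <- current
    for (cc in cand) {
      sc <- sum(z[c(members, cc)]) / sqrt(length(members) + 1)
      if (sc > best_score) {
        best <- cc
        best_score <- sc
      }
    }
    if (is.null(best)) break
    members <- c(members, best)
  }
  list(members = sort(members),
       score = sum(z[members]) / sqrt(length(members)))
}

# Random small scored graph for oracle comparisons: returns the igraph,
# an edge table, and a score map covering every node.
random_scored_graph <- function(n_nodes, p_edge = 0.4) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- if (n_nodes > 1) t(utils::combn(nodes, 2)) else
    matrix(character(0), 0, 2)
  keep <- stats::runif(nrow(pairs)) < p_edge
  edges <- data.frame(a = pairs[keep, 1], b = pairs[keep, 2],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  z <- stats::rnorm(n_nodes, 0, 2)
  names(z) <- nodes
  list(graph = g, edges = edges, z = z)
}

# Build a named igraph from an edge list given as a two-column matrix-like.
graph_from_pairs <- function(a, b, isolated = character(0)) {
  igraph::graph_from_data_frame(
    data.frame(from = a, to = b, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = unique(c(a, b, isolated)),
                          stringsAsFactors = FALSE))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
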