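test_that("module_score is the normalized score sum", {
  z <- c(g1 = 2, g2 = 1, g3 = 3, g4 = 4)
  expect_equal(module_score("g1", z), 2)
  expect_equal(module_score(c(g1 = "g1", "g2", "g3", "g4"), z), 10 / 2)
  expect_error(module_score(c("g1", "nope"), z), "unscored")
  expect_error(module_score(character(0), z), "no members")
  # matches independent recomputation on random modules
  set.seed(5)
  zz <- rnorm(30)
  names(zz) <- sprintf("x%02d", 1:30)
  for (i in 1:10) {
    mem <- sample(names(zz), sample(1:10, 1))
    expect_equal(module_score(mem, zz), sum(zz[mem]) / sqrt(length(mem)),
                 tolerance = 1e-12)
  }
})

test_that("greedy growth follows the strict-improvement rule", {
  # path A-B-C: adding B (2/sqrt(2)) would lower the score, so stop at {A}
  g <- graph_from_pairs(c("A", "B"), c("B", "C"))
  z <- c(A = 2, B = 0, C = 3)
  m <- grow_module("A", g, z)
  expect_equal(m$members, "A")
  expect_equal(m$score, 2)

  # star H-L1, H-L2: ties broken lexicographically, both leaves added
  g2 <- graph_from_pairs(c("H", "H"), c("L1", "L2"))
  z2 <- c(H = 1, L1 = 3, L2 = 3)
  m2 <- grow_module("H", g2, z2)
  expect_equal(m2$members, c("H", "L1", "L2"))
  expect_equal(m2$score, 7 / sqrt(3), tolerance = 1e-12)
  expect_equal(m2$trajectory[2], 4 / sqrt(2), tolerance = 1e-12)

  # isolated seed
  g3 <- graph_from_pairs("A", "B", isolated = "D")
  z3 <- c(A = 1, B = 1, D = 1.5)
  m3 <- grow_module("D", g3, z3)
  expect_equal(m3$members, "D")
  expect_equal(m3$score, 1.5)

  expect_error(grow_module("Q", g3, z3), "unscored")
})

test_that("growth equals the step-by-step reference on small random graphs", {
  set.seed(31)
  for (rep in 1:60) {
    rg <- random_scored_graph(sample(2:8, 1))
    for (seed_gene in names(rg$z)) {
      got <- grow_module(seed_gene, rg$graph, rg$z)
      want <- oracle_grow(seed_gene, rg$edges, rg$z)
      expect_identical(got$members, want$members)
      expect_equal(got$score, want$score, tolerance = 1e-12)
      # monotone growth: trajectory strictly increasing, >= seed alone
      expect_true(all(diff(got$trajectory) > 0) || got$k == 1)
      expect_gte(got$score, rg$z[[seed_gene]])
      # connectivity
      expect_true(igraph::is_connected(
        igraph::induced_subgraph(rg$graph, got$members)))
    }
  }
})

test_that("search_all yields one module per scored seed, duplicates retained", {
  sim <- simulate_network(tiny_config(seed = 17))
  set.seed(17)
  z <- rnorm(igraph::vcount(sim$graph))
  names(z) <- igraph::V(sim$graph)$name
  mods <- search_all(sim$graph, z)
  expect_length(mods, igraph::vcount(sim$graph))
  expect_identical(names(mods), sort(igraph::V(sim$graph)$name))

  # a high-scoring triangle is reached identically from each of its seeds
  g <- graph_from_pairs(c("A", "B", "C", "C"), c("B", "C", "A", "D"))
  z2 <- c(A = 3, B = 3, C = 3, D = -5)
  mods2 <- search_all(g, z2)
  expect_length(mods2, 4)
  expect_identical(mods2[["A"]]$members, c("A", "B", "C"))
  expect_identical(mods2[["B"]]$members, c("A", "B", "C"))
  expect_identical(mods2[["C"]]$members, c("A", "B", "C"))
})

test_that("top-fraction merge selects by ceiling rule with induced edges", {
  # triangle A-B-C: two modules covering {A,B} and {B,C} merge to the
  # full triangle with all induced edges
  g <- graph_from_pairs(c("A", "B", "A"), c("B", "C", "C"))
  fake <- function(seed, members, score)
    structure(list(seed = seed, members = members, k = length(members),
                   score = score, trajectory = score), class = "af_module")
  mods <- list(fake("A", c("A", "B"), 3), fake("B", c("B", "C"), 2.5))
  sn <- select_and_merge(mods, 1.0, g)
  expect_setequal(sn$nodes, c("A", "B", "C"))
  expect_equal(nrow(sn$edges), 3)

  # ceiling rule: 2 modules at top_fraction 0.6 -> ceiling(1.2) = 2
  expect_equal(select_and_merge(mods, 0.6, g)$n_modules, 2)
  expect_equal(select_and_merge(mods, 0.5, g)$n_modules, 1)

  # ties at the cutoff break lexicographically by seed
  tied <- list(fake("B", "B", 1), fake("A", "A", 1), fake("C", "C", 1))
  sel <- select_and_merge(tied, 2 / 3, g)
  expect_equal(sel$selected_seeds, c("A", "B"))

  expect_error(select_and_merge(list(), 0.5, g), "empty")
  expect_error(select_and_merge(mods, 0, g), "top_fraction")
})

test_that("subnetwork edges are exactly the induced PPI edges", {
  sim <- simulate_network(tiny_config(seed = 23))
  set.seed(23)
  z <- abs(rnorm(igraph::vcount(sim$graph)))
  names(z) <- igraph::V(sim$graph)$name
  mods <- search_all(sim$graph, z)
  sn <- select_and_merge(mods, 0.05, sim$graph)
  # every module connected; every subnetwork node in >= 1 selected module
  for (m in mods) {
    expect_true(igraph::is_connected(
      igraph::induced_subgraph(sim$graph, m$members)))
  }
  covered <- sort(unique(unlist(
    lapply(mods[sn$selected_seeds], `[[`, "members"))))
  expect_identical(sn$nodes, covered)
  want <- igraph::as_edgelist(igraph::induced_subgraph(sim$graph, sn$nodes))
  norm <- function(e) sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  expect_identical(norm(sn$edges), norm(want))
})
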