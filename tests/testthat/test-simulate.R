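test_that("generators are pure functions of config and seed", {
  cfg <- tiny_config(seed = 42)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$samples, b$samples)
  expect_identical(igraph::as_edgelist(a$network),
                   igraph::as_edgelist(b$network))
  expect_identical(unclass(a$gene_sets), unclass(b$gene_sets))
  expect_identical(a$signal_genes, b$signal_genes)

  c <- simulate_study(tiny_config(seed = 43))
  expect_false(identical(a$expression, c$expression))
})

test_that("prevalent-AF count follows the configured fraction exactly", {
  cfg <- tiny_config(n_samples = 300, af_prevalent_frac = 0.08)
  sim <- simulate_cohort(cfg)
  expect_equal(sum(sim$samples$af_group == "prevalent"), 24)
  expect_equal(nrow(sim$samples), 300)
  expect_equal(dim(sim$expression), c(cfg$n_genes, 300))
})

test_that("cohort satisfies the phenotype-table invariants", {
  sim <- simulate_cohort(tiny_config(seed = 5))
  s <- sim$samples
  expect_false(anyDuplicated(s$sample_id) > 0)
  expect_true(all(s$af_group %in% c("none", "prevalent", "incident")))
  expect_true(all(s$event[s$af_group != "incident"] == 0))
  expect_true(all(s$event[s$af_group == "incident"] == 1))
  expect_true(all(!is.na(s$followup_time[s$af_group != "prevalent"])))
  expect_true(all(s$followup_time <= 7, na.rm = TRUE))
  # expression: signal genes shifted only in prevalent samples
  expect_true(all(sim$truth[sim$signal_genes] > 0))
  expect_true(all(sim$truth[setdiff(rownames(sim$expression),
                                    sim$signal_genes)] == 0))
  # planted module genes carry the boosted shift
  expect_true(all(sim$truth[sim$planted_genes] ==
                    0.5 * tiny_config()$planted_module_z_boost))
})

test_that("planted module is connected and drawn from signal genes", {
  for (seed in 1:3) {
    cfg <- tiny_config(seed = seed)
    nw <- simulate_network(cfg)
    co <- simulate_cohort(cfg)
    expect_setequal(nw$planted_module, co$planted_genes)
    expect_true(all(nw$planted_module %in% co$signal_genes))
    sub <- igraph::induced_subgraph(nw$graph, nw$planted_module)
    expect_true(igraph::is_connected(sub))
    expect_equal(igraph::vcount(sub), cfg$planted_module_size)
    # simple graph: no loops or multi-edges
    expect_false(igraph::any_loop(nw$graph))
    expect_false(igraph::any_multiple(nw$graph))
  }
})

test_that("scale-free networks have heavy-tailed degree distributions", {
  cfg <- simulation_config(n_genes = 1000, n_samples = 100, n_families = 30,
                           mean_degree = 4, seed = 7)
  nw <- simulate_network(cfg)
  deg <- igraph::degree(nw$graph)
  expect_gt(mean(deg), 2.5)
  expect_lt(mean(deg), 6)
  expect_gt(max(deg), 10 * stats::median(deg))
})

test_that("configuration-model networks are simple and reproducible", {
  cfg <- tiny_config(network_model = "configuration", seed = 9)
  a <- simulate_network(cfg)
  b <- simulate_network(cfg)
  expect_identical(igraph::as_edgelist(a$graph), igraph::as_edgelist(b$graph))
  expect_false(igraph::any_loop(a$graph))
  expect_true(igraph::is_connected(
    igraph::induced_subgraph(a$graph, a$planted_module)))
})

test_that("gene sets honour the enrichment construction rules", {
  cfg <- tiny_config(n_gene_sets = 50, seed = 3)
  gs <- simulate_gene_sets(cfg)
  nw <- simulate_network(cfg)
  expect_length(gs, 50)
  sizes <- lengths(gs)
  expect_true(all(sizes >= 5 & sizes <= 15))
  designated <- gs[[attr(gs, "enriched_set")]]
  overlap <- length(intersect(designated, nw$planted_module))
  expect_gte(overlap, ceiling(cfg$planted_module_size / 2))
  # GMT round trip preserves the collection
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gene_sets(gs, path)
  back <- read_gene_sets(path)
  expect_length(back, 50)
  expect_identical(names(back), names(gs))
  for (i in seq_along(gs)) expect_identical(back[[i]], gs[[i]])
})

test_that("impossible configurations are rejected", {
  expect_error(tiny_config(n_samples = 50, n_families = 90), "families")
  expect_error(tiny_config(planted_module_size = 11, n_signal_genes = 10),
               "planted_module_size")
  expect_error(tiny_config(n_signal_genes = 200), "n_signal_genes")
  expect_error(tiny_config(af_prevalent_frac = 0.9, af_incident_frac = 0.2),
               "< 1")
  expect_error(simulation_config(n_genes = 50,
                                 gene_set_size_range = c(30L, 500L)),
               "universe")
  expect_error(tiny_config(noise_sd = 0), "noise_sd")
})
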