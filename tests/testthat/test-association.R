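test_that("BH adjustment matches the brute-force step-up oracle", {
  set.seed(101)
  for (m in c(1, 2, 7, 50, 200)) {
    p <- runif(m)
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-15)
  }
  # q >= p, q <= 1, single test is the identity
  p <- runif(100)
  q <- bh_fdr(p)
  expect_true(all(q >= p - 1e-15))
  expect_true(all(q <= 1))
  expect_equal(bh_fdr(0.2), 0.2)
  # order-equivariance: adjusting sorted input and restoring order agrees
  o <- order(p)
  expect_equal(bh_fdr(p[o])[order(o)], q, tolerance = 1e-15)
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("mixed model collapses to OLS when families are uninformative", {
  # singleton pedigrees: the random intercept is unidentifiable, so every
  # feature drops to the cluster-robust OLS path with identical estimates
  sim <- simulate_cohort(tiny_config(seed = 21, n_genes = 40))
  s <- sim$samples
  s$pedigree_id <- s$sample_id
  lmm <- suppressMessages(fit_prevalent(sim$expression, s, method = "lmm"))
  ols <- suppressMessages(fit_prevalent(sim$expression, s, method = "ols"))
  expect_equal(lmm$effect, ols$effect, tolerance = 1e-10)
  expect_equal(lmm$se, ols$se, tolerance = 1e-10)

  # family_sd = 0: the REML variance estimate sits at or near the zero
  # boundary, so mixed and OLS estimates agree closely, exactly so for
  # boundary fits
  sim0 <- simulate_cohort(tiny_config(family_sd = 0, seed = 21, n_genes = 40))
  lmm0 <- suppressMessages(fit_prevalent(sim0$expression, sim0$samples))
  ols0 <- suppressMessages(
    fit_prevalent(sim0$expression, sim0$samples, method = "ols"))
  diffs <- abs(lmm0$effect - ols0$effect)
  expect_lt(max(diffs / ols0$se), 0.5)  # well within half a standard error
  expect_true(any(diffs < 1e-8))        # boundary fits agree exactly
})

test_that("degenerate features are flagged, not fatal", {
  sim <- simulate_cohort(tiny_config(seed = 3, n_genes = 10))
  expr <- sim$expression
  expr[4, ] <- 5.0
  res <- suppressMessages(fit_prevalent(expr, sim$samples))
  expect_equal(res$note[4], "constant")
  expect_equal(res$effect[4], 0)
  expect_equal(res$p[4], 1)
  expect_true(all(res$se[res$note == "lmm"] > 0))
  expect_true(all(res$q >= res$p - 1e-12, na.rm = TRUE))
})

test_that("prevalent model recovers planted expression shifts", {
  # unboosted signal genes carry a 0.15 log2 shift; the mean estimate
  # across seeds should land within 0.02 of truth, with positive signs
  est <- c()
  signs <- c()
  for (seed in 1:20) {
    cfg <- simulation_config(n_samples = 2000, n_families = 600,
                             n_genes = 60, n_signal_genes = 12,
                             planted_module_size = 4,
                             planted_module_z_boost = 1, seed = seed)
    sim <- simulate_cohort(cfg)
    res <- suppressMessages(fit_prevalent(sim$expression, sim$samples))
    sig <- res$effect[res$feature_id %in% sim$signal_genes]
    est <- c(est, sig)
    signs <- c(signs, sig > 0)
  }
  expect_lt(abs(mean(est) - 0.15), 0.02)
  expect_gte(mean(signs), 0.95)
})

test_that("incident-AF referent handling and medication substitution agree", {
  # with no incident samples and a medication flag equal to the
  # prevalent-AF indicator, both models are the same regression
  sim <- simulate_cohort(tiny_config(seed = 8, n_genes = 25))
  s <- sim$samples[sim$samples$af_group != "incident", ]
  s$warfarin <- as.integer(s$af_group == "prevalent")
  expr <- sim$expression[, s$sample_id]
  prev <- suppressMessages(fit_prevalent(expr, s))
  med <- suppressMessages(fit_medication(expr, s, "warfarin"))
  expect_equal(med$effect, prev$effect, tolerance = 1e-10)
  expect_equal(med$p, prev$p, tolerance = 1e-10)

  s$warfarin <- 1L
  expect_error(suppressMessages(fit_medication(expr, s, "warfarin")),
               "non-users")
  expect_error(suppressMessages(fit_medication(expr, s, "aspirin")),
               "aspirin")
})

test_that("Cox p-values are calibrated under the null", {
  set.seed(77)
  n <- 200
  samples <- data.frame(
    sample_id = sprintf("s%03d", 1:n),
    pedigree_id = sprintf("f%03d", rep(1:50, 4)),
    af_group = "none", age = rnorm(n, 66, 9),
    sex = sample(c("male", "female"), n, TRUE),
    followup_time = 5, event = 0L, stringsAsFactors = FALSE)
  ev <- sample(n, 40)
  samples$event[ev] <- 1L
  samples$af_group[ev] <- "incident"
  expr <- matrix(rnorm(50 * n), 50, n,
                 dimnames = list(sprintf("g%02d", 1:50), samples$sample_id))
  res <- suppressMessages(fit_incident(expr, samples))
  expect_gt(stats::ks.test(res$p, "punif")$p.value, 0.01)
})

test_that("Cox model recovers a planted log hazard ratio", {
  est <- c()
  for (seed in 1:20) {
    cfg <- simulation_config(n_samples = 2000, n_families = 600,
                             n_genes = 30, n_signal_genes = 6,
                             planted_module_size = 3,
                             af_incident_frac = 0.075,
                             gene_set_size_range = c(5L, 20L), seed = seed)
    sim <- simulate_cohort(cfg)
    inc <- suppressMessages(
      fit_incident(sim$expression[sim$incident_signal_genes, , drop = FALSE],
                   sim$samples))
    est <- c(est, inc$effect[1])
  }
  expect_lt(abs(mean(est) - 0.5), 0.1)
})

test_that("incident model enforces its event floor", {
  sim <- simulate_cohort(tiny_config(seed = 2, n_genes = 5,
                                     n_signal_genes = 2,
                                     planted_module_size = 2))
  s <- sim$samples[1, , drop = FALSE]
  expect_error(suppressMessages(fit_incident(sim$expression, s)),
               "insufficient events")
})

test_that("medication-shifted genes reach significance", {
  hits <- c()
  for (seed in 1:20) {
    cfg <- simulation_config(n_samples = 2000, n_families = 600,
                             n_genes = 100, n_signal_genes = 10,
                             planted_module_size = 5,
                             medication_effect = 0.2,
                             n_medication_signal_genes = 1, seed = seed)
    sim <- simulate_cohort(cfg)
    med <- suppressMessages(
      fit_medication(sim$expression, sim$samples, "beta_blocker"))
    hits <- c(hits,
              med$q[med$feature_id == sim$medication_signal_genes] < 0.05)
  }
  expect_gte(mean(hits), 0.9)
})
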