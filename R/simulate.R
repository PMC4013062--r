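#' Simulation settings for a synthetic AF transcriptome study
#'
#' Bundles every parameter of the synthetic data generator: a
#' pedigree-clustered cohort with a minority atrial-fibrillation (AF) group,
#' a log2 expression matrix with planted over-expressed genes, a scale-free
#' protein-protein interaction (PPI) network containing a planted connected
#' high-score module, and gene-set collections enriched for that module.
#'
#' Defaults mirror a community cohort of ~2400 adults with roughly 7%
#' prevalent and 6% incident AF, family clustering, and differential
#' expression shifts of ~0.15 log2 units, at a desk-scale gene count of 500.
#'
#' @param n_samples Number of participants.
#' @param n_families Number of pedigrees; samples are spread near-uniformly.
#' @param n_genes Number of expression features (gene level).
#' @param n_signal_genes Number of genes over-expressed in prevalent AF.
#' @param af_prevalent_frac Fraction of samples with prevalent AF
#'   (AF diagnosed before the blood draw). The realized count is
#'   `round(af_prevalent_frac * n_samples)`.
#' @param af_incident_frac Target fraction with incident AF (AF after the
#'   blood draw). Incident status is generative — drawn from an exponential
#'   hazard — so the realized count matches this in expectation only.
#' @param signal_effect Expression shift, in log2 units, added to signal
#'   genes in prevalent-AF samples.
#' @param family_sd Standard deviation of the per-pedigree (per gene)
#'   Gaussian random intercept.
#' @param noise_sd Residual standard deviation of log2 expression.
#' @param network_model `"scale-free"` (preferential attachment) or
#'   `"configuration"` (fixed degree sequence drawn from a truncated
#'   Poisson).
#' @param mean_degree Target mean degree of the PPI network.
#' @param planted_module_size Size of the planted connected module; its
#'   members are drawn from the signal genes.
#' @param planted_module_z_boost Multiplier applied to `signal_effect` for
#'   planted-module genes, inflating their association evidence so the
#'   module carries a high aggregate score.
#' @param n_gene_sets Number of gene sets generated.
#' @param gene_set_size_range Length-2 integer vector `(min, max)` of set
#'   sizes.
#' @param beta_age,beta_sex Fixed covariate effects on expression (log2
#'   units per year of age, and for male vs female), small and nonzero so
#'   covariate adjustment is non-degenerate.
#' @param incident_loghr Log hazard ratio of incident AF per log2-unit of
#'   the designated incident-risk gene's expression.
#' @param n_incident_signal_genes Number of signal genes whose expression
#'   feeds the incident-AF hazard (default 1, which keeps the per-gene Cox
#'   model well-specified).
#' @param age_loghr Log hazard ratio per year of age in the incident model
#'   (induces the age confounding that covariate adjustment must absorb).
#' @param medication_effect Log2 expression shift in medication-signal genes
#'   for beta-blocker users (0 disables).
#' @param n_medication_signal_genes Number of genes shifted by
#'   `medication_effect`; drawn from non-signal genes.
#' @param followup_horizon Administrative censoring time, in years.
#' @param seed Master RNG seed; together with the other fields it fully
#'   determines every generator output.
#'
#' @return An object of class `afnet_config` (a validated list).
#' @export
simulation_config <- function(n_samples = 2446,
                              n_families = 700,
                              n_genes = 500,
                              n_signal_genes = 25,
                              af_prevalent_frac = 0.072,
                              af_incident_frac = 0.058,
                              signal_effect = 0.15,
                              family_sd = 0.2,
                              noise_sd = 0.5,
                              network_model = c("scale-free", "configuration"),
                              mean_degree = 4,
                              planted_module_size = 12,
                              planted_module_z_boost = 2,
                              n_gene_sets = 50,
                              gene_set_size_range = c(10L, 40L),
                              beta_age = 0.002,
                              beta_sex = 0.05,
                              incident_loghr = 0.5,
                              n_incident_signal_genes = 1,
                              age_loghr = 0.04,
                              medication_effect = 0,
                              n_medication_signal_genes = 0,
                              followup_horizon = 7,
                              seed = 1) {
  network_model <- match.arg(network_model)
  for (nm in c("n_samples", "n_families", "n_genes", "n_signal_genes",
               "planted_module_size", "n_gene_sets")) {
    if (!is_count(get(nm))) abort("'%s' must be a positive integer", nm)
  }
  if (!is_prop(af_prevalent_frac) || !is_prop(af_incident_frac))
    abort("AF fractions must lie in (0, 1)")
  if (af_prevalent_frac + af_incident_frac >= 1)
    abort("af_prevalent_frac + af_incident_frac must be < 1")
  if (n_samples < n_families)
    abort("fewer samples (%d) than families (%d)", n_samples, n_families)
  if (n_signal_genes > n_genes)
    abort("n_signal_genes exceeds n_genes")
  if (planted_module_size > n_signal_genes)
    abort("planted_module_size (%d) exceeds n_signal_genes (%d)",
          planted_module_size, n_signal_genes)
  if (n_incident_signal_genes > n_signal_genes)
    abort("n_incident_signal_genes exceeds n_signal_genes")
  if (n_medication_signal_genes > n_genes - n_signal_genes)
    abort("n_medication_signal_genes exceeds available non-signal genes")
  if (length(gene_set_size_range) != 2L ||
      gene_set_size_range[1] > gene_set_size_range[2] ||
      gene_set_size_range[1] < 1)
    abort("gene_set_size_range must be (min, max) with 1 <= min <= max")
  if (gene_set_size_range[2] > n_genes)
    abort("gene_set_size_range max exceeds the gene universe")
  if (!(is.numeric(seed) && length(seed) == 1 && seed == floor(seed) &&
        seed >= 0 && seed < .Machine$integer.max))
    abort("seed must be a non-negative 32-bit integer")
  for (nm in c("signal_effect", "family_sd", "noise_sd", "mean_degree",
               "beta_age", "beta_sex", "incident_loghr", "age_loghr",
               "medication_effect", "followup_horizon"))
    if (!(is.numeric(get(nm)) && length(get(nm)) == 1 && is.finite(get(nm))))
      abort("'%s' must be a finite number", nm)
  if (family_sd < 0 || noise_sd <= 0) abort("noise_sd must be > 0, family_sd >= 0")

  cfg <- list(
    n_samples = as.integer(n_samples), n_families = as.integer(n_families),
    n_genes = as.integer(n_genes), n_signal_genes = as.integer(n_signal_genes),
    af_prevalent_frac = af_prevalent_frac, af_incident_frac = af_incident_frac,
    signal_effect = signal_effect, family_sd = family_sd, noise_sd = noise_sd,
    network_model = network_model, mean_degree = mean_degree,
    planted_module_size = as.integer(planted_module_size),
    planted_module_z_boost = planted_module_z_boost,
    n_gene_sets = as.integer(n_gene_sets),
    gene_set_size_range = as.integer(gene_set_size_range),
    beta_age = beta_age, beta_sex = beta_sex,
    incident_loghr = incident_loghr,
    n_incident_signal_genes = as.integer(n_incident_signal_genes),
    age_loghr = age_loghr,
    medication_effect = medication_effect,
    n_medication_signal_genes = as.integer(n_medication_signal_genes),
    followup_horizon = followup_horizon,
    seed = as.integer(seed))
  class(cfg) <- "afnet_config"
  cfg
}

#' @export
print.afnet_config <- function(x, ...) {
  cat("afnet simulation config:",
      sprintf("%d samples / %d families, %d genes (%d signal, module %d)",
              x$n_samples, x$n_families, x$n_genes, x$n_signal_genes,
              x$planted_module_size),
      sprintf("AF fractions: %.3f prevalent, %.3f incident; seed %d",
              x$af_prevalent_frac, x$af_incident_frac, x$seed),
      sep = "\n")
  invisible(x)
}

gene_ids <- function(config) sprintf("G%05d", seq_len(config$n_genes))

# Deterministic gene-role assignment shared by all generator components:
# signal genes, the planted-module subset (first planted_module_size of the
# signal genes), the incident-risk gene(s), and medication-signal genes.
designate_genes <- function(config) {
  ids <- gene_ids(config)
  seeds <- derive_seeds(config$seed, 6L)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seeds[1])
  signal <- sort(sample(ids, config$n_signal_genes))
  planted <- signal[seq_len(config$planted_module_size)]
  incident_pool <- setdiff(signal, planted)
  incident <- if (length(incident_pool) >= config$n_incident_signal_genes) {
    incident_pool[seq_len(config$n_incident_signal_genes)]
  } else {
    signal[seq_len(config$n_incident_signal_genes)]
  }
  med <- if (config$n_medication_signal_genes > 0) {
    sort(sample(setdiff(ids, signal), config$n_medication_signal_genes))
  } else {
    character(0)
  }
  list(gene_ids = ids, signal = signal, planted = planted,
       incident = incident, medication = med)
}

#' Simulate a pedigree-clustered cohort with expression and AF phenotypes
#'
#' Generates a log2 expression matrix (genes x samples) and a matching
#' phenotype table. Expression for gene g in sample s is
#' `baseline_g + beta_age*(age_s - 66) + beta_sex*male_s + u_{g,ped(s)} +
#' shift + N(0, noise_sd^2)`, where `u` is a per-gene, per-pedigree Gaussian
#' intercept and `shift` is `signal_effect` for signal genes in prevalent-AF
#' samples (multiplied by `planted_module_z_boost` for planted-module
#' genes). Prevalent-AF status is assigned to exactly
#' `round(af_prevalent_frac * n_samples)` samples; incident AF is drawn from
#' an exponential hazard proportional to
#' `exp(incident_loghr * x + age_loghr * (age - 66))`, where x is the
#' centered expression of the designated incident-risk gene(s), with
#' administrative censoring at `followup_horizon` years.
#'
#' Ages, sex ratios, clinical covariates, and medication flags are drawn
#' group-wise to resemble an older community cohort in which prevalent AF
#' cases are older, more often male, and carry more cardiovascular disease.
#'
#' @param config An [simulation_config()] object.
#' @return A list with elements `expression` (numeric matrix, genes x
#'   samples), `samples` (phenotype `data.frame`), `signal_genes`,
#'   `planted_genes`, `incident_signal_genes`, `medication_signal_genes`,
#'   and `truth` (per-gene prevalent-AF expression shift).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "afnet_config"))
  roles <- designate_genes(config)
  seeds <- derive_seeds(config$seed, 6L)
  n <- config$n_samples
  nf <- config$n_families
  G <- config$n_genes

  set.seed(seeds[2])
  ## pedigrees: sizes differ by at most one, membership shuffled
  pedigree <- sprintf("F%04d", sample(rep_len(seq_len(nf), n)))
  sample_id <- sprintf("S%05d", seq_len(n))

  n_prev <- round(config$af_prevalent_frac * n)
  if (n_prev < 1) abort("af_prevalent_frac too small: no prevalent cases")
  prev <- logical(n)
  prev[sample(n, n_prev)] <- TRUE

  age <- ifelse(prev, stats::rnorm(n, 73, 8), stats::rnorm(n, 66, 9))
  age <- pmin(pmax(age, 40), 95)
  sex <- ifelse(stats::runif(n) < ifelse(prev, 0.36, 0.57),
                "female", "male")
  male <- as.numeric(sex == "male")

  rb <- function(p_prev, p_other) stats::rbinom(n, 1, ifelse(prev, p_prev, p_other))
  samples <- data.frame(
    sample_id = sample_id, pedigree_id = pedigree,
    af_group = ifelse(prev, "prevalent", "none"),
    age = age, sex = sex,
    smoking = rb(0.04, 0.09),
    height = stats::rnorm(n, 66 + 2.5 * male, 3),
    weight = stats::rnorm(n, ifelse(prev, 186, 175), 40),
    sbp = stats::rnorm(n, ifelse(prev, 128, 129), 18),
    dbp = stats::rnorm(n, ifelse(prev, 69, 74), 10),
    diabetes = rb(0.32, 0.16),
    mi = rb(0.23, 0.01),
    heart_failure = rb(0.25, 0.03),
    htn_treatment = rb(0.73, 0.47),
    warfarin = rb(0.45, 0.02),
    beta_blocker = rb(0.60, 0.25),
    digoxin = rb(0.30, 0.02),
    ccb = rb(0.25, 0.12),
    stringsAsFactors = FALSE)

  ## expression
  set.seed(seeds[3])
  baseline <- stats::rnorm(G, 7, 1)
  names(baseline) <- roles$gene_ids
  fam_idx <- match(pedigree, sort(unique(pedigree)))
  fam_eff <- matrix(stats::rnorm(G * nf, 0, config$family_sd), G, nf)
  expr <- matrix(stats::rnorm(G * n, 0, config$noise_sd), G, n,
                 dimnames = list(roles$gene_ids, sample_id))
  expr <- expr + baseline + fam_eff[, fam_idx]
  expr <- expr + rep(config$beta_age * (age - 66) + config$beta_sex * male,
                     each = G)

  shift <- numeric(G)
  names(shift) <- roles$gene_ids
  shift[roles$signal] <- config$signal_effect
  shift[roles$planted] <- config$signal_effect * config$planted_module_z_boost
  expr[, prev] <- expr[, prev] + shift

  if (config$n_medication_signal_genes > 0 && config$medication_effect != 0) {
    bb <- samples$beta_blocker == 1
    expr[roles$medication, bb] <- expr[roles$medication, bb] +
      config$medication_effect
  }

  ## incident AF: exponential hazard on non-prevalent samples
  set.seed(seeds[4])
  nonprev <- !prev
  xs <- expr[roles$incident, nonprev, drop = FALSE]
  lin <- config$incident_loghr * colSums(xs - rowMeans(xs)) +
    config$age_loghr * (age[nonprev] - 66)
  target <- config$af_incident_frac / (1 - config$af_prevalent_frac)
  lambda0 <- -log(1 - target) / config$followup_horizon / mean(exp(lin))
  tt <- stats::rexp(sum(nonprev), rate = lambda0 * exp(lin))
  event <- as.integer(tt < config$followup_horizon)
  samples$followup_time <- NA_real_
  samples$followup_time[nonprev] <- pmin(tt, config$followup_horizon)
  samples$event <- 0L
  samples$event[nonprev] <- event
  samples$af_group[nonprev][event == 1L] <- "incident"

  list(expression = expr, samples = samples,
       signal_genes = roles$signal, planted_genes = roles$planted,
       incident_signal_genes = roles$incident,
       medication_signal_genes = roles$medication,
       truth = shift)
}

#' Simulate a PPI network with a planted connected module
#'
#' Builds an undirected simple graph over the configured gene universe,
#' either by preferential attachment (`"scale-free"`, giving a heavy-tailed
#' degree distribution) or from a truncated-Poisson degree sequence
#' (`"configuration"`). A connected subgraph of `planted_module_size`
#' vertices is selected by snowball sampling and labelled with the planted
#' (signal) genes, so the high-evidence genes form a connected module the
#' downstream search can recover.
#'
#' @param config An [simulation_config()] object.
#' @param signal_genes Optional; retained for pipeline symmetry. The planted
#'   gene subset is derived deterministically from `config`, so the
#'   generator is reproducible standalone; if supplied, it is checked for
#'   consistency.
#' @return List with `graph` (a named, simple, undirected `igraph`) and
#'   `planted_module` (character vector of planted gene IDs).
#' @export
simulate_network <- function(config, signal_genes = NULL) {
  stopifnot(inherits(config, "afnet_config"))
  roles <- designate_genes(config)
  if (!is.null(signal_genes) && !all(roles$planted %in% signal_genes))
    abort("planted module is not contained in the supplied signal genes")
  seeds <- derive_seeds(config$seed, 6L)
  set.seed(seeds[5])
  G <- config$n_genes
  k <- config$planted_module_size

  if (config$network_model == "scale-free") {
    g <- igraph::sample_pa(G, m = max(1, round(config$mean_degree / 2)),
                           directed = FALSE)
  } else {
    deg <- pmax(1L, stats::rpois(G, config$mean_degree))
    if (sum(deg) %% 2L == 1L) deg[1] <- deg[1] + 1L
    g <- igraph::simplify(igraph::sample_degseq(deg, method = "fast.heur.simple"))
  }
  g <- igraph::simplify(g)

  comp <- igraph::components(g)
  big <- which(comp$membership == which.max(comp$csize))
  if (length(big) < k)
    abort("largest network component (%d) smaller than planted_module_size (%d)",
          length(big), k)
  ## snowball: grow a connected vertex set of size k
  current <- sample(big, 1)
  while (length(current) < k) {
    nbrs <- setdiff(unique(unlist(igraph::adjacent_vertices(g, current))),
                    current)
    current <- c(current, sample(rep(nbrs, 2L), 1))  # rep() guards length-1 sample
  }
  ids <- roles$gene_ids
  labels <- character(G)
  labels[current] <- sample(roles$planted)
  labels[-current] <- sample(setdiff(ids, roles$planted))
  igraph::V(g)$name <- labels
  list(graph = g, planted_module = roles$planted)
}

#' Simulate gene-set collections enriched for the planted module
#'
#' Generates `n_gene_sets` gene sets over the configured gene universe. The
#' first set is designated "enriched": it contains at least half of the
#' planted module, topped up with random background genes; all remaining
#' sets are uniform draws. Set sizes are uniform on `gene_set_size_range`.
#'
#' @param config An [simulation_config()] object.
#' @param planted_module Optional; checked for consistency if supplied (the
#'   planted set is derived from `config`).
#' @return A `gene_set_collection` (see [read_gene_sets()]); the designated
#'   enriched set's name is stored in `attr(x, "enriched_set")`.
#' @export
simulate_gene_sets <- function(config, planted_module = NULL) {
  stopifnot(inherits(config, "afnet_config"))
  roles <- designate_genes(config)
  if (!is.null(planted_module) && !setequal(planted_module, roles$planted))
    abort("supplied planted_module disagrees with the config")
  seeds <- derive_seeds(config$seed, 6L)
  set.seed(seeds[6])
  rng <- config$gene_set_size_range
  ids <- roles$gene_ids
  n_half <- ceiling(length(roles$planted) / 2)
  if (rng[2] < n_half)
    abort("gene_set_size_range max (%d) below half the planted module (%d)",
          rng[2], n_half)

  sizes <- sample(seq(rng[1], rng[2]), config$n_gene_sets, replace = TRUE)
  sizes[1] <- max(sizes[1], n_half)
  sets <- vector("list", config$n_gene_sets)
  core <- roles$planted[seq_len(n_half)]
  sets[[1]] <- sort(c(core, sample(setdiff(ids, core), sizes[1] - n_half)))
  for (i in seq_len(config$n_gene_sets)[-1])
    sets[[i]] <- sort(sample(ids, sizes[i]))
  names(sets) <- sprintf("PW_%04d", seq_along(sets))
  out <- structure(sets,
                   descriptions = ifelse(seq_along(sets) == 1,
                                         "planted-module enriched set",
                                         "random background set"),
                   class = "gene_set_collection")
  attr(out, "enriched_set") <- names(sets)[1]
  out
}

#' Simulate a full synthetic study (cohort + network + gene sets)
#'
#' Convenience wrapper calling [simulate_cohort()], [simulate_network()] and
#' [simulate_gene_sets()] under one configuration.
#'
#' @param config An [simulation_config()] object.
#' @return A list with `expression`, `samples`, `network`, `gene_sets`, and
#'   the truth elements of the component generators.
#' @export
simulate_study <- function(config) {
  co <- simulate_cohort(config)
  nw <- simulate_network(config, co$signal_genes)
  gs <- simulate_gene_sets(config, nw$planted_module)
  c(co, list(network = nw$graph, planted_module = nw$planted_module,
             gene_sets = gs))
}
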