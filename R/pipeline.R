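#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. The
#' pipeline runs up to five stages in order: `simulate` (write a synthetic
#' study to the run directory), `assoc` (prevalent-AF association),
#' `score`, `modules` (dense-module search and top-fraction merge) and
#' `enrich`. When `simulate` is disabled, paths to an expression TSV,
#' phenotype CSV, network edge list, and GMT file must be supplied.
#'
#' @param outdir Run directory (created if absent).
#' @param seed Master seed for all randomness.
#' @param stages Character vector of stages to run, in order.
#' @param simulation Named list of overrides passed to
#'   [simulation_config()] (its `seed` is taken from `seed`).
#' @param covariate_set `"age_sex"` or `"full"`.
#' @param top_fraction Fraction of modules merged into the subnetwork.
#' @param fdr_threshold Significance threshold on BH-adjusted values.
#' @param expression,phenotypes,network,gene_sets Input paths, used by the
#'   stages that need them when `simulate` is not run.
#' @return A validated list of class `afnet_pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            seed = 1,
                            stages = c("simulate", "assoc", "score",
                                       "modules", "enrich"),
                            simulation = list(),
                            covariate_set = "age_sex",
                            top_fraction = 0.01,
                            fdr_threshold = 0.05,
                            expression = NULL, phenotypes = NULL,
                            network = NULL, gene_sets = NULL) {
  known <- c("simulate", "assoc", "score", "modules", "enrich")
  bad <- setdiff(stages, known)
  if (length(bad)) abort("unknown stage(s): %s", paste(bad, collapse = ", "))
  if (!covariate_set %in% c("age_sex", "full"))
    abort("unknown covariate set: '%s'", covariate_set)
  if (!is_prop(top_fraction, closed_right = TRUE) ||
      !is_prop(fdr_threshold, closed_right = TRUE))
    abort("top_fraction and fdr_threshold must lie in (0, 1]")
  if (!"simulate" %in% stages) {
    need <- c(expression = expression, phenotypes = phenotypes,
              network = network, gene_sets = gene_sets)
    needed_by <- list(
      assoc = c("expression", "phenotypes"),
      score = c("network"), modules = c("network"),
      enrich = c("gene_sets"))
    wanted <- unique(unlist(needed_by[intersect(stages, names(needed_by))]))
    for (w in wanted) {
      if (is.null(need[[w]]) || !file.exists(need[[w]]))
        abort("stage input '%s' missing or nonexistent", w)
    }
  }
  structure(list(outdir = outdir, seed = as.integer(seed),
                 stages = intersect(known, stages), simulation = simulation,
                 covariate_set = covariate_set, top_fraction = top_fraction,
                 fdr_threshold = fdr_threshold,
                 expression = expression, phenotypes = phenotypes,
                 network = network, gene_sets = gene_sets),
            class = "afnet_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file holds the arguments of [pipeline_config()]; fields given
#' in `...` override the file (command-line precedence).
#'
#' @param path Path to a YAML file.
#' @param ... Overrides (e.g. `seed`, `outdir`).
#' @return An `afnet_pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  over <- list(...)
  cfg[names(over)] <- over
  do.call(pipeline_config, cfg)
}

#' Run the AF transcriptome-network pipeline
#'
#' Executes the enabled stages in order (simulate, assoc, score, modules,
#' enrich), writing every stage output as plain text under the run
#' directory: `expression.tsv`, `phenotypes.csv`, `network_edges.tsv`,
#' `gene_sets.gmt`, truth files, `association_prevalent.tsv` (sorted by
#' p), `gene_scores.tsv`, `modules.tsv`, `subnetwork_edges.tsv`,
#' `subnetwork_nodes.tsv`, `enrichment.tsv`, and a `manifest.json`
#' recording the configuration, seed, package version, and an MD5 checksum
#' of every output. Identical configuration and seed give byte-identical
#' outputs. A stage failure halts the run with a stage-named error;
#' outputs of completed stages are retained.
#'
#' @param config An `afnet_pipeline_config` (see [pipeline_config()]) or a
#'   path to a YAML file of its fields.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "afnet_pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  written <- character(0)
  state <- list()

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      abort("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  if ("simulate" %in% config$stages) {
    state <- run_stage("simulate", function() {
      sim_args <- config$simulation
      sim_args$seed <- config$seed
      sim <- simulate_study(do.call(simulation_config, sim_args))
      write_expression(sim$expression, out("expression.tsv"))
      write_phenotypes(sim$samples, out("phenotypes.csv"))
      write_network(sim$network, out("network_edges.tsv"))
      write_gene_sets(sim$gene_sets, out("gene_sets.gmt"))
      writeLines(sim$signal_genes, out("truth_signal_genes.txt"))
      writeLines(sim$planted_module, out("truth_planted_module.txt"))
      written <<- c(written, "expression.tsv", "phenotypes.csv",
                    "network_edges.tsv", "gene_sets.gmt",
                    "truth_signal_genes.txt", "truth_planted_module.txt")
      list(expression = sim$expression, samples = sim$samples,
           network = sim$network, gene_sets = sim$gene_sets)
    })
  }

  load_input <- function(slot, reader, default_file) {
    if (!is.null(state[[slot]])) return(state[[slot]])
    path <- config[[slot]]
    if (is.null(path)) path <- out(default_file)
    if (!file.exists(path)) abort("input '%s' not found at %s", slot, path)
    reader(path)
  }

  if ("assoc" %in% config$stages) {
    state$assoc <- run_stage("assoc", function() {
      expr <- load_input("expression", read_expression, "expression.tsv")
      pheno <- load_input("phenotypes", read_phenotypes, "phenotypes.csv")
      res <- fit_prevalent(expr, pheno, covariates = config$covariate_set)
      write_results(res[order(res$p, res$feature_id), ],
                    out("association_prevalent.tsv"))
      written <<- c(written, "association_prevalent.tsv")
      res
    })
  }

  if ("score" %in% config$stages || "modules" %in% config$stages) {
    state$network <- load_input("network", read_network, "network_edges.tsv")
  }

  if ("score" %in% config$stages) {
    state$scores <- run_stage("score", function() {
      res <- state$assoc
      if (is.null(res)) res <- read_results(out("association_prevalent.tsv"))
      z <- build_score_map(res, state$network)
      utils::write.table(
        data.frame(gene_id = names(z), z = as.numeric(z)),
        out("gene_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      written <<- c(written, "gene_scores.tsv")
      z
    })
  }

  if ("modules" %in% config$stages) {
    state$subnetwork <- run_stage("modules", function() {
      if (is.null(state$scores)) abort("module search needs the score stage")
      mods <- search_all(state$network, state$scores)
      utils::write.table(modules_to_df(mods), out("modules.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      subnet <- select_and_merge(mods, config$top_fraction, state$network)
      write_network(subnet$graph, out("subnetwork_edges.tsv"))
      utils::write.table(
        data.frame(gene_id = subnet$nodes,
                   z = as.numeric(state$scores[subnet$nodes])),
        out("subnetwork_nodes.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      written <<- c(written, "modules.tsv", "subnetwork_edges.tsv",
                    "subnetwork_nodes.tsv")
      state$modules <<- mods
      subnet
    })
  }

  if ("enrich" %in% config$stages) {
    state$enrichment <- run_stage("enrich", function() {
      if (is.null(state$subnetwork)) abort("enrichment needs the modules stage")
      sets <- load_input("gene_sets", read_gene_sets, "gene_sets.gmt")
      res <- enrich(state$subnetwork$nodes, sets,
                    universe = names(state$scores))
      utils::write.table(res, out("enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      written <<- c(written, "enrichment.tsv")
      res
    })
  }

  manifest <- list(
    package = "afnet",
    version = as.character(utils::packageVersion("afnet")),
    seed = config$seed,
    stages = config$stages,
    covariate_set = config$covariate_set,
    top_fraction = config$top_fraction,
    fdr_threshold = config$fdr_threshold,
    simulation = config$simulation,
    outputs = as.list(tools::md5sum(file.path(config$outdir, written))))
  names(manifest$outputs) <- written
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  state$manifest <- manifest
  invisible(state)
}
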