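# afnet

Gene expression profiling of whole blood in large community cohorts offers a
non-invasive window on the transcriptional state that accompanies atrial
fibrillation (AF). `afnet` implements the full analysis chain for such a
study, for statistical geneticists and cardiovascular epidemiologists working
with pedigree-clustered cohorts:

1. **Gene-wise association.** For prevalent AF (diagnosed before the blood
   draw), each feature's log2 expression is regressed on an AF indicator plus
   covariates with a Gaussian random intercept per pedigree (linear mixed
   model, REML), primary adjustment age + sex, secondary adjustment for the
   classical AF risk factors. For incident AF (onset during follow-up), a Cox
   proportional hazards model of time-to-AF on continuous expression with
   robust sandwich standard errors clustered by pedigree. Medication screens
   (warfarin, beta blocker, digoxin, calcium channel blocker) reuse the
   prevalent model family with a dichotomous drug flag.
2. **Multiple testing.** Benjamini–Hochberg step-up adjustment
   q₍ᵢ₎ = min₍ⱼ≥ᵢ₎ p₍ⱼ₎·m/j over the m features tested; significance at
   q < 0.05.
3. **Gene scoring.** zᵢ = Φ⁻¹(1 − pᵢ), the upper-tail inverse-normal
   transform of the association p-value.
4. **Dense-module search.** On a protein–protein interaction (PPI) network,
   every scored gene seeds one greedy search that maximizes the module score
   Zₘ = Σzᵢ/√k (k = module size), adding the best neighboring gene only while
   the score strictly increases. The top 1% of modules by score are merged —
   union of members with induced PPI edges — into the AF subnetwork.
5. **Pathway enrichment.** Hypergeometric upper-tail tests of subnetwork
   genes in GMT gene sets against the scored-gene universe, with BH control
   and `k/K (ratio)` reporting.

Because the motivating cohort data are access-controlled, the package ships a
first-class synthetic generator (`simulate_cohort()`, `simulate_network()`,
`simulate_gene_sets()`): a pedigree-clustered cohort with a minority AF
group, planted over-expressed genes, a scale-free PPI graph containing a
planted connected high-score module, and gene sets enriched for that module.
Every downstream stage is tested against this generator's known truth.

## Worked example

```r
library(afnet)

cfg <- simulation_config(n_samples = 400, n_families = 120, n_genes = 120,
                         n_signal_genes = 12, planted_module_size = 6,
                         signal_effect = 0.5, n_gene_sets = 20,
                         gene_set_size_range = c(5, 20), seed = 11)
sim <- simulate_study(cfg)

res <- fit_prevalent(sim$expression, sim$samples)      # LMM per gene
#> fitting 120 features on 386 samples (0 excluded, lmm model)
z   <- build_score_map(res, sim$network)               # p -> z on the PPI graph
#> score map: 120 scored network genes; 0 unscored node(s) dropped; ...
mods <- search_all(sim$network, z)                     # one module per seed
sn   <- select_and_merge(mods, top_fraction = 0.05, sim$network)
sn
#> af_subnetwork: 7 nodes, 6 edges (union of 6 modules)
length(intersect(sn$nodes, sim$planted_module)) /
  length(union(sn$nodes, sim$planted_module))
#> [1] 0.8571429
head(enrich(sn$nodes, sim$gene_sets, universe = names(z))[, 1:7], 3)
#>   set_name n_overlap n_set     ratio ratio_label          p         q
#> 1  PW_0020         3    16 0.1875000 3/16 (0.19) 0.04926440 0.5978091
#> 2  PW_0001         3    18 0.1666667 3/18 (0.17) 0.06789846 0.5978091
#> 3  PW_0012         3    20 0.1500000 3/20 (0.15) 0.08967136 0.5978091
```

The association table carries one row per feature (`effect` = log2
expression difference AF vs referent, `se`, Wald `p`, BH `q`); the
subnetwork is the union of the top-scoring modules with its induced PPI
edges; the enrichment table mirrors a canonical-pathway report (`ratio` =
subnetwork genes over pathway size). At this toy scale the planted module is
recovered almost exactly (Jaccard 0.86) while pathway enrichment is
underpowered — the defaults in `simulation_config()` reproduce the
full-cohort operating characteristics.

`run_pipeline(pipeline_config(outdir, seed = 1))` executes
simulate → associate → score → search → enrich end-to-end, writing every
stage table plus a checksummed manifest; `inst/scripts/afnet-run.R` is a thin
command-line wrapper around it.

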