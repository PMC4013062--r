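---
title: "Whole-blood transcriptome association and dense-module network analysis for atrial fibrillation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-blood transcriptome association and dense-module network analysis for atrial fibrillation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`afnet` implements a complete analysis chain for studying whole-blood gene
expression in relation to atrial fibrillation (AF) in a family-based cohort:
per-gene association models, false-discovery-rate control, conversion of
association evidence into gene scores, a greedy dense-module search over a
protein–protein interaction (PPI) network, and pathway enrichment of the
resulting disease subnetwork. This vignette is the package's account of the
statistical models, the design choices that were genuinely open, and what
the synthetic-data tests do and do not establish.

## Study design and association models

The cohort design the package targets is cross-sectional expression
profiling in a pedigree-based sample: a few thousand adults, a minority with
AF diagnosed *before* the blood draw (prevalent AF), a second minority who
develop AF *during follow-up* (incident AF), and an AF-free majority.
Samples within a pedigree are correlated, so naive per-gene regression
understates uncertainty.

**Prevalent AF.** For each feature (gene, transcript cluster, probeset, or
exon — the model does not care which granularity the rows carry), `afnet`
fits

$$y_{gs} = \beta_0 + \beta_{AF}\,\mathrm{AF}_s + \boldsymbol\gamma^\top
\mathbf{x}_s + u_{\mathrm{ped}(s)} + \varepsilon_{gs}, \qquad
u \sim N(0, \tau^2),\; \varepsilon \sim N(0, \sigma^2),$$

a linear mixed model with a Gaussian random intercept per pedigree,
estimated by REML (`lme4`). The reported effect is $\hat\beta_{AF}$ — the
log2 expression difference between AF cases and referents — with a
two-sided Wald p-value. The primary covariate set is age and sex; the
secondary set adds the classical AF risk factors (smoking, height, weight,
systolic and diastolic blood pressure, diabetes, myocardial infarction,
heart failure, antihypertensive treatment) and is intended for nominal
follow-up of primary hits rather than genome-wide screening. The referent
group excludes incident cases by default: referents are participants who
never developed AF, and a flag restores the larger referent set if wanted.
When a mixed fit fails (non-convergence, or an unidentifiable design such
as singleton pedigrees) the feature falls back to OLS with cluster-robust
(pedigree) sandwich standard errors, and the per-feature `note` column
records this. Constant features are flagged (`effect = 0`, `p = 1`) rather
than fatal, and singular designs produce flagged failure rows so a
genome-wide run never dies on one bad feature.

A numerical point worth documenting: when the true between-family variance
is zero, the per-feature REML estimate $\hat\tau^2$ sits on the zero
boundary only about half the time — small positive estimates arise from
sampling noise — so mixed-model and OLS estimates agree *exactly* only for
boundary fits and agree closely otherwise. The test suite asserts the exact
identity in the singleton-pedigree case, where the model is degenerate by
construction, and closeness under `family_sd = 0`.

**Incident AF.** Time from blood draw to AF onset is modelled with a Cox
proportional hazards model (`survival`), expression entering as a
continuous covariate alongside age and sex, with robust sandwich standard
errors clustered by pedigree and censoring at the end of follow-up. The
effect is a log hazard ratio per log2-expression unit. Whether expression
should enter continuously or dichotomized is not dictated by the problem;
continuous is the default here because it uses the full dynamic range and
matches how the synthetic generator plants incident risk. A configurable
floor (default 10 events) guards against fitting survival models to
near-empty risk sets.

**Medication screens.** Expression is regressed on a dichotomous medication
flag (warfarin, beta blocker, digoxin, calcium channel blocker) with the
same mixed-model machinery; by default adjusted for age and sex,
configurable off, since the appropriate adjustment set for drug-expression
screens is context-dependent.

**Multiple testing.** `bh_fdr()` applies the Benjamini–Hochberg step-up
rule $q_{(i)} = \min_{j \ge i} p_{(j)} m / j$ (capped at 1) with $m$ equal
to the number of features actually tested in the run — never a hard-coded
universe size. Significance is claimed at $q < 0.05$.

## Gene scores and the dense-module search

Association evidence is converted to a per-gene score
$z_i = \Phi^{-1}(1 - p_i)$, the upper-tail inverse-normal transform, so
$z(0.5) = 0$ and smaller p-values give larger scores. Two choices here were
genuinely open and are worth stating:

* **Functional form.** The score is adopted from the dense-module-search
  tradition of probit-transformed gene evidence; the package treats it as
  an assumption, not a derivation. It is direction-agnostic (built from the
  two-sided p-value) because the target subnetwork deliberately mixes up-
  and down-regulated evidence; a signed variant (`signed = TRUE`) is
  available for directional analyses.
* **Clipping.** p is clipped into $[10^{-16}, 1 - 10^{-16}]$ before the
  transform so scores stay finite (|z| ≲ 8.2); p = 1 therefore maps to the
  most negative representable transform rather than $-\infty$.

When multiple expression features map to one network gene, the gene is
scored from its *minimum* p-value — a collapse rule the package documents
as its own choice (the appropriate rule depends on annotation quality).
Network nodes without any scored feature are dropped from the search graph
(with a reported count) rather than imputed at $z = 0$, which would dilute
module scores with fabricated neutrality.

The module score of a connected gene set of size $k$ is
$Z_m = \sum_{i \in m} z_i / \sqrt{k}$. Starting from every scored gene as a
seed exactly once, `grow_module()` repeatedly evaluates all first-order
neighbors of the current module and adds the single best candidate, but
only if the score *strictly* increases; the search stops when no neighbor
improves it. Several readings of "add neighboring genes sequentially while
the score increases" are possible; the package fixes the steepest-ascent,
strict-improvement reading because it is deterministic, terminates on any
finite graph (scores strictly increase along the trajectory), and reduces
to the obvious behaviour on hand-checkable graphs. Ties among equally good
candidates break lexicographically by gene ID. The candidate set is
first-order neighbors only — no distance-2 expansion is implemented. One
module per seed is retained even when different seeds converge to the same
member set, so the module count equals the scored-gene count.

The AF subnetwork is the union of the top `top_fraction` (default 1%) of
modules by score — `ceiling(top_fraction * M)` modules, ties at the cutoff
again broken by seed ID so the count is exact — with the PPI edges induced
on the union. No edges are invented and every subnetwork node belongs to at
least one selected module.

## Pathway enrichment

Enrichment of the subnetwork in a gene-set collection (GMT) is the
hypergeometric upper tail: drawing $n$ subnetwork genes from a universe of
$N$, of which $K$ belong to the set, $p = P(X \ge k)$ for an observed
overlap $k$; this equals the one-sided Fisher exact test on the
corresponding 2×2 table, which the test suite verifies. The universe is the
set of scored genes present in the PPI graph — the population the
subnetwork was actually drawn from. Commercial pathway tools use their own
proprietary backgrounds, so enrichment q-values from such tools are not
comparable quantity-for-quantity; the overlap *ratio* $k/K$ (reported as
`"k/K (r)"` with r rounded to two decimals) is comparable and is what the
package's acceptance checks reproduce. Sets smaller than 3 genes after
universe intersection are skipped as vacuous, with a reported count.

## The synthetic study

Because the motivating cohort is access-controlled, the generator in
`simulation_config()` / `simulate_study()` is a first-class, tested
component that creates data with the statistical structure the analysis
assumes:

* **Cohort.** `n_samples = 2446` participants in `n_families = 700`
  pedigrees (sizes within one of each other, membership shuffled), a
  prevalent-AF fraction of 0.072 assigned exactly by rounding, and an
  incident-AF fraction targeting 0.058. Prevalent cases are drawn older
  (73 ± 8 vs 66 ± 9 years), more often male, and with higher rates of
  diabetes, infarction, heart failure, and antihypertensive treatment, so
  covariate adjustment is doing real work. Medication flags are strongly
  AF-associated (e.g. warfarin 45% vs 2%), emulating confounding by
  indication.
* **Expression.** $y_{gs} = b_g + 0.002\,(\mathrm{age}_s - 66) +
  0.05\,\mathrm{male}_s + u_{g,\mathrm{ped}(s)} + \delta_g
  \mathrm{AF}_s + \varepsilon_{gs}$ with $b_g \sim N(7,1)$,
  $u \sim N(0, 0.2^2)$ per gene × pedigree, $\varepsilon \sim N(0, 0.5^2)$,
  and $\delta_g = 0.15$ log2 units for the 25 signal genes in prevalent
  samples — the magnitude of shift a realistic whole-blood AF signature
  shows — doubled (`planted_module_z_boost = 2`) for the 12 genes forming
  the planted module. The gene count defaults to 500, a desk-scale
  stand-in for a ~18k-transcript array; all operating characteristics
  below are stated at that size.
* **Incident AF.** Rather than fixing the incident count, incident status
  is *generative*: each non-prevalent sample draws an exponential event
  time with hazard proportional to
  $\exp(0.5\,x_s + 0.04\,(\mathrm{age}_s - 66))$, where $x$ is the
  centered expression of one designated incident-risk gene, censored
  administratively at 7 years; the baseline rate is calibrated so the
  expected incident fraction matches the configuration. This keeps the
  per-gene Cox model well-specified (a single risk gene means no omitted
  expression covariates), which is why parameter recovery of the planted
  log hazard ratio is a meaningful oracle. The cost is that the realized
  incident count varies by seed — a deliberate trade against the fixed
  count, which would have broken the hazard→event link.
* **Network.** A preferential-attachment graph (mean degree ≈ 4, heavy
  right tail of hub degrees) or a truncated-Poisson configuration model;
  a connected subgraph of 12 vertices found by snowball sampling is
  labelled with the planted-module genes, so the high-evidence genes are
  guaranteed to form a connected module. The planted module is always a
  subset of the signal genes.
* **Gene sets.** 50 sets with sizes uniform on 10–40; the first set is
  seeded with at least half the planted module plus random background, the
  rest are uniform draws.

A single master seed derives fixed per-component substreams, so each
generator is individually reproducible and every output is a pure function
of (configuration, seed).

**What the generator does not emulate:** probe-level microarray noise,
batch effects, blood-cell composition, pedigree genetics (random
intercepts are exchangeable Gaussians, not kinship-structured), correlated
expression between genes, and exon-level structure beyond treating exons
as extra feature rows. Passing tests therefore demonstrate that the
*pipeline machinery* is correct and well-calibrated under the assumed
generative model — not that real cohort data would yield any particular
gene list.

## Operating characteristics (computed by the test suite)

All thresholds below were calibrated empirically on the generator at the
stated sizes before being frozen into tests, and the tests recompute them
at fixed seeds:

* **Null calibration** (no planted effects, 500 genes, 500 samples, 10
  seeds): the pooled fraction of association p-values below 0.05 is
  compatible with 0.05 within binomial error, and module scores for
  planted-module seeds are indistinguishable from the rest (Wilcoxon).
* **Recovery at defaults** (10 seeds): mean sensitivity for signal genes
  at $q < 0.05$ exceeds 0.8; the planted module's Jaccard overlap with the
  final subnetwork exceeds 0.6 on average; estimated expression shifts
  average within 0.02 of the planted 0.15; planted shifts come out
  positive in ≥95% of signal-gene fits.
* **Cox recovery** (20 seeds, ~150 events): the mean estimated log hazard
  ratio lands within 0.1 of the planted 0.5.
* **Exactness oracles:** the greedy growth matches an independent
  step-by-step reference on hundreds of random ≤8-node scored graphs; BH
  matches a brute-force step-up oracle; the hypergeometric tail matches
  exhaustive enumeration and one-sided Fisher.

Problem sizes in the test suite (500 genes, 300–2446 samples, ≤20 seeds
per property) were chosen as the smallest at which these properties are
stable; they are the package's documented defaults for verification runs.

## Numerical choices and degenerate inputs

* REML throughout for the mixed models; `lme4` defaults govern convergence
  (fallback path as described above).
* Strict `>` comparisons in the greedy search; equal-score additions are
  rejected, guaranteeing termination without a size cap.
* p-value clipping bounds scores at |z| ≈ 8.2; BH values are capped at 1.
* Empty network files parse to empty graphs; self-loops are dropped with a
  warning and count; duplicate edges (either orientation) collapse.
* Readers fail loudly with the offending row/column named; writers emit 15
  significant digits so read/write round trips preserve values.

## Limitations

The module search is greedy and seed-local: it finds locally dense
neighbourhoods, not globally optimal subnetworks, and the "top 1%" merge
inherits whatever redundancy the module population carries. Gene scores
ignore effect direction by default and inherit every bias of the
underlying p-values. Enrichment results depend on the supplied gene-set
collection and on the universe choice; both are explicit arguments
precisely because neither has a canonical value. And the synthetic
generator, by design, cannot certify behaviour on real microarray data —
it certifies the statistics, not the biology.
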