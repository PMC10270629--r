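---
title: "Personalized constraint-based flux analysis of two-group cohorts"
author: "FluxCohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized constraint-based flux analysis of two-group cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FluxCohort)
```

## The model and the question

FluxCohort asks how the *metabolic capability* of a tissue differs between
two groups of individuals — say healthy and disease — when all we measure
is bulk RNA-Seq. The core object is a constraint-based metabolic model: a
stoichiometric matrix $S$ over metabolites and reactions, flux bounds
$lb \le v \le ub$ (mmol·gDW$^{-1}$·h$^{-1}$), and boolean
gene–protein–reaction (GPR) rules linking each reaction to the genes whose
products catalyse it. Steady-state metabolism is the polytope
$\{v : Sv = 0,\ lb \le v \le ub\}$.

Expression enters through **E-Flux**: each gene-associated reaction's
bounds are scaled by its GPR activity relative to the sample's most active
reaction, so a weakly expressed enzyme caps the flux its reaction can
carry. GPR activities follow the complex/isozyme logic: `and` takes the
minimum of its children (a complex is limited by its scarcest subunit),
`or` sums them (isozymes add capacity; an `orMode = "max"` variant is
available). Genes missing from the expression matrix are dropped from
their rule rather than zeroed, so annotation gaps do not block reactions.
Exchange reactions carry no enzyme and are exempt; the growth medium
alone (a list of extracellular metabolites open for uptake) governs them.

Per individual, **flux variability analysis** (FVA) then reports for each
reaction the interval $[\min v_r, \max v_r]$ over the polytope, subject to
two physiological constraints:

* a viability floor — biomass production must reach at least a fraction
  $\beta$ (default 0.8) of the biomass optimum of the *healthy
  group-average model*, so every individual faces the same floor;
* an objective fraction — flux to the designated objective (a
  mitochondrial ATP demand in the toy models) is held at a fraction
  $\gamma$ (default 1, the COBRA convention) of its own optimum, which is
  computed *after* the biomass floor is imposed.

All linear programs are solved with the GLPK library (dual simplex with
primal fallback, warm-started across the FVA loop); infinite bounds are
capped at $\pm 1000$ before solving.

## From flux ranges to biology

Per reaction, Welch two-sample t-tests compare the per-individual minimum
fluxes and maximum fluxes between groups. Benjamini–Hochberg adjustment is
applied within the min family and the max family separately, and a
reaction is *perturbed* when either adjusted value falls below
$\alpha = 0.1$ (union rule). We kept the two families separate — the
min and max fluxes of a reaction are typically strongly dependent, so the
union's false-discovery rate stays near the nominal level, which the null
simulations below confirm; a pooled variant would be slightly more
conservative without changing the calls materially. FVA fluxes are often
constant across individuals, so the degenerate t-test cases are defined
rather than fatal: equal constants give $p = 1$, different constants give
the $p = 0$ sentinel.

Perturbed reactions are summarized three ways:

* **Enrichment** over pathway, metabolite and compartment reaction-sets:
  one-sided hypergeometric p-values with BH adjustment per set kind, and
  the *enrichment score* $100\,k/K$ — the percentage of a set's reactions
  that are perturbed. The universe is all reactions of the
  context-specific model carrying the relevant annotation; currency
  metabolites are *not* excluded here (ATP or NADH enrichment is
  meaningful), only in the network below.
* A **metabolite-centric network**: nodes are compartment-collapsed
  ("unique") metabolite ids; each perturbed internal reaction connects
  every substrate to every product after dropping a configurable currency
  list (ATP, NAD(H), H2O, ...); transport and exchange reactions are
  excluded. Nodes whose metabolite-enrichment $q > 0.05$ are filtered and
  connected components reported largest-first, with ties broken by the
  lexicographically smallest member. We connect *all* substrate–product
  pairs; with the currency cofactors removed, the spurious shortcuts this
  could create are largely gone, and the choice keeps the construction
  parameter-free.
* A **compartment summary**: raw perturbed counts per compartment and the
  adjusted percentage (perturbed over total per compartment), with
  transport reactions excluded from numerator and denominator since they
  span membranes.

## Flux markers

Candidate biofluid markers are exchange reactions whose FVA interval in
the disease group-average model is *shifted* against the healthy one. We
quantify "shifted" as interval Jaccard similarity
$J = |h \cap d| / |h \cup d| < 1 - \delta$ with $\delta = 0.1$ by
default; point intervals are compared by endpoint distance against an
absolute tolerance. This rule is an explicit modelling assumption — the
shift criterion is stated qualitatively in the methods literature — and
$\delta$ is exposed as a parameter.

Each candidate contributes two features per individual (its FVA minimum
and maximum), classified by an SVM with a polynomial kernel of degree 2
($C = 1$, `coef0 = 1`), evaluated by stratified 10-fold cross-validation
with per-fold z-score standardization fit on the training folds only.
Unstated SVM hyperparameters follow e1071 defaults and are configurable.
Feature selection is a binary genetic algorithm over feature subsets:
population 300, at most 100 generations, early stop once the best
cross-validated accuracy reaches 0.90; tournament selection (size 2),
uniform crossover (rate 0.8), per-bit mutation ($1/L$), elitism 1. The
fitness of a chromosome is the cross-validated accuracy of the SVM on its
features — cross-validated rather than resubstitution, to keep the
wrapper from rewarding overfit subsets — computed against one fold
assignment fixed per GA run so chromosome comparisons are consistent, and
cached per chromosome. Across repeated GA runs a reaction's *selection
frequency* is the share of runs whose final subset contains either of its
features; reactions at or above 80% form the top-ranked panel, which can
be validated on an external cohort with `validatePanel()` (optionally
excluding a confounded subgroup).

## What the synthetic data emulate — and what they do not

`makeToyModel()` builds two deterministic templates. `mini` (12 reactions)
is the smallest network with the full anatomy: uptake, glycolysis-like
conversion, fermentation, a mitochondrial ATP demand and a
three-precursor biomass. `core` (113 reactions, 82 metabolites, 127
genes) spans cytosol, mitochondria, golgi and the extracellular space:
central glycolysis/TCA/oxidative phosphorylation with balanced ATP and
NAD cycles, a four-precursor biomass, eight labelled peripheral pathways
built as dense five-metabolite motifs, and a dedicated marker pathway
feeding an exchange metabolite. Two design choices matter:

* Peripheral pathway reactions have base bounds of 20 against a media
  uptake of 50, so their E-Flux caps are the *binding* constraints —
  expression changes must propagate to flux ranges. Central and biomass
  reactions keep wide bounds (1000), so the viability floor stays feasible
  for every individual and central fluxes act as nulls.
* The disease effect is planted at the **gene** level only
  (`makeCohort()` multiplies disease-group negative-binomial means of the
  planted pathways' genes by `effectSize`): the E-Flux→FVA chain is what
  must transduce it. With the defaults (means log-uniform on 50–500,
  dispersion 0.1, `effectSize = 0.5`) the induced flux effect is about
  two standard deviations — the regime the differential tests are meant
  for. The planted marker uses a stronger factor (0.1) so a single
  exchange feature separates the classes cleanly.

Counts are negative binomial with a common dispersion (0.1, a typical
bulk RNA-Seq value); gene lengths are uniform on 500–3000 bp. What the
generator does **not** emulate: genome-scale model size (thousands of
reactions), correlated gene–gene expression structure, covariates such as
BMI or sex, batch effects, isoform-level length biases, or biologically
curated biomass composition and media. Passing the recovery tests
therefore shows that the pipeline's machinery is correct and sensitive
under its own assumptions — not that those assumptions hold in any real
tissue.

## Numerical and design choices

* **Preprocessing order** is fixed: filter genes with fewer than 5 counts
  in fewer than 25% of samples (read as *keep* genes with ≥ 5 counts in
  ≥ 25% of samples — the common-sense reading of an ambiguous phrasing),
  then median-of-ratios size factors, then division by gene length in kb,
  then $\log_2(x + 1)$. Length adjustment after size factors; the
  geometric-mean reference uses genes positive in all samples.
* **Dead-end pruning** is purely topological and iterated to a fixed
  point: a metabolite only produced or only consumed (reversible
  reactions count both sides; exchanges count as both) blocks its
  reactions. Topological pruning is deterministic and solver-free; an
  FVA-based flux-consistency pass can be emulated by inspecting `fva()`
  output, but is not the default. Pruning that would delete the biomass
  or objective reaction errors out rather than silently returning a
  non-viable model.
* **GPR grammar**: `and` binds tighter than `or` (SBML/BiGG convention);
  parsing and serialization are exact inverses, and the serialized form is
  the normalized rule string stored in the model.
* **LP tolerances**: feasibility comparisons use $10^{-6}$; FVA results
  are clamped into the (floored) bounds to absorb solver round-off.
* **Problem sizes in the tests**: the acceptance checks run the full
  chain on the core template with 20 + 20 individuals (effect 0.5), a
  200-repeat null study on the mini template with 15 + 15, and 20 GA
  repeats (population 100, 30 generations) against a planted marker —
  sizes chosen so the whole suite completes on a laptop-class single
  CPU in a few minutes while keeping the planted effect at the intended
  two-standard-deviation regime.

## A worked run

```{r example, eval = FALSE}
core  <- makeToyModel("core")
media <- toyMedia("core")
sim <- makeCohort(core, nHealthy = 20, nDisease = 20,
                  perturbedPathways = c("Glycerolipid metabolism",
                                        "Chondroitin biosynthesis"),
                  effectSize = 0.5, seed = 42)
cfg <- pipelineConfig(model = core, counts = sim$cohort, media = media,
                      seed = 42, gaRepeats = 20,
                      ga = gaConfig(populationSize = 100, generations = 30))
res <- runPipeline(cfg, "results/run1")
res$enrichment$pathway[1:3, c("set", "score", "q")]
networkComponents(res$network)
```

The run writes every intermediate artifact (normalized matrix, context
model, flux ranges, differential table, enrichment tables, SIF/GraphML
network, marker panel, manifest) into the output directory; re-running
the same configuration reproduces the statistical outputs byte for byte.

## Known limitations

* E-Flux is the only extraction method (no GIMME/iMAT/tINIT), matching
  the analysis this package implements; the scaling convention makes
  personalized models differ only in bounds.
* The t-test treats FVA endpoints as independent observations per
  individual; endpoint pairs of one reaction are dependent, which the
  separate-family BH handles conservatively.
* Flux polytope sampling, quadratic objectives and covariate adjustment
  are out of scope.
* SBML support targets Level 3 with the fbc package as written by this
  package and cobra-style exporters; exotic SBML constructs (species
  references with ids, initial assignments) are ignored.
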