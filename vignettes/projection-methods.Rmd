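---
title: "Methods: scaffold projection, GPR rewriting, and growth validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scaffold projection, GPR rewriting, and growth validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoGEM)
```

orthoGEM projects a curated genome-scale metabolic model (the *scaffold*)
onto a related species (the *target*) through ortholog maps, then validates
the projected draft by flux-balance growth simulation. This vignette
documents the model behind each step, the parameters that matter, the
numerical choices, and what the synthetic fixtures do and do not emulate.

## The projection model and its assumptions

The central assumption is that core metabolism is conserved between
phylogenetically related species: if the genes encoding a scaffold reaction
have orthologs in the target genome, the reaction is presumed present. Gene
*function* conservation is approximated by sequence-derived orthology, which
the package consumes as input (pairwise maps and paralog families from
several detection methods) and never computes itself — duplications,
family expansions and losses are visible in those maps, but fusion/fission
events and neofunctionalization are not, which bounds what projection can
see.

A reaction's gene dependency is a boolean GPR formula (`and` = complex
subunits, `or` = isozymes). Internally every formula is also available as
its list of **minimal gene sets** — the alternative gene combinations that
each suffice to carry the reaction. The field sometimes describes this
normal form as conjunctive; what is actually meant (and what
`minimal_gene_sets()` implements) is the disjunctive list of alternatives:
the reaction is available iff all genes of at least one set are present.
That is the semantics the rewrite and knockout machinery rely on, and the
form is canonical (sets sorted, supersets absorbed), which gives
reproducible output and a decidable equivalence test (`gpr_equivalent()`).

### Consensus orthology

Each detection method contributes a map from scaffold genes to target genes
with optional paralog-group labels. `build_consensus()` forms candidate
groups per scaffold gene (shared label within a method, else singletons),
merges groups across methods when they share any target gene (connected
components of the support graph), and scores each merged group with one
vote per supporting method. Two knobs are exposed because the election
procedure itself is a modeling choice:

* `min_votes` (default 1) — drop groups with less support;
* `consensus = "top"` (default) or `"all"` — in divergent cases keep only
  the top-voted group(s), or every group passing `min_votes`.

A tie at the top is resolved conservatively: all tied groups are kept and
their genes are unioned at rewrite time (ties are logged on the returned
object). This keeps reactions rather than dropping them, at the cost of
occasionally over-inclusive isozyme lists.

### GPR rewriting and the M1–M7 case labels

`rewrite_gpr()` substitutes each scaffold-gene leaf by the OR of its mapped
target genes. Two structural rules follow from the minimal-gene-set
semantics:

* an unmapped leaf inside an **OR** is dropped — some other isozyme
  alternative may still be complete;
* an unmapped leaf inside an **AND** invalidates that conjunct — a complex
  missing a subunit is not functional.

If no complete alternative survives, the association is lost (case M1) and
the unresolved genes are reported for manual curation. Otherwise the result
is labelled M3 (one-to-one throughout), M4/M5 (two / three-or-more scaffold
genes collapsing onto one target gene), M6/M7 (one scaffold gene expanding
to two / three-or-more targets), or `mixed` when several signatures (or a
partial loss) co-occur — published examples label whole reactions with
single cases only, so the mixed label is this package's extension for
formulas that combine them. Family expansions are always unioned (OR), never
intersected: nothing in the underlying biology suggests that all members of
an expanded family would be simultaneously required. After substitution the
tree is simplified (flattening, duplicate-leaf merging, absorption) so that
`minimal_gene_sets()` of the output is canonical.

### Conservation rule

`project()` decides conservation per GPR-bearing reaction:

* `"any-complete-gene-set"` (default): conserved iff the rewritten formula
  retains at least one complete minimal gene set — equivalently, iff it
  evaluates true with every mapped target gene present. This matches the
  functional semantics of a GPR.
* `"any-mapped-leaf"`: a looser alternative — conserved as soon as any
  scaffold gene of the formula is mapped, with the mapped targets joined by
  OR if the strict rewrite collapsed. Useful when ortholog maps are known
  to be incomplete and the draft will be manually reviewed anyway.

Reactions without gene association (spontaneous, non-enzymatic transport,
exchange) and all compartments are copied verbatim under
`keep_spontaneous` / `keep_exchanges` (both default `TRUE`); metabolite
identifiers and annotations are preserved from the scaffold. Lost reactions
are reported, never silently dropped, and a curation table
(`reaction_id`, `Lost`/`Retained`) can overrule the orthology verdict in
either direction — `Retained` reactions are copied without gene
association, mirroring how an expert reviewer upholds a reaction on
empirical evidence.

### Biomass adjustment

Only the DNA precursors are adjusted, because that is the one biomass
component that follows directly from genome properties: dGTP and dCTP each
receive a share proportional to `gc_content/2`, dATP and dTTP to
`(1 - gc_content)/2`, rescaled so the summed precursor coefficient equals
`dna_mass_fraction` (mmol/gDW) or, when that is not given, the scaffold's
original precursor total (mass conservation; verified to 1e-9 in the
tests). All other biomass coefficients pass through unchanged — protein,
RNA and lipid composition cannot be derived from the genome sequence and
belong to manual curation.

## Simulation and validation

### Media model

A media condition is a set of exchange-reaction bounds layered on a base
state: first every exchange's uptake is closed (lower bound raised to 0),
then the configured base (non-carbon) nutrient exchanges are opened, then
the condition's own bounds are applied last. Uptake is a negative exchange
flux; the default uptake magnitude is 10 mmol/gDW/h, the conventional
carbon-limited setting in constraint-based modeling. Media presets live in
a TSV (`media`, `exchange`, `lower`, `upper`; rows with media `base` define
the base state), so a study's conditions are data, not code.

### FBA and the LP core

`fba()` maximizes the biomass flux subject to S·v = 0 (boundary metabolites
excluded from the balance) and the flux bounds. The LP is solved by
`lp_bounded()`, a two-phase bounded-variable primal simplex written for
this package: Bland's smallest-index rule for both entering and leaving
variables makes it immune to cycling and fully deterministic (identical
input gives identical pivots, so degenerate optima are resolved the same
way every run); phase 1 artificials absorb rank-deficient stoichiometries.
Pivot/feasibility tolerance is 1e-9; every optimal solution is re-checked
against mass balance and bounds at 1e-6 and the solve fails loudly rather
than return a violating flux vector. Only the objective value is
contract-guaranteed — at degenerate optima the flux vector is one optimal
vertex among several. Because all structural variables carry finite bounds
(default ±1000 mmol/gDW/h, the COBRA convention), the LP is never
unbounded. The simplex is validated in the test suite against a
vertex-enumeration oracle on small networks and was cross-checked against
an independent interior-point/HiGHS implementation during development.

### Knockouts and binarization

`knockout()` evaluates every GPR with the deleted genes absent and closes
(bounds 0,0) the reactions whose formula fails; GPR-less reactions are
untouched, and unknown gene ids are logged, not fatal. Predicted growth is
binarized by a strict threshold: `rate > threshold` with an absolute
default of 1e-6 /h (effectively "any nonzero growth"), or a relative
threshold as a fraction of a wild-type reference rate. Experimental OD
curves are binarized against one third of the cohort's mean OD — the
convention used when literature reports growth curves for a panel of
mutants rather than explicit growth calls.

### Scoring

Observed-vs-predicted pairs produce a confusion matrix with growth as the
positive class (a false positive is predicted growth where none was
observed — the signature of an over-permissive network). The summary
statistic is the geometric mean of sensitivity and specificity, which
penalizes models that buy sensitivity by predicting growth everywhere. When
a fixture contains only one observed class the undefined metric is `NA`,
the geometric mean falls back to the defined one and the result is flagged
(`gmean_defined = FALSE`). Reports round accuracy to two decimals; the JSON
output keeps full precision.

### Census formatting

`census()` partitions reactions into five classes (transport with/without
gene association, exchange, enzymatic with/without) with shares rounded to
one decimal. The human-readable report prints a share as a whole percent
when it is at least 5% and its one-decimal value lies within 0.1 of an
integer (7% rather than 6.9% or 7.0%) — the convention seen in published
model descriptions — while machine outputs always keep the one-decimal
value.

## The synthetic fixtures

`fixture_spec()` defines the study conditions for a fully synthetic
pipeline run. `make_scaffold()` builds a compartmentalized model of
`n_linear_pathways` (default 6) carbon sources, each an exchange, a
spontaneous transport and a `pathway_length`-step (default 4) enzymatic
chain into a common precursor pool; every second pathway routes through an
internal organelle, creating both gene-associated and spontaneous transport
reactions; four gene-associated reactions derive the DNA precursors and the
biomass consumes the pool plus precursors at a scaffold GC content of 0.38.
Defaults were chosen once as the smallest network that exhibits every
structural feature the pipeline must handle (isozymes, complexes,
compartment routing, essential and dispensable genes) while keeping a full
test run fast; the acceptance-scale runs use 8 pathways and 152 experiment
rows, matching the shape of a published validation campaign.

`make_ortholog_maps()` plants one evolutionary event per GPR-bearing
reaction, drawn from `event_mix` (default: 50% one-to-one, 10% each for
loss and the four duplication/expansion cases) restricted to what the
reaction's GPR shape admits, and returns the ground truth for recovery
testing. The four DNA-precursor reactions are never assigned a loss: losing
a universally essential reaction produces a model that can never grow,
whereas the projection workflow targets functional models, so planted
losses live in dispensable routes (a broken pathway then shows up as a
true no-growth condition, which is exactly the informative case).
`make_experiments()` computes each (media × knockout) row's ground truth by
simulation on the uncorrupted target and plants disagreements by flipping a
chosen number of observations, so the expected confusion matrix is known by
construction.

Determinism: a single integer seed derives one named pseudo-random stream
per generator stage, so adding a stage never perturbs earlier outputs, and
identical specs produce byte-identical SBML. The generators restore the
caller's RNG state.

What the fixtures do *not* emulate: real biochemistry (no mass-balanced
stoichiometry beyond unit coefficients, no cofactors, no thermodynamics),
annotation noise correlated between methods, partially overlapping paralog
families, or media uncertainty. A pipeline that passes on fixtures is
structurally and logically correct; its accuracy on a real species is still
bounded by ortholog-map quality and curation effort, which is why every
lost reaction and unresolved gene is surfaced for review rather than
decided silently.

## Numerical and formatting choices, collected

| Quantity | Value | Rationale |
|---|---|---|
| Default flux bounds | ±1000 mmol/gDW/h | constraint-based modeling convention |
| Default carbon uptake | 10 mmol/gDW/h | conventional carbon-limited setting |
| Growth threshold | 1e-6 /h, strict `>` | "any nonzero growth"; equality is no-growth |
| OD growth threshold | cohort mean / 3 | growth-curve panel convention |
| LP pivot tolerance | 1e-9 | below model-scale numerics, above double noise |
| Mass-balance assertion | 1e-6 | contract on every optimal solution |
| FVA "blocked" tolerance | 1e-9 | matches LP tolerance |
| Census shares | one decimal; ≥5% within 0.1 of integer printed as integer | published-report convention |
| Accuracy rounding | two decimals in reports, full precision in JSON | readable yet lossless |

## Known limitations

* The ortholog election procedure is a reproducible stand-in for an
  under-specified manual practice; alternative grouping rules (e.g.
  per-method groups only) can change votes for entangled families.
* Gap analysis is diagnostic only: dead ends, blocked reactions and
  candidate lists are reported, but no MILP-style automatic gap filling is
  attempted — candidate acceptance is a curation decision.
* FBA cannot distinguish isozyme-specific activities within one reaction;
  chain-length-specific family members all satisfy the same OR clause.
  Kinetic modeling is out of scope.
* Only the binary growth/no-growth comparison is implemented; quantitative
  rate comparison would need calibrated uptake rates, which the validation
  data generally do not provide.
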