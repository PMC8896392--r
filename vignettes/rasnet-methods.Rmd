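---
title: "Methods: layered Ras-effector network reconstruction and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: layered Ras-effector network reconstruction and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rasnet)
```

## The reconstruction model

`rasnet` treats a signaling network as an *oriented graph of layered binary
interactions*. Layer 0 is the effector roster — by default the 43
high-confidence Ras effectors in 12 functional pathway classes returned by
`ras_effector_roster()`. Layer k (k = 1..3) is the set of targets of admitted
edges whose source occupies layer k-1. Three layers is the default depth: it
is deep enough to contain the canonical three-tier kinase cascades
(RAF/MEK/ERK, PI3K/AKT/mTOR) while already covering on the order of 10% of
the proteome; deeper expansion would dilute the network into essentially all
cellular processes.

Assumptions worth making explicit:

* **Evidence precedence.** Directed records (a SignaLink-style table filtered
  to the *Directed* / *Predicted as directed* labels, plus directed edge
  lists hand-derived from pathway diagrams) always take precedence.
  Undirected records (STRING/HuRI style) are a fallback admitted for an
  expanding protein only when that protein has *no directed record as a
  source*; the record is then oriented from the expanding protein to its
  partner. We read "has no directed records" as "as a source" because
  expansion only ever consumes source-side records; a protein that is only
  ever a directed *target* still has nothing to expand from.
* **Fallback depth.** By default the undirected fallback applies only when
  expanding the effectors themselves (layer 1): iterated mining at deeper
  layers uses the directed databases. Whether deeper undirected expansion is
  appropriate is genuinely open; `undirected_at_depth = TRUE` relaxes it, and
  the option is echoed in every pipeline summary.
* **Re-entry.** An edge whose target already occupies an upper layer is kept
  and the target simply gains the new layer membership. This is what lets an
  effector re-appear at L2/L3 and is the substrate of feedback detection.
  A protein present in two layers expands from both (its records fire at both
  depths).
* **Self-loops** (`source == target`) are dropped by default
  (`keep_self_loops` restores them): an autoregulatory record carries no
  layering information in this model.
* **De-duplication.** Edges are keyed by `(source, target, layer)`;
  duplicates merge with set-union of databases, interaction types and
  effector classes. The same protein pair at *different* layers remains two
  edges, because per-layer counts sum over layers.

Symbols are standardized by exact, case-insensitive matching against a
reference symbol list; unmatched names are discarded together with every
record touching them, and reported. No alias resolution is attempted — silent
aliasing is a worse failure mode for replication work than a documented drop
list.

## Analysis definitions and their open choices

**Degrees and hubs.** Degree counts occurrences over all layered edges, so an
edge repeated at two layers counts twice; this matches counting "interactions
from the three layers". The hub cutoff defaults to 10 total occurrences.

**Crosstalk.** Each downstream protein is assigned to the subgroup equal to
its full class-membership set; the non-empty subgroups partition the
downstream proteins (the package asserts disjointness and exhaustiveness in
its tests). Pairwise closure sharing has no single natural denominator, so
`pairwise_class_sharing()` offers Jaccard (default), min-closure and per-row
variants; replication work should report which one is used.

**Feedback loops.** A loop is an edge from a protein occupying layer 2 or 3
onto a protein occupying layer 0 or 1 with a layer gap ≥ 2; one-layer-back
edges are excluded as likely complex/scaffold bonds. Because the rule is
stated on *layers* and a protein occupies several, every membership
combination is examined and results are de-duplicated per
`(source, target, target_layer)`. The natural counting unit is ambiguous
(per back-edge or per regulated target), so both counts are reported
(`n_loops`, `n_loops_per_target`).

**Compatibility.** Localization compatibility is a reflexive symmetric 0/1
relation over the 19 merged localization classes. The full published relation
behind any given analysis is rarely printed, so the package ships a
documented, editable default (cytosol compatible with the membrane-bounded
and cytoskeletal compartments, extracellular with the cell surface and
junction/ECM classes, nucleus with cytosol; see
`inst/extdata/localization_compatibility_default.csv`) and accepts a
user-supplied CSV for exact replication; every report names its options.
Proteins with unknown localization are excluded from the denominator by
default (`unknown_policy`), which is conservative; forcing them compatible
can only raise the fraction (a property the tests assert). Interaction-type
compatibility holds when an edge carries at least one of the four SignaLink
categories describing direct physical contact. Since only the deduplicated
edge multiset is unambiguous, fractions are also reported on the
class-expanded multiset (each edge counted once per effector class reaching
it), which is the larger basis a per-class bookkeeping would produce.

**Class-normalized enrichment.** A protein downstream of k classes carries
weight 1/k in each (weights sum to exactly 1 per protein — asserted, not
assumed). Weighted (class, category) counts are rounded to integers before a
two-sided Fisher's exact test against the reference proteome annotation.
Rounding is *half away from zero* by default so that a weight of 0.5 counts
as a protein rather than vanishing; banker's rounding is available and the
rule in force is echoed in the summary. Raw p < 0.05 drives the significance
flag (the convention of the analysis style this reproduces), with
Benjamini-Hochberg adjusted p-values always reported alongside. Two-sided
tests cover both enrichment and depletion; a one-sided variant per direction
was considered and rejected to keep a single uniform p-value column.
Degenerate tables (a zero margin) report p = 1 with an undefined odds ratio
and a `degenerate` flag. Exact-test p-values are clamped at 1 against
floating-point overshoot.

**Overlap.** External lists are intersected with the union of layer members;
the per-layer distribution counts a multi-layer protein once per layer, so
percentages may sum above 100 — stated in the report schema rather than
hidden.

## What the synthetic generator emulates

`generate_sources()` wires a network exactly the way the builder will
reconstruct it, then emits it as the three source dialects plus annotation
tables, recording every planted structure:

* **Scale.** The defaults are sized to the study conditions this package
  implements: 43 effectors / 12 classes, a 19,300-symbol reference, mean
  branching `c(10, 5.5, 13)` with fresh-protein probabilities
  `c(0.6, 0.85, 0.03)`, landing near 2,300 proteins and 19,000 layered edges
  distributed ~440/~1,700/~17,000 across layers; 28 of 43 effectors carry
  undirected-only evidence and 2 are isolated. Out-degrees at layers 2-3 are
  drawn from a rounded lognormal (`branch_sdlog`), reflecting that database
  mining yields a few heavily-curated proteins with very many targets;
  re-entry targets are sampled by preferential attachment (degree + 1), which
  together produce the heavy-tailed degree structure of real interactomes
  (roughly 55-60% non-hubs at cutoff 10 at the default scale).
* **Planted feedbacks** are explicit back-edges added after layering is
  fixed, from a protein occupying layers {2,3} onto a layer-1 protein —
  a guaranteed layer gap of 2. Feedbacks onto layer-0 effectors are not
  planted by the generator: giving an effector a layer-3 membership turns
  each of its forward edges into a further detected loop, so exact-recovery
  ground truth would no longer be the planted set alone. The forward wiring
  never targets L0/L1 proteins, making the planted edges provably the only
  backward edges; L0-targeted loops are exercised by hand-built networks in
  the unit tests.
* **Multi-layer effectors** are planted separately (`n_effector_reentries`,
  default 15 ≈ 35% of the roster) as L1→effector edges, whose sources are
  chosen so that they can never acquire a layer-3 membership themselves.
* **Planted class-specific proteins** are reserved extra L1 targets of a
  single class, excluded from every other sampling pool.
* **Annotations.** Localization is drawn per protein from a per-layer mix
  planting the extracellular→L1 / cytosol→L2 / nucleus→L3 gradient over a
  cytosol-heavy background (the cytosol is the most common main localization
  and co-habits with most compartments, which is also what makes ~¾ of edges
  localization-compatible under the default matrix). Process classes use a
  signaling-heavy, metabolism-poor distribution for network proteins against
  a flatter reference, plus one planted (class, process) odds multiplier.
  Interaction types are drawn with ~82% mass on the four direct-contact
  categories.

What it deliberately does **not** emulate: correlated annotation errors,
database-specific curation biases, literature-driven edge redundancy across
sources, secondary localizations, and any mass-spectrometry-level detail in
external lists (these are plain symbol lists with a controlled overlap
fraction). Passing recovery tests therefore demonstrates the *pipeline's*
correctness on data with the right shape and scale — not that any particular
biological claim holds on real exports.

## Numerical and testing choices

* Determinism: the generator runs under a local RNG stream fully determined
  by `config$seed` and restores the caller's stream; building a network is
  order-independent (asserted under row permutation).
* Set-valued edge fields are canonicalized as sorted, semicolon-joined
  strings, so equality of edge tables is exact and the TSV round-trip
  reproduces the edge multiset identically.
* Layering correctness is checked against an exhaustive path-enumeration
  oracle (protein ∈ Lk iff an admitted chain of length k exists) on 100
  random graphs of up to 50 nodes; feedback detection against a brute-force
  scan over all edge × layer-membership combinations on 50 seeded
  generations; Fisher p-values against direct hypergeometric summation on
  every 2×2 table with total ≤ 32 and 2,000 random tables up to n = 200, at
  1e-10.
* The null calibration of the enrichment test samples 150-protein classes
  from a 10,000-protein reference at a 25% category rate — sizes chosen so
  the exact test's discreteness is small; exact tests are conservative by
  construction, so the attained level sits slightly below 0.05.
* The planted-enrichment power check uses a dedicated all-fresh Poisson
  configuration (8 effectors, 4 classes) whose planted-class closure averages
  200 proteins, with an odds multiplier of 5.
* Test problem sizes: unit tests run on ~3,000-symbol references with mean
  branching `c(4, 3, 3)` (a few hundred proteins per network); the
  full-scale configuration (≈2,400 proteins, ≈19,000 edges) is exercised
  once end-to-end, which completes in well under a minute.

## Known limitations

* Only each protein's *main* localization is modeled, so the
  localization-compatible fraction is a lower bound on true co-compartment
  plausibility.
* The default compatibility matrix is a curated starting point, not a
  published standard; quantitative replication requires supplying the matrix
  actually used.
* The undirected fallback orientation (away from the expanding protein) is a
  modeling convention, not evidence of causality.
* Enrichment treats the reference annotation as flat categories; no ontology
  propagation is performed (a mapping to coarser categories is consumed, not
  built).
* When a deposited network table is read back (`read_network_tsv()`) without
  a roster, layer-0 classes are inferred from layer-1 edges, which cannot
  recover effectors that had no interactors; published protein totals that
  include such effectors (e.g. counting 2,290 with them but running
  centrality on 2,262 without) can differ by exactly that margin, so the
  package reports both `n_proteins` and `n_downstream`.
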