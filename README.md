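# rasnet

Reconstruction and analysis of layered Ras-effector signaling networks in R.

Ras proteins are central signaling hubs: they bind a roster of effector
proteins (each carrying a Ras-binding domain), and each effector triggers its
own downstream pathway. Beyond the famous RAF-MEK-ERK and PI3K-AKT cascades,
most effector pathways are poorly mapped, and the knowledge that exists is
scattered across pathway and protein-protein interaction (PPI) databases with
incompatible formats and directionality conventions. `rasnet` is for systems
biologists who want to assemble that scattered evidence into one oriented,
layer-indexed network downstream of the effectors and interrogate its
topology, crosstalk and functional content — and to validate every step of
that pipeline against synthetic data with known ground truth.

## The model

Starting from the effector roster (43 high-confidence Ras effectors grouped
into 12 functional classes, the layer-0 nodes), the network is grown
breadth-first for three layers:

* **L1** — targets of admitted edges whose source is an effector,
* **Lk** — targets of admitted edges whose source belongs to L(k-1), for
  k ≤ 3.

Directed evidence (SignaLink-style records labeled *Directed* / *Predicted as
directed*, and KEGG/WikiPathways-style directed edge lists) is always used
first; undirected records (STRING/HuRI style) are admitted for an expanding
protein only when it has no directed record as a source, oriented from the
expanding protein to its partner. A protein may occupy several layers (an
effector reached again at L2 stays an effector *and* an L2 member); edges are
keyed by `(source, target, layer)` with database, interaction-type and
effector-class provenance unioned on duplicates.

On the built network `N` the package computes:

* **Hubs** — degree over all layered edges; a protein with
  `in + out ≥ 10` (configurable) is a hub.
* **Crosstalk** — the partition of downstream proteins into effector-class
  subgroups (a protein's subgroup is the full set of classes whose closures
  contain it); singleton subgroups are the class-specific proteins; pairwise
  closure sharing is reported as Jaccard/min/row fractions.
* **Feedback loops** — edges `u → v` with a layer of `u` in {2, 3}, a layer
  of `v` in {0, 1}, and a layer gap ≥ 2 (L1→L0 and L2→L1 edges are excluded
  as likely scaffolding bonds rather than regulation).
* **Compatibility** — each edge is scored for localization compatibility
  (a reflexive symmetric relation over 19 merged subcellular-localization
  classes) and for interaction-type compatibility (four of the six SignaLink
  interaction categories describe direct physical contact), plus the 2×2
  agreement between the two definitions.
* **Class-normalized enrichment** — each downstream protein is weighted
  1/k across the k classes it belongs to (weights sum to 1 per protein);
  per (class, process) the rounded weighted counts enter a two-sided
  Fisher's exact test against a reference proteome annotation, with raw
  p-values flagged at 0.05 and Benjamini-Hochberg adjusted p-values
  alongside.
* **Overlap** — coverage of external protein lists (AP-MS / BioID /
  complex-database exports) with per-layer distribution (multi-layer
  proteins counted once per layer).

The synthetic-data generator (`synthetic_config()` / `generate_sources()`)
emits the three source-table dialects, a reference symbol list and an
annotation table with *planted, recorded* structure — hubs, feedback
back-edges, class-specific proteins, localization gradients, an enrichment
effect — so every analysis stage can be tested for exact recovery.

## Worked example

```r
library(rasnet)

syn <- generate_sources(synthetic_config(seed = 1))
net <- syn$network
net
#> <layered_network> 2443 proteins, 18721 layered edges, depth 3
#>   L1: 410 edges
#>   L2: 1737 edges
#>   L3: 16574 edges

loops <- find_feedback_loops(net)
attr(loops, "n_loops")                        # 206
attr(loops, "multilayer_effector_fraction")   # 0.349 (15/43 effectors)

deg <- degree_centrality(net, hub_cutoff = 10)
attr(deg, "nonhub_fraction")                  # 0.553

lf <- localization_compatibility(net, syn$annotations)
tf <- interaction_type_compatibility(net)
compatibility_agreement(lf, tf)
#> <compat_report> 18721 edges
#>   localization-compatible: 12677 (74.4%)
#>   type-compatible:         13790 (82.2%)
#>   agreement: 66.0% of 15302 jointly evaluated edges

w <- class_weights(net)
enr <- fisher_enrichment(w, syn$annotations, syn$annotations)
dplyr::arrange(tibble::as_tibble(enr), p_value)[1:2, c("class_id", "category", "fold", "p_value", "direction")]
#>   class_id category   fold  p_value direction
#> 1        9 Signaling  2.37 1.13e-35 enriched
#> 2        2 Signaling  2.45 6.33e-27 enriched
```

The network print shows the per-layer edge counts of the reconstructed
3-layer graph. The 206 feedback loops are exactly the generator's planted
back-edges; 35% of effectors re-appear at deeper layers. About three quarters
of edges connect compatible compartments under the default matrix
(`inst/extdata/localization_compatibility_default.csv`; supply your own via
`read_compatibility_matrix()` for replication work), and the enrichment table
flags the signaling-heavy, metabolism-poor functional profile the generator
plants in network proteins.

Real data enter the same way: `read_source_table()` for each database export,
`standardize_symbols()` against your reference list, then
`build_layered_network()` and the same analysis battery, or
`run_full_pipeline()` driven by a YAML config (`read_run_config()`).

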