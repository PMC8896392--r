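#' Degree centrality and hub classification
#'
#' Counts, for every network protein, its occurrences as a source
#' (out-degree) and as a target (in-degree) over all layered edges — an edge
#' repeated at two layers counts twice, matching a per-layer edge table. A
#' protein is a hub when its total degree meets the cutoff.
#'
#' @param network A `layered_network`.
#' @param hub_cutoff Minimum total degree defining a hub (default 10).
#' @return A tibble with columns `protein`, `in_degree`, `out_degree`,
#'   `total`, `is_hub`, sorted by decreasing total; the hub and non-hub
#'   fractions are attached as attributes `hub_fraction` / `nonhub_fraction`.
#' @export
degree_centrality <- function(network, hub_cutoff = 10) {
  stopifnot(inherits(network, "layered_network"))
  if (!is.numeric(hub_cutoff) || hub_cutoff < 1) {
    stop_config("hub_cutoff must be a positive integer (got %s)", hub_cutoff)
  }
  edges <- network$edges
  out_d <- count(edges, protein = .data$source, name = "out_degree")
  in_d <- count(edges, protein = .data$target, name = "in_degree")
  deg <- tibble(protein = network_proteins(network)) %>%
    left_join(in_d, by = "protein") %>%
    left_join(out_d, by = "protein") %>%
    mutate(
      in_degree = as.integer(ifelse(is.na(.data$in_degree), 0L, .data$in_degree)),
      out_degree = as.integer(ifelse(is.na(.data$out_degree), 0L, .data$out_degree)),
      total = .data$in_degree + .data$out_degree,
      is_hub = .data$total >= hub_cutoff
    ) %>%
    arrange(dplyr::desc(.data$total), .data$protein)
  attr(deg, "hub_fraction") <- mean(deg$is_hub)
  attr(deg, "nonhub_fraction") <- mean(!deg$is_hub)
  deg
}

# Downstream class-membership sets, one row per protein in any class closure.
downstream_class_sets <- function(network) {
  network$protein_classes
}

#' Decompose downstream proteins into effector-class subgroups
#'
#' Every protein in at least one class closure is assigned to exactly one
#' subgroup: the full set of effector classes it sits downstream of. The
#' non-empty subgroups partition the downstream protein set; singleton
#' subgroups contain the class-specific proteins.
#'
#' @param network A `layered_network`.
#' @return A tibble with one row per non-empty subgroup: `classes`
#'   (semicolon-joined class ids), `n_classes`, `n_proteins`, `proteins`
#'   (list-column). Attributes `class_specific` (character vector of proteins
#'   in singleton subgroups) and `n_class_specific`.
#' @export
class_subgroup_decomposition <- function(network) {
  stopifnot(inherits(network, "layered_network"))
  sets <- downstream_class_sets(network)
  if (nrow(sets) == 0) {
    out <- tibble(classes = character(), n_classes = integer(),
                  n_proteins = integer(), proteins = list())
    attr(out, "class_specific") <- character()
    attr(out, "n_class_specific") <- 0L
    return(out)
  }
  out <- sets %>%
    group_by(classes = .data$classes) %>%
    summarise(n_proteins = n(), proteins = list(sort(.data$protein)),
              .groups = "drop") %>%
    mutate(n_classes = lengths(split_set(.data$classes))) %>%
    select("classes", "n_classes", "n_proteins", "proteins") %>%
    arrange(.data$n_classes, .data$classes)
  specific <- sort(unlist(out$proteins[out$n_classes == 1L]))
  attr(out, "class_specific") <- specific
  attr(out, "n_class_specific") <- length(specific)
  out
}

#' Pairwise shared-protein fractions between class closures
#'
#' Entry (a, b) quantifies how much of the downstream protein sets two
#' effector classes share. Three denominators are available: `"jaccard"`
#' (intersection over union, the default), `"min"` (intersection over the
#' smaller closure), and `"row"` (intersection over closure a, asymmetric).
#'
#' @param network A `layered_network`.
#' @param method One of `"jaccard"`, `"min"`, `"row"`.
#' @return A numeric matrix (classes x classes) of shared fractions in
#'   percent; entries involving an empty closure are `NA`.
#' @export
pairwise_class_sharing <- function(network, method = c("jaccard", "min", "row")) {
  method <- arg_match(method)
  stopifnot(inherits(network, "layered_network"))
  closures <- network$class_closure
  ids <- names(closures)
  k <- length(ids)
  m <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      a <- closures[[i]]
      b <- closures[[j]]
      if (length(a) == 0 || length(b) == 0) next
      inter <- length(intersect(a, b))
      denom <- switch(method,
                      jaccard = length(union(a, b)),
                      min = min(length(a), length(b)),
                      row = length(a))
      m[i, j] <- 100 * inter / denom
    }
  }
  m
}

#' Detect feedback loops
#'
#' A feedback loop is a backward regulation: an edge from a protein occupying
#' layer 2 or 3 onto a protein at least two layers upstream (onto L0 from
#' L2/L3, onto L1 from L3). Edges one layer back (L1 to L0, L2 to L1) are
#' excluded, as those may be scaffolding bonds rather than regulation. Because
#' a protein can occupy several layers, every combination of source-layer and
#' target-layer membership is examined; loops are de-duplicated per
#' `(downstream_source, upstream_target, target_layer)`.
#'
#' @param network A `layered_network` built with re-entry edges retained.
#' @return A tibble with columns `downstream_source`, `source_layers`
#'   (semicolon-joined memberships in 2..3 that close the loop),
#'   `upstream_target`, `target_layer`, `via_layer` (layer of the edge
#'   itself). Attributes: `n_loops` (rows), `n_loops_per_target` (distinct
#'   upstream targets — the per-target counting convention),
#'   `multilayer_effectors` (roster effectors appearing at any layer >= 1) and
#'   `multilayer_effector_fraction`.
#' @export
find_feedback_loops <- function(network) {
  stopifnot(inherits(network, "layered_network"))
  members <- network$members
  edges <- distinct(network$edges, .data$source, .data$target, .data$layer)

  src_layers <- members %>%
    filter(.data$layer >= 2L) %>%
    select(source = "protein", source_layer = "layer")
  tgt_layers <- members %>%
    filter(.data$layer <= 1L) %>%
    select(target = "protein", target_layer = "layer")

  hits <- edges %>%
    inner_join(src_layers, by = "source", relationship = "many-to-many") %>%
    inner_join(tgt_layers, by = "target", relationship = "many-to-many") %>%
    filter(.data$source_layer - .data$target_layer >= 2L)

  if (nrow(hits) == 0) {
    loops <- tibble(downstream_source = character(), source_layers = character(),
                    upstream_target = character(), target_layer = integer(),
                    via_layer = integer())
  } else {
    loops <- hits %>%
    group_by(downstream_source = .data$source, upstream_target = .data$target,
             target_layer = .data$target_layer) %>%
    summarise(source_layers = join_set(.data$source_layer),
              via_layer = min(.data$layer), .groups = "drop") %>%
    select("downstream_source", "source_layers", "upstream_target",
           "target_layer", "via_layer") %>%
    arrange(.data$upstream_target, .data$downstream_source, .data$target_layer)
  }

  eff <- network$roster$effector
  multilayer <- sort(unique(
    members$protein[members$layer >= 1L & members$protein %in% eff]
  ))
  attr(loops, "n_loops") <- nrow(loops)
  attr(loops, "n_loops_per_target") <- n_distinct(loops$upstream_target)
  attr(loops, "multilayer_effectors") <- multilayer
  attr(loops, "multilayer_effector_fraction") <- length(multilayer) / length(eff)
  loops
}
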