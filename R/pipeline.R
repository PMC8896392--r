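#' Load a pipeline run configuration from YAML
#'
#' A run configuration either points at source files (`inputs:` with keys
#' `signalink`, `directed_edgelist`, `undirected_edgelist` — each a path or
#' list of paths — plus `effectors`, `reference`, `annotations`, and
#' optionally `compat_matrix`) or requests a synthetic run (`synthetic:` with
#' [synthetic_config()] fields). Builder and analysis options (`max_depth`,
#' `keep_self_loops`, `undirected_at_depth`, `hub_cutoff`, `unknown_policy`,
#' `sharing_method`, `rounding`, `seed`, `output_dir`) sit at the top level.
#'
#' @param path YAML file path.
#' @return A validated config list for [run_full_pipeline()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("run config not found: %s", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config An in-memory config list.
#' @export
validate_run_config <- function(config) {
  defaults <- list(max_depth = 3, keep_self_loops = FALSE,
                   undirected_at_depth = FALSE, hub_cutoff = 10,
                   unknown_policy = "exclude", sharing_method = "jaccard",
                   rounding = "half_away", seed = 1L, output_dir = NULL)
  config <- modifyList(defaults, config)
  if (is.null(config$inputs) && is.null(config$synthetic)) {
    stop_config("run config needs either 'inputs' or 'synthetic'")
  }
  if (!is.null(config$inputs)) {
    required <- c("effectors", "reference", "annotations")
    for (key in required) {
      if (is.null(config$inputs[[key]])) {
        stop_config("run config inputs are missing '%s'", key)
      }
    }
    paths <- unlist(config$inputs, use.names = FALSE)
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0) {
      stop_config("input path(s) do not exist: %s", paste(missing, collapse = ", "))
    }
  }
  config
}

#' Run the full reconstruction and analysis pipeline
#'
#' Executes read-or-simulate, build, and the complete analysis battery, and
#' collects the headline numbers in one summary object. Every decision option
#' in effect (rounding rule, unknown policy, sharing denominator, hub cutoff)
#' is echoed in the summary so any replication discrepancy is attributable.
#'
#' @param config A config list (see [read_run_config()] /
#'   [validate_run_config()]), or a [synthetic_config()] for a pure synthetic
#'   run under default options.
#' @return A `ras_summary` list: `options`, `network` (the `layered_network`),
#'   `summary` (named headline numbers), `tables` (normalized class PPIs,
#'   subgroups, degree table, enrichment, localization tables), `compat`
#'   (the `compat_report`), `loops`.
#' @export
run_full_pipeline <- function(config) {
  if (inherits(config, "synthetic_config")) {
    config <- list(synthetic = config)
  }
  config <- validate_run_config(config)

  if (!is.null(config$synthetic)) {
    syn_cfg <- if (inherits(config$synthetic, "synthetic_config")) {
      config$synthetic
    } else {
      do.call(synthetic_config, config$synthetic)
    }
    synthesis <- generate_sources(syn_cfg)
    records <- bind_rows(
      source_records_from_table(synthesis$tables$signalink, "signalink", "signalink"),
      source_records_from_table(synthesis$tables$directed_edgelist,
                                "directed_edgelist", "kegg"),
      source_records_from_table(synthesis$tables$undirected_edgelist,
                                "undirected_edgelist", "string")
    )
    roster <- syn_cfg$roster
    reference <- synthesis$reference
    annotations <- synthesis$annotations
    reference_annotations <- synthesis$annotations
  } else {
    inp <- config$inputs
    read_many <- function(paths, dialect) {
      if (is.null(paths)) return(NULL)
      bind_rows(lapply(unlist(paths), read_source_table, dialect = dialect))
    }
    records <- bind_rows(
      read_many(inp$signalink, "signalink"),
      read_many(inp$directed_edgelist, "directed_edgelist"),
      read_many(inp$undirected_edgelist, "undirected_edgelist")
    )
    roster <- as_effector_roster(
      readr::read_tsv(inp$effectors, show_col_types = FALSE, progress = FALSE))
    reference <- read_symbol_list(inp$reference)
    annotations <- read_annotation_table(inp$annotations)
    reference_annotations <- annotations
  }

  std <- standardize_symbols(records, reference)
  network <- build_layered_network(
    roster, std$kept, max_depth = config$max_depth,
    keep_self_loops = config$keep_self_loops,
    undirected_at_depth = config$undirected_at_depth
  )

  counts <- layer_edge_counts(network)
  degrees <- degree_centrality(network, hub_cutoff = config$hub_cutoff)
  subgroups <- class_subgroup_decomposition(network)
  sharing <- pairwise_class_sharing(network, method = config$sharing_method)
  loops <- find_feedback_loops(network)
  compat_matrix <- if (!is.null(config$inputs$compat_matrix)) {
    read_compatibility_matrix(config$inputs$compat_matrix)
  } else {
    default_compatibility_matrix()
  }
  loc_flags <- localization_compatibility(network, annotations,
                                          matrix = compat_matrix,
                                          unknown_policy = config$unknown_policy)
  type_flags <- interaction_type_compatibility(network,
                                               unknown_policy = config$unknown_policy)
  compat <- compatibility_agreement(loc_flags, type_flags)
  weights <- class_weights(network)
  enrichment <- fisher_enrichment(weights, annotations, reference_annotations,
                                  vocabulary = "process15",
                                  rounding = config$rounding)
  by_layer_loc <- localization_by_layer(network, annotations)

  summary_values <- list(
    n_proteins = length(network_proteins(network)),
    n_downstream = length(unique(unlist(network$class_closure))),
    n_edges_total = counts$total,
    n_edges_by_layer = setNames(counts$by_layer$n_edges,
                                paste0("L", counts$by_layer$layer)),
    n_dropped_symbols = length(std$dropped_symbols),
    n_class_specific = attr(subgroups, "n_class_specific"),
    n_subgroups = nrow(subgroups),
    n_feedback_loops = attr(loops, "n_loops"),
    n_feedback_loops_per_target = attr(loops, "n_loops_per_target"),
    multilayer_effector_fraction = attr(loops, "multilayer_effector_fraction"),
    hub_fraction = attr(degrees, "hub_fraction"),
    nonhub_fraction = attr(degrees, "nonhub_fraction"),
    loc_compat_fraction = attr(loc_flags, "fraction"),
    loc_compat_fraction_class_expanded = attr(loc_flags, "fraction_class_expanded"),
    type_compat_fraction = attr(type_flags, "fraction"),
    type_compat_fraction_class_expanded = attr(type_flags, "fraction_class_expanded"),
    compat_agreement_fraction = compat$agreement_fraction,
    n_enriched_significant = sum(enrichment$significant_05 &
                                   enrichment$direction == "enriched")
  )
  options_used <- config[c("max_depth", "keep_self_loops", "undirected_at_depth",
                           "hub_cutoff", "unknown_policy", "sharing_method",
                           "rounding", "seed")]

  result <- structure(
    list(options = options_used,
         network = network,
         summary = summary_values,
         tables = list(normalized_class_ppi = normalized_class_ppi(network),
                       subgroups = subgroups,
                       degrees = degrees,
                       sharing = sharing,
                       enrichment = enrichment,
                       localization_by_layer = by_layer_loc),
         compat = compat,
         loops = loops,
         dropped_symbols = std$dropped_symbols),
    class = "ras_summary"
  )
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_network(network, file.path(config$output_dir, "network.tsv"), "tsv")
    jsonlite::write_json(c(list(options = options_used), summary_values),
                         file.path(config$output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' @export
print.ras_summary <- function(x, ...) {
  s <- x$summary
  cat("<ras_summary>\n")
  cat(sprintf("  proteins: %d (downstream: %d)\n", s$n_proteins, s$n_downstream))
  cat(sprintf("  layered edges: %d (%s)\n", s$n_edges_total,
              paste(sprintf("%s=%d", names(s$n_edges_by_layer), s$n_edges_by_layer),
                    collapse = ", ")))
  cat(sprintf("  class-specific proteins: %d in %d subgroups\n",
              s$n_class_specific, s$n_subgroups))
  cat(sprintf("  feedback loops: %d (%d per-target); multi-layer effectors: %.0f%%\n",
              s$n_feedback_loops, s$n_feedback_loops_per_target,
              100 * s$multilayer_effector_fraction))
  cat(sprintf("  non-hub fraction: %.0f%%; compat: loc %.0f%%, type %.0f%%, agreement %.0f%%\n",
              100 * s$nonhub_fraction, 100 * s$loc_compat_fraction,
              100 * s$type_compat_fraction, 100 * s$compat_agreement_fraction))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.ras_summary <- function(x, ...) {
  s <- x$summary
  tibble(n_proteins = s$n_proteins, n_downstream = s$n_downstream,
         n_edges = s$n_edges_total, n_class_specific = s$n_class_specific,
         n_subgroups = s$n_subgroups, n_feedback_loops = s$n_feedback_loops,
         nonhub_fraction = s$nonhub_fraction,
         loc_compat_fraction = s$loc_compat_fraction,
         type_compat_fraction = s$type_compat_fraction,
         agreement_fraction = s$compat_agreement_fraction)
}
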