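#' Build the layered oriented network downstream of the effector roster
#'
#' Starting from the layer-0 effectors, the network is expanded one layer at a
#' time up to `max_depth`: the targets of admitted edges whose source belongs
#' to layer k-1 form layer k. Directed records are always used first; the
#' undirected fallback (STRING/HuRI-style records, oriented from the expanding
#' protein to its partner) is admitted for an expanding protein only when that
#' protein has no directed record as a source — and, by default, only when
#' expanding the effectors themselves (layer 1), since deeper mining iterates
#' the directed databases. Set `undirected_at_depth = TRUE` to allow the
#' fallback at every layer.
#'
#' A target already belonging to an upper layer is kept and simply gains the
#' new layer membership — this re-entry is what makes effectors re-appear at
#' L2/L3 and what feedback detection relies on. Edges are de-duplicated per
#' `(source, target, layer)` with provenance, interaction-type and class-set
#' union; the same protein pair at different layers yields distinct edges.
#' Every edge inherits the effector-class set of the expansion path that
#' created it.
#'
#' @param roster Effector roster (see [as_effector_roster()];
#'   [ras_effector_roster()] is the default 43-effector/12-class roster).
#' @param sources Source-record tibble, already standardized against the
#'   reference symbol set (see [standardize_symbols()]).
#' @param max_depth Number of downstream layers (default 3).
#' @param keep_self_loops Keep records with `source == target` (default FALSE).
#' @param undirected_at_depth Allow the undirected fallback beyond layer 1.
#' @return A `layered_network` object: list with `edges` (tibble with columns
#'   `source`, `target`, `layer`, `directed_evidence`, `databases`,
#'   `interaction_types`, `classes` — the latter three semicolon-joined sets),
#'   `members` (tibble `protein`, `layer`, `classes`), `class_closure` (named
#'   list: class id to downstream protein set), `protein_classes`,
#'   `roster`, `max_depth`.
#' @examples
#' roster <- tibble::tibble(effector = "RAF1", class_id = 1)
#' src <- tibble::tibble(
#'   source = c("RAF1", "MAP2K1", "MAPK1"),
#'   target = c("MAP2K1", "MAPK1", "MYC"),
#'   directed = TRUE
#' )
#' net <- build_layered_network(roster, src)
#' glance(net)
#' @export
build_layered_network <- function(roster, sources, max_depth = 3,
                                  keep_self_loops = FALSE,
                                  undirected_at_depth = FALSE) {
  roster <- as_effector_roster(roster)
  sources <- as_source_records(sources)
  if (!is.numeric(max_depth) || max_depth < 1) {
    stop_config("max_depth must be a positive integer (got %s)", max_depth)
  }
  max_depth <- as.integer(max_depth)
  if (!keep_self_loops) {
    sources <- filter(sources, .data$source != .data$target)
  }

  directed <- filter(sources, .data$directed)
  undirected <- filter(sources, !.data$directed)
  # An undirected record can be expanded from either endpoint.
  und_sym <- bind_rows(
    undirected,
    rename(undirected, source = "target", target = "source")
  ) %>%
    distinct(.data$source, .data$target, .data$database,
             .data$interaction_type)
  has_directed_out <- unique(directed$source)

  frontier <- roster %>%
    group_by(protein = .data$effector) %>%
    summarise(classes = join_set(.data$class_id), .groups = "drop")

  edge_layers <- vector("list", max_depth)
  for (k in seq_len(max_depth)) {
    exp_dir <- inner_join(frontier, directed,
                          by = c(protein = "source"), relationship = "many-to-many") %>%
      mutate(directed_evidence = TRUE)
    use_und <- k == 1L || isTRUE(undirected_at_depth)
    if (use_und && nrow(und_sym) > 0) {
      exp_und <- frontier %>%
        filter(!(.data$protein %in% has_directed_out)) %>%
        inner_join(und_sym, by = c(protein = "source"),
                   relationship = "many-to-many") %>%
        mutate(directed_evidence = FALSE)
      expanded <- bind_rows(exp_dir, exp_und)
    } else {
      expanded <- exp_dir
    }
    if (nrow(expanded) == 0) {
      frontier <- frontier[0, ]
      next
    }
    layer_edges <- expanded %>%
      group_by(source = .data$protein, target = .data$target) %>%
      summarise(
        layer = k,
        directed_evidence = any(.data$directed_evidence),
        databases = join_set(.data$database),
        interaction_types = join_set(.data$interaction_type),
        classes = join_set(unlist(split_set(.data$classes))),
        .groups = "drop"
      )
    edge_layers[[k]] <- layer_edges
    frontier <- layer_edges %>%
      group_by(protein = .data$target) %>%
      summarise(classes = join_set(unlist(split_set(.data$classes))),
                .groups = "drop")
  }

  edges <- bind_rows(edge_layers)
  if (nrow(edges) == 0) {
    edges <- tibble(source = character(), target = character(),
                    layer = integer(), directed_evidence = logical(),
                    databases = character(), interaction_types = character(),
                    classes = character())
  }
  edges <- edges %>%
    mutate(layer = as.integer(.data$layer)) %>%
    select("source", "target", "layer", "directed_evidence",
           "databases", "interaction_types", "classes") %>%
    arrange(.data$layer, .data$source, .data$target)
  new_layered_network(edges, roster, max_depth)
}

# Construct the layered_network object, recomputing memberships and closures
# from the edge table (so a network read back from TSV is identical).
new_layered_network <- function(edges, roster, max_depth) {
  l0 <- roster %>%
    group_by(protein = .data$effector) %>%
    summarise(classes = join_set(.data$class_id), .groups = "drop") %>%
    mutate(layer = 0L)
  if (nrow(edges) > 0) {
    down <- edges %>%
      group_by(protein = .data$target, layer = .data$layer) %>%
      summarise(classes = join_set(unlist(split_set(.data$classes))),
                .groups = "drop")
  } else {
    down <- tibble(protein = character(), layer = integer(),
                   classes = character())
  }
  members <- bind_rows(l0[c("protein", "layer", "classes")], down) %>%
    arrange(.data$layer, .data$protein)

  if (nrow(down) > 0) {
    protein_classes <- down %>%
      group_by(protein = .data$protein) %>%
      summarise(classes = join_set(unlist(split_set(.data$classes))),
                .groups = "drop")
  } else {
    protein_classes <- tibble(protein = character(), classes = character())
  }
  class_ids <- sort(unique(roster$class_id))
  class_closure <- lapply(class_ids, function(cid) {
    protein_classes$protein[set_contains(protein_classes$classes, cid)]
  })
  names(class_closure) <- as.character(class_ids)

  structure(
    list(edges = edges, members = members, protein_classes = protein_classes,
         class_closure = class_closure, roster = roster,
         max_depth = as.integer(max_depth)),
    class = "layered_network"
  )
}

#' @export
print.layered_network <- function(x, ...) {
  cat(sprintf("<layered_network> %d proteins, %d layered edges, depth %d\n",
              n_distinct(c(x$edges$source, x$edges$target, x$roster$effector)),
              nrow(x$edges), x$max_depth))
  counts <- layer_edge_counts(x)
  cat(paste(sprintf("  L%d: %d edges", counts$by_layer$layer,
                    counts$by_layer$n_edges), collapse = "\n"), "\n")
  invisible(x)
}

#' Proteins of the network
#'
#' @param network A `layered_network`.
#' @param layers Optional integer vector restricting to these layer
#'   memberships.
#' @return Character vector of protein symbols.
#' @export
network_proteins <- function(network, layers = NULL) {
  m <- network$members
  if (!is.null(layers)) m <- m[m$layer %in% layers, , drop = FALSE]
  sort(unique(m$protein))
}

# One row per protein with joined layer/class memberships (graphml export).
network_proteins_table <- function(network) {
  network$members %>%
    group_by(protein = .data$protein) %>%
    summarise(layers = join_set(.data$layer),
              classes = join_set(unlist(split_set(.data$classes))),
              .groups = "drop") %>%
    mutate(is_effector = .data$protein %in% network$roster$effector)
}

#' Per-layer edge counts
#'
#' Counts distinct `(source, target, layer)` edge keys per layer.
#'
#' @param network A `layered_network`.
#' @return A list with `by_layer` (tibble `layer`, `n_edges`, zero-filled for
#'   every layer up to `max_depth`) and `total`.
#' @export
layer_edge_counts <- function(network) {
  stopifnot(inherits(network, "layered_network"))
  by_layer <- tibble(layer = seq_len(network$max_depth)) %>%
    left_join(count(network$edges, .data$layer, name = "n_edges"),
              by = "layer") %>%
    mutate(n_edges = as.integer(ifelse(is.na(.data$n_edges), 0L, .data$n_edges)))
  list(by_layer = by_layer, total = sum(by_layer$n_edges))
}

#' Per-effector-class normalized downstream PPI counts
#'
#' For each effector class, the number of layered edges reached through that
#' class divided by the number of effectors in the class — the per-effector
#' downstream PPI load, comparable across classes of different sizes.
#'
#' @param network A `layered_network`.
#' @return Tibble with `class_id`, `class_name`, `n_effectors`, `n_edges`,
#'   `normalized`.
#' @export
normalized_class_ppi <- function(network) {
  stopifnot(inherits(network, "layered_network"))
  roster <- network$roster
  classes <- roster %>%
    group_by(class_id = .data$class_id, class_name = .data$class_name) %>%
    summarise(n_effectors = n(), .groups = "drop")
  edge_classes <- split_int_set(network$edges$classes)
  classes$n_edges <- vapply(classes$class_id, function(cid) {
    sum(vapply(edge_classes, function(s) cid %in% s, logical(1)))
  }, numeric(1))
  classes %>%
    mutate(normalized = .data$n_edges / .data$n_effectors) %>%
    arrange(.data$class_id)
}

#' @rdname build_layered_network
#' @param x A `layered_network`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.layered_network <- function(x, ...) {
  x$edges
}

#' @rdname build_layered_network
#' @exportS3Method generics::glance
glance.layered_network <- function(x, ...) {
  counts <- layer_edge_counts(x)
  tibble(
    n_proteins = length(network_proteins(x)),
    n_downstream = length(unique(unlist(x$class_closure))),
    n_effectors = nrow(x$roster),
    n_classes = n_distinct(x$roster$class_id),
    max_depth = x$max_depth,
    n_edges = counts$total
  )
}

#' @rdname build_layered_network
#' @param object A `layered_network`.
#' @exportS3Method ggplot2::autoplot
autoplot.layered_network <- function(object, ...) {
  df <- layer_edge_counts(object)$by_layer
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$layer), y = .data$n_edges)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "layer", y = "binary PPIs",
                  title = "Layered edges by network depth") +
    ggplot2::theme_minimal()
}
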