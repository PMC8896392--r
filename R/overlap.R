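#' Overlap between the network and an external protein list
#'
#' Compares network membership (union of layer members L0 up to the network
#' depth) against an external list, e.g. proteins detected in AP-MS or BioID
#' experiments or exported from a complex database. The per-layer distribution
#' of the overlapping proteins follows the multi-counting convention: a
#' protein in several layers contributes to each layer's percentage, so the
#' percentages may sum to more than 100.
#'
#' @param network A `layered_network`.
#' @param proteins Character vector of protein symbols, standardized against
#'   the same reference as the network.
#' @return An `overlap_report`: list with `list_name`, `n_list`, `n_overlap`,
#'   `fraction`, `layer_distribution` (tibble `layer`, `n`, `percent` of the
#'   overlap set), `effectors_found`, `overlap` (the intersecting symbols).
#' @param list_name Label stored in the report.
#' @export
overlap_with_list <- function(network, proteins, list_name = "external") {
  stopifnot(inherits(network, "layered_network"))
  proteins <- unique(normalize_symbols(proteins))
  net_proteins <- network_proteins(network)
  overlap <- intersect(proteins, net_proteins)
  n_list <- length(proteins)
  layers <- seq(0L, network$max_depth)
  dist <- tibble(layer = layers) %>%
    mutate(n = vapply(.data$layer, function(k) {
      length(intersect(overlap, network$members$protein[network$members$layer == k]))
    }, integer(1)),
    percent = if (length(overlap) > 0) 100 * .data$n / length(overlap) else NA_real_)
  structure(
    list(list_name = list_name,
         n_list = n_list,
         n_overlap = length(overlap),
         fraction = if (n_list > 0) length(overlap) / n_list else NA_real_,
         layer_distribution = dist,
         effectors_found = sort(intersect(proteins, network$roster$effector)),
         overlap = sort(overlap)),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> '%s': %d/%d proteins in network (%.1f%%)\n",
              x$list_name, x$n_overlap, x$n_list, 100 * x$fraction))
  cat(sprintf("  effectors found: %d\n", length(x$effectors_found)))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.overlap_report <- function(x, ...) {
  tibble(list_name = x$list_name, n_list = x$n_list, n_overlap = x$n_overlap,
         fraction = x$fraction,
         n_effectors_found = length(x$effectors_found))
}

#' Merge several external protein lists keeping provenance
#'
#' Utility for the "identified in at least one experiment" convention: the
#' union of the lists, with the experiments each protein came from.
#'
#' @param lists Named list of character vectors.
#' @return Tibble with `protein` and `sources` (semicolon-joined list names).
#' @export
merge_protein_lists <- function(lists) {
  stopifnot(is.list(lists), !is.null(names(lists)), all(nzchar(names(lists))))
  purrr::imap_dfr(lists, function(x, nm) {
    tibble(protein = unique(normalize_symbols(x)), list_name = nm)
  }) %>%
    group_by(protein = .data$protein) %>%
    summarise(sources = join_set(.data$list_name), .groups = "drop") %>%
    arrange(.data$protein)
}
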