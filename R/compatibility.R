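#' Localization compatibility matrices
#'
#' A compatibility matrix is a reflexive, symmetric boolean relation over the
#' 19 merged localization classes declaring which compartment pairs can
#' plausibly host a physical interaction (e.g. cytosol with Golgi apparatus,
#' cell-cell junctions with microfilaments). The default matrix shipped here
#' is a documented, editable starting point: every class is compatible with
#' itself; the cytosol is compatible with the membrane-bounded compartments
#' and cytoskeletal classes it exchanges proteins with; the extracellular
#' space with the cell membrane and ECM/junction classes; the nucleus with the
#' cytosol. For exact replication of a published analysis, supply the matrix
#' used there via [read_compatibility_matrix()].
#'
#' @return A named logical matrix over [localization_classes()].
#' @export
default_compatibility_matrix <- function() {
  classes <- localization_classes()
  pairs <- list(
    c("Cytosol", "Ribosomes"),
    c("Cytosol", "Nucleus"),
    c("Cytosol", "Cell membrane"),
    c("Cytosol", "Microfilaments"),
    c("Cytosol", "Mitochondria"),
    c("Cytosol", "Endoplasmic reticulum"),
    c("Cytosol", "Golgi apparatus"),
    c("Cytosol", "Proteasome"),
    c("Cytosol", "Other vesicles"),
    c("Cytosol", "Cilia, centrosome"),
    c("Cytosol", "Lysosomes"),
    c("Cytosol", "Peroxisomes"),
    c("Cytosol", "Focal adhesion sites"),
    c("Cytosol", "Cell cortex"),
    c("Extracellular", "Cell membrane"),
    c("Extracellular", "Cell-ECM junctions"),
    c("Extracellular", "Cell-cell junctions"),
    c("Cell membrane", "Cell cortex"),
    c("Cell membrane", "Focal adhesion sites"),
    c("Cell membrane", "Cell-cell junctions"),
    c("Cell membrane", "Cell-ECM junctions"),
    c("Cell membrane", "Microfilaments"),
    c("Microfilaments", "Cell-cell junctions"),
    c("Microfilaments", "Focal adhesion sites"),
    c("Microfilaments", "Cell cortex"),
    c("Microfilaments", "Cilia, centrosome"),
    c("Endoplasmic reticulum", "Golgi apparatus"),
    c("Golgi apparatus", "Other vesicles"),
    c("Other vesicles", "Lysosomes")
  )
  m <- diag(TRUE, length(classes))
  dimnames(m) <- list(classes, classes)
  for (p in pairs) {
    m[p[1], p[2]] <- TRUE
    m[p[2], p[1]] <- TRUE
  }
  m
}

#' @rdname default_compatibility_matrix
#' @param m A square 0/1 or logical matrix with identical row/column names.
#' @export
as_compatibility_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || is.null(rownames(m)) ||
      !identical(rownames(m), colnames(m))) {
    stop_config("compatibility matrix must be square with matching row/column names")
  }
  storage.mode(m) <- "logical"
  if (any(is.na(m))) stop_config("compatibility matrix contains NA entries")
  if (!all(diag(m))) stop_config("compatibility matrix must be reflexive")
  if (!isTRUE(all(m == t(m)))) stop_config("compatibility matrix must be symmetric")
  m
}

#' @rdname default_compatibility_matrix
#' @param path CSV file: first column the class names, remaining columns 0/1
#'   with class-name headers.
#' @export
read_compatibility_matrix <- function(path) {
  if (!file.exists(path)) stop_format("compatibility matrix not found: %s", path)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  as_compatibility_matrix(m)
}

#' @rdname default_compatibility_matrix
#' @export
write_compatibility_matrix <- function(m, path) {
  m <- as_compatibility_matrix(m)
  df <- as_tibble(m * 1L)
  df <- tibble::add_column(df, class = rownames(m), .before = 1)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

# Look up the main localization of each symbol; proteins without an
# annotation row fall back to "UNKNOWN".
lookup_localization <- function(symbols, annotations) {
  loc <- setNames(annotations$localization, annotations$symbol)
  out <- unname(loc[symbols])
  out[is.na(out)] <- "UNKNOWN"
  out
}

#' Score edges for subcellular-localization compatibility
#'
#' An edge is localization-compatible when the compatibility matrix holds for
#' the main localizations of its two endpoints. Proteins whose localization is
#' `"UNKNOWN"` (or missing from the annotation table) are handled per
#' `unknown_policy`: `"exclude"` (default) removes the edge from the
#' denominator, `"compatible"`/`"incompatible"` force the flag.
#'
#' @param network A `layered_network`.
#' @param annotations Annotation table (see [as_annotation_table()]).
#' @param matrix Compatibility matrix (default [default_compatibility_matrix()]).
#' @param unknown_policy One of `"exclude"`, `"compatible"`, `"incompatible"`.
#' @return The edge tibble with added columns `loc_source`, `loc_target`,
#'   `loc_compatible` (logical, `NA` when excluded). Attributes: `fraction`
#'   (compatible among evaluated edges), `fraction_class_expanded` (same, with
#'   each edge counted once per effector class reaching it), `n_evaluated`.
#' @export
localization_compatibility <- function(network, annotations,
                                       matrix = default_compatibility_matrix(),
                                       unknown_policy = c("exclude", "compatible",
                                                          "incompatible")) {
  stopifnot(inherits(network, "layered_network"))
  unknown_policy <- arg_match(unknown_policy)
  matrix <- as_compatibility_matrix(matrix)
  edges <- network$edges
  loc_s <- lookup_localization(edges$source, annotations)
  loc_t <- lookup_localization(edges$target, annotations)
  known_classes <- setdiff(rownames(matrix), "UNKNOWN")
  unknown <- !(loc_s %in% known_classes) | !(loc_t %in% known_classes)
  flag <- rep(NA, nrow(edges))
  if (any(!unknown)) {
    flag[!unknown] <- matrix[cbind(loc_s[!unknown], loc_t[!unknown])]
  }
  if (unknown_policy == "compatible") flag[unknown] <- TRUE
  if (unknown_policy == "incompatible") flag[unknown] <- FALSE
  out <- mutate(edges, loc_source = loc_s, loc_target = loc_t,
                loc_compatible = flag)
  n_classes_per_edge <- lengths(split_set(edges$classes))
  attr(out, "fraction") <- mean(flag, na.rm = TRUE)
  attr(out, "fraction_class_expanded") <-
    sum(n_classes_per_edge[which(flag)], na.rm = TRUE) /
    sum(n_classes_per_edge[!is.na(flag)])
  attr(out, "n_evaluated") <- sum(!is.na(flag))
  out
}

#' Score edges for interaction-type (directness) compatibility
#'
#' SignaLink-style records carry one of six interaction-type categories; the
#' first four ("Interaction between pathway members", "Directed
#' protein-protein interaction", "Post-translational modification",
#' "Transcriptional regulation") describe two proteins in direct physical
#' contact, so edges carrying at least one such type are type-compatible.
#' Edges whose only type is `"unknown"` (non-SignaLink provenance) are handled
#' per `unknown_policy`, default excluded from the denominator.
#'
#' @inheritParams localization_compatibility
#' @return Edge tibble with added `type_compatible` column; same attributes
#'   as [localization_compatibility()].
#' @export
interaction_type_compatibility <- function(network,
                                           unknown_policy = c("exclude",
                                                              "compatible",
                                                              "incompatible")) {
  stopifnot(inherits(network, "layered_network"))
  unknown_policy <- arg_match(unknown_policy)
  edges <- network$edges
  type_sets <- split_set(edges$interaction_types)
  admissible <- c(signalink_interaction_types(), "unknown")
  bad <- setdiff(unique(unlist(type_sets)), admissible)
  if (length(bad) > 0) {
    stop_format("unrecognized interaction-type categor%s: %s (admissible: %s)",
                if (length(bad) > 1) "ies" else "y",
                paste(bad, collapse = ", "), paste(admissible, collapse = "; "))
  }
  known <- lapply(type_sets, setdiff, y = "unknown")
  all_unknown <- lengths(known) == 0
  flag <- rep(NA, nrow(edges))
  flag[!all_unknown] <- vapply(known[!all_unknown], function(s) {
    any(s %in% direct_interaction_types())
  }, logical(1))
  if (unknown_policy == "compatible") flag[all_unknown] <- TRUE
  if (unknown_policy == "incompatible") flag[all_unknown] <- FALSE
  out <- mutate(edges, type_compatible = flag)
  n_classes_per_edge <- lengths(split_set(edges$classes))
  attr(out, "fraction") <- mean(flag, na.rm = TRUE)
  attr(out, "fraction_class_expanded") <-
    sum(n_classes_per_edge[which(flag)], na.rm = TRUE) /
    sum(n_classes_per_edge[!is.na(flag)])
  attr(out, "n_evaluated") <- sum(!is.na(flag))
  out
}

#' Agreement between the two compatibility definitions
#'
#' Cross-tabulates the localization-based and interaction-type-based
#' compatibility flags over the edges evaluated under both definitions. The
#' two definitions rest on independent annotations, so their agreement is a
#' validation signal for the reconstructed network.
#'
#' @param loc_flags Result of [localization_compatibility()].
#' @param type_flags Result of [interaction_type_compatibility()] on the same
#'   network.
#' @return A `compat_report`: list with `n_edges`, `loc_compatible` /
#'   `type_compatible` (count and fraction over each definition's evaluated
#'   edges), `agreement_table` (2x2 counts, localization x type),
#'   `agreement_fraction` (both-true plus both-false over jointly evaluated
#'   edges), `n_joint`.
#' @export
compatibility_agreement <- function(loc_flags, type_flags) {
  if (nrow(loc_flags) != nrow(type_flags)) {
    stop_config("flag tables must cover the same edge set")
  }
  l <- loc_flags$loc_compatible
  t_ <- type_flags$type_compatible
  joint <- !is.na(l) & !is.na(t_)
  tab <- matrix(0L, 2, 2,
                dimnames = list(loc = c("compatible", "incompatible"),
                                type = c("compatible", "incompatible")))
  if (any(joint)) {
    tab <- table(factor(ifelse(l[joint], "compatible", "incompatible"),
                        levels = c("compatible", "incompatible")),
                 factor(ifelse(t_[joint], "compatible", "incompatible"),
                        levels = c("compatible", "incompatible")))
    tab <- unclass(tab)
    names(dimnames(tab)) <- c("loc", "type")
  }
  agreement <- if (sum(tab) > 0) (tab[1, 1] + tab[2, 2]) / sum(tab) else NA_real_
  structure(
    list(n_edges = nrow(loc_flags),
         loc_compatible = list(n = sum(l, na.rm = TRUE),
                               fraction = attr(loc_flags, "fraction")),
         type_compatible = list(n = sum(t_, na.rm = TRUE),
                                fraction = attr(type_flags, "fraction")),
         agreement_table = tab,
         agreement_fraction = agreement,
         n_joint = sum(joint)),
    class = "compat_report"
  )
}

#' @export
print.compat_report <- function(x, ...) {
  cat(sprintf("<compat_report> %d edges\n", x$n_edges))
  cat(sprintf("  localization-compatible: %d (%.1f%%)\n",
              x$loc_compatible$n, 100 * x$loc_compatible$fraction))
  cat(sprintf("  type-compatible:         %d (%.1f%%)\n",
              x$type_compatible$n, 100 * x$type_compatible$fraction))
  cat(sprintf("  agreement: %.1f%% of %d jointly evaluated edges\n",
              100 * x$agreement_fraction, x$n_joint))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.compat_report <- function(x, ...) {
  tibble(n_edges = x$n_edges,
         loc_fraction = x$loc_compatible$fraction,
         type_fraction = x$type_compatible$fraction,
         agreement_fraction = x$agreement_fraction,
         n_joint = x$n_joint)
}

#' Localization counts by layer and by function
#'
#' `localization_by_layer()` counts network proteins per (layer, localization)
#' cell; a protein belonging to several layers contributes one count per layer
#' membership. `localization_by_function()` counts unique network proteins per
#' (localization, process class) cell. Proteins without an annotation row are
#' counted under `"UNKNOWN"`.
#'
#' @param network A `layered_network`.
#' @param annotations Annotation table.
#' @return A tibble of counts (`layer`/`localization`/`n`, or
#'   `localization`/`process15`/`n`).
#' @export
localization_by_layer <- function(network, annotations) {
  stopifnot(inherits(network, "layered_network"))
  network$members %>%
    mutate(localization = lookup_localization(.data$protein, annotations)) %>%
    count(.data$layer, .data$localization, name = "n")
}

#' @rdname localization_by_layer
#' @export
localization_by_function <- function(network, annotations) {
  stopifnot(inherits(network, "layered_network"))
  proc <- setNames(annotations$process15, annotations$symbol)
  tibble(protein = network_proteins(network)) %>%
    mutate(localization = lookup_localization(.data$protein, annotations),
           process15 = unname(proc[.data$protein]),
           process15 = ifelse(is.na(.data$process15), "Unknown", .data$process15)) %>%
    count(.data$localization, .data$process15, name = "n")
}

#' @rdname localization_by_layer
#' @param counts Result of [localization_by_layer()].
#' @export
plot_localization_by_layer <- function(counts) {
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = factor(.data$layer), y = .data$n,
                               fill = .data$localization)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::labs(x = "layer", y = "fraction of proteins",
                  fill = "main localization") +
    ggplot2::theme_minimal()
}
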