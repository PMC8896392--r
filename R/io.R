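#' Read a PPI source table in one of three dialects
#'
#' Pathway and PPI database exports come in three shapes: SignaLink-style
#' tables with an explicit directionality label and an interaction-type
#' category; directed binary edge lists derived from pathway diagrams
#' (KEGG Pathway / WikiPathways style); and undirected edge lists
#' (STRING / HuRI style). All three are normalized into one record schema.
#'
#' For the `signalink` dialect only rows labeled `"Directed"` or
#' `"Predicted as directed"` are kept (case-insensitive); rows failing the
#' filter are dropped and counted in the `dropped_direction` attribute of the
#' result. Undirected-dialect rows yield `directed = FALSE` records whose
#' orientation is decided later, at network-expansion time. Duplicate rows
#' (same endpoints, direction and type) are de-duplicated at read time.
#'
#' @param path Path to a TSV or CSV file (delimiter sniffed from the header
#'   line). Required columns by dialect: `signalink` —
#'   `source_name`, `target_name`, `directness_label`, `layer_category`;
#'   `directed_edgelist` — `source`, `target`;
#'   `undirected_edgelist` — `protein_a`, `protein_b`. Extra columns ignored.
#' @param dialect One of `"signalink"`, `"directed_edgelist"`,
#'   `"undirected_edgelist"`.
#' @param database Provenance tag stored on every record; defaults to the
#'   file name without extension.
#' @return A tibble of source records with columns `source`, `target`,
#'   `directed`, `database`, `interaction_type` (`"unknown"` outside the
#'   signalink dialect), carrying a `dropped_direction` attribute with the
#'   number of signalink rows removed by the directionality filter.
#' @export
read_source_table <- function(path,
                              dialect = c("signalink", "directed_edgelist",
                                          "undirected_edgelist"),
                              database = NULL) {
  dialect <- arg_match(dialect)
  if (!file.exists(path)) stop_format("source table not found: %s", path)
  if (is.null(database)) {
    database <- sub("\\.[^.]*$", "", basename(path))
  }
  header <- readLines(path, n = 1L, warn = FALSE)
  delim <- if (grepl("\t", header)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  records <- source_records_from_table(df, dialect, database)
  if (nrow(records) == 0) {
    warn(sprintf("source table %s produced no records", path))
  }
  records
}

# Dialect contract shared by the file reader and the synthetic generator.
source_records_from_table <- function(df, dialect, database) {
  dropped_direction <- 0L
  if (dialect == "signalink") {
    require_columns(df, c("source_name", "target_name", "directness_label",
                          "layer_category"), "signalink table")
    keep <- tolower(trimws(df$directness_label)) %in% admitted_directness_labels()
    dropped_direction <- sum(!keep)
    df <- df[keep, , drop = FALSE]
    out <- tibble(
      source = normalize_symbols(df$source_name),
      target = normalize_symbols(df$target_name),
      directed = TRUE,
      database = database,
      interaction_type = trimws(df$layer_category)
    )
  } else if (dialect == "directed_edgelist") {
    require_columns(df, c("source", "target"), "directed edge list")
    out <- tibble(
      source = normalize_symbols(df$source),
      target = normalize_symbols(df$target),
      directed = TRUE,
      database = database,
      interaction_type = "unknown"
    )
  } else {
    require_columns(df, c("protein_a", "protein_b"), "undirected edge list")
    out <- tibble(
      source = normalize_symbols(df$protein_a),
      target = normalize_symbols(df$protein_b),
      directed = FALSE,
      database = database,
      interaction_type = "unknown"
    )
  }
  out <- distinct(out, .data$source, .data$target, .data$directed,
                  .data$interaction_type, .keep_all = TRUE)
  attr(out, "dropped_direction") <- dropped_direction
  out
}

#' Validate an in-memory source-record table
#'
#' @param records A data frame with columns `source`, `target`, `directed`,
#'   and optionally `database` and `interaction_type`.
#' @return A tibble in the canonical source-record schema.
#' @export
as_source_records <- function(records) {
  require_columns(records, c("source", "target", "directed"), "source records")
  records <- as_tibble(records)
  if (!"database" %in% names(records)) records$database <- "user"
  if (!"interaction_type" %in% names(records)) records$interaction_type <- "unknown"
  records$source <- normalize_symbols(records$source)
  records$target <- normalize_symbols(records$target)
  records$directed <- as.logical(records$directed)
  records[c("source", "target", "directed", "database", "interaction_type")]
}

#' Standardize record symbols against a reference symbol set
#'
#' Both endpoints of every record are matched (exactly, after upper-casing)
#' against the reference set of official symbols. A record is kept iff both
#' endpoints match; records touching an unmatched symbol are removed together
#' with the symbol. No alias or fuzzy matching is attempted — unmatched names
#' are reported, mirroring how curated compilations discard them.
#'
#' @param records A source-record tibble (see [as_source_records()]).
#' @param reference Character vector of official gene symbols.
#' @return A list with elements `kept` (record tibble), `dropped_symbols`
#'   (character), `dropped_records` (record tibble).
#' @export
standardize_symbols <- function(records, reference) {
  if (length(reference) == 0) stop_config("reference symbol set is empty")
  records <- as_source_records(records)
  reference <- unique(normalize_symbols(reference))
  ok <- records$source %in% reference & records$target %in% reference
  dropped <- records[!ok, , drop = FALSE]
  dropped_symbols <- sort(unique(c(
    dropped$source[!dropped$source %in% reference],
    dropped$target[!dropped$target %in% reference]
  )))
  list(kept = records[ok, , drop = FALSE],
       dropped_symbols = dropped_symbols,
       dropped_records = dropped)
}

#' Read a reference symbol list or plain protein list
#'
#' One symbol per line; blank lines and `#` comments ignored.
#'
#' @param path File path.
#' @return Character vector of normalized unique symbols.
#' @export
read_symbol_list <- function(path) {
  if (!file.exists(path)) stop_format("symbol list not found: %s", path)
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(normalize_symbols(x))
}

#' Read a per-protein annotation table
#'
#' @param path TSV/CSV with columns `symbol`, `localization`, `process15`,
#'   and optionally `process_full`, `tissue_class`.
#' @param loc_vocab,proc_vocab Closed vocabularies the labels must belong to;
#'   defaults to the built-in 19 localization / 15 process classes.
#' @return A tibble with one row per protein (exactly one main localization).
#' @export
read_annotation_table <- function(path,
                                  loc_vocab = localization_classes(),
                                  proc_vocab = process_classes()) {
  if (!file.exists(path)) stop_format("annotation table not found: %s", path)
  header <- readLines(path, n = 1L, warn = FALSE)
  delim <- if (grepl("\t", header)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  as_annotation_table(df, loc_vocab, proc_vocab)
}

#' @rdname read_annotation_table
#' @param annotations In-memory data frame in the same schema.
#' @export
as_annotation_table <- function(annotations,
                                loc_vocab = localization_classes(),
                                proc_vocab = process_classes()) {
  require_columns(annotations, c("symbol", "localization", "process15"),
                  "annotation table")
  ann <- as_tibble(annotations)
  ann$symbol <- normalize_symbols(ann$symbol)
  if (anyDuplicated(ann$symbol)) {
    stop_format("annotation table assigns multiple rows to: %s",
                join_set(ann$symbol[duplicated(ann$symbol)]))
  }
  bad_loc <- setdiff(unique(ann$localization), loc_vocab)
  if (length(bad_loc) > 0) {
    stop_format("unrecognized localization class(es): %s (admissible: %s)",
                paste(bad_loc, collapse = ", "), paste(loc_vocab, collapse = "; "))
  }
  bad_proc <- setdiff(unique(ann$process15), proc_vocab)
  if (length(bad_proc) > 0) {
    stop_format("unrecognized process class(es): %s", paste(bad_proc, collapse = ", "))
  }
  ann
}

#' Write a layered network to disk
#'
#' `tsv` writes one row per layered edge with every field and round-trips
#' exactly through [read_network_tsv()]. `sif` collapses each edge to a
#' `source  L<layer>  target` triple. `graphml` (via igraph) carries the
#' layer memberships and class memberships as node attributes (`layers`,
#' `classes`, semicolon-joined) and the per-edge fields as edge attributes.
#'
#' @param network A `layered_network` (see [build_layered_network()]).
#' @param path Output file path.
#' @param format One of `"tsv"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("tsv", "sif", "graphml")) {
  format <- arg_match(format)
  stopifnot(inherits(network, "layered_network"))
  edges <- network$edges
  if (format == "tsv") {
    readr::write_tsv(edges, path, progress = FALSE)
  } else if (format == "sif") {
    lines <- sprintf("%s\tL%d\t%s", edges$source, edges$layer, edges$target)
    writeLines(lines, path)
  } else {
    nodes <- network_proteins_table(network)
    g <- igraph::graph_from_data_frame(
      d = data.frame(from = edges$source, to = edges$target,
                     layer = edges$layer,
                     directed_evidence = edges$directed_evidence,
                     databases = edges$databases,
                     interaction_types = edges$interaction_types,
                     classes = edges$classes,
                     stringsAsFactors = FALSE),
      directed = TRUE,
      vertices = data.frame(name = nodes$protein,
                            layers = nodes$layers,
                            classes = nodes$classes,
                            is_effector = nodes$is_effector,
                            stringsAsFactors = FALSE)
    )
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a layered-network edge TSV back into a network object
#'
#' Layer memberships and class closures are recomputed from the stored edge
#' fields. If no roster is supplied, layer-0 membership is inferred from the
#' sources of layer-1 edges.
#'
#' @param path Path to a TSV written by [write_network()] (or a deposited
#'   layered-edge table exported to the same columns).
#' @param roster Optional effector roster (see [as_effector_roster()]).
#' @param max_depth Network depth; defaults to the maximum stored layer.
#' @return A `layered_network`.
#' @export
read_network_tsv <- function(path, roster = NULL, max_depth = NULL) {
  if (!file.exists(path)) stop_format("network TSV not found: %s", path)
  edges <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(
                             source = readr::col_character(),
                             target = readr::col_character(),
                             layer = readr::col_integer(),
                             directed_evidence = readr::col_logical(),
                             databases = readr::col_character(),
                             interaction_types = readr::col_character(),
                             classes = readr::col_character()
                           ))
  if (is.null(roster)) {
    l1 <- edges[edges$layer == 1L, , drop = FALSE]
    roster <- distinct(tibble(
      effector = l1$source,
      class_id = vapply(split_int_set(l1$classes), min, integer(1))
    ))
  }
  roster <- as_effector_roster(roster)
  if (is.null(max_depth)) max_depth <- max(edges$layer, 0L)
  new_layered_network(edges, roster, as.integer(max_depth))
}
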