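# Shared fixtures built in code.

tiny_roster <- function() {
  tibble::tibble(effector = c("RAF1", "PIK3CA"), class_id = c(1L, 2L),
                 class_name = c("RAF-MEK-ERK signaling", "PI3K-AKT signaling"))
}

# The canonical four-protein signaling chain used in the worked examples.
raf_chain_records <- function() {
  rasnet::as_source_records(tibble::tibble(
    source = c("RAF1", "MAP2K1", "MAPK1"),
    target = c("MAP2K1", "MAPK1", "MYC"),
    directed = TRUE,
    database = "signalink",
    interaction_type = "Post-translational modification"
  ))
}

# A small synthetic configuration that keeps per-test generation cheap while
# exercising every planted structure.
small_synth_config <- function(seed, ...) {
  args <- list(
    seed = seed,
    n_reference = 3000L,
    branching = c(4, 3, 3),
    branch_sdlog = c(0.5, 0.5, 0.8),
    new_protein_prob = c(0.7, 0.85, 0.3),
    n_planted_feedbacks = 5L,
    n_planted_hubs = 2L,
    hub_degree = 15L,
    n_class_specific = 1L,
    n_effector_reentries = 6L,
    n_decoy_undirected = 20L,
    n_decoy_signalink = 10L
  )
  do.call(rasnet::synthetic_config, utils::modifyList(args, list(...)))
}

# Rebuild a network from a synthesis object the way a user would: read the
# three dialect tables back through the io layer and run the builder.
rebuild_from_tables <- function(synthesis, ...) {
  records <- dplyr::bind_rows(
    rasnet:::source_records_from_table(synthesis$tables$signalink,
                                       "signalink", "signalink"),
    rasnet:::source_records_from_table(synthesis$tables$directed_edgelist,
                                       "directed_edgelist", "kegg"),
    rasnet:::source_records_from_table(synthesis$tables$undirected_edgelist,
                                       "undirected_edgelist", "string")
  )
  std <- rasnet::standardize_symbols(records, synthesis$reference)
  rasnet::build_layered_network(synthesis$config$roster, std$kept, ...)
}

write_temp_table <- function(df, ext = "tsv") {
  path <- tempfile(fileext = paste0(".", ext))
  if (ext == "tsv") readr::write_tsv(df, path, progress = FALSE)
  else readr::write_csv(df, path, progress = FALSE)
  path
}
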