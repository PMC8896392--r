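#' Configuration for the synthetic source-table generator
#'
#' The generator emulates the data situation the reconstruction pipeline is
#' designed for: a reference proteome; a SignaLink-style directed table with
#' directionality labels and interaction-type categories; a KEGG/WikiPathways
#' style directed edge list partially overlapping it; a STRING/HuRI style
#' undirected edge list covering the effectors that have no directed pathway
#' records; and a per-protein annotation table. Known structures are planted
#' and recorded so every downstream stage can be validated against ground
#' truth. The defaults reproduce the study conditions of the reconstruction
#' this package implements: 43 effectors in 12 classes, a 19,300-symbol
#' reference, per-layer mean branching sized to land near 2300 proteins and
#' 19,000 layered edges, 28/43 effectors with undirected-only evidence, 2
#' isolated effectors, 15 effectors re-appearing at deeper layers, and 206
#' planted feedback back-edges.
#'
#' @param seed Integer seed; fully determines all outputs.
#' @param n_reference Size of the reference symbol set (effectors included).
#' @param roster Effector roster (default [ras_effector_roster()]).
#' @param branching Mean out-degree per expanded protein for layers 1..3.
#' @param branch_sdlog Dispersion of the out-degree draw per layer: 0 gives a
#'   Poisson draw at the branching mean, a positive value a rounded lognormal
#'   with that log-sd (mean preserved) — the skewed out-degrees characteristic
#'   of pathway-database mining, where few proteins have very many curated
#'   targets.
#' @param new_protein_prob Probability that an expansion target is a fresh
#'   protein per layer. At layer 1 the alternative is a layer-1 protein
#'   already targeted by another effector (cross-class sharing); at layers
#'   2-3 it is re-entry of an existing layer>=2 protein.
#' @param undirected_fraction Fraction of effectors whose layer-1 evidence is
#'   undirected-only (STRING/HuRI style).
#' @param n_isolated Number of effectors with no records in any source.
#' @param n_effector_reentries Number of effectors re-entering at layer 2
#'   (targets of an L1 protein), emulating multi-layer effectors.
#' @param n_planted_feedbacks Number of planted feedback back-edges (each from
#'   a protein occupying layers \{2,3\} onto an L1 protein, layer gap 2).
#' @param n_planted_hubs,hub_degree Planted hubs: layer-2 proteins given at
#'   least `hub_degree` distinct out-edges.
#' @param n_class_specific Planted class-specific proteins per effector class
#'   (reachable from exactly that class).
#' @param enrichment_effect List `(class_id, category, odds_multiplier)`: the
#'   annotation odds of `category` are multiplied for proteins downstream of
#'   `class_id`.
#' @param localization_mix Named list (`"0"`..`"3"`) of probability vectors
#'   over [localization_classes()] used to draw each protein's main
#'   localization from its first layer; the default plants the
#'   extracellular-to-L1 / cytosol-to-L2 / nucleus-to-L3 gradient.
#' @param process_probs_reference,process_probs_network Probability vectors
#'   over [process_classes()] for reference resp. network proteins (the
#'   network baseline is signaling-heavy and metabolism-poor).
#' @param type_probs Probabilities of the six SignaLink interaction-type
#'   categories on directed records.
#' @param preferential Use preferential-attachment re-entry sampling (degree
#'   plus one weights), giving the heavy-tailed degree structure of real
#'   interactomes; `FALSE` samples re-entries uniformly.
#' @param n_decoy_undirected Undirected noise pairs among non-network symbols.
#' @param n_decoy_signalink SignaLink rows with a non-admitted directionality
#'   label (exercise the read-time filter).
#' @param kegg_only_fraction,kegg_overlap_fraction Fractions of directed
#'   records emitted only in / also in the KEGG-style edge list.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_reference = 19300L,
                             roster = ras_effector_roster(),
                             branching = c(10, 5.5, 13),
                             branch_sdlog = c(0.8, 1, 1.6),
                             new_protein_prob = c(0.6, 0.85, 0.03),
                             undirected_fraction = 28 / 43,
                             n_isolated = 2L,
                             n_effector_reentries = 15L,
                             n_planted_feedbacks = 206L,
                             n_planted_hubs = 5L,
                             hub_degree = 30L,
                             n_class_specific = 2L,
                             enrichment_effect = list(class_id = 3L,
                                                      category = "Organelles",
                                                      odds_multiplier = 5),
                             localization_mix = default_localization_mix(),
                             process_probs_reference = default_process_probs("reference"),
                             process_probs_network = default_process_probs("network"),
                             type_probs = c(0.25, 0.25, 0.20, 0.12, 0.10, 0.08),
                             preferential = TRUE,
                             n_decoy_undirected = 200L,
                             n_decoy_signalink = 100L,
                             kegg_only_fraction = 0.10,
                             kegg_overlap_fraction = 0.10) {
  roster <- as_effector_roster(roster)
  cfg <- list(seed = as.integer(seed), n_reference = as.integer(n_reference),
              roster = roster, branching = branching,
              branch_sdlog = branch_sdlog,
              new_protein_prob = new_protein_prob,
              undirected_fraction = undirected_fraction,
              n_isolated = as.integer(n_isolated),
              n_effector_reentries = as.integer(n_effector_reentries),
              n_planted_feedbacks = as.integer(n_planted_feedbacks),
              n_planted_hubs = as.integer(n_planted_hubs),
              hub_degree = as.integer(hub_degree),
              n_class_specific = as.integer(n_class_specific),
              enrichment_effect = enrichment_effect,
              localization_mix = localization_mix,
              process_probs_reference = process_probs_reference,
              process_probs_network = process_probs_network,
              type_probs = type_probs,
              preferential = isTRUE(preferential),
              n_decoy_undirected = as.integer(n_decoy_undirected),
              n_decoy_signalink = as.integer(n_decoy_signalink),
              kegg_only_fraction = kegg_only_fraction,
              kegg_overlap_fraction = kegg_overlap_fraction)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  n_eff <- nrow(cfg$roster)
  if (cfg$n_reference < n_eff + 10L) {
    stop_config("n_reference (%d) too small for %d effectors", cfg$n_reference, n_eff)
  }
  if (length(cfg$branching) != 3 || any(cfg$branching <= 0)) {
    stop_config("branching must be 3 positive means")
  }
  if (length(cfg$branch_sdlog) != 3 || any(cfg$branch_sdlog < 0)) {
    stop_config("branch_sdlog must be 3 non-negative values")
  }
  if (any(cfg$new_protein_prob < 0 | cfg$new_protein_prob > 1)) {
    stop_config("new_protein_prob must lie in [0, 1]")
  }
  if (cfg$undirected_fraction < 0 || cfg$undirected_fraction > 1) {
    stop_config("undirected_fraction must lie in [0, 1]")
  }
  n_und <- round(cfg$undirected_fraction * n_eff)
  if (cfg$n_isolated > n_und) {
    stop_config("n_isolated (%d) exceeds the undirected-only effector count (%d)",
                cfg$n_isolated, n_und)
  }
  if (cfg$hub_degree > cfg$n_reference) {
    stop_config("hub_degree (%d) exceeds n_reference (%d)", cfg$hub_degree,
                cfg$n_reference)
  }
  if (cfg$n_effector_reentries > n_eff) {
    stop_config("n_effector_reentries exceeds the roster size")
  }
  ee <- cfg$enrichment_effect
  if (!is.null(ee)) {
    if (!all(c("class_id", "category", "odds_multiplier") %in% names(ee))) {
      stop_config("enrichment_effect needs class_id, category, odds_multiplier")
    }
    if (!ee$class_id %in% cfg$roster$class_id) {
      stop_config("enrichment_effect class_id %s is not a roster class", ee$class_id)
    }
    if (!ee$category %in% names(cfg$process_probs_network)) {
      stop_config("enrichment_effect category '%s' not in the process vocabulary",
                  ee$category)
    }
  }
  invisible(cfg)
}

#' @rdname synthetic_config
#' @export
default_localization_mix <- function() {
  # One dominant compartment per layer (the gradient: extracellular proteins
  # early, cytosolic in the middle, nuclear deep) over a realistic background:
  # the cytosol is the most common main localization and co-habits with most
  # compartments, so it carries secondary mass at every layer.
  make_mix <- function(main, p_main = 0.45) {
    cls <- localization_classes()
    p_cyt <- if (main == "Cytosol") 0 else 0.22
    p_unk <- 0.05
    rest <- setdiff(cls, c(main, "Cytosol", "UNKNOWN"))
    p <- setNames(rep((1 - p_main - p_cyt - p_unk) / length(rest),
                      length(cls)), cls)
    p[main] <- p_main
    if (main != "Cytosol") p["Cytosol"] <- p_cyt
    p["UNKNOWN"] <- p_unk
    p
  }
  list(`0` = make_mix("Cell membrane"),
       `1` = make_mix("Extracellular"),
       `2` = make_mix("Cytosol", 0.60),
       `3` = make_mix("Nucleus"))
}

#' @rdname synthetic_config
#' @param which `"reference"` or `"network"`.
#' @export
default_process_probs <- function(which = c("reference", "network")) {
  which <- arg_match(which)
  p <- if (which == "reference") {
    c(0.15, 0.18, 0.12, 0.10, 0.08, 0.05, 0.06, 0.06, 0.05, 0.04, 0.04,
      0.02, 0.02, 0.02, 0.01)
  } else {
    c(0.45, 0.08, 0.10, 0.12, 0.04, 0.04, 0.04, 0.03, 0.03, 0.02, 0.01,
      0.01, 0.01, 0.01, 0.01)
  }
  setNames(p, process_classes())
}

# Run code under a local RNG state (restores the caller's stream).
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate synthetic source tables with planted ground truth
#'
#' Wires a layered network exactly the way the builder will reconstruct it,
#' emits it as the three source-table dialects, and plants recorded
#' structures: class-specific proteins (extra layer-1 targets reachable from
#' one class only), feedback back-edges (from a protein occupying layers 2 and
#' 3 onto a layer-1 protein, i.e. a layer gap of 2), hubs (layer-2 proteins
#' with at least `hub_degree` out-edges), effector re-entries (multi-layer
#' effectors), and an annotation-level enrichment effect. Non-planted
#' re-entry wiring uses preferential attachment, giving the heavy-tailed
#' degree distribution typical of interactomes; it never targets layer-0/1
#' proteins, so the planted feedback edges are provably the only backward
#' edges.
#'
#' @param config A [synthetic_config()].
#' @return A `ras_synthesis` list: `tables` (tibbles `signalink`,
#'   `directed_edgelist`, `undirected_edgelist` in the dialect column
#'   schemas), `annotations`, `reference` (symbol vector), `ground_truth`
#'   (planted structures and layer membership bookkeeping), `network` (the
#'   layered network built from the emitted records), `config`.
#' @export
generate_sources <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(config$seed, generate_sources_impl(config))
}

generate_sources_impl <- function(cfg) {
  roster <- cfg$roster
  effectors <- roster$effector
  n_eff <- length(effectors)

  # Fresh-symbol supply (reference = effectors + filler, all uppercase).
  filler <- sprintf("SYN%05d", seq_len(cfg$n_reference - n_eff))
  reference <- c(effectors, filler)
  pool_env <- new.env(parent = emptyenv())
  pool_env$next_i <- 1L
  take_fresh <- function(n) {
    if (pool_env$next_i + n - 1L > length(filler)) {
      stop_config("reference proteome exhausted; increase n_reference")
    }
    out <- filler[pool_env$next_i:(pool_env$next_i + n - 1L)]
    pool_env$next_i <- pool_env$next_i + n
    out
  }

  # Effector partition: undirected-only (STRING/HuRI evidence) and isolated.
  n_und <- round(cfg$undirected_fraction * n_eff)
  und_eff <- sort(sample(effectors, n_und))
  isolated <- if (cfg$n_isolated > 0) sort(sample(und_eff, cfg$n_isolated)) else character()
  dir_eff <- setdiff(effectors, und_eff)

  directed_rec <- list()   # tibbles: source, target
  undirected_rec <- list() # tibbles: protein_a, protein_b
  degree <- new.env(parent = emptyenv()) # preferential-attachment weights
  bump <- function(p) {
    for (s in p) {
      cur <- degree[[s]]
      degree[[s]] <- if (is.null(cur)) 1L else cur + 1L
    }
  }
  add_directed <- function(src, tgt) {
    directed_rec[[length(directed_rec) + 1L]] <<- tibble(source = src, target = tgt)
    bump(c(src, tgt))
  }
  add_undirected <- function(a, b) {
    undirected_rec[[length(undirected_rec) + 1L]] <<- tibble(protein_a = a, protein_b = b)
    bump(c(a, b))
  }

  draw_outdeg <- function(k) {
    mu <- cfg$branching[k]
    sdl <- cfg$branch_sdlog[k]
    if (sdl <= 0) rpois(1L, mu)
    else as.integer(round(stats::rlnorm(1L, log(mu) - sdl^2 / 2, sdl)))
  }

  # --- Layer 1 -------------------------------------------------------------
  # Effectors share part of their layer-1 targets across classes (crosstalk
  # starts at layer 1 in real pathway data); the rest are fresh proteins.
  l1_members <- character()
  l1_parents <- new.env(parent = emptyenv()) # L1 protein -> effector vector
  planted_specific <- list()
  for (e in effectors) {
    if (e %in% isolated) next
    deg <- max(1L, draw_outdeg(1L))
    fresh_flags <- runif(deg) < cfg$new_protein_prob[1]
    targets <- character(deg)
    n_fresh <- sum(fresh_flags)
    if (n_fresh > 0) targets[fresh_flags] <- take_fresh(n_fresh)
    n_re <- deg - n_fresh
    if (n_re > 0) {
      if (length(l1_members) == 0) {
        targets[!fresh_flags] <- take_fresh(n_re)
      } else {
        w <- if (cfg$preferential) {
          vapply(l1_members, function(s) {
            d <- degree[[s]]; if (is.null(d)) 1 else d + 1
          }, numeric(1))
        } else rep(1, length(l1_members))
        targets[!fresh_flags] <- sample(l1_members, n_re, replace = TRUE, prob = w)
      }
    }
    targets <- unique(targets)
    if (e %in% und_eff) add_undirected(rep(e, length(targets)), targets)
    else add_directed(rep(e, length(targets)), targets)
    for (t in targets) l1_parents[[t]] <- c(l1_parents[[t]], e)
    l1_members <- unique(c(l1_members, targets))
  }
  # Planted class-specific proteins: extra L1 targets of one class only,
  # reserved from every other sampling pool. Their planter effectors must not
  # re-enter at deeper layers (a re-entered effector re-fires its layer-1
  # records at layer 3, which would propagate foreign classes onto them).
  planters <- character()
  if (cfg$n_class_specific > 0) {
    for (cid in sort(unique(roster$class_id))) {
      class_eff <- setdiff(roster$effector[roster$class_id == cid], isolated)
      if (length(class_eff) == 0) next
      planter <- intersect(class_eff, dir_eff)
      planter <- if (length(planter) > 0) planter[1] else class_eff[1]
      planters <- c(planters, planter)
      prot <- take_fresh(cfg$n_class_specific)
      if (planter %in% und_eff) add_undirected(rep(planter, length(prot)), prot)
      else add_directed(rep(planter, length(prot)), prot)
      for (t in prot) l1_parents[[t]] <- c(l1_parents[[t]], planter)
      l1_members <- unique(c(l1_members, prot))
      planted_specific[[as.character(cid)]] <- prot
    }
  }

  # --- Layer 2 -------------------------------------------------------------
  sample_targets <- function(n_tgt, p_new, eligible) {
    fresh_flags <- runif(n_tgt) < p_new
    n_fresh <- sum(fresh_flags)
    out <- character(n_tgt)
    if (n_fresh > 0) out[fresh_flags] <- take_fresh(n_fresh)
    n_re <- n_tgt - n_fresh
    if (n_re > 0) {
      if (length(eligible) == 0) {
        out[!fresh_flags] <- take_fresh(n_re)
      } else {
        w <- if (cfg$preferential) {
          vapply(eligible, function(s) {
            d <- degree[[s]]; if (is.null(d)) 1 else d + 1
          }, numeric(1))
        } else rep(1, length(eligible))
        out[!fresh_flags] <- sample(eligible, n_re, replace = TRUE, prob = w)
      }
    }
    unique(out)
  }

  l2_members <- character()
  for (p in l1_members) {
    deg <- draw_outdeg(2L)
    if (deg == 0L) next
    targets <- sample_targets(deg, cfg$new_protein_prob[2], l2_members)
    add_directed(rep(p, length(targets)), targets)
    l2_members <- unique(c(l2_members, targets))
  }
  # Effector re-entries: an L1 protein points back to an effector, which then
  # re-appears at layer 2 (and its own targets at layer 3). The pointing
  # protein must never gain a layer-3 membership, or the pointing edge itself
  # would read as an L3->L0 loop: so it is drawn from L1 proteins none of
  # whose parent effectors re-enter, and is excluded from feedback targets.
  reentry_eff <- character()
  reentry_sources <- character()
  if (cfg$n_effector_reentries > 0 && length(l1_members) > 0) {
    eligible_eff <- setdiff(effectors, c(isolated, planters))
    reentry_eff <- sort(sample(eligible_eff,
                               min(cfg$n_effector_reentries, length(eligible_eff))))
    safe_l1 <- l1_members[vapply(l1_members, function(t) {
      !any(l1_parents[[t]] %in% reentry_eff)
    }, logical(1))]
    safe_l1 <- setdiff(safe_l1, unlist(planted_specific))
    if (length(safe_l1) < 1) stop_config("no safe layer-1 protein for effector re-entry")
    for (e in reentry_eff) {
      w <- sample(safe_l1, 1L)
      reentry_sources <- unique(c(reentry_sources, w))
      add_directed(w, e)
    }
  }

  l2_nodes <- unique(c(l2_members, reentry_eff))
  l2_pool <- setdiff(l2_nodes, effectors)

  # --- Planted feedback back-edges ----------------------------------------
  planted_fb <- tibble(downstream_source = character(),
                       upstream_target = character())
  if (cfg$n_planted_feedbacks > 0) {
    v_pool <- setdiff(l1_members, c(unlist(planted_specific), reentry_sources))
    if (length(l2_pool) < 2 || length(v_pool) < 1) {
      stop_config("network too small to plant %d feedback edges",
                  cfg$n_planted_feedbacks)
    }
    max_pairs <- length(l2_pool) * length(v_pool)
    if (cfg$n_planted_feedbacks > max_pairs) {
      stop_config("cannot plant %d distinct feedback edges (only %d pairs available)",
                  cfg$n_planted_feedbacks, max_pairs)
    }
    seen <- character()
    u_vec <- character(cfg$n_planted_feedbacks)
    v_vec <- character(cfg$n_planted_feedbacks)
    i <- 1L
    while (i <= cfg$n_planted_feedbacks) {
      u <- sample(l2_pool, 1L)
      v <- sample(v_pool, 1L)
      key <- paste(u, v)
      if (key %in% seen) next
      seen <- c(seen, key)
      u_vec[i] <- u; v_vec[i] <- v
      i <- i + 1L
    }
    # Give every feedback source a layer-3 membership via a supporting
    # forward edge from another layer-2 protein.
    for (u in unique(u_vec)) {
      w2 <- sample(setdiff(l2_pool, u), 1L)
      add_directed(w2, u)
    }
    add_directed(u_vec, v_vec)
    planted_fb <- tibble(downstream_source = u_vec, upstream_target = v_vec,
                         target_layer = 1L, layer_gap = 2L)
  }

  # --- Planted hubs --------------------------------------------------------
  planted_hubs <- character()
  if (cfg$n_planted_hubs > 0) {
    if (length(l2_pool) < cfg$n_planted_hubs) {
      stop_config("network too small to plant %d hubs", cfg$n_planted_hubs)
    }
    planted_hubs <- sort(sample(l2_pool, cfg$n_planted_hubs))
    for (h in planted_hubs) {
      targets <- take_fresh(cfg$hub_degree)
      add_directed(rep(h, cfg$hub_degree), targets)
    }
  }

  # --- Layer 3 -------------------------------------------------------------
  for (p in l2_pool) {
    deg <- draw_outdeg(3L)
    if (deg == 0L) next
    targets <- sample_targets(deg, cfg$new_protein_prob[3], l2_pool)
    targets <- setdiff(targets, p)
    if (length(targets) > 0) add_directed(rep(p, length(targets)), targets)
  }

  directed_tbl <- distinct(bind_rows(directed_rec))
  undirected_tbl <- if (length(undirected_rec) > 0) {
    distinct(bind_rows(undirected_rec))
  } else {
    tibble(protein_a = character(), protein_b = character())
  }

  # --- Dialect tables ------------------------------------------------------
  n_dir <- nrow(directed_tbl)
  types <- sample(signalink_interaction_types(), n_dir, replace = TRUE,
                  prob = cfg$type_probs)
  grp <- runif(n_dir)
  kegg_only <- grp < cfg$kegg_only_fraction
  kegg_also <- !kegg_only & grp < cfg$kegg_only_fraction + cfg$kegg_overlap_fraction
  # KEGG-only records must not strip an undirected-only effector's evidence,
  # nor hide planted structure; restrict them to plain random forward edges.
  protected <- unique(c(planted_fb$downstream_source, planted_hubs, effectors))
  kegg_only <- kegg_only & !(directed_tbl$source %in% protected) &
    !(directed_tbl$target %in% effectors)

  signalink <- tibble(
    source_name = directed_tbl$source[!kegg_only],
    target_name = directed_tbl$target[!kegg_only],
    directness_label = sample(c("Directed", "Predicted as directed"),
                              sum(!kegg_only), replace = TRUE, prob = c(0.7, 0.3)),
    layer_category = types[!kegg_only]
  )
  if (cfg$n_decoy_signalink > 0) {
    decoy <- tibble(
      source_name = take_fresh(cfg$n_decoy_signalink),
      target_name = take_fresh(cfg$n_decoy_signalink),
      directness_label = "Undirected",
      layer_category = sample(signalink_interaction_types(),
                              cfg$n_decoy_signalink, replace = TRUE)
    )
    signalink <- bind_rows(signalink, decoy)
  }
  kegg <- tibble(source = directed_tbl$source[kegg_only | kegg_also],
                 target = directed_tbl$target[kegg_only | kegg_also])
  if (cfg$n_decoy_undirected > 0) {
    undirected_tbl <- bind_rows(
      undirected_tbl,
      tibble(protein_a = take_fresh(cfg$n_decoy_undirected),
             protein_b = take_fresh(cfg$n_decoy_undirected))
    )
  }
  tables <- list(signalink = signalink, directed_edgelist = kegg,
                 undirected_edgelist = undirected_tbl)

  # --- Build once to fix memberships/closures, then annotate ---------------
  records <- bind_rows(
    source_records_from_table(signalink, "signalink", "signalink"),
    source_records_from_table(kegg, "directed_edgelist", "kegg"),
    source_records_from_table(undirected_tbl, "undirected_edgelist", "string")
  )
  network <- build_layered_network(roster, records, max_depth = 3)

  annotations <- annotate_synthetic(network, reference, cfg)

  ground_truth <- list(
    planted_feedback_edges = planted_fb,
    planted_hubs = planted_hubs,
    planted_class_specific = planted_specific,
    planted_enriched = cfg$enrichment_effect,
    effector_reentries = reentry_eff,
    undirected_only_effectors = und_eff,
    isolated_effectors = isolated,
    members = network$members,
    network_proteins = network_proteins(network)
  )
  structure(list(tables = tables, annotations = annotations,
                 reference = reference, ground_truth = ground_truth,
                 network = network, config = cfg),
            class = "ras_synthesis")
}

# Draw annotations: localization from the per-layer mix (first layer of each
# protein), process classes from the network/reference baselines with the
# planted odds boost on the planted class closure, tissue classes skewed to
# broad expression for network proteins.
annotate_synthetic <- function(network, reference, cfg) {
  members <- network$members
  first_layer <- members %>%
    group_by(protein = .data$protein) %>%
    summarise(layer = min(.data$layer), .groups = "drop")
  net_proteins <- first_layer$protein
  other <- setdiff(reference, net_proteins)

  loc_classes <- localization_classes()
  draw_loc <- function(layer_key, n) {
    p <- cfg$localization_mix[[layer_key]]
    sample(names(p), n, replace = TRUE, prob = p)
  }
  loc_net <- character(length(net_proteins))
  for (k in unique(first_layer$layer)) {
    idx <- first_layer$layer == k
    loc_net[idx] <- draw_loc(as.character(k), sum(idx))
  }
  loc_other <- sample(loc_classes, length(other), replace = TRUE,
                      prob = rep(1 / length(loc_classes), length(loc_classes)))

  p_ref <- cfg$process_probs_reference
  p_net <- cfg$process_probs_network
  proc_other <- sample(names(p_ref), length(other), replace = TRUE, prob = p_ref)
  proc_net <- sample(names(p_net), length(net_proteins), replace = TRUE, prob = p_net)
  ee <- cfg$enrichment_effect
  if (!is.null(ee)) {
    boosted <- network$class_closure[[as.character(ee$class_id)]]
    idx <- which(net_proteins %in% boosted)
    if (length(idx) > 0) {
      p0 <- p_net[[ee$category]]
      p1 <- ee$odds_multiplier * p0 / (1 - p0 + ee$odds_multiplier * p0)
      p_boost <- p_net * (1 - p1) / (1 - p0)
      p_boost[[ee$category]] <- p1
      proc_net[idx] <- sample(names(p_boost), length(idx), replace = TRUE,
                              prob = p_boost)
    }
  }

  tc <- tissue_classes()
  tissue_net <- sample(tc, length(net_proteins), replace = TRUE,
                       prob = c(0.01, 0.02, 0.07, 0.45, 0.45))
  tissue_other <- sample(tc, length(other), replace = TRUE,
                         prob = c(0.15, 0.15, 0.25, 0.25, 0.20))

  bind_rows(
    tibble(symbol = net_proteins, localization = loc_net, process15 = proc_net,
           tissue_class = tissue_net),
    tibble(symbol = other, localization = loc_other, process15 = proc_other,
           tissue_class = tissue_other)
  ) %>%
    arrange(.data$symbol)
}

#' @export
print.ras_synthesis <- function(x, ...) {
  cat(sprintf(paste0("<ras_synthesis> seed %d: %d signalink rows, %d directed, ",
                     "%d undirected; %d network proteins\n"),
              x$config$seed, nrow(x$tables$signalink),
              nrow(x$tables$directed_edgelist), nrow(x$tables$undirected_edgelist),
              length(x$ground_truth$network_proteins)))
  invisible(x)
}

#' Write the synthetic source tables to a directory
#'
#' Emits exactly the dialect files [read_source_table()] consumes, plus the
#' reference list, annotation table and a ground-truth JSON.
#'
#' @param synthesis Result of [generate_sources()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_sources <- function(synthesis, dir) {
  stopifnot(inherits(synthesis, "ras_synthesis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    signalink = file.path(dir, "signalink.tsv"),
    directed_edgelist = file.path(dir, "kegg.tsv"),
    undirected_edgelist = file.path(dir, "string.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    reference = file.path(dir, "reference_symbols.txt"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  readr::write_tsv(synthesis$tables$signalink, paths["signalink"], progress = FALSE)
  readr::write_tsv(synthesis$tables$directed_edgelist, paths["directed_edgelist"],
                   progress = FALSE)
  readr::write_tsv(synthesis$tables$undirected_edgelist, paths["undirected_edgelist"],
                   progress = FALSE)
  readr::write_tsv(synthesis$annotations, paths["annotations"], progress = FALSE)
  writeLines(synthesis$reference, paths["reference"])
  gt <- synthesis$ground_truth
  gt$members <- NULL
  jsonlite::write_json(gt, paths["ground_truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Generate an external protein list with a controlled network overlap
#'
#' Emulates an AP-MS/BioID-style protein list: `round(overlap_fraction *
#' n_list)` proteins are drawn from the synthetic network (optionally biased
#' by layer) and the remainder from reference symbols outside the network.
#'
#' @param synthesis Result of [generate_sources()].
#' @param overlap_fraction Proportion of the list inside the network.
#' @param n_list List size.
#' @param layer_bias Optional named weights over layers `0..3` used when
#'   drawing the in-network part (by first layer of each protein).
#' @param seed Seed (default derived from the generating config).
#' @return Character vector of protein symbols.
#' @export
generate_external_list <- function(synthesis, overlap_fraction, n_list = 200L,
                                   layer_bias = NULL, seed = NULL) {
  stopifnot(inherits(synthesis, "ras_synthesis"))
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop_config("overlap_fraction must lie in [0, 1]")
  }
  if (is.null(seed)) seed <- synthesis$config$seed + 1L
  with_local_seed(seed, {
    net <- synthesis$ground_truth$network_proteins
    outside <- setdiff(synthesis$reference, net)
    n_in <- round(overlap_fraction * n_list)
    n_out <- n_list - n_in
    if (n_in > length(net) || n_out > length(outside)) {
      stop_config("list size infeasible for this synthesis")
    }
    if (!is.null(layer_bias)) {
      first_layer <- synthesis$network$members %>%
        group_by(protein = .data$protein) %>%
        summarise(layer = min(.data$layer), .groups = "drop")
      w <- layer_bias[as.character(first_layer$layer)]
      w[is.na(w)] <- 0
      inside <- sample(first_layer$protein, n_in, prob = w + 1e-9)
    } else {
      inside <- sample(net, n_in)
    }
    sample(c(inside, sample(outside, n_out)))
  })
}
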