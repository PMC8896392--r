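test_that("the RAF chain layers as effector/L1/L2/L3", {
  net <- build_layered_network(tiny_roster(), raf_chain_records())
  m <- net$members
  expect_equal(m$layer[m$protein == "RAF1"], 0L)
  expect_equal(m$layer[m$protein == "MAP2K1"], 1L)
  expect_equal(m$layer[m$protein == "MAPK1"], 2L)
  expect_equal(m$layer[m$protein == "MYC"], 3L)
  # PIK3CA has no records: present at L0 with empty closure
  expect_true("PIK3CA" %in% m$protein[m$layer == 0])
  expect_equal(net$class_closure[["2"]], character(0))
  expect_setequal(net$class_closure[["1"]], c("MAP2K1", "MAPK1", "MYC"))
})

test_that("effectors without any source record keep empty closures", {
  roster <- as_effector_roster(ras_effector_roster())
  # records for one effector only; ARHGAP20 and ARAP2 get nothing
  rec <- as_source_records(tibble::tibble(
    source = "RAF1", target = "MAP2K1", directed = TRUE))
  net <- build_layered_network(roster, rec)
  expect_true(all(c("ARHGAP20", "ARAP2") %in% network_proteins(net, layers = 0)))
  arhgap_class <- roster$class_id[roster$effector == "ARHGAP20"]
  expect_false("ARHGAP20" %in% unlist(net$class_closure))
  closure7 <- net$class_closure[[as.character(arhgap_class)]]
  expect_equal(closure7, character(0))
})

test_that("undirected records are used only for sources without directed records", {
  roster <- tibble::tibble(effector = c("A", "B"), class_id = c(1L, 2L))
  rec <- as_source_records(tibble::tibble(
    source = c("A", "A", "B"),
    target = c("X", "Y", "Z"),
    directed = c(TRUE, FALSE, FALSE)
  ))
  net <- build_layered_network(roster, rec)
  # A has a directed record, so its undirected one is ignored
  expect_setequal(net$edges$target[net$edges$source == "A"], "X")
  # B has none: the undirected record is admitted, oriented B -> Z
  expect_true(any(net$edges$source == "B" & net$edges$target == "Z"))
  expect_false(net$edges$directed_evidence[net$edges$source == "B"])
})

test_that("undirected records orient from the expanding protein", {
  roster <- tibble::tibble(effector = "B", class_id = 1L)
  rec <- as_source_records(tibble::tibble(
    source = "Z", target = "B", directed = FALSE))
  net <- build_layered_network(roster, rec)
  expect_equal(net$edges$source, "B")
  expect_equal(net$edges$target, "Z")
})

test_that("undirected fallback beyond layer 1 requires the depth flag", {
  roster <- tibble::tibble(effector = "A", class_id = 1L)
  rec <- as_source_records(tibble::tibble(
    source = c("A", "X"), target = c("X", "Y"), directed = c(TRUE, FALSE)))
  net_default <- build_layered_network(roster, rec)
  expect_false("Y" %in% network_proteins(net_default))
  net_deep <- build_layered_network(roster, rec, undirected_at_depth = TRUE)
  expect_true("Y" %in% network_proteins(net_deep, layers = 2))
})

test_that("re-entry targets gain layer memberships; self-loops honour the option", {
  roster <- tibble::tibble(effector = "RIN1", class_id = 6L)
  rec <- as_source_records(tibble::tibble(
    source = c("RIN1", "ABL1", "RIN1"),
    target = c("ABL1", "RIN1", "RIN1"),
    directed = TRUE
  ))
  net <- build_layered_network(roster, rec)
  expect_setequal(net$members$layer[net$members$protein == "RIN1"], c(0L, 2L))
  expect_false(any(net$edges$source == net$edges$target))
  net_sl <- build_layered_network(roster, rec, keep_self_loops = TRUE)
  expect_true(any(net_sl$edges$source == "RIN1" & net_sl$edges$target == "RIN1"))
})

test_that("same-layer duplicates merge with provenance union; layers stay distinct", {
  roster <- tibble::tibble(effector = c("A", "B"), class_id = c(1L, 2L))
  rec <- as_source_records(tibble::tibble(
    source = c("A", "A", "B", "X"),
    target = c("X", "X", "X", "A"),
    directed = TRUE,
    database = c("db1", "db2", "db3", "db1"),
    interaction_type = c("Post-translational modification", "unknown",
                         "unknown", "unknown")
  ))
  net <- build_layered_network(roster, rec)
  e_ax <- net$edges[net$edges$source == "A" & net$edges$target == "X", ]
  # layer-1 edge A->X merged from both databases
  expect_equal(nrow(e_ax[e_ax$layer == 1, ]), 1)
  expect_equal(e_ax$databases[e_ax$layer == 1], "db1;db2")
  expect_equal(e_ax$interaction_types[e_ax$layer == 1],
               "Post-translational modification;unknown")
  # A re-enters at layer 2 (X->A), so A->X also exists at layer 3
  expect_setequal(e_ax$layer, c(1L, 3L))
  # class provenance: X reached from classes 1 and 2 at layer 1
  expect_equal(e_ax$classes[e_ax$layer == 1], "1")
  x_l1 <- net$members[net$members$protein == "X" & net$members$layer == 1, ]
  expect_equal(x_l1$classes, "1;2")
})

test_that("building is deterministic and independent of record order", {
  rr <- random_records(42, n_nodes = 30, n_edges = 80)
  net1 <- build_layered_network(rr$roster, rr$records)
  net2 <- build_layered_network(rr$roster, rr$records[sample(nrow(rr$records)), ])
  expect_identical(net1$edges, net2$edges)
  expect_identical(net1$members, net2$members)
})

test_that("layering and closures match the exhaustive oracle on random graphs", {
  for (seed in 1:20) {
    rr <- random_records(seed, n_nodes = 30, n_edges = 70, n_effectors = 4)
    net <- build_layered_network(rr$roster, rr$records)
    orc <- oracle_layering(rr$roster, rr$records)
    expect_setequal(paste(net$members$protein, net$members$layer),
                    paste(orc$members$protein, orc$members$layer))
    expect_setequal(
      paste(net$edges$source, net$edges$target, net$edges$layer, net$edges$classes),
      paste(orc$edges$source, orc$edges$target, orc$edges$layer, orc$edges$classes)
    )
    for (cid in names(net$class_closure)) {
      expect_setequal(net$class_closure[[cid]], orc$closures[[cid]])
    }
  }
})

test_that("class closures grow monotonically with depth", {
  for (seed in 1:5) {
    rr <- random_records(seed + 100, n_nodes = 25, n_edges = 60)
    nets <- lapply(1:4, function(d) {
      build_layered_network(rr$roster, rr$records, max_depth = d)
    })
    for (d in 2:4) {
      for (cid in names(nets[[d]]$class_closure)) {
        expect_true(all(nets[[d - 1]]$class_closure[[cid]] %in%
                          nets[[d]]$class_closure[[cid]]))
      }
    }
  }
})

test_that("provenance fields are always populated", {
  syn <- generate_sources(small_synth_config(seed = 5))
  net <- rebuild_from_tables(syn)
  expect_true(all(nzchar(net$edges$databases)))
  expect_true(all(nzchar(net$edges$classes)))
  cls <- unique(unlist(strsplit(net$edges$classes, ";")))
  expect_true(all(as.integer(cls) %in% 1:12))
})

test_that("layer_edge_counts matches a direct recount of the written TSV", {
  syn <- generate_sources(small_synth_config(seed = 9))
  net <- syn$network
  counts <- layer_edge_counts(net)
  path <- tempfile(fileext = ".tsv")
  write_network(net, path, "tsv")
  recount <- table(readr::read_tsv(path, show_col_types = FALSE)$layer)
  for (k in 1:3) {
    expect_equal(counts$by_layer$n_edges[counts$by_layer$layer == k],
                 unname(recount[as.character(k)]),
                 ignore_attr = TRUE)
  }
  expect_equal(counts$total, nrow(net$edges))

  empty <- build_layered_network(tiny_roster(),
                                 raf_chain_records()[0, ])
  ec <- layer_edge_counts(empty)
  expect_equal(ec$by_layer$n_edges, c(0L, 0L, 0L))
  expect_equal(ec$total, 0)
})

test_that("normalized class PPIs divide per-class edge counts by class size", {
  roster <- tibble::tibble(effector = c("A", "B"), class_id = c(1L, 1L))
  rec <- as_source_records(tibble::tibble(
    source = c("A", "B", "X", "X", "Y"),
    target = c("X", "X", "Y", "Z", "W"),
    directed = TRUE
  ))
  net <- build_layered_network(roster, rec)
  norm <- normalized_class_ppi(net)
  # 5 distinct layered edges through class 1 (A->X, B->X at L1; X->Y, X->Z at
  # L2; Y->W at L3), 2 effectors
  expect_equal(norm$n_edges, 5)
  expect_equal(norm$normalized, 2.5)

  # class with no downstream edges scores 0
  net2 <- build_layered_network(tiny_roster(), raf_chain_records())
  norm2 <- normalized_class_ppi(net2)
  expect_equal(norm2$normalized[norm2$class_id == 2], 0)
  expect_equal(norm2$normalized[norm2$class_id == 1], 3)
})

test_that("normalized class PPIs equal a brute-force recount on synthetic data", {
  syn <- generate_sources(small_synth_config(seed = 13))
  net <- syn$network
  norm <- normalized_class_ppi(net)
  n_eff <- table(net$roster$class_id)
  for (i in seq_len(nrow(norm))) {
    cid <- norm$class_id[i]
    brute <- sum(vapply(strsplit(net$edges$classes, ";"),
                        function(s) as.character(cid) %in% s, logical(1)))
    expect_equal(norm$n_edges[i], brute)
    expect_equal(norm$normalized[i], brute / n_eff[[as.character(cid)]])
  }
})

test_that("builder rejects invalid configuration", {
  expect_error(build_layered_network(tiny_roster(), raf_chain_records(),
                                     max_depth = 0),
               class = "rasnet_config_error")
  dup_roster <- tibble::tibble(effector = c("RAF1", "RAF1"), class_id = 1:2)
  expect_error(build_layered_network(dup_roster, raf_chain_records()),
               class = "rasnet_config_error")
})

test_that("tidy and glance summarize the network object", {
  net <- build_layered_network(tiny_roster(), raf_chain_records())
  expect_identical(tidy(net), net$edges)
  g <- glance(net)
  expect_equal(g$n_proteins, 5)
  expect_equal(g$n_downstream, 3)
  expect_equal(g$n_edges, 3)
})
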