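test_that("degree centrality counts occurrences as source and target", {
  # star: center with 12 out-edges reached from one effector
  roster <- tibble::tibble(effector = "E", class_id = 1L)
  spokes <- sprintf("S%02d", 1:12)
  rec <- as_source_records(tibble::tibble(
    source = c("E", rep("HUB", 12)),
    target = c("HUB", spokes),
    directed = TRUE
  ))
  net <- build_layered_network(roster, rec)
  deg <- degree_centrality(net, hub_cutoff = 10)
  hub_row <- deg[deg$protein == "HUB", ]
  expect_equal(hub_row$out_degree, 12L)
  expect_equal(hub_row$in_degree, 1L)
  expect_true(hub_row$is_hub)
  expect_false(any(deg$is_hub[deg$protein %in% spokes]))
  # an isolated effector has zero degree and is a non-hub
  roster2 <- tibble::tibble(effector = c("E", "LONER"), class_id = c(1L, 2L))
  deg2 <- degree_centrality(build_layered_network(roster2, rec))
  expect_equal(deg2$total[deg2$protein == "LONER"], 0L)
  expect_false(deg2$is_hub[deg2$protein == "LONER"])
  expect_error(degree_centrality(net, hub_cutoff = 0),
               class = "rasnet_config_error")
})

test_that("degree totals balance the layered edge count", {
  syn <- generate_sources(small_synth_config(seed = 21))
  net <- syn$network
  deg <- degree_centrality(net)
  expect_equal(sum(deg$out_degree), nrow(net$edges))
  expect_equal(sum(deg$in_degree), nrow(net$edges))
  # recount oracle: tabulate the edge table directly
  out_tab <- table(net$edges$source)
  in_tab <- table(net$edges$target)
  for (p in sample(deg$protein, 50)) {
    expect_equal(deg$out_degree[deg$protein == p],
                 if (p %in% names(out_tab)) unname(out_tab[[p]]) else 0L,
                 ignore_attr = TRUE)
    expect_equal(deg$in_degree[deg$protein == p],
                 if (p %in% names(in_tab)) unname(in_tab[[p]]) else 0L,
                 ignore_attr = TRUE)
  }
  expect_equal(attr(deg, "hub_fraction") + attr(deg, "nonhub_fraction"), 1)
})

test_that("class subgroups partition the downstream proteins", {
  # a protein downstream of exactly classes 1 and 12 lands in that subgroup
  roster <- tibble::tibble(effector = c("RAF1", "GRB7", "PLCE1"),
                           class_id = c(1L, 12L, 5L))
  rec <- as_source_records(tibble::tibble(
    source = c("RAF1", "GRB7", "PLCE1"),
    target = c("AAAS", "AAAS", "PLCB1"),
    directed = TRUE
  ))
  net <- build_layered_network(roster, rec)
  sg <- class_subgroup_decomposition(net)
  expect_setequal(sg$classes, c("1;12", "5"))
  expect_equal(sg$proteins[[which(sg$classes == "1;12")]], "AAAS")
  expect_equal(attr(sg, "class_specific"), "PLCB1")

  # single-class network: one subgroup holding every downstream protein
  net1 <- build_layered_network(tiny_roster(), raf_chain_records())
  sg1 <- class_subgroup_decomposition(net1)
  expect_equal(nrow(sg1), 1)
  expect_equal(sg1$n_proteins, 3L)
})

test_that("subgroup decomposition matches a per-protein membership scan", {
  for (seed in c(2, 8)) {
    syn <- generate_sources(small_synth_config(seed = seed))
    net <- syn$network
    sg <- class_subgroup_decomposition(net)
    downstream <- unique(unlist(net$class_closure))
    # partition: disjoint and exhaustive
    all_assigned <- unlist(sg$proteins)
    expect_equal(length(all_assigned), length(unique(all_assigned)))
    expect_setequal(all_assigned, downstream)
    expect_equal(sum(sg$n_proteins), length(downstream))
    expect_true(nrow(sg) <= 2^12 - 1)
    # membership scan oracle on a sample of proteins
    for (p in sample(downstream, min(40, length(downstream)))) {
      member_of <- names(net$class_closure)[vapply(net$class_closure,
                                                   function(s) p %in% s,
                                                   logical(1))]
      subgroup <- sg$classes[vapply(sg$proteins, function(s) p %in% s,
                                    logical(1))]
      expect_equal(subgroup, paste(sort(member_of), collapse = ";"))
    }
  }
})

test_that("pairwise sharing handles identical, disjoint and random closures", {
  roster <- tibble::tibble(effector = c("A", "B", "C"), class_id = 1:3)
  rec <- as_source_records(tibble::tibble(
    source = c("A", "B", "C"),
    target = c("X", "X", "Z"),
    directed = TRUE
  ))
  net <- build_layered_network(roster, rec)
  m <- pairwise_class_sharing(net)
  expect_equal(m["1", "2"], 100)   # identical closures {X}
  expect_equal(m["1", "3"], 0)     # disjoint {X} vs {Z}
  expect_equal(diag(m), c(`1` = 100, `2` = 100, `3` = 100))

  syn <- generate_sources(small_synth_config(seed = 4))
  net2 <- syn$network
  for (method in c("jaccard", "min", "row")) {
    ms <- pairwise_class_sharing(net2, method = method)
    a <- net2$class_closure[["1"]]; b <- net2$class_closure[["4"]]
    denom <- switch(method, jaccard = length(union(a, b)),
                    min = min(length(a), length(b)), row = length(a))
    expect_equal(ms["1", "4"], 100 * length(intersect(a, b)) / denom)
  }
  # empty closure reported as undefined
  net3 <- build_layered_network(tiny_roster(), raf_chain_records())
  m3 <- pairwise_class_sharing(net3)
  expect_true(is.na(m3["1", "2"]))
})

test_that("feedback loops require a layer gap of at least two", {
  # RIN1-style: effector re-reached at L2; an L2 protein points back at it
  roster <- tibble::tibble(effector = "RIN1", class_id = 6L)
  rec <- as_source_records(tibble::tibble(
    source = c("RIN1", "ABL1", "RAB5A"),
    target = c("ABL1", "RAB5A", "RIN1"),
    directed = TRUE
  ))
  net <- build_layered_network(roster, rec)
  loops <- find_feedback_loops(net)
  back <- loops[loops$upstream_target == "RIN1", ]
  expect_equal(back$downstream_source, "RAB5A")
  expect_equal(back$target_layer, 0L)
  # RIN1 itself now occupies layers 0 and 3, so its forward edge onto the L1
  # protein also reads as an L3 -> L1 loop
  expect_setequal(loop_keys(loops),
                  c("RAB5A\tRIN1\t0", "RIN1\tABL1\t1"))
  expect_true("RIN1" %in% attr(loops, "multilayer_effectors"))

  # an L2 -> L1 edge is NOT a loop
  rec2 <- as_source_records(tibble::tibble(
    source = c("RIN1", "ABL1", "RAB5A"),
    target = c("ABL1", "RAB5A", "ABL1"),
    directed = TRUE
  ))
  loops2 <- find_feedback_loops(build_layered_network(roster, rec2))
  expect_equal(nrow(loops2), 0)

  # purely feed-forward chain: empty
  loops3 <- find_feedback_loops(build_layered_network(tiny_roster(),
                                                      raf_chain_records()))
  expect_equal(nrow(loops3), 0)
  expect_equal(attr(loops3, "multilayer_effector_fraction"), 0)
})

test_that("feedback detection equals the brute-force membership scan", {
  for (seed in 1:10) {
    rr <- random_records(seed + 200, n_nodes = 25, n_edges = 80, n_effectors = 5)
    net <- build_layered_network(rr$roster, rr$records)
    loops <- find_feedback_loops(net)
    expect_identical(loop_keys(loops), oracle_feedbacks(net))
  }
})

test_that("planted feedback edges are recovered exactly", {
  syn <- generate_sources(small_synth_config(seed = 31))
  net <- rebuild_from_tables(syn)
  loops <- find_feedback_loops(net)
  planted <- syn$ground_truth$planted_feedback_edges
  expect_setequal(
    paste(loops$downstream_source, loops$upstream_target, loops$target_layer),
    paste(planted$downstream_source, planted$upstream_target, planted$target_layer)
  )
})

test_that("adding a forward edge never removes a detected loop", {
  rr <- random_records(77, n_nodes = 20, n_edges = 50, n_effectors = 4)
  net <- build_layered_network(rr$roster, rr$records)
  before <- loop_keys(find_feedback_loops(net))
  extra <- tibble::tibble(source = "P01", target = "PNEW", directed = TRUE,
                          database = "x", interaction_type = "unknown")
  net2 <- build_layered_network(rr$roster,
                                dplyr::bind_rows(rr$records, extra))
  after <- loop_keys(find_feedback_loops(net2))
  expect_true(all(before %in% after))
})
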