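ann_for <- function(...) {
  pairs <- list(...)
  tibble::tibble(symbol = names(pairs),
                 localization = unname(unlist(pairs)),
                 process15 = "Signaling")
}

test_that("compatibility matrices must be reflexive and symmetric", {
  m <- default_compatibility_matrix()
  expect_true(all(diag(m)))
  expect_identical(m, t(m))
  bad <- m; bad["Cytosol", "Nucleus"] <- FALSE
  expect_error(as_compatibility_matrix(bad), "symmetric",
               class = "rasnet_config_error")
  bad2 <- m; diag(bad2)[1] <- FALSE
  expect_error(as_compatibility_matrix(bad2), "reflexive",
               class = "rasnet_config_error")
  # round-trips through the CSV form
  path <- tempfile(fileext = ".csv")
  write_compatibility_matrix(m, path)
  expect_identical(read_compatibility_matrix(path), m)
})

test_that("localization compatibility follows the matrix and unknown policy", {
  roster <- tibble::tibble(effector = "A", class_id = 1L)
  rec <- as_source_records(tibble::tibble(
    source = c("A", "A", "A"), target = c("B", "C", "D"), directed = TRUE))
  net <- build_layered_network(roster, rec)
  ann <- ann_for(A = "Cytosol", B = "Cytosol", C = "Golgi apparatus",
                 D = "Extracellular")
  flags <- localization_compatibility(net, ann)
  expect_true(flags$loc_compatible[flags$target == "B"])  # reflexive
  expect_true(flags$loc_compatible[flags$target == "C"])  # cytosol-Golgi
  expect_false(flags$loc_compatible[flags$target == "D"])
  expect_equal(attr(flags, "fraction"), 2 / 3)

  # unknown localization: excluded by default, forced under other policies
  ann2 <- ann_for(A = "Cytosol", B = "UNKNOWN", C = "Golgi apparatus",
                  D = "Extracellular")
  f_ex <- localization_compatibility(net, ann2)
  expect_true(is.na(f_ex$loc_compatible[f_ex$target == "B"]))
  expect_equal(attr(f_ex, "n_evaluated"), 2)
  f_comp <- localization_compatibility(net, ann2, unknown_policy = "compatible")
  f_inc <- localization_compatibility(net, ann2, unknown_policy = "incompatible")
  expect_true(attr(f_comp, "fraction") >= attr(f_ex, "fraction"))
  expect_true(f_comp$loc_compatible[f_comp$target == "B"])
  expect_false(f_inc$loc_compatible[f_inc$target == "B"])
})

test_that("relaxing the unknown policy never lowers the compatible fraction", {
  syn <- generate_sources(small_synth_config(seed = 17))
  # strip some annotations to create unknowns
  ann <- syn$annotations[-sample(nrow(syn$annotations), 500), ]
  f_ex <- localization_compatibility(syn$network, ann)
  f_comp <- localization_compatibility(syn$network, ann,
                                       unknown_policy = "compatible")
  expect_true(attr(f_comp, "fraction") >= attr(f_ex, "fraction"))
})

test_that("per-edge localization flags equal a brute-force evaluation", {
  syn <- generate_sources(small_synth_config(seed = 19))
  net <- syn$network
  m <- default_compatibility_matrix()
  flags <- localization_compatibility(net, syn$annotations)
  loc <- stats::setNames(syn$annotations$localization, syn$annotations$symbol)
  idx <- sample(nrow(flags), 100)
  for (i in idx) {
    ls <- loc[[flags$source[i]]]; lt <- loc[[flags$target[i]]]
    expected <- if (ls == "UNKNOWN" || lt == "UNKNOWN") NA else m[ls, lt]
    expect_equal(flags$loc_compatible[i], expected)
  }
  brute <- mapply(function(s, t) {
    ls <- loc[[s]]; lt <- loc[[t]]
    if (ls == "UNKNOWN" || lt == "UNKNOWN") NA else m[ls, lt]
  }, flags$source, flags$target)
  expect_equal(attr(flags, "fraction"), mean(brute, na.rm = TRUE))
})

test_that("interaction-type compatibility admits the four direct categories", {
  roster <- tibble::tibble(effector = "A", class_id = 1L)
  rec <- as_source_records(tibble::tibble(
    source = rep("A", 3), target = c("B", "C", "D"), directed = TRUE,
    interaction_type = c("Post-translational modification",
                         "Pathway regulation", "unknown")))
  net <- build_layered_network(roster, rec)
  flags <- interaction_type_compatibility(net)
  expect_true(flags$type_compatible[flags$target == "B"])
  expect_false(flags$type_compatible[flags$target == "C"])
  expect_true(is.na(flags$type_compatible[flags$target == "D"]))
  expect_equal(attr(flags, "fraction"), 0.5)

  # unrecognized category: format error listing admissible labels
  rec_bad <- rec; rec_bad$interaction_type[1] <- "Binding-ish"
  net_bad <- build_layered_network(roster, rec_bad)
  expect_error(interaction_type_compatibility(net_bad), "Binding-ish",
               class = "rasnet_format_error")

  # all-unknown network under exclude policy: fraction undefined
  rec_unk <- as_source_records(tibble::tibble(
    source = "A", target = "B", directed = TRUE))
  f_unk <- interaction_type_compatibility(build_layered_network(roster, rec_unk))
  expect_true(is.nan(attr(f_unk, "fraction")))
  expect_equal(attr(f_unk, "n_evaluated"), 0)
})

test_that("agreement cross-tabulates the two definitions", {
  syn <- generate_sources(small_synth_config(seed = 23))
  net <- syn$network
  lf <- localization_compatibility(net, syn$annotations)
  tf <- interaction_type_compatibility(net)
  rep_ <- compatibility_agreement(lf, tf)
  joint <- !is.na(lf$loc_compatible) & !is.na(tf$type_compatible)
  expect_equal(sum(rep_$agreement_table), sum(joint))
  expect_equal(rep_$agreement_fraction,
               mean(lf$loc_compatible[joint] == tf$type_compatible[joint]))
  # symmetric under swapping the two definitions
  lf2 <- tf; names(lf2)[names(lf2) == "type_compatible"] <- "loc_compatible"
  tf2 <- lf; names(tf2)[names(tf2) == "loc_compatible"] <- "type_compatible"
  attr(lf2, "fraction") <- attr(tf, "fraction")
  attr(tf2, "fraction") <- attr(lf, "fraction")
  rep_sw <- compatibility_agreement(lf2, tf2)
  expect_equal(rep_sw$agreement_fraction, rep_$agreement_fraction)

  # identical flag vectors agree fully; complementary flags not at all
  same <- compatibility_agreement(lf, transform(lf, type_compatible = loc_compatible))
  expect_equal(same$agreement_fraction, 1)
  opp <- compatibility_agreement(lf, transform(lf, type_compatible = !loc_compatible))
  expect_equal(opp$agreement_fraction, 0)
})

test_that("localization tables count one entry per layer membership", {
  roster <- tibble::tibble(effector = "RIN1", class_id = 6L)
  rec <- as_source_records(tibble::tibble(
    source = c("RIN1", "ABL1"), target = c("ABL1", "RIN1"), directed = TRUE))
  net <- build_layered_network(roster, rec)
  ann <- ann_for(RIN1 = "Cell membrane", ABL1 = "Cytosol")
  tab <- localization_by_layer(net, ann)
  # RIN1 occupies layers 0 and 2: two Cell membrane cells
  expect_equal(tab$n[tab$localization == "Cell membrane"], c(1L, 1L))
  expect_equal(tab$layer[tab$localization == "Cell membrane"], c(0L, 2L))

  # single L1 protein: exactly one non-zero cell beyond layer 0
  net2 <- build_layered_network(tiny_roster(),
                                as_source_records(tibble::tibble(
                                  source = "RAF1", target = "X", directed = TRUE)))
  ann2 <- ann_for(X = "Extracellular")
  tab2 <- localization_by_layer(net2, ann2)
  expect_equal(tab2$n[tab2$layer == 1], 1L)
  expect_equal(tab2$localization[tab2$layer == 1], "Extracellular")
  # proteins missing from the annotation table count as UNKNOWN
  expect_true(all(tab2$localization[tab2$layer == 0] == "UNKNOWN"))

  fun_tab <- localization_by_function(net, ann)
  expect_equal(sum(fun_tab$n), 2)
  expect_true(all(fun_tab$process15 == "Signaling"))
})

test_that("the planted localization gradient is recovered per layer", {
  cfg <- small_synth_config(seed = 29,
                            new_protein_prob = c(0.7, 0.9, 0.8))
  syn <- generate_sources(cfg)
  tab <- localization_by_layer(syn$network, syn$annotations)
  expected <- c(`1` = "Extracellular", `2` = "Cytosol", `3` = "Nucleus")
  for (k in 1:3) {
    sub <- tab[tab$layer == k, ]
    expect_equal(sub$localization[which.max(sub$n)], unname(expected[as.character(k)]))
  }
})
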