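herb3 <- c(A = "ATR", B = "CR", C = "ATR")

test_that("network construction filters to disease targets and prunes", {
  edges <- make_edge_list(c("A", "A", "B", "C"), c("T1", "T2", "T2", "X9"))
  net <- build_ct_network(edges, herb3, c("T1", "T2"))
  expect_setequal(net$compounds$id, c("A", "B"))
  expect_equal(nrow(net$edges), 3)
  expect_false("C" %in% net$compounds$id)
  expect_equal(net$degree_compound[["A"]], 2)
  expect_equal(net$degree_target[["T2"]], 2)

  expect_error(build_ct_network(edges, herb3, "Z1"), "empty network")
  expect_error(build_ct_network(edges, c(A = "ATR"), c("T1", "T2")),
               "without a herb label")
})

test_that("degree conservation holds on random networks", {
  set.seed(5)
  for (i in 1:30) {
    inst <- random_bipartite(sample(2:8, 1), sample(2:8, 1))
    net <- build_ct_network(inst$edges, inst$herb_map,
                            unique(inst$edges$target))
    expect_equal(sum(net$degree_compound), nrow(net$edges))
    expect_equal(sum(net$degree_target), nrow(net$edges))
  }
})

test_that("pruning matches a brute-force filter on small instances", {
  set.seed(9)
  for (i in 1:20) {
    inst <- random_bipartite(sample(2:5, 1), sample(2:5, 1))
    disease <- sample(unique(inst$edges$target),
                      max(1, sample.int(length(unique(inst$edges$target)), 1)))
    kept <- inst$edges[inst$edges$target %in% disease, ]
    kept <- kept[!duplicated(kept), ]
    if (nrow(kept) == 0) {
      expect_error(build_ct_network(inst$edges, inst$herb_map, disease),
                   "empty network")
    } else {
      net <- build_ct_network(inst$edges, inst$herb_map, disease)
      expect_equal(nrow(net$edges), nrow(kept))
      expect_setequal(net$compounds$id, unique(kept$compound))
      expect_setequal(net$targets, unique(kept$target))
    }
  }
})

test_that("degree summary reports the stated ratios and rounding", {
  sim <- generate_network(sim_config(11))
  net <- build_ct_network(sim$edges, sim$herbs, unique(sim$edges$target))
  summ <- degree_summary(net)
  expect_equal(summ$n_edges, 373)
  expect_equal(summ$n_compounds, 53)
  expect_equal(summ$n_targets, 62)
  expect_equal(summ$mean_targets_per_compound, 373 / 53)
  expect_equal(summ$mean_targets_per_compound_rounded, 7.0)
  expect_equal(summ$mean_compounds_per_target_rounded, 6.0)

  # complete bipartite 2 x 3
  edges <- make_edge_list(rep(c("A", "B"), each = 3), rep(c("T1", "T2", "T3"), 2))
  k23 <- degree_summary(build_ct_network(edges, c(A = "ATR", B = "CR"),
                                         c("T1", "T2", "T3")))
  expect_equal(k23$mean_targets_per_compound, 3.0)
  expect_equal(k23$mean_compounds_per_target, 2.0)
})

test_that("top-k degree ties break lexicographically", {
  edges <- make_edge_list(c("B", "A", "C", "C"), c("T1", "T2", "T1", "T2"))
  summ <- degree_summary(build_ct_network(edges,
                                          c(A = "ATR", B = "ATR", C = "CR"),
                                          c("T1", "T2")), k = 3)
  expect_equal(names(summ$top_compounds), c("C", "A", "B"))
  expect_equal(names(summ$top_targets), c("T1", "T2"))
})

test_that("target provenance classification follows herb reachability", {
  edges <- make_edge_list(c("A", "B", "A", "S"), c("T1", "T1", "T2", "T3"))
  net <- build_ct_network(edges, c(A = "ATR", B = "CR", S = "SHARED"),
                          c("T1", "T2", "T3"))
  cls <- classify_target_sources(net)
  labels <- setNames(cls$labels$label, cls$labels$target)
  expect_equal(labels[["T1"]], "SHARED")    # ATR + CR compound
  expect_equal(labels[["T2"]], "ATR_ONLY")
  expect_equal(labels[["T3"]], "SHARED")    # shared compound counts for both
  expect_equal(cls$fraction_shared, 100 * 2 / 3)
})

test_that("classification is invariant under edge and compound order", {
  set.seed(21)
  inst <- random_bipartite(6, 6)
  net <- build_ct_network(inst$edges, inst$herb_map,
                          unique(inst$edges$target))
  base <- classify_target_sources(net)
  for (i in 1:5) {
    perm <- inst$edges[sample.int(nrow(inst$edges)), ]
    net_p <- build_ct_network(perm, sample(inst$herb_map),
                              unique(perm$target))
    expect_equal(classify_target_sources(net_p)$labels[
      order(classify_target_sources(net_p)$labels$target), ],
      base$labels[order(base$labels$target), ], ignore_attr = TRUE)
  }
})

test_that("a shared fraction of 42 of 62 targets reports 67.7 percent", {
  sim <- generate_network(sim_config(11))
  net <- build_ct_network(sim$edges, sim$herbs, unique(sim$edges$target))
  cls <- classify_target_sources(net)
  expect_equal(sum(cls$labels$label == "SHARED"), 42)
  expect_equal(round_half_up(cls$fraction_shared, 1), 67.7)
})

test_that("target-pathway network keeps strictly sub-alpha terms", {
  enr <- data.frame(term = c("P1", "P2", "P3"),
                    p_adj = c(0.049, 0.05, 0.001),
                    genes = c("APP,TNF", "BAX", "APP,BAX,BCL2"),
                    stringsAsFactors = FALSE)
  tp <- build_tp_network(enr, alpha = 0.05)
  expect_setequal(unique(tp$edges$term), c("P1", "P3"))
  expect_equal(as.integer(tp$degree_pathway[["P3"]]), 3)
  expect_equal(as.integer(tp$degree_pathway[["P1"]]), 2)
  expect_equal(as.integer(tp$degree_target[["APP"]]), 2)

  empty <- build_tp_network(enr[0, ], alpha = 0.05)
  expect_equal(nrow(empty$edges), 0)
})

test_that("compound-target-organ network links each target to one organ", {
  edges <- make_edge_list(c("A", "A", "B"), c("T1", "T2", "T2"))
  net <- build_ct_network(edges, c(A = "ATR", B = "CR"), c("T1", "T2"))
  organs <- c(T1 = "whole blood", T2 = "whole blood")
  cto <- build_cto_network(net, organs)
  expect_equal(nrow(cto$to_edges), 2)
  expect_equal(as.integer(cto$degree_organ[["whole blood"]]), 2)

  expect_error(build_cto_network(net, c(T1 = "brain")), "T2")
})
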