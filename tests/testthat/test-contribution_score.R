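test_that("edge-share weights are degree fractions summing to one", {
  edges <- make_edge_list(c("A", "A", "B", "B", "B", "C"),
                          c("T1", "T2", "T1", "T2", "T3", "T3"))
  net <- build_ct_network(edges, c(A = "CR", B = "CR", C = "ATR"),
                          c("T1", "T2", "T3"))
  w <- omega(net)
  expect_equal(sum(w), 1)
  expect_equal(w[["A"]], 2 / 6)

  one <- build_ct_network(make_edge_list(c("A", "A"), c("T1", "T2")),
                          c(A = "CR"), c("T1", "T2"))
  expect_equal(unname(omega(one)), 1.0)

  two <- build_ct_network(make_edge_list(c("A", "B", "B", "B"),
                                         c("T1", "T1", "T2", "T3")),
                          c(A = "CR", B = "CR"), c("T1", "T2", "T3"))
  expect_equal(unname(omega(two)[c("A", "B")]), c(0.25, 0.75))
})

test_that("affinity index matches direct substitution into the formula", {
  expect_equal(affinity_index(0.75, 3, 0), 1.75)  # CR-only
  expect_equal(affinity_index(1.0, 0, 2), 0)      # ATR-only, degenerate
  expect_equal(affinity_index(0.5, 2, 2), 4.5)    # shared, guarded denom
  expect_error(affinity_index(0.5, 0, 0), "zero degree")
  expect_error(affinity_index(0.5, 2, 2, "as_printed_strict"),
               "zero denominator")
  expect_equal(affinity_index(0.5, 3, 1, "as_printed_strict"), 0.5 + 4 / 2)
})

test_that("toy network scores match hand evaluation", {
  # x, y CR-only; deg(x) = 1, deg(y) = 3; four targets of degree 1
  edges <- make_edge_list(c("X", "Y", "Y", "Y"), c("T1", "T2", "T3", "T4"))
  net <- build_ct_network(edges, c(X = "CR", Y = "CR"),
                          c("T1", "T2", "T3", "T4"))
  cs <- contribution_scores(net)
  sc <- cs$scores
  expect_equal(sc$cs[sc$id == "X"], 1 * 1.25 * 1)
  expect_equal(sc$cs[sc$id == "Y"], 3 * 1.75 * 3)
  expect_equal(sc$cs_percent[sc$id == "X"], 100 * 1.25 / 17)
  expect_equal(round_half_up(sc$cs_percent, 2), c(92.65, 7.35))
})

test_that("symmetric compounds split the score evenly", {
  edges <- make_edge_list(c("A", "A", "B", "B"), c("T1", "T2", "T1", "T2"))
  net <- build_ct_network(edges, c(A = "CR", B = "CR"), c("T1", "T2"))
  cs <- contribution_scores(net)
  expect_equal(cs$scores$cs_percent, c(50, 50))
})

test_that("scores match the brute-force oracle on random small networks", {
  set.seed(303)
  for (i in 1:50) {
    inst <- random_bipartite(sample(2:6, 1), sample(2:8, 1))
    net <- build_ct_network(inst$edges, inst$herb_map,
                            unique(inst$edges$target))
    want <- oracle_cs(net$edges, as.list(inst$herb_map))
    if (sum(want) == 0) {
      expect_error(contribution_scores(net), "undefined")
      next
    }
    cs <- contribution_scores(net)
    got <- setNames(cs$scores$cs, cs$scores$id)
    expect_equal(got[sort(names(got))], want[sort(names(want))])
    expect_equal(sum(cs$scores$cs_percent), 100, tolerance = 1e-9)
    expect_true(all(diff(cs$scores$cumulative_percent) >= -1e-12))
  }
})

test_that("results are invariant under input permutation", {
  set.seed(17)
  inst <- random_bipartite(5, 6)
  net <- build_ct_network(inst$edges, inst$herb_map,
                          unique(inst$edges$target))
  base <- contribution_scores(net)$scores
  perm <- inst$edges[sample.int(nrow(inst$edges)), ]
  net_p <- build_ct_network(perm, sample(inst$herb_map),
                            unique(perm$target))
  expect_equal(contribution_scores(net_p)$scores, base)
})

test_that("adding an edge never decreases a compound's score", {
  set.seed(77)
  for (i in 1:25) {
    inst <- random_bipartite(sample(2:5, 1), 6)
    net <- build_ct_network(inst$edges, inst$herb_map,
                            unique(inst$edges$target))
    cs0 <- try(contribution_scores(net), silent = TRUE)
    if (inherits(cs0, "try-error")) next
    cp <- sample(net$compounds$id, 1)
    free_t <- setdiff(sprintf("T%02d", 1:6),
                      inst$edges$target[inst$edges$compound == cp])
    if (length(free_t) == 0) next
    extra <- rbind(inst$edges,
                   data.frame(compound = cp, target = sample(free_t, 1)))
    net1 <- build_ct_network(extra, inst$herb_map, unique(extra$target))
    cs1 <- contribution_scores(net1)
    get <- function(cs) cs$scores$cs[cs$scores$id == cp]
    expect_gte(get(cs1), get(cs0) - 1e-12)
  }
})

test_that("coverage prefix and herb subtotals are consistent", {
  sim <- generate_network(sim_config(11))
  net <- build_ct_network(sim$edges, sim$herbs, unique(sim$edges$target))
  cs <- contribution_scores(net, coverage = 0.90)
  expect_gte(cs$coverage_percent, 90)
  expect_lt(cs$scores$cumulative_percent[cs$coverage_n - 1], 90)
  expect_equal(sum(unlist(cs$herb_subtotals)), 100, tolerance = 1e-9)
  expect_true(all(cs$herb_subtotals > 0))

  # shared compounds split between herbs per shared_split
  all_atr <- contribution_scores(net, shared_split = 1)
  shared_pct <- sum(cs$scores$cs_percent[cs$scores$herb == "SHARED"])
  expect_equal(all_atr$herb_subtotals[["ATR"]] - cs$herb_subtotals[["ATR"]],
               shared_pct / 2, tolerance = 1e-9)
})

test_that("an all-zero score total is reported as degenerate", {
  # a single ATR-only compound has omega = 1 and |A| = 0
  edges <- make_edge_list(c("A", "A"), c("T1", "T2"))
  net <- build_ct_network(edges, c(A = "ATR"), c("T1", "T2"))
  expect_error(contribution_scores(net), "undefined")
})
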