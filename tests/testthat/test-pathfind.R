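records_from_edges <- function(...) {
  e <- matrix(c(...), ncol = 2, byrow = TRUE)
  tibble::tibble(
    regulator_id = e[, 1], regulator_class = "TF",
    target_id = e[, 2], target_class = "TF", source_db = ""
  )
}

test_that("sources and sinks are relative to the searched network", {
  fix <- sts_fixture()
  expect_equal(find_sources(fix$network), c("AP2", "BMP-2"))
  expect_equal(find_sinks(fix$network), "TYMS")

  cyc <- build_network(records_from_edges("A", "B", "B", "A"))
  expect_length(find_sources(cyc), 0)
  expect_length(find_sinks(cyc), 0)

  # an isolated node is both source and sink
  net <- build_network(records_from_edges("A", "B"))
  net$nodes <- dplyr::bind_rows(net$nodes, tibble::tibble(node = "X", class = "gene"))
  expect_setequal(find_sources(net), c("A", "X"))
  expect_setequal(find_sinks(net), c("B", "X"))
})

test_that("length bounds are enforced in nodes, with walks abandoned not truncated", {
  net <- build_network(records_from_edges("A", "B", "B", "C", "A", "C"))
  paths <- enumerate_acyclic_paths(net, min_len = 3, max_len = 30)
  expect_equal(paths$path, "A->B->C") # A->C alone is only 2 nodes

  # chain of 5 nodes with max_len 4: the walk is abandoned, nothing truncated
  chain <- build_network(records_from_edges("A", "B", "B", "C", "C", "D", "D", "E"))
  expect_equal(nrow(enumerate_acyclic_paths(chain, min_len = 3, max_len = 4)), 0)
  expect_equal(enumerate_acyclic_paths(chain, min_len = 3, max_len = 5)$path,
               "A->B->C->D->E")
})

test_that("cyclic input is traversed without revisiting and without hanging", {
  net <- build_network(records_from_edges(
    "A", "B", "B", "A", # 2-cycle, unreachable from any source
    "D", "E"
  ))
  paths <- enumerate_acyclic_paths(net, min_len = 2, max_len = 30)
  expect_equal(paths$path, "D->E")

  # cycle hanging off a source->sink route is entered but never closed
  net2 <- build_network(records_from_edges(
    "S", "X", "X", "Y", "Y", "X", "Y", "T"
  ))
  p2 <- enumerate_acyclic_paths(net2, min_len = 2, max_len = 30)
  expect_equal(p2$path, "S->X->Y->T")
})

test_that("the merged sarcoma network yields the 24 recombined source-sink routes", {
  fix <- sts_fixture()
  paths <- enumerate_acyclic_paths(fix$network)
  expect_equal(nrow(paths), 24)
  expect_true(all(fix$paths$path %in% paths$path))
  # matches the independent igraph enumeration
  oracle <- igraph_path_oracle(
    as.data.frame(fix$network$edges[c("regulator", "target")]),
    fix$network$nodes$node
  )
  expect_equal(paths$path, oracle)
})

test_that("enumeration agrees with brute force and DP count on random DAGs", {
  withr::local_seed(404)
  n_checked <- 0
  for (i in 1:200) {
    n <- sample(4:12, 1)
    recs <- random_digraph_records(n, stats::runif(1, 0.1, 0.35), acyclic = TRUE)
    if (nrow(recs) == 0) next
    nodes <- nodes_of_records(recs)
    net <- build_network(recs)
    got <- enumerate_acyclic_paths(net, min_len = 2, max_len = n)
    oracle <- igraph_path_oracle(
      as.data.frame(net$edges[c("regulator", "target")]), nodes,
      min_len = 2, max_len = n
    )
    expect_equal(got$path, oracle)
    # without a binding length cap, the count matches topological-order DP
    dp <- dag_path_count_oracle(
      as.data.frame(net$edges[c("regulator", "target")]), nodes
    )
    expect_equal(nrow(got), dp)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 150)
})

test_that("emitted paths always satisfy the acyclic-path invariants", {
  withr::local_seed(405)
  for (i in 1:40) {
    n <- sample(5:12, 1)
    recs <- random_digraph_records(n, stats::runif(1, 0.1, 0.4), acyclic = i %% 2 == 0)
    if (nrow(recs) == 0) next
    net <- build_network(recs)
    srcs <- find_sources(net)
    snks <- find_sinks(net)
    edge_keys <- paste(net$edges$regulator, net$edges$target)
    paths <- enumerate_acyclic_paths(net, min_len = 2, max_len = 8)
    for (v in paths$nodes) {
      expect_false(anyDuplicated(v) > 0)
      expect_true(all(paste(v[-length(v)], v[-1]) %in% edge_keys))
      expect_true(v[1] %in% srcs)
      expect_true(v[length(v)] %in% snks)
      expect_true(length(v) >= 2 && length(v) <= 8)
    }
  }
})

test_that("raising the length cap never removes paths; raising the DE bar never adds", {
  withr::local_seed(406)
  recs <- random_digraph_records(12, 0.25)
  net <- build_network(recs)
  p_short <- enumerate_acyclic_paths(net, min_len = 2, max_len = 5)
  p_long <- enumerate_acyclic_paths(net, min_len = 2, max_len = 12)
  expect_true(all(p_short$path %in% p_long$path))

  de <- sample(net$nodes$node, 6)
  loose <- filter_by_de_fraction(p_long, de, min_fraction = 0.3)
  tight <- filter_by_de_fraction(p_long, de, min_fraction = 0.7)
  expect_true(all(tight$path %in% loose$path))
})

test_that("DE filtering is inclusive at the boundary and counts all node classes", {
  paths <- tibble::tibble(
    path = c("a->b->c->d", "x->y->z"),
    nodes = list(c("a", "b", "c", "d"), c("x", "y", "z")),
    length = c(4L, 3L)
  )
  kept <- filter_by_de_fraction(paths, c("a", "b", "y"), min_fraction = 0.5)
  expect_equal(kept$path, "a->b->c->d") # 2/4 passes, 1/3 does not
  expect_equal(kept$de_fraction, 0.5)
  expect_equal(nrow(filter_by_de_fraction(paths, character(), 0.5)), 0)
  expect_equal(nrow(filter_by_de_fraction(paths, character(), 0)), 2)
})

test_that("path populations count distinct nodes and their known members", {
  paths <- tibble::tibble(
    path = c("A->B->C", "A->C->D"),
    nodes = list(c("A", "B", "C"), c("A", "C", "D")),
    length = c(3L, 3L)
  )
  pop <- build_path_population(paths, known_ids = c("C", "D", "ZZZ"))
  expect_equal(pop$n_pop, 4L)
  expect_equal(pop$k_pop, 2L)
  expect_equal(build_path_population(paths, character())$k_pop, 0L)
  expect_error(build_path_population(paths[0, ], "C"), class = "regpath_contract_error")
  expect_error(path_population(10, 11), class = "regpath_argument_error")
})

test_that("scoring yields coverage ratios and hypergeometric p-values per path", {
  fix <- sts_fixture()
  scored <- score_paths(fix$paths, fix$known_ids, fix$population, de_ids = fix$de_ids)
  expect_equal(unique(scored$n_known), 7L)
  expect_equal(unique(scored$coverage_ratio), 0.7)
  expect_equal(unique(scored$de_fraction), 1)
  expect_equal(unique(scored$p_value), hypergeom_upper_tail(127, 27, 10, 7))

  # k = 0 gives coverage 0 and p = 1
  nul <- score_paths(fix$paths[1, ], character(), fix$population)
  expect_equal(nul$n_known, 0L)
  expect_equal(nul$coverage_ratio, 0)
  expect_equal(nul$p_value, 1)

  # a path longer than the population is a contract violation
  long_path <- tibble::tibble(path = "p", nodes = list(sprintf("n%d", 1:10)), length = 10L)
  expect_error(score_paths(long_path, character(), path_population(5, 2)),
               class = "regpath_argument_error")
})

test_that("significance selection is strict at alpha and sorted by p", {
  scored <- tibble::tibble(
    path = c("b", "a", "c"),
    nodes = list("b", "a", "c"),
    length = 1L,
    n_known = 0L, coverage_ratio = 0,
    p_value = c(0.0007, 0.001, 0.5)
  )
  sel <- select_significant(scored, alpha = 0.001)
  expect_equal(sel$path, "b") # p = 0.001 exactly is dropped
  expect_equal(nrow(select_significant(scored[0, ])), 0)
  expect_error(select_significant(scored, alpha = 0), class = "regpath_argument_error")
})

test_that("merging paths unions nodes and consecutive edges, idempotently", {
  fix <- sts_fixture()
  merged <- merge_paths(fix$paths, net = fix$network)
  expect_equal(nrow(merged$nodes), 15)
  expect_equal(nrow(merged$edges), 18)
  expect_equal(merged$nodes, fix$network$nodes)

  # idempotent and order-independent
  again <- merge_paths(fix$paths[sample(12), ], net = fix$network)
  expect_equal(again$edges[c("regulator", "target")],
               merged$edges[c("regulator", "target")])

  # merging a single path reproduces its own chain
  one <- merge_paths(fix$paths[1, ], net = fix$network)
  expect_equal(nrow(one$edges), 9)
  expect_equal(nrow(one$nodes), 10)

  expect_error(merge_paths(fix$paths[0, ]), class = "regpath_contract_error")
})
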