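mini_records <- function(...) {
  m <- matrix(c(...), ncol = 4, byrow = TRUE)
  tibble::tibble(
    regulator_id = m[, 1], regulator_class = m[, 2],
    target_id = m[, 3], target_class = m[, 4], source_db = ""
  )
}

test_that("building collapses duplicate edges, unions provenance and prunes self-loops", {
  recs <- tibble::tribble(
    ~regulator_id, ~regulator_class, ~target_id, ~target_class, ~source_db,
    "A", "TF", "B", "gene", "db1",
    "A", "TF", "B", "gene", "db2",
    "B", "TF", "B", "TF", "db1"
  )
  net <- build_network(recs)
  expect_equal(nrow(net$edges), 1)
  expect_equal(nrow(net$nodes), 2)
  expect_equal(net$edges$sources[[1]], c("db1", "db2"))
  expect_equal(net$n_self_loops_dropped, 1L)
  expect_equal(net$n_duplicates_collapsed, 1L)
})

test_that("node classes resolve with precedence TF > miRNA > gene", {
  # G is a regulatory target and also regulates a miRNA as a TF: stays TF
  recs <- mini_records(
    "A", "TF", "G", "gene",
    "G", "TF", "miR-1", "miRNA",
    "miR-1", "miRNA", "H", "gene"
  )
  net <- build_network(recs)
  cls <- setNames(net$nodes$class, net$nodes$node)
  expect_equal(unname(cls["G"]), "TF")
  expect_equal(unname(cls["miR-1"]), "miRNA")
  expect_equal(unname(cls["H"]), "gene")

  # a node recorded as both TF and miRNA is contradictory
  bad <- mini_records("X", "TF", "G1", "gene", "X", "miRNA", "G2", "gene")
  expect_error(build_network(bad), "X", class = "regpath_validation_error")
})

test_that("build_network is idempotent on its own edge dump", {
  fix <- sts_fixture()
  net <- fix$network
  dump <- tibble::tibble(
    regulator_id = net$edges$regulator,
    regulator_class = setNames(net$nodes$class, net$nodes$node)[net$edges$regulator],
    target_id = net$edges$target,
    target_class = setNames(net$nodes$class, net$nodes$node)[net$edges$target],
    source_db = ""
  )
  net2 <- build_network(dump)
  expect_equal(net2$nodes, net$nodes)
  expect_equal(net2$edges[c("regulator", "target")],
               net$edges[c("regulator", "target")])
})

test_that("one-hop extraction keeps seeds plus neighbours and the induced edges", {
  recs <- mini_records("A", "TF", "S", "TF", "S", "TF", "B", "TF", "B", "TF", "C", "gene")
  sub <- extract_active_subnetwork(build_network(recs), "S")
  expect_setequal(sub$nodes$node, c("A", "S", "B"))
  expect_setequal(paste(sub$edges$regulator, sub$edges$target), c("A S", "S B"))
  expect_equal(sub$mapped_seed_count, 1L)

  # induced mode retains edges among non-seed neighbours; incident mode does not
  recs2 <- mini_records("A", "TF", "S", "TF", "A", "TF", "B", "TF", "S", "TF", "B", "TF")
  net2 <- build_network(recs2)
  sub_ind <- extract_active_subnetwork(net2, "S")
  expect_equal(nrow(sub_ind$edges), 3)
  sub_inc <- extract_active_subnetwork(net2, "S", seed_incident_only = TRUE)
  expect_setequal(paste(sub_inc$edges$regulator, sub_inc$edges$target),
                  c("A S", "S B"))
})

test_that("unmapped seeds warn and yield an empty sub-network, not an error", {
  net <- build_network(mini_records("A", "TF", "B", "gene"))
  expect_warning(sub <- extract_active_subnetwork(net, c("Q", "R")),
                 class = "regpath_empty_subnetwork")
  expect_equal(nrow(sub$nodes), 0)
  expect_equal(sub$mapped_seed_count, 0L)
  expect_equal(sub$unmapped_seed_count, 2L)
})

test_that("induced subgraph soundness holds on random networks", {
  withr::local_seed(401)
  for (i in 1:20) {
    recs <- random_digraph_records(12, 0.15)
    if (nrow(recs) == 0) next
    net <- build_network(recs)
    seeds <- sample(net$nodes$node, 2)
    sub <- extract_active_subnetwork(net, seeds)
    # every sub-network edge exists in the parent
    expect_true(all(
      paste(sub$edges$regulator, sub$edges$target) %in%
        paste(net$edges$regulator, net$edges$target)
    ))
    # every non-seed node touches a seed (in either direction)
    touching <- unique(c(
      net$edges$target[net$edges$regulator %in% sub$seeds],
      net$edges$regulator[net$edges$target %in% sub$seeds]
    ))
    expect_true(all(setdiff(sub$nodes$node, sub$seeds) %in% touching))
    # degree conservation survives extraction
    d <- degrees(sub)
    expect_equal(sum(d$in_degree), nrow(sub$edges))
    expect_equal(sum(d$out_degree), nrow(sub$edges))
  }
})

test_that("degree summaries conserve edge counts and rank a star correctly", {
  recs <- mini_records("H", "TF", "L1", "gene", "H", "TF", "L2", "gene", "H", "TF", "L3", "gene")
  d <- degrees(build_network(recs))
  expect_equal(d$node[1], "H")
  expect_equal(d$out_degree[1], 3L)
  expect_equal(d$in_degree[1], 0L)
  expect_equal(d$total_degree[1], 3L)
  expect_equal(sum(d$in_degree), 3)
  expect_equal(sum(d$out_degree), 3)

  empty <- build_network(mini_records("A", "TF", "B", "gene")[0, ])
  expect_equal(nrow(degrees(empty)), 0)
})

test_that("degree histograms partition the node set by class", {
  fix <- sts_fixture()
  net <- fix$network
  hists <- lapply(c("TF", "miRNA", "gene"), function(cl) degree_distribution(net, cl))
  expect_equal(sum(vapply(hists, function(h) sum(h$count), 0)), nrow(net$nodes))
  expect_equal(sum(degree_distribution(net, "gene")$count),
               sum(net$nodes$class == "gene"))
  expect_error(degree_distribution(net, "protein"), class = "regpath_argument_error")
})

test_that("hub screening is inclusive at the threshold with a strict option", {
  # star with hub degree 10 exactly
  leaves <- sprintf("L%02d", 1:10)
  recs <- tibble::tibble(
    regulator_id = "HUB", regulator_class = "TF",
    target_id = leaves, target_class = "gene", source_db = ""
  )
  net <- build_network(recs)
  expect_equal(find_hubs(net)$node, "HUB")
  expect_equal(nrow(find_hubs(net, strict = TRUE)), 0)
  expect_equal(nrow(find_hubs(net, min_total_degree = 1)), nrow(net$nodes))
  expect_equal(nrow(find_hubs(net, min_total_degree = 0)), nrow(net$nodes))
})
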