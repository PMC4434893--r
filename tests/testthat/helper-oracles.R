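# Independent oracles used across the suite. Deliberately written without
# reference to the package's own code paths.

# --- exact big-integer arithmetic (base 1e7 limbs, little-endian) ----------
BIG_BASE <- 1e7

big_from_int <- function(x) {
  stopifnot(x >= 0, x < BIG_BASE)
  as.numeric(x)
}

big_trim <- function(a) {
  while (length(a) > 1 && a[length(a)] == 0) a <- a[-length(a)]
  a
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  out <- a + b
  carry <- 0
  for (i in seq_len(n)) {
    out[i] <- out[i] + carry
    carry <- out[i] %/% BIG_BASE
    out[i] <- out[i] %% BIG_BASE
  }
  if (carry > 0) out <- c(out, carry)
  big_trim(out)
}

big_mul_small <- function(a, s) {
  stopifnot(s >= 0, s < BIG_BASE)
  out <- numeric(0)
  carry <- 0
  for (i in seq_along(a)) {
    v <- a[i] * s + carry
    out[i] <- v %% BIG_BASE
    carry <- v %/% BIG_BASE
  }
  while (carry > 0) {
    out <- c(out, carry %% BIG_BASE)
    carry <- carry %/% BIG_BASE
  }
  big_trim(if (length(out) == 0) 0 else out)
}

big_div_small_exact <- function(a, s) {
  # exact division by a small integer, most-significant limb first
  out <- numeric(length(a))
  rem <- 0
  for (i in rev(seq_along(a))) {
    v <- rem * BIG_BASE + a[i]
    out[i] <- v %/% s
    rem <- v %% s
  }
  stopifnot(rem == 0)
  big_trim(out)
}

big_mul <- function(a, b) {
  out <- 0
  for (i in seq_along(b)) {
    if (b[i] == 0) next
    term <- big_mul_small(a, b[i])
    term <- c(rep(0, i - 1), term)
    out <- big_add(out, term)
  }
  out
}

big_to_double <- function(a) {
  # top limbs dominate; relative error ~1e-16
  v <- 0
  for (i in rev(seq_along(a))) v <- v * BIG_BASE + a[i]
  v
}

big_log10 <- function(a) {
  top <- big_to_double(tail(a, 3))
  log10(top) + 7 * (length(a) - min(length(a), 3))
}

big_ratio <- function(num, den) {
  # num / den as a double, robust to magnitudes far beyond double range
  l10 <- big_log10(num) - big_log10(den)
  10^l10
}

big_choose <- function(n, k) {
  # exact C(n, k) by multiplicative formula with exact small divisions
  stopifnot(k >= 0, k <= n)
  k <- min(k, n - k)
  acc <- big_from_int(1)
  if (k == 0) return(acc)
  for (i in seq_len(k)) {
    acc <- big_mul_small(acc, n - k + i)
    acc <- big_div_small_exact(acc, i)
  }
  acc
}

# exact-rational upper tail P(X >= k) for hypergeometric(N, K, n)
hyper_tail_oracle <- function(N, K, n, k) {
  hi <- min(K, n)
  if (k > hi) return(0)
  num <- 0
  for (j in seq(k, hi)) {
    if (n - j > N - K) next
    num <- big_add(num, big_mul(big_choose(K, j), big_choose(N - K, n - j)))
  }
  big_ratio(num, big_choose(N, n))
}

# exact-rational point mass P(X = j)
hyper_pmf_oracle <- function(N, K, n, j) {
  if (j > min(K, n) || n - j > N - K) return(0)
  big_ratio(big_mul(big_choose(K, j), big_choose(N - K, n - j)), big_choose(N, n))
}

# --- graph oracles ---------------------------------------------------------

# exhaustive source->sink simple-path enumeration through igraph, independent
# of the package's DFS
igraph_path_oracle <- function(edges_df, nodes, min_len = 3, max_len = 30) {
  g <- igraph::graph_from_data_frame(edges_df, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  indeg <- igraph::degree(g, mode = "in")
  outdeg <- igraph::degree(g, mode = "out")
  sources <- nodes[indeg[nodes] == 0]
  sinks <- nodes[outdeg[nodes] == 0]
  out <- list()
  for (s in sources) {
    for (t in setdiff(sinks, s)) {
      ps <- igraph::all_simple_paths(g, from = s, to = t, mode = "out")
      for (p in ps) {
        v <- names(p)
        if (length(v) >= min_len && length(v) <= max_len) {
          out[[length(out) + 1]] <- v
        }
      }
    }
  }
  sort(vapply(out, paste, "", collapse = "->"))
}

# source->sink path count on a DAG by dynamic programming over a topological
# order (no length cap)
dag_path_count_oracle <- function(edges_df, nodes) {
  g <- igraph::graph_from_data_frame(edges_df, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  topo <- names(igraph::topo_sort(g, mode = "out"))
  indeg <- igraph::degree(g, mode = "in")
  outdeg <- igraph::degree(g, mode = "out")
  ways <- setNames(numeric(length(nodes)), nodes)
  ways[names(indeg)[indeg == 0]] <- 1
  total <- 0
  for (v in topo) {
    succ <- names(igraph::neighbors(g, v, mode = "out"))
    for (w in succ) ways[w] <- ways[w] + ways[v]
    if (outdeg[v] == 0 && indeg[v] > 0) total <- total + ways[v]
  }
  # exclude isolated nodes (counted as trivial length-1 walks) and include
  # only true source->sink walks with >= 1 edge
  unname(total)
}

# random digraph as regulation records (all nodes class TF, which permits
# any ordered pair)
random_digraph_records <- function(n_nodes, p_edge, acyclic = FALSE) {
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- expand.grid(from = seq_len(n_nodes), to = seq_len(n_nodes))
  pairs <- pairs[pairs$from != pairs$to, ]
  if (acyclic) {
    perm <- sample(n_nodes)
    pairs <- pairs[match(pairs$from, perm) < match(pairs$to, perm), ]
  }
  keep <- pairs[stats::runif(nrow(pairs)) < p_edge, , drop = FALSE]
  tibble::tibble(
    regulator_id = nodes[keep$from], regulator_class = "TF",
    target_id = nodes[keep$to], target_class = "TF",
    source_db = ""
  )
}

nodes_of_records <- function(recs) {
  sort(unique(c(recs$regulator_id, recs$target_id)))
}
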