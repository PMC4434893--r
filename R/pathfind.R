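#' Source and sink nodes of a directed network
#'
#' Sources are nodes with in-degree zero; sinks have out-degree zero, both
#' evaluated on the network as given (for path mining on an active
#' sub-network, endpoints are therefore relative to the sub-network, not to
#' any parent network). An isolated node is both a source and a sink.
#'
#' @param net A `regulatory_network`.
#' @return A sorted character vector of node identifiers.
#' @export
find_sources <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  sort(setdiff(net$nodes$node, unique(net$edges$target)))
}

#' @rdname find_sources
#' @export
find_sinks <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  sort(setdiff(net$nodes$node, unique(net$edges$regulator)))
}

path_tibble <- function(node_lists) {
  tibble(
    path = map_chr(node_lists, paste, collapse = "->"),
    nodes = node_lists,
    length = lengths(node_lists)
  )
}

#' Enumerate acyclic source-to-sink paths
#'
#' Depth-first enumeration of every simple (repeat-free) directed path from a
#' zero-indegree node to a zero-outdegree node, representing a complete
#' regulatory cascade from an upstream regulator to a terminal target. Cyclic
#' input is permitted: a walk never revisits a node, so cycles are simply
#' never closed. A walk is abandoned as soon as it exceeds `max_len` nodes
#' (long paths are not truncated into shorter ones), and a terminal walk is
#' emitted only when its node count lies within `[min_len, max_len]`.
#'
#' @param net A `regulatory_network` (typically an active sub-network).
#' @param min_len Minimum path length in nodes (default 3, i.e. at least one
#'   intermediate node between source and sink).
#' @param max_len Maximum path length in nodes (default 30).
#' @return A tibble with one row per path, in lexicographic order of the
#'   path string: `path` (ids joined by `->`), `nodes` (list-column of
#'   character vectors), `length` (node count).
#' @examples
#' recs <- tibble::tribble(
#'   ~regulator_id, ~regulator_class, ~target_id, ~target_class, ~source_db,
#'   "A", "TF", "B", "TF", "", "B", "TF", "C", "gene", "", "A", "TF", "C", "gene", ""
#' )
#' enumerate_acyclic_paths(build_network(recs))
#' @export
enumerate_acyclic_paths <- function(net, min_len = 3, max_len = 30) {
  stopifnot(inherits(net, "regulatory_network"))
  if (min_len < 2) abort("`min_len` must be >= 2", class = "regpath_argument_error")
  if (max_len < min_len) abort("`max_len` must be >= `min_len`", class = "regpath_argument_error")

  node_names <- net$nodes$node
  nn <- length(node_names)
  if (nn == 0) return(path_tibble(list()))
  idx <- seq_len(nn)
  names(idx) <- node_names
  from <- idx[net$edges$regulator]
  to <- idx[net$edges$target]
  adj <- vector("list", nn)
  for (i in idx) adj[[i]] <- integer()
  if (length(from) > 0) {
    o <- order(from, to)
    adj_split <- split(to[o], from[o])
    for (nm in names(adj_split)) adj[[as.integer(nm)]] <- adj_split[[nm]]
  }
  is_sink <- lengths(adj) == 0
  sources <- idx[!node_names %in% net$edges$target]

  found <- new.env(parent = emptyenv())
  found$paths <- list()
  visited <- logical(nn)
  walk <- function(v, trail) {
    trail <- c(trail, v)
    len <- length(trail)
    if (is_sink[[v]]) {
      if (len >= min_len && len <= max_len) {
        found$paths[[length(found$paths) + 1L]] <- trail
      }
      return(invisible())
    }
    if (len == max_len) return(invisible()) # extending would exceed the cap
    visited[[v]] <<- TRUE
    for (w in adj[[v]]) {
      if (!visited[[w]]) walk(w, trail)
    }
    visited[[v]] <<- FALSE
    invisible()
  }
  for (s in sources) walk(s, integer())

  node_lists <- unique(map(found$paths, function(p) unname(node_names[p])))
  out <- path_tibble(node_lists)
  arrange(out, .data$path)
}

#' Filter paths by differential-expression content
#'
#' Retains paths in which at least `min_fraction` of the member nodes (all
#' classes — TFs, miRNAs and target genes alike) are differentially
#' expressed. The boundary is inclusive: a 4-node path with 2 DE members
#' passes the default 50% rule.
#'
#' @param paths Path tibble from [enumerate_acyclic_paths()].
#' @param de_ids Character vector of differentially expressed identifiers.
#' @param min_fraction Minimum DE fraction, in `[0, 1]` (default 0.5).
#' @return The subset of `paths` passing the filter, with a `de_fraction`
#'   column added.
#' @export
filter_by_de_fraction <- function(paths, de_ids, min_fraction = 0.5) {
  if (min_fraction < 0 || min_fraction > 1) {
    abort("`min_fraction` must lie in [0, 1]", class = "regpath_argument_error")
  }
  de_ids <- unique(as.character(de_ids))
  paths |>
    mutate(de_fraction = map_dbl(.data$nodes, function(v) mean(v %in% de_ids))) |>
    filter(.data$de_fraction >= min_fraction)
}

#' Path population for per-path enrichment
#'
#' The reference population against which individual paths are tested: all
#' distinct nodes appearing in any candidate path (`n_pop`) and how many of
#' those are known disease-associated (`k_pop`). Using the candidate-path
#' union — rather than the whole network — asks whether a given path
#' concentrates known nodes beyond what the candidate paths as a whole
#' already do.
#'
#' @param paths Non-empty path tibble.
#' @param known_ids Character vector of known disease-associated identifiers.
#' @return A `path_population` with fields `n_pop`, `k_pop`, `nodes`,
#'   `known_nodes`.
#' @seealso [path_population()] for fixing the counts directly.
#' @export
build_path_population <- function(paths, known_ids) {
  if (nrow(paths) == 0) {
    abort("Cannot build a path population from zero paths",
          class = "regpath_contract_error")
  }
  known_ids <- unique(as.character(known_ids))
  all_nodes <- sort(unique(unlist(paths$nodes)))
  known_in <- intersect(all_nodes, known_ids)
  path_population(length(all_nodes), length(known_in),
                  nodes = all_nodes, known_nodes = known_in)
}

#' Construct a path population from fixed counts
#'
#' @param n_pop Number of distinct nodes across all candidate paths.
#' @param k_pop Number of those nodes that are known disease-associated.
#' @param nodes,known_nodes Optional identifier vectors backing the counts.
#' @return A `path_population`.
#' @export
path_population <- function(n_pop, k_pop, nodes = NULL, known_nodes = NULL) {
  if (k_pop > n_pop) {
    abort("`k_pop` cannot exceed `n_pop`", class = "regpath_argument_error")
  }
  structure(
    list(n_pop = as.integer(n_pop), k_pop = as.integer(k_pop),
         nodes = nodes, known_nodes = known_nodes),
    class = "path_population"
  )
}

#' @export
print.path_population <- function(x, ...) {
  cat(sprintf("<path_population> %d candidate-path nodes, %d known disease-associated\n",
              x$n_pop, x$k_pop))
  invisible(x)
}

#' Score paths by disease coverage and hypergeometric significance
#'
#' For each path of length `L` containing `k` known disease-associated
#' nodes, computes the coverage ratio `k / L` — the fraction of the cascade
#' already implicated in the disease, read as the path's chance of being
#' operative — and the inclusive upper-tail hypergeometric probability of
#' observing at least `k` known nodes in a draw of `L` from the candidate
#' population (`n_pop` nodes, `k_pop` known).
#'
#' @param paths Path tibble (optionally already carrying a `de_fraction`
#'   column from [filter_by_de_fraction()]).
#' @param known_ids Character vector of known disease-associated identifiers.
#' @param population A `path_population`, normally built from the same
#'   candidate path set via [build_path_population()].
#' @param de_ids Optional DE identifiers; when supplied, `de_fraction` is
#'   (re)computed.
#' @return A tibble with columns `path`, `nodes`, `length`, `de_fraction`,
#'   `n_known`, `coverage_ratio`, `p_value`, sorted by ascending `p_value`
#'   then `path`.
#' @export
score_paths <- function(paths, known_ids, population, de_ids = NULL) {
  stopifnot(inherits(population, "path_population"))
  known_ids <- unique(as.character(known_ids))
  if (nrow(paths) > 0 && any(paths$length > population$n_pop)) {
    abort("Path length exceeds the population size; population and paths disagree",
          class = "regpath_argument_error")
  }
  out <- paths
  if (!is.null(de_ids)) {
    de_ids <- unique(as.character(de_ids))
    out$de_fraction <- map_dbl(out$nodes, function(v) mean(v %in% de_ids))
  } else if (!"de_fraction" %in% names(out)) {
    out$de_fraction <- NA_real_
  }
  out |>
    mutate(
      n_known = map_int(.data$nodes, function(v) sum(v %in% known_ids)),
      coverage_ratio = .data$n_known / .data$length,
      p_value = hypergeom_upper_tail(population$n_pop, population$k_pop,
                                     .data$length, .data$n_known)
    ) |>
    arrange(.data$p_value, .data$path)
}

#' Select significantly disease-enriched paths
#'
#' Retains scored paths with `p_value` strictly below `alpha` (default
#' 0.001), sorted by ascending p-value then path string. A path sitting
#' exactly at `alpha` is excluded.
#'
#' @param scored Scored path tibble from [score_paths()].
#' @param alpha Significance cutoff (default 0.001).
#' @return The significant subset, same columns as `scored`.
#' @export
select_significant <- function(scored, alpha = 0.001) {
  if (alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1)", class = "regpath_argument_error")
  }
  scored |>
    filter(.data$p_value < alpha) |>
    arrange(.data$p_value, .data$path)
}

#' Merge paths into a composite path graph
#'
#' Significant paths usually share components; merging them — node set as
#' the union of path nodes, edge set as the union of consecutive pairs —
#' yields a single composite regulatory path graph. Merging is idempotent
#' and order-independent. Node classes are inherited from `net` when given;
#' otherwise nodes with outgoing edges default to class `TF` and pure sinks
#' to `gene`.
#'
#' @param paths Path tibble (scored or not) with a `nodes` list-column.
#' @param net Optional `regulatory_network` supplying node classes (the
#'   network the paths were mined from).
#' @return A `regulatory_network`.
#' @export
merge_paths <- function(paths, net = NULL) {
  if (nrow(paths) == 0) {
    abort("Cannot merge zero paths", class = "regpath_contract_error")
  }
  edge_df <- dplyr::bind_rows(map(paths$nodes, function(v) {
    if (length(v) < 2) return(NULL)
    tibble(regulator = v[-length(v)], target = v[-1])
  })) |>
    distinct() |>
    arrange(.data$regulator, .data$target)
  all_nodes <- sort(unique(unlist(paths$nodes)))
  if (!is.null(net)) {
    stopifnot(inherits(net, "regulatory_network"))
    cls_map <- setNames(net$nodes$class, net$nodes$node)
    missing <- setdiff(all_nodes, names(cls_map))
    if (length(missing) > 0) {
      abort(paste0("Path nodes missing from `net`: ",
                   paste(head(missing, 10), collapse = ", ")),
            class = "regpath_argument_error")
    }
    cls <- unname(cls_map[all_nodes])
  } else {
    cls <- ifelse(all_nodes %in% edge_df$regulator, "TF", "gene")
  }
  nodes <- tibble(node = all_nodes, class = cls)
  edges <- mutate(edge_df, sources = map(seq_len(nrow(edge_df)), function(i) character()))
  new_regulatory_network(nodes, edges)
}
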