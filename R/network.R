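new_regulatory_network <- function(nodes, edges,
                                   n_self_loops_dropped = 0L,
                                   n_duplicates_collapsed = 0L,
                                   ..., class = character()) {
  structure(
    list(
      nodes = nodes,
      edges = edges,
      n_self_loops_dropped = as.integer(n_self_loops_dropped),
      n_duplicates_collapsed = as.integer(n_duplicates_collapsed),
      ...
    ),
    class = c(class, "regulatory_network")
  )
}

#' Build a curated regulatory network from regulation records
#'
#' Turns a table of directed regulations (see [read_regulations()]) into a
#' simple directed network: redundant edges between the same ordered pair are
#' collapsed into one (their provenance labels are unioned) and self-directed
#' loops are pruned. Each node receives a single class with precedence
#' `TF > miRNA > gene`, so a transcription-factor gene that is itself a
#' regulatory target keeps class `TF` — "gene" is reserved for non-TF
#' targets. A node recorded both as a TF and as a miRNA is contradictory and
#' raises an error naming the offenders.
#'
#' @param records Tibble of regulation records with columns `regulator_id`,
#'   `regulator_class`, `target_id`, `target_class`, and optionally
#'   `source_db`.
#' @return A `regulatory_network`: a list with a `nodes` tibble
#'   (`node`, `class`), an `edges` tibble (`regulator`, `target`, `sources`
#'   list-column), and the counts of dropped self-loops and collapsed
#'   duplicate edges.
#' @examples
#' recs <- tibble::tribble(
#'   ~regulator_id, ~regulator_class, ~target_id, ~target_class, ~source_db,
#'   "TFA", "TF", "G1", "gene", "db1",
#'   "TFA", "TF", "G1", "gene", "db2",
#'   "miR-1", "miRNA", "TFA", "TF", "db1"
#' )
#' build_network(recs)
#' @export
build_network <- function(records) {
  req <- c("regulator_id", "regulator_class", "target_id", "target_class")
  if (!all(req %in% names(records))) {
    abort("`records` must have regulation-record columns", class = "regpath_contract_error")
  }
  if (!"source_db" %in% names(records)) records$source_db <- ""
  bad_rc <- !records$regulator_class %in% c("TF", "miRNA")
  bad_tc <- !records$target_class %in% c("TF", "gene", "miRNA")
  bad_mm <- records$regulator_class == "miRNA" & records$target_class == "miRNA"
  if (any(bad_rc | bad_tc | bad_mm)) {
    abort("`records` contains invalid class tokens or miRNA -> miRNA rows",
          class = "regpath_validation_error")
  }

  # resolve node classes with precedence TF > miRNA > gene
  roles <- dplyr::bind_rows(
    tibble(node = records$regulator_id, class = records$regulator_class),
    tibble(node = records$target_id, class = records$target_class)
  ) |> distinct()
  conflict <- roles |>
    group_by(.data$node) |>
    summarise(
      is_tf = any(.data$class == "TF"),
      is_mirna = any(.data$class == "miRNA"),
      .groups = "drop"
    ) |>
    filter(.data$is_tf & .data$is_mirna)
  if (nrow(conflict) > 0) {
    abort(
      paste0("Nodes recorded as both TF and miRNA: ",
             paste(sort(conflict$node), collapse = ", ")),
      class = "regpath_validation_error"
    )
  }
  nodes <- roles |>
    group_by(node = .data$node) |>
    summarise(
      class = if (any(.data$class == "TF")) "TF"
              else if (any(.data$class == "miRNA")) "miRNA"
              else "gene",
      .groups = "drop"
    ) |>
    arrange(.data$node)

  self_loop <- records$regulator_id == records$target_id
  kept <- records[!self_loop, , drop = FALSE]
  edges <- kept |>
    group_by(regulator = .data$regulator_id, target = .data$target_id) |>
    summarise(
      sources = list(sort(unique(.data$source_db[nzchar(.data$source_db)]))),
      .groups = "drop"
    ) |>
    arrange(.data$regulator, .data$target)

  new_regulatory_network(
    nodes, edges,
    n_self_loops_dropped = sum(self_loop),
    n_duplicates_collapsed = nrow(kept) - nrow(edges)
  )
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf(
    "<regulatory_network> %d nodes (%d TF, %d miRNA, %d gene), %d edges\n",
    nrow(x$nodes),
    sum(x$nodes$class == "TF"), sum(x$nodes$class == "miRNA"),
    sum(x$nodes$class == "gene"), nrow(x$edges)
  ))
  if (x$n_self_loops_dropped > 0 || x$n_duplicates_collapsed > 0) {
    cat(sprintf("  pruned %d self-loop(s), collapsed %d duplicate edge(s)\n",
                x$n_self_loops_dropped, x$n_duplicates_collapsed))
  }
  invisible(x)
}

#' @export
print.active_subnetwork <- function(x, ...) {
  NextMethod()
  cat(sprintf("  anchored on %d mapped seed node(s) (%d seed id(s) did not map)\n",
              x$mapped_seed_count, x$unmapped_seed_count))
  invisible(x)
}

# igraph view of a network; nodes carry `class`, edges carry `relation`
# (reg/inh by regulator class) and `sources` (';'-joined provenance)
as_igraph <- function(net) {
  edges <- net$edges
  edf <- data.frame(
    from = edges$regulator, to = edges$target,
    stringsAsFactors = FALSE
  )
  if (nrow(edf) > 0) {
    edf$relation <- sif_relation(net)
    edf$sources <- map_chr(edges$sources, paste, collapse = ";")
  }
  vdf <- data.frame(name = net$nodes$node, class = net$nodes$class,
                    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
}

#' Extract the seed-anchored active sub-network
#'
#' Maps a set of seed identifiers (typically differentially expressed,
#' disease-relevant genes and miRNAs) onto the network and extracts every
#' node adjacent to a mapped seed, in either direction — neighbour discovery
#' ignores edge direction, but edge direction itself is preserved. By default
#' the result is the full induced subgraph on the retained nodes (all parent
#' edges among them); `seed_incident_only = TRUE` keeps only edges incident
#' to a seed, the narrower reading of one-hop extraction.
#'
#' Seed identifiers absent from the network are counted and reported, not
#' fatal. If no seed maps, an empty sub-network is returned with a warning.
#'
#' @param net A `regulatory_network`.
#' @param seed_ids Character vector of seed identifiers.
#' @param seed_incident_only Logical; restrict edges to those touching a
#'   seed node.
#' @return An `active_subnetwork`: a `regulatory_network` with additional
#'   fields `seeds` (the mapped seed ids), `mapped_seed_count` and
#'   `unmapped_seed_count`.
#' @export
extract_active_subnetwork <- function(net, seed_ids, seed_incident_only = FALSE) {
  stopifnot(inherits(net, "regulatory_network"))
  seed_ids <- unique(trimws(as.character(seed_ids)))
  seed_ids <- seed_ids[nzchar(seed_ids)]
  mapped <- sort(intersect(seed_ids, net$nodes$node))
  unmapped <- length(seed_ids) - length(mapped)
  if (length(mapped) == 0) {
    warn("No seed identifiers mapped to the network; returning an empty sub-network",
         class = "regpath_empty_subnetwork")
    return(new_regulatory_network(
      net$nodes[0, ], net$edges[0, ],
      seeds = character(), mapped_seed_count = 0L,
      unmapped_seed_count = as.integer(unmapped),
      class = "active_subnetwork"
    ))
  }
  touches_seed <- net$edges$regulator %in% mapped | net$edges$target %in% mapped
  neighbours <- unique(c(
    net$edges$target[net$edges$regulator %in% mapped],
    net$edges$regulator[net$edges$target %in% mapped]
  ))
  retained <- sort(union(mapped, neighbours))
  keep_edge <- if (seed_incident_only) {
    touches_seed
  } else {
    net$edges$regulator %in% retained & net$edges$target %in% retained
  }
  new_regulatory_network(
    filter(net$nodes, .data$node %in% retained),
    net$edges[keep_edge, , drop = FALSE],
    seeds = mapped,
    mapped_seed_count = length(mapped),
    unmapped_seed_count = as.integer(unmapped),
    class = "active_subnetwork"
  )
}

#' Node degree summaries
#'
#' In-degree, out-degree and total degree for every node of the network,
#' sorted by decreasing total degree (ties broken by node id). The sums of
#' in-degrees and of out-degrees both equal the edge count.
#'
#' @param net A `regulatory_network`.
#' @return A tibble with columns `node`, `class`, `in_degree`, `out_degree`,
#'   `total_degree`.
#' @export
degrees <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  if (nrow(net$nodes) == 0) {
    return(tibble(node = character(), class = character(),
                  in_degree = integer(), out_degree = integer(),
                  total_degree = integer()))
  }
  g <- as_igraph(net)
  tibble(
    node = igraph::vertex_attr(g, "name"),
    class = igraph::vertex_attr(g, "class"),
    in_degree = as.integer(igraph::degree(g, mode = "in")),
    out_degree = as.integer(igraph::degree(g, mode = "out"))
  ) |>
    mutate(total_degree = .data$in_degree + .data$out_degree) |>
    arrange(desc(.data$total_degree), .data$node)
}

#' Total-degree histogram for one node class
#'
#' Degree distributions of regulatory networks are typically strongly
#' right-skewed: most nodes have low degree and a few highly connected hubs
#' carry most links. This tabulates total degree for nodes of one class.
#'
#' @param net A `regulatory_network`.
#' @param node_class One of `"TF"`, `"miRNA"`, `"gene"`.
#' @return A tibble with columns `degree` and `count`; counts sum to the
#'   number of nodes of that class.
#' @export
degree_distribution <- function(net, node_class) {
  if (!is.character(node_class) || length(node_class) != 1 ||
      !node_class %in% c("TF", "miRNA", "gene")) {
    abort('`node_class` must be one of "TF", "miRNA", "gene"',
          class = "regpath_argument_error")
  }
  degrees(net) |>
    filter(.data$class == node_class) |>
    count(degree = .data$total_degree, name = "count") |>
    arrange(.data$degree)
}

#' Identify network hubs by total degree
#'
#' Screens nodes whose total degree (in + out) reaches a threshold as
#' potential hubs. The default rule is inclusive (`total_degree >= 10`), so
#' that nodes sitting exactly at the threshold are retained; set
#' `strict = TRUE` for a strictly-greater-than rule.
#'
#' @param net A `regulatory_network`.
#' @param min_total_degree Hub threshold on total degree (default 10).
#' @param strict Logical; require total degree strictly greater than the
#'   threshold instead of greater-or-equal.
#' @return A tibble of degree summaries (as [degrees()]) restricted to hubs,
#'   sorted by decreasing total degree then node id.
#' @export
find_hubs <- function(net, min_total_degree = 10, strict = FALSE) {
  d <- degrees(net)
  if (strict) {
    filter(d, .data$total_degree > min_total_degree)
  } else {
    filter(d, .data$total_degree >= min_total_degree)
  }
}
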