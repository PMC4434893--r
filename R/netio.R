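#' Read a curated regulation edge list
#'
#' Reads a delimited file of directed regulatory interactions, one regulation
#' per row: regulator id, regulator class, target id, target class, and an
#' optional provenance label (the source database). Regulator classes are
#' `TF` or `miRNA`; target classes are `TF`, `gene` or `miRNA`. miRNAs act
#' post-transcriptionally on transcripts, so a miRNA may target a TF or a
#' gene but never another miRNA; such rows are rejected with their line
#' number.
#'
#' Identifiers are whitespace-trimmed. Duplicate rows are retained here —
#' redundant edges are collapsed later by [build_network()]. Lines starting
#' with `#` and blank lines are skipped.
#'
#' @param file Path to the edge-list file.
#' @param header Logical; does the first non-comment line carry column names?
#' @param delim Field delimiter; tab by default, set `","` for CSV exports.
#' @param uppercase_genes Logical; when `TRUE`, gene/TF identifiers (rows
#'   where the class is not `miRNA`) are upper-cased, a convenience for
#'   symbol-mode inputs. miRNA names keep their case.
#' @return A tibble with columns `regulator_id`, `regulator_class`,
#'   `target_id`, `target_class`, `source_db`, one row per input row, in
#'   input order.
#' @seealso [write_regulations()], [build_network()]
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("TFA\tTF\tG1\tgene\tdb1", "miR-1\tmiRNA\tG2\tgene\tdb2"), tf)
#' read_regulations(tf)
#' @export
read_regulations <- function(file, header = FALSE, delim = "\t",
                             uppercase_genes = FALSE) {
  if (!file.exists(file)) {
    abort(paste0("Regulation file not found: ", file), class = "regpath_io_error")
  }
  lines <- readLines(file, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (header && length(lines) > 0) {
    lines <- lines[-1]
    line_no <- line_no[-1]
  }
  if (length(lines) == 0) {
    return(tibble(
      regulator_id = character(), regulator_class = character(),
      target_id = character(), target_class = character(),
      source_db = character()
    ))
  }
  fields <- strsplit(lines, delim, fixed = TRUE)
  fields <- map(fields, trimws)

  problems <- character()
  note <- function(msg) problems[[length(problems) + 1]] <<- msg

  recs <- map2(fields, line_no, function(f, ln) {
    if (length(f) < 4) {
      note(sprintf("line %d: expected >= 4 fields, found %d", ln, length(f)))
      return(NULL)
    }
    rc <- f[[2]]
    tc <- f[[4]]
    if (!rc %in% c("TF", "miRNA")) {
      note(sprintf("line %d: unknown regulator class '%s'", ln, rc))
      return(NULL)
    }
    if (!tc %in% c("TF", "gene", "miRNA")) {
      note(sprintf("line %d: unknown target class '%s'", ln, tc))
      return(NULL)
    }
    if (rc == "miRNA" && tc == "miRNA") {
      note(sprintf("line %d: miRNA -> miRNA regulation is not permitted", ln))
      return(NULL)
    }
    if (!nzchar(f[[1]]) || !nzchar(f[[3]])) {
      note(sprintf("line %d: empty regulator or target identifier", ln))
      return(NULL)
    }
    tibble(
      regulator_id = f[[1]], regulator_class = rc,
      target_id = f[[3]], target_class = tc,
      source_db = if (length(f) >= 5) f[[5]] else ""
    )
  })

  if (length(problems) > 0) {
    abort(
      c("Invalid rows in regulation file:", stats::setNames(head(problems, 10), rep("x", length(head(problems, 10))))),
      class = "regpath_parse_error"
    )
  }
  out <- dplyr::bind_rows(recs)
  if (uppercase_genes) {
    out <- out |>
      mutate(
        regulator_id = ifelse(.data$regulator_class == "miRNA",
                              .data$regulator_id, toupper(.data$regulator_id)),
        target_id = ifelse(.data$target_class == "miRNA",
                           .data$target_id, toupper(.data$target_id))
      )
  }
  out
}

#' Write a regulation edge list
#'
#' Inverse of [read_regulations()]: writes a 5-column tab-separated file with
#' a header row, preserving row order, so that reading it back with
#' `read_regulations(file, header = TRUE)` reproduces the records
#' field-for-field.
#'
#' @param records Tibble of regulation records as returned by
#'   [read_regulations()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_regulations <- function(records, file) {
  req <- c("regulator_id", "regulator_class", "target_id", "target_class", "source_db")
  if (!all(req %in% names(records))) {
    abort("`records` must have the regulation-record columns", class = "regpath_contract_error")
  }
  readr::write_tsv(records[req], file)
  invisible(file)
}

#' Read a plain-text identifier list
#'
#' One identifier per line; `#` starts a comment line and blank lines are
#' skipped. Used for seed lists (differentially expressed, disease-relevant
#' genes and miRNAs), known disease-association lists, and DE lists.
#'
#' @param file Path to the list file.
#' @return A character vector of unique, trimmed identifiers.
#' @examples
#' f <- tempfile()
#' writeLines(c("# known genes", "TP53", "MYC", "TP53"), f)
#' read_id_list(f)
#' @export
read_id_list <- function(file) {
  if (!file.exists(file)) {
    abort(paste0("ID list not found: ", file), class = "regpath_io_error")
  }
  x <- trimws(readLines(file, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

#' Write a plain-text identifier list
#'
#' @param ids Character vector of identifiers.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_id_list <- function(ids, file) {
  writeLines(unique(trimws(as.character(ids))), file)
  invisible(file)
}

sif_relation <- function(net) {
  cls <- setNames(net$nodes$class, net$nodes$node)
  ifelse(cls[net$edges$regulator] == "miRNA", "inh", "reg")
}

#' Write a network in SIF format
#'
#' Simple interaction format, one edge per line: `regulator relation target`.
#' The relation token is `reg` for edges driven by a TF and `inh` for edges
#' driven by a miRNA (miRNA regulation is drawn as inhibition of the target).
#' Isolated nodes are emitted as single-token lines. Output order is
#' deterministic: edges sorted lexicographically, then isolated nodes.
#'
#' @param net A `regulatory_network`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @seealso [read_sif()], [write_graphml()]
#' @export
write_sif <- function(net, file) {
  stopifnot(inherits(net, "regulatory_network"))
  edge_lines <- character()
  if (nrow(net$edges) > 0) {
    rel <- sif_relation(net)
    edge_lines <- paste(net$edges$regulator, rel, net$edges$target)
    edge_lines <- sort(edge_lines)
  }
  connected <- unique(c(net$edges$regulator, net$edges$target))
  isolated <- sort(setdiff(net$nodes$node, connected))
  writeLines(c(edge_lines, isolated), file)
  invisible(file)
}

#' Read a SIF file
#'
#' Returns the edge table of a SIF file; isolated nodes (single-token lines)
#' appear as rows with `NA` relation and target.
#'
#' @param file Path to a SIF file.
#' @return A tibble with columns `regulator`, `relation`, `target`.
#' @export
read_sif <- function(file) {
  if (!file.exists(file)) {
    abort(paste0("SIF file not found: ", file), class = "regpath_io_error")
  }
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  dplyr::bind_rows(map(fields, function(f) {
    if (length(f) == 1) {
      tibble(regulator = f[[1]], relation = NA_character_, target = NA_character_)
    } else {
      tibble(regulator = f[[1]], relation = f[[2]], target = f[[3]])
    }
  }))
}

#' Export a network to GraphML
#'
#' Writes a GraphML file with node attribute `class` (TF/miRNA/gene) and edge
#' attributes `relation` (reg/inh) and `sources` (provenance labels joined by
#' `;`), suitable for Cytoscape import.
#'
#' @param net A `regulatory_network`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_graphml <- function(net, file) {
  stopifnot(inherits(net, "regulatory_network"))
  g <- as_igraph(net)
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
}

#' Read a GraphML network export
#'
#' Re-imports a network written by [write_graphml()], restoring node classes
#' and edge provenance.
#'
#' @param file Path to a GraphML file.
#' @return A `regulatory_network`.
#' @export
read_graphml <- function(file) {
  if (!file.exists(file)) {
    abort(paste0("GraphML file not found: ", file), class = "regpath_io_error")
  }
  g <- igraph::read_graph(file, format = "graphml")
  nodes <- tibble(
    node = igraph::vertex_attr(g, "name"),
    class = igraph::vertex_attr(g, "class") %||% rep("gene", igraph::vcount(g))
  ) |> arrange(.data$node)
  el <- igraph::as_edgelist(g, names = TRUE)
  src <- igraph::edge_attr(g, "sources") %||% rep("", nrow(el))
  edges <- tibble(
    regulator = el[, 1], target = el[, 2],
    sources = map(src, function(s) if (nzchar(s)) strsplit(s, ";", fixed = TRUE)[[1]] else character())
  ) |> arrange(.data$regulator, .data$target)
  new_regulatory_network(nodes, edges)
}

#' Write a scored-path table
#'
#' Writes scored paths as TSV with columns `path` (node identifiers joined by
#' `->`), `path_length`, `n_known`, `de_fraction`, `coverage_ratio`,
#' `p_value`. Rows are sorted by ascending p-value, ties broken
#' lexicographically by the path string, so output is diff-stable.
#'
#' @param scored Tibble of scored paths from [score_paths()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_paths_table <- function(scored, file) {
  req <- c("path", "length", "n_known", "de_fraction", "coverage_ratio", "p_value")
  if (!all(req %in% names(scored))) {
    abort(
      "Paths must be scored (score_paths()) before writing a paths table",
      class = "regpath_contract_error"
    )
  }
  out <- scored |>
    arrange(.data$p_value, .data$path) |>
    select(path = "path", path_length = "length", n_known = "n_known",
           de_fraction = "de_fraction", coverage_ratio = "coverage_ratio",
           p_value = "p_value")
  readr::write_tsv(out, file)
  invisible(file)
}
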