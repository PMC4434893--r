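#' Analysis thresholds
#'
#' The tunable cutoffs of the workflow, with the defaults the method is
#' normally run at: hubs at total degree 10 (inclusive), paths of 3 to 30
#' nodes, at least 50% differentially expressed members per path, and a
#' strict per-path significance cutoff of 0.001.
#'
#' @param hub_min_total_degree Hub threshold on total degree.
#' @param min_path_len,max_path_len Path length bounds in nodes.
#' @param de_fraction_min Minimum DE fraction per path, in `[0, 1]`.
#' @param alpha Per-path significance cutoff, in `(0, 1)`; strict.
#' @return A validated `path_thresholds` list.
#' @export
path_thresholds <- function(hub_min_total_degree = 10, min_path_len = 3,
                            max_path_len = 30, de_fraction_min = 0.5,
                            alpha = 0.001) {
  if (min_path_len < 2) abort("`min_path_len` must be >= 2", class = "regpath_argument_error")
  if (max_path_len < min_path_len) {
    abort("`max_path_len` must be >= `min_path_len`", class = "regpath_argument_error")
  }
  if (de_fraction_min < 0 || de_fraction_min > 1) {
    abort("`de_fraction_min` must lie in [0, 1]", class = "regpath_argument_error")
  }
  if (alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1)", class = "regpath_argument_error")
  }
  structure(
    list(hub_min_total_degree = hub_min_total_degree,
         min_path_len = as.integer(min_path_len),
         max_path_len = as.integer(max_path_len),
         de_fraction_min = de_fraction_min, alpha = alpha),
    class = "path_thresholds"
  )
}

as_records <- function(x) {
  if (is.character(x) && length(x) == 1) read_regulations(x) else as_tibble(x)
}

as_ids <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) read_id_list(x) else as.character(x)
}

#' Run the full regulatory-path workflow
#'
#' Wires the stages together: build the curated network, extract the
#' seed-anchored active sub-network, summarise degrees and hubs, test the
#' sub-network's enrichment for known disease nodes, enumerate and filter
#' acyclic source-to-sink paths, score them against the candidate-path
#' population, select the significant ones and merge them into a composite
#' path. All artifacts are written under `out_dir`; identical inputs produce
#' identical outputs (only `run.log` carries timestamps).
#'
#' Files written: `net.graphml`, `subnet.graphml`, `hubs.tsv`,
#' `enrichment.json`, `paths.tsv`, `merged.sif` (only when something is
#' significant) and `run.log`.
#'
#' @param regulations Regulation records: a tibble or a path to a TSV for
#'   [read_regulations()].
#' @param seeds,known,de Identifier vectors or paths to ID-list files:
#'   seeds anchoring the sub-network, known disease-associated ids, and
#'   differentially expressed ids.
#' @param out_dir Output directory (created if absent); `NULL` to skip
#'   writing files.
#' @param thresholds A [path_thresholds()] object.
#' @param seed_incident_only Passed to [extract_active_subnetwork()].
#' @param population Optional fixed [path_population()]; by default it is
#'   built from the DE-filtered candidate paths.
#' @return Invisibly, a list with components `network`, `subnetwork`,
#'   `degrees`, `hubs`, `enrichment`, `candidate_paths`, `scored`,
#'   `significant`, `merged` (NULL when nothing is significant), and
#'   `counts` (the stage-by-stage summary written to the log).
#' @export
run_pipeline <- function(regulations, seeds, known, de, out_dir = NULL,
                         thresholds = path_thresholds(),
                         seed_incident_only = FALSE, population = NULL) {
  stopifnot(inherits(thresholds, "path_thresholds"))
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines[[length(log_lines) + 1]] <<- line
    inform(line)
  }

  records <- as_records(regulations)
  seeds <- as_ids(seeds)
  known <- as_ids(known)
  de <- as_ids(de)

  net <- build_network(records)
  say("network: %d nodes, %d edges (%d self-loops pruned, %d duplicates collapsed)",
      nrow(net$nodes), nrow(net$edges),
      net$n_self_loops_dropped, net$n_duplicates_collapsed)

  sub <- extract_active_subnetwork(net, seeds, seed_incident_only = seed_incident_only)
  say("subnetwork: %d nodes, %d edges from %d mapped seed(s) (%d unmapped)",
      nrow(sub$nodes), nrow(sub$edges), sub$mapped_seed_count, sub$unmapped_seed_count)

  deg <- degrees(sub)
  hubs <- find_hubs(sub, min_total_degree = thresholds$hub_min_total_degree)
  say("hubs: %d node(s) at total degree >= %s",
      nrow(hubs), format(thresholds$hub_min_total_degree))

  enr <- node_set_enrichment(net$nodes$node, known, sub$nodes$node)
  say("subnetwork enrichment: k = %d / n = %d vs K = %d / N = %d, p = %.4g",
      enr$k, enr$n, enr$K, enr$N, enr$p_value)

  cand_all <- enumerate_acyclic_paths(sub, min_len = thresholds$min_path_len,
                                      max_len = thresholds$max_path_len)
  say("candidate paths: %d", nrow(cand_all))
  cand <- filter_by_de_fraction(cand_all, de, min_fraction = thresholds$de_fraction_min)
  say("candidate paths after DE filter (>= %.2f): %d",
      thresholds$de_fraction_min, nrow(cand))

  scored <- cand[0, ]
  signif_paths <- cand[0, ]
  merged <- NULL
  if (nrow(cand) > 0) {
    # the per-path reference population spans ALL potential paths; the DE
    # filter selects which of them go forward for scoring
    pop <- population %||% build_path_population(cand_all, known)
    say("path population: %d nodes, %d known", pop$n_pop, pop$k_pop)
    scored <- score_paths(cand, known, pop)
    signif_paths <- select_significant(scored, alpha = thresholds$alpha)
    say("significant paths (p < %g): %d", thresholds$alpha, nrow(signif_paths))
    if (nrow(signif_paths) > 0) {
      merged <- merge_paths(signif_paths, net = sub)
      say("merged composite path: %d nodes, %d edges",
          nrow(merged$nodes), nrow(merged$edges))
    }
  } else {
    say("no candidate paths; nothing to score")
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_graphml(net, file.path(out_dir, "net.graphml"))
    write_graphml(sub, file.path(out_dir, "subnet.graphml"))
    readr::write_tsv(hubs, file.path(out_dir, "hubs.tsv"))
    jsonlite::write_json(
      tidy(enr), file.path(out_dir, "enrichment.json"),
      auto_unbox = TRUE, digits = NA
    )
    empty_scored <- tibble(
      path = character(), nodes = list(), length = integer(),
      de_fraction = double(), n_known = integer(),
      coverage_ratio = double(), p_value = double()
    )
    write_paths_table(if (nrow(scored) > 0) scored else empty_scored,
                      file.path(out_dir, "paths.tsv"))
    if (!is.null(merged)) write_sif(merged, file.path(out_dir, "merged.sif"))
    writeLines(
      c(sprintf("# run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")), log_lines),
      file.path(out_dir, "run.log")
    )
  }

  invisible(list(
    network = net, subnetwork = sub, degrees = deg, hubs = hubs,
    enrichment = enr, candidate_paths = cand, scored = scored,
    significant = signif_paths, merged = merged, counts = log_lines
  ))
}

#' Read a pipeline configuration file
#'
#' YAML configuration mirroring the [run_pipeline()] arguments: input paths
#' (`regulations`, `seeds`, `known`, `de`), `out_dir`, and any of the
#' [path_thresholds()] fields. Unknown keys are rejected.
#'
#' @param file Path to a YAML file.
#' @return A list with elements `regulations`, `seeds`, `known`, `de`,
#'   `out_dir`, `thresholds`, `seed_incident_only`.
#' @export
read_run_config <- function(file) {
  if (!file.exists(file)) {
    abort(paste0("Config file not found: ", file), class = "regpath_io_error")
  }
  raw <- yaml::read_yaml(file)
  thr_keys <- c("hub_min_total_degree", "min_path_len", "max_path_len",
                "de_fraction_min", "alpha")
  io_keys <- c("regulations", "seeds", "known", "de", "out_dir",
               "seed_incident_only")
  unknown <- setdiff(names(raw), c(thr_keys, io_keys))
  if (length(unknown) > 0) {
    abort(paste0("Unknown config keys: ", paste(unknown, collapse = ", ")),
          class = "regpath_argument_error")
  }
  base <- dirname(normalizePath(file))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  list(
    regulations = resolve(raw$regulations),
    seeds = resolve(raw$seeds),
    known = resolve(raw$known),
    de = resolve(raw$de),
    out_dir = resolve(raw$out_dir),
    thresholds = do.call(path_thresholds, raw[intersect(names(raw), thr_keys)]),
    seed_incident_only = isTRUE(raw$seed_incident_only)
  )
}
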