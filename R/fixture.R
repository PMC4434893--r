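sts_path_strings <- function() {
  mid1 <- c("hsa-miR-26a", "hsa-miR-221")
  mid2 <- c("hsa-miR-22", "hsa-miR-19a", "hsa-miR-302c")
  paths <- list()
  for (a in mid1) {
    for (b in mid2) {
      paths[[length(paths) + 1]] <- c(
        "AP2", "MYC", a, "PTEN", b, "ESR1", "FOS", "TP53", "hsa-miR-215", "TYMS"
      )
      paths[[length(paths) + 1]] <- c(
        "BMP-2", "hsa-miR-24", "MYC", a, "PTEN", b, "ESR1", "TP53",
        "hsa-miR-215", "TYMS"
      )
    }
  }
  paths[order(map_chr(paths, paste, collapse = "->"))]
}

sts_classes <- function() {
  c(
    "AP2" = "TF", "BMP-2" = "TF", "MYC" = "TF", "PTEN" = "TF",
    "ESR1" = "TF", "FOS" = "TF", "TP53" = "TF",
    "hsa-miR-24" = "miRNA", "hsa-miR-26a" = "miRNA", "hsa-miR-221" = "miRNA",
    "hsa-miR-22" = "miRNA", "hsa-miR-19a" = "miRNA", "hsa-miR-302c" = "miRNA",
    "hsa-miR-215" = "miRNA", "TYMS" = "gene"
  )
}

#' Curated soft tissue sarcoma path example
#'
#' A small curated example drawn from published work on TF-miRNA regulatory
#' crosstalk in soft tissue sarcoma (STS) metastasis: twelve significant
#' 10-node regulatory cascades that share components and merge into a single
#' 15-node, 18-edge composite path running from the sources `AP2` and
#' `BMP-2` to the terminal target `TYMS`, with the chemotherapy-relevant
#' `TP53 -> hsa-miR-215 -> TYMS` tail common to every cascade.
#'
#' Nine of the fifteen nodes are known STS-associated (`AP2`, `BMP-2`,
#' `MYC`, `hsa-miR-26a`, `hsa-miR-221`, `PTEN`, `ESR1`, `TP53`, `TYMS`), so
#' each 10-node cascade contains exactly 7 known nodes. The per-path
#' enrichment population is fixed at 127 candidate-path nodes of which 27
#' are known STS-associated, the values the cascades were originally scored
#' against. All fifteen nodes are marked differentially expressed by
#' convention (their individual DE status is not part of the published
#' tables), so the 50% DE filter is non-restrictive when replaying the
#' example.
#'
#' @return A list with elements:
#'   \describe{
#'     \item{regulations}{18-row regulation tibble (the distinct consecutive
#'       pairs of the twelve cascades).}
#'     \item{network}{the merged 15-node `regulatory_network`.}
#'     \item{paths}{tibble of the twelve cascades in path-table form.}
#'     \item{known_ids}{the nine known STS-associated identifiers.}
#'     \item{de_ids}{all fifteen node identifiers.}
#'     \item{population}{`path_population(127, 27)`.}
#'   }
#' @examples
#' fix <- sts_fixture()
#' score_paths(fix$paths, fix$known_ids, fix$population)
#' @export
sts_fixture <- function() {
  paths <- sts_path_strings()
  cls <- sts_classes()
  regulations <- dplyr::bind_rows(map(paths, function(v) {
    tibble(regulator_id = v[-length(v)], target_id = v[-1])
  })) |>
    distinct() |>
    mutate(
      regulator_class = unname(cls[.data$regulator_id]),
      target_class = unname(cls[.data$target_id]),
      source_db = "curated"
    ) |>
    select("regulator_id", "regulator_class", "target_id", "target_class",
           "source_db") |>
    arrange(.data$regulator_id, .data$target_id)

  known <- c("AP2", "BMP-2", "MYC", "hsa-miR-26a", "hsa-miR-221",
             "PTEN", "ESR1", "TP53", "TYMS")
  list(
    regulations = regulations,
    network = build_network(regulations),
    paths = path_tibble(paths),
    known_ids = sort(known),
    de_ids = sort(names(cls)),
    population = path_population(127L, 27L)
  )
}
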