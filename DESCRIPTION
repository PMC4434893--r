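Package: regpath
Title: Mining Significant Acyclic Paths in TF-miRNA Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds curated directed transcription-factor (TF) and microRNA
    (miRNA) regulatory networks from edge lists, extracts seed-anchored active
    sub-networks, characterises degree topology and hubs, and discovers
    statistically significant acyclic regulatory paths running from
    zero-indegree sources to zero-outdegree sinks. Candidate paths are filtered
    by their fraction of differentially expressed members, scored by the
    coverage ratio of known disease-associated genes and miRNAs, and assessed
    with an exact upper-tail hypergeometric test. Includes a layered synthetic
    network generator with planted benchmark paths, a curated soft tissue
    sarcoma example network, readers and writers for regulation TSV, SIF and
    GraphML interchange, and a full pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
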