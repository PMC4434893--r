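---
title: "Mining significant acyclic paths in TF–miRNA regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining significant acyclic paths in TF-miRNA regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(regpath)
library(dplyr)
```

## The problem

Transcription factors (TFs) regulate genes and microRNAs; miRNAs in turn
repress TFs and other transcripts. Disease processes such as tumour
metastasis are driven not by single regulators but by cascades through this
two-layer regulatory system. Given (i) a curated collection of directed
regulations (TF→gene, TF→miRNA, miRNA→gene/TF), (ii) a list of
differentially expressed (DE), disease-relevant seed molecules, and (iii) a
list of genes and miRNAs already known to be associated with the disease,
`regpath` asks: *which complete regulatory cascades — from an upstream
regulator nobody regulates, down to a terminal target that regulates nothing
— are unexpectedly rich in known disease molecules?*

The workflow has four stages, each an ordinary function on data frames:

1. **Network construction** (`build_network()`): redundant edges between the
   same ordered pair are collapsed (provenance is unioned) and self-loops are
   pruned, giving a simple directed graph with one class per node
   (`TF`/`miRNA`/`gene`).
2. **Active sub-network extraction** (`extract_active_subnetwork()`): the
   seeds are mapped onto the network and every immediate neighbour —
   ignoring direction for *discovery* but preserving it in the result — is
   pulled in.
3. **Topology** (`degrees()`, `find_hubs()`): degree summaries and hub
   screening at total degree ≥ 10.
4. **Path mining** (`enumerate_acyclic_paths()` → `filter_by_de_fraction()` →
   `build_path_population()` → `score_paths()` → `select_significant()` →
   `merge_paths()`): the statistical core, described next.

## The path model and its score

A *path* is a simple (repeat-free) directed walk from a **source**
(in-degree 0) to a **sink** (out-degree 0) of the searched network, with
length counted in nodes and bounded to 3–30 by default. Endpoints are
relative to the network being searched: when mining an active sub-network,
"source" means unregulated *within that sub-network*. Length-2 source→sink
hops carry no intermediate biology and are excluded by the default floor of
3; the cap of 30 bounds the depth-first walk, and a walk that exceeds it is
abandoned, never truncated (a truncated walk would end at a non-sink).

Paths are first filtered for activity: at least 50% of a path's members
(all classes count — TF genes are genes) must be differentially expressed,
boundary inclusive.

Each path of length $L$ containing $k$ known disease-associated members is
then scored two ways:

* **coverage ratio** $c = k / L$, a direct interpretable measure of how much
  of the cascade is already implicated in the disease; and
* an **inclusive upper-tail hypergeometric probability**
  $$p = \sum_{j=k}^{\min(K,n)} \frac{\binom{K}{j}\binom{N-K}{L-j}}{\binom{N}{L}},$$
  where the reference population $(N, K)$ is the union of nodes over *all*
  candidate paths and its known subset — not the whole network. This asks
  whether the path concentrates known molecules beyond what the candidate
  paths collectively already do. The population is computed *before* the DE
  filter (the filter selects which paths go forward; it does not define the
  reference universe), and it is overridable via `path_population()` when a
  published population is to be replayed.

Paths with $p$ strictly below $\alpha = 0.001$ are reported, and since
significant paths usually share segments, `merge_paths()` unions their nodes
and consecutive edges into one composite path graph.

## Tail conventions

`hypergeom_upper_tail()` is the inclusive survival function
$P(X \ge k)$ computed through `stats::phyper(..., lower.tail = FALSE)`,
which works in log space internally; tails near $10^{-10}$ and far below are
exact to double precision rather than underflowing. Inclusive $P(X \ge k)$
is the standard over-representation convention and is the default
everywhere.

Published enrichment figures are not always tails, however: some
correspond to the point mass $P(X = k)$ at the observed count. For the
curated example shipped with the package, the sub-network enrichment figure
of $3.12\times10^{-10}$ at $(N{=}3184, K{=}158, n{=}239, k{=}36)$ is the
point probability (the inclusive tail of the same counts is
$4.08\times10^{-10}$), while the path-level figures match the inclusive
tail. `node_set_enrichment()` therefore exposes
`convention = c("upper", "point")`, defaulting to `"upper"`.

## The curated sarcoma example

`sts_fixture()` ships a small curated network from the soft tissue sarcoma
(STS) metastasis literature: twelve significant 10-node cascades that merge
into a 15-node, 18-edge composite path from the sources AP2 and BMP-2 to
the terminal target TYMS.

```{r fixture}
fix <- sts_fixture()
fix$network

scored <- score_paths(fix$paths, fix$known_ids, fix$population,
                      de_ids = fix$de_ids)
scored |> select(path, length, n_known, coverage_ratio, p_value) |> head(3)

merged <- merge_paths(select_significant(scored), net = fix$network)
merged
find_sources(merged); find_sinks(merged)
```

Each cascade carries 7 known STS nodes of 10
($c = 0.7$, $p = 7.4\times10^{-4}$ against the population of 127
candidate-path nodes with 27 known), and the merged composite carries 9
known of 15 ($p = 5.4\times10^{-4}$). Two conventions in this fixture are
the package's own: the known set is taken as the nine path members with
direct disease association (the complementary six members are the ones
annotated only indirectly), and all fifteen members are marked DE so the
50% DE filter is non-restrictive when the printed table is replayed — the
table does not record per-node DE status. Note that enumerating paths on
the *merged* network yields 24 cascades, not 12: merging creates
recombined routes (e.g. an AP2 start joined to a BMP-2-style ESR1→TP53
tail) that were absent from the sub-network the twelve originals were mined
from.

## The synthetic generator

`generate_network()` draws layered random networks for benchmarking every
stage without any external data. Design choices, in order of consequence:

* **Layered, not Erdős–Rényi.** TFs regulate genes and miRNAs; miRNAs
  regulate genes and TFs; genes regulate nothing. Sources (TFs not
  repressed by any miRNA) and sinks (all pure target genes) therefore exist
  in abundance, as they do in curated TF–miRNA networks, so source→sink
  mining is well posed.
* **Planted cascades.** Each benchmark cascade alternates TF and miRNA
  nodes and ends in a gene, so every consecutive pair is a legal regulation
  class. Its head receives no incoming edge and its tail none outgoing, so
  it is a complete source→sink path by construction; interior nodes are
  wired into the background (one TF→gene out-edge per interior TF, one
  background-TF in-edge per interior miRNA) so that the cascade is embedded
  in, not separate from, the network.
* **Default scale.** 200 background nodes (40 TF / 30 miRNA / 130 gene) at
  edge densities 0.04/0.04/0.04/0.02 — about 2.2 regulations per node,
  matching the edge density of curated disease networks — with 20% of
  background nodes offered as additional seeds. Under these defaults the
  candidate-path population spans on the order of 120 nodes.
* **Annotation rates.** The planted 10-node cascade carries 8 known nodes
  (coverage 0.8, a strongly disease-annotated path). The background known
  rate of 0.16 is chosen so that the *population* annotation — planted
  knowns included — lands near 27/127 ≈ 0.21, the annotation rate typical
  of candidate-path nodes in curated disease networks. At these rates the
  planted cascade sits comfortably below the α = 0.001 cutoff (its expected
  p is ≈ 5×10⁻⁵, and the cutoff is only crossed if the realised population
  annotation drifts above ≈ 0.30, a ≈ 2.4σ excursion), so pipeline recovery
  of the planted path is expected in well over 95% of seeds.
* **Determinism.** Generation is a pure function of `(spec, seed)`; the
  global RNG state is saved and restored around it.

What the generator does *not* emulate: expression matrices and DE calling
(DE status is assigned, not estimated), database-specific edge biases,
hub-dominated scale-free degree tails, and identifier messiness (miRNA name
variants). A green synthetic benchmark therefore shows the machinery is
correct under controlled conditions, not that any particular biological
network will yield significant paths.

```{r synthetic}
sim <- generate_network(synthetic_spec(), seed = 1)
res <- run_pipeline(sim$records, sim$seeds, sim$known_ids, sim$de_ids)
res$significant |> select(path, n_known, coverage_ratio, p_value) |> head(3)
```

## Numerical and boundary conventions

* Hub rule: *inclusive* at the threshold (`total_degree >= 10` by default).
  Published hub tables list nodes sitting exactly at 10, so the inclusive
  reading reproduces them; `strict = TRUE` gives the strictly-greater rule.
* DE filter: inclusive at 0.5 (2 DE of 4 passes). Significance: *strict* at
  α (p = 0.001 exactly is dropped).
* Class conflicts: a node recorded as both TF and miRNA is an input error;
  TF beats miRNA beats gene otherwise, so a TF that is also a target stays
  TF.
* Sub-network edges: the full induced subgraph on seeds + neighbours by
  default (all parent edges among retained nodes);
  `seed_incident_only = TRUE` keeps only seed-touching edges for the
  narrower one-hop reading.
* Ordering: every writer sorts its output (edges lexicographically, paths
  by p then path string), so identical inputs give byte-identical files.
* No multiple-testing correction is applied to per-path p-values — the
  selection rule is a raw p < α cutoff by design; apply `p.adjust()` to the
  scored table downstream if a corrected workflow is wanted.
* miRNA identifiers are treated verbatim; reconciling name versions (e.g.
  `-26a` vs `-26a-5p`) across source databases is upstream curation, out of
  scope here.

## Problem sizes used in the test suite

The suite verifies the enumerator against an exhaustive independent
enumeration and a topological-order path count on 200 random DAGs of up to
12 nodes; the hypergeometric tail against an exact big-integer rational
oracle for populations up to 200; and full-pipeline planted-path recovery
across 100 generator seeds at the defaults above, requiring ≥ 95 recoveries.
These sizes keep the whole suite under a minute while exercising every
branch; the algorithms themselves have no embedded size limits beyond the
path-length cap.

## Limitations

* Path enumeration is exponential in the worst case (that is inherent to
  reporting *all* simple source→sink paths); the length cap and the
  sub-network restriction keep practice tractable, but a dense sub-network
  with long braided corridors can still blow up combinatorially.
* The candidate-path population convention makes per-path p-values
  conditional on the mined path set; they are not comparable across runs
  with different sub-networks.
* Coverage ratio treats all node classes equally; no weighting by degree,
  edge sign, or regulation strength is attempted.
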