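# stressnet

Ranked knowledge networks and intervention analysis for plant
stress-signaling research.

Molecular-interaction knowledge for plants is scattered across dozens of
resources of very different credibility: hand-curated signaling reactions,
targeted experiments, high-throughput screens, literature mining and pure
in-silico prediction. `stressnet` provides the computational machinery to
merge such evidence into one analyzable network and to reason over it:

* **Integration** — per-resource pairwise interaction tables are merged into
  a multigraph and *condensed*: all parallel interactions of the same type
  between a pair of interactors collapse to one edge carrying a
  **reliability rank** `r ∈ {0,…,4}` (0 = manually curated, 4 = purely
  in-silico), where the condensed rank is `min` over contributing edges and
  the provenance is the union of all contributing resources. Identifier
  updates (renamed / obsolete gene loci) are applied with a full change
  report.
* **Reaction hypergraph** — curated signaling is modeled bipartitely:
  entities and functional clusters (redundancy groups of genes) link to
  typed reaction nodes through role-annotated participant edges
  (`SUBSTRATE`, `PRODUCT`, `ACTIVATES`, `INHIBITS`, `CATALYZES`,
  `TRANSPORT_FROM`, `TRANSPORT_TO`). The **bipartite projection** turns each
  reaction into directed signed entity–entity edges (input-like roles →
  output-like roles; `INHIBITS` yields an inhibition sign).
* **Path hypotheses** — *all* shortest paths between a source set and a
  target set (directed traversal with undirected binding edges passable
  both ways), per-target **closest-source** restriction, merged path
  networks, first-neighbor expansion and path-length histograms.
* **Intervention planning** — a rank-capacitated **max-flow / min-cut**
  planner: edge capacity `c(e) = rank(e) + 1`, a dummy super-source wired
  to all sources with effectively infinite capacity, and a canonical
  source-side cut extracted from the residual graph. By strong duality the
  reported flow always equals the cut capacity, and every reported cut-set
  is certified by an explicit disconnection check. A node-knockout mode
  (standard node splitting) reports which genes, rather than which edges,
  must be removed.
* **Omics responder filter** — the two-contrast design: keep protein groups
  detected in ≥ 3 of 5 replicates in some treatment group, call
  significance at |FC| > 1.5 and FDR < 0.05, subtract (direction-specific)
  the stimulus-under-blocker contrast from the stimulus contrast, and
  require `|L1 − L2| ≥ 1` between the two log2 fold changes.
* **Export** — SIF (+ edge-attribute sidecar), Graphviz DOT, Boolean rules
  in the boolnet `targets, factors` dialect (with a synchronous simulator),
  and lossless TSV tables.
* **Synthetic fixtures** — seeded generators with planted ground truth
  (unique shortest paths, unique bottleneck cuts, hubs, planted omics
  responders) so every analysis is testable offline.

## Worked example

```r
library(stressnet)

## two resources report the same binding pair with different evidence
raw <- integrateSources(list(
  data.frame(source_id = "CML12", target_id = "MPK3",
             interaction_type = "binding", directed = FALSE,
             sign = "unknown", evidence_class = "targeted_experimental",
             resource_name = "resA", reference = "doi:1"),
  data.frame(source_id = "cml12", target_id = "MPK3",
             interaction_type = "binding", directed = FALSE,
             sign = "unknown", evidence_class = "in_silico_prediction",
             resource_name = "resB", reference = "")))
net <- condenseEdges(raw)
edges(net)[, c("source_id", "target_id", "rank", "provenance")]
#>   source_id target_id rank    provenance
#> 1     CML12      MPK3    1 resA:doi:1;resB

## intervention planning on the shipped two-regulator motif
motif <- twoRegulatorMotif()
res <- minCut(motif$network, motif$sources, motif$target)
res
#> CutResult: capacity 2 = flow 2; 2 cut edge(s)
res@cutEdges[, c("source_id", "target_id", "rank")]
#>   source_id target_id rank
#> 1      REG1      TGT1    0
#> 2      REG2      TGT1    0
```

The condensed edge keeps the better (targeted-experimental) rank 1 while
retaining both resources in its provenance. The min-cut answer says: to
disconnect the target from all four upstream sources, both rank-0
regulatory edges must be severed (capacity 2 = the certified max-flow); in
node-knockout mode (`node_knockout = TRUE`) the same query names the two
regulator genes instead.

A thin command-line wrapper over the same functions ships at
`inst/cli/stressnet-cli.R` (subcommands `build`, `filter`, `paths`, `cut`,
`omics`, `export`, `fixture`; every run writes a manifest with parameter
echo and content hashes).

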