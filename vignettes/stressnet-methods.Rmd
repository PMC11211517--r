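---
title: "Models and methods behind stressnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stressnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressnet)
```

This vignette is the package's own account of its models, conventions and
numerical choices. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The two network models

`stressnet` works with two complementary representations of molecular
knowledge.

The **knowledge network** (`KnowledgeNetwork`) is a condensed pairwise
interaction graph: entities (genes, proteins, complexes, metabolites,
non-coding RNAs, processes, and foreign stressors) joined by typed edges
(binding, transcription-factor regulation, ncRNA interaction,
post-translational modification, other). Each edge carries directionality,
a regulatory sign, a provenance set, and a **reliability rank**:

| rank | evidence class |
|-----:|----------------|
| 0 | manually curated reactions from the hand-built signaling model |
| 1 | targeted experimental evidence (reporter assays, co-IP, enzymatic assays) |
| 2 | solely high-throughput detection (HT-Y2H, ChIP-seq, degradome-seq) |
| 3 | literature extraction (co-citation) or predictions validated with data |
| 4 | purely in-silico binding prediction |

Lower numbers are more reliable; the rank vocabulary is closed and the map
from evidence class to rank is a bijection (`assignRank()`).

The **reaction network** (`ReactionNetwork`) models curated signaling at
reaction resolution. Reactions are first-class nodes typed by a
ten-element vocabulary shipped as editable configuration data
(`inst/extdata/reaction_types.txt`) — the vocabulary is data, not code,
because curation teams adjust it. Entities and **functional clusters**
(sets of genes, possibly from several species, that carry the same
function — encoding genetic redundancy) attach to reactions through
role-annotated participant links; each link also records the subcellular
location and molecular form of the participant. A gene may belong to more
than one cluster; `validateNetwork()` flags this rather than forbidding
it, since redundancy groupings legitimately overlap.

All identifiers are compared case-insensitively after trimming while the
stored capitalization is preserved, accommodating mixed-case gene-locus
conventions across resources.

## Condensation

`condenseEdges()` collapses a multigraph of raw interactions into at most
one edge per (interactor pair, interaction type):

* condensed rank = numerical **minimum** of contributing ranks ("highest
  ranked takes precedence", and rank 0 is the most reliable);
* direction and sign are taken from the most reliable contributing edge;
  when a directed and an undirected edge tie at the best rank, the result
  is directed (information is preserved);
* sign conflicts at the best rank resolve to `unknown` and are recorded in
  `metadata(net)$condense_report` — no silent arbitration;
* provenance is the union over *all* contributing resources;
* directed duplicates in opposite orientations (`A→B` and `B→A` of a
  directed type) are kept as two edges, because regulation is
  orientation-specific.

One corner case is not dictated by the rules above: a (pair, type) group
containing *both* directed orientations *and* undirected contributors.
The package emits one condensed edge per orientation and merges the
undirected contributors' provenance into the orientation holding the most
reliable directed edge (tie: the lexicographically forward orientation).
This keeps the per-orientation edges intact while losing no provenance.

Condensation is idempotent, which the suite checks by re-condensing
condensed tables.

## Bipartite projection

`bipartiteProjection()` converts the reaction hypergraph into a directed,
signed pairwise graph: for every reaction, each input-like participant
(`SUBSTRATE`, `ACTIVATES`, `INHIBITS`, `CATALYZES`, `TRANSPORT_FROM`)
sends an edge to each output-like participant (`PRODUCT`,
`TRANSPORT_TO`). The sign is inhibition exactly when the originating role
is `INHIBITS`. Parallel projected edges condense per sign, so an
activation and an inhibition between the same ordered pair both survive —
discarding either would erase curated knowledge. Reactions with no
output-like participant are skipped with a warning unless flagged as
source/sink.

## Path queries

`allShortestPaths()` enumerates **all** minimum-length paths between a
source set and a target set. Conventions:

* a step is one edge; edges are unit length regardless of rank (ranks
  weight *cuts*, not paths);
* in directed mode, directed edges are traversed forward only while
  undirected binding edges are traversable both ways — binding has no
  causal orientation but does carry signal in curated pathways;
* a node in both sets contributes a zero-length self-path, tallied in its
  own `0` bin of `pathLengthHistogram()`;
* paths are node sequences: parallel edges between a pair (e.g. binding
  plus regulation) do not duplicate a path;
* output is sorted lexicographically by node-id sequence, and enumeration
  is capped (default 10 000 paths per pair, `truncated` flag set) because
  all-shortest-paths can explode on dense graphs.

`closestSources()` / `restrictToClosest()` implement per-target
closest-source selection: for each target only the source(s) at minimum
distance are kept, all ties retained; distances themselves are facts about
the network and are never altered by the restriction.
`expandFirstNeighbors()` is the radius-1 context expansion applied to
merged path networks (the suite cross-checks it against
`neighborhoodSubnetwork()`).

Connectivity questions (`largestConnectedComponent()`,
`neighborhoodSubnetwork()`) deliberately ignore direction — weak
connectivity — while path queries respect it; these are different
scientific questions (membership vs. signal flow), and weak connectivity
is the standard choice for membership questions on mixed
directed/undirected interaction graphs.

## The cut planner

`minCut()` finds a minimum-capacity set of interactions whose removal
disconnects all upstream sources from a downstream target:

* capacity rule `c(e) = rank(e) + 1`, exactly as stated for this analysis
  class. Note the interpretive tension: under min-cut semantics this makes
  *low-numbered* (most reliable) edges the cheapest to sever, although the
  accompanying prose suggests highly ranked edges should be likelier cut
  members. The numeric rule is implemented as printed; a `unit` capacity
  mode (all capacities 1: minimize the number of severed interactions) is
  provided for users who prefer the count semantics.
* multi-source queries add a dummy super-source with an arc to each
  source. "Arbitrarily high" capacity is realized as 1 + the total real
  capacity — no finite flow can saturate it, so dummy arcs never appear in
  a cut (a property the suite checks over random instances).
* an undirected edge becomes two opposing arcs sharing one capacity
  budget, so a binding interaction is a single severable object appearing
  at most once in a cut.
* when several minimum cuts exist, the reported one is the canonical
  source-side cut: arcs from the residual-graph reachable set to its
  complement, deterministic given node order.
* the flow engine is `igraph::max_flow` (any exact max-flow algorithm
  would do; correctness is defined by the exhaustive-enumeration oracle in
  the test suite, not by the algorithm choice).

`verifyCut()` independently certifies every cut by searching for a
surviving source-to-target path; `minCutPerTarget()` runs targets
independently and merges the deduplicated cut edges.

Node-knockout mode answers "which genes must be perturbed" with the same
machinery via standard node splitting: every intermediate node becomes an
in/out pair joined by an arc carrying the node's capacity. The default
node capacity is the minimum capacity among the node's incident edges —
knocking out a node can never be dearer than severing its cheapest
incident edge, which keeps the edge-cut and node-cut scales comparable —
and is configurable per node.

## The omics responder filter

The two-contrast design: a stimulus contrast (`L1`, e.g. peroxide vs.
mock) and a conditional contrast (`L2`, stimulus under a blocker vs.
blocker alone), per timepoint. Defaults follow proteomics convention:

* replicate filter: detected in ≥ 3 of 5 replicates in ≥ 1 treatment
  group;
* significance: |fold change| > 1.5 and FDR < 0.05. Fold changes are
  log2, so the cutoff is `|L| > log2(1.5) ≈ 0.585` — the threshold is
  stated on the natural scale, the data on the log scale;
* subtraction is **direction-specific**: an up-regulation under stimulus
  is cancelled only by an up-regulation under stimulus+blocker (up- and
  down-lists are subtracted separately);
* compelling-difference filter `|L1 − L2| ≥ 1`, applied per timepoint,
  with the responder set the union over timepoints (responses at either
  sampling time count).

Two consequences worth knowing. First, the responder set is monotone
non-increasing in the delta threshold (it appears only as a ≥
comparison) but **not** in the fold-change cutoff: raising the cutoff can
demote the conditional contrast's call to non-significant and thereby
*create* a responder. The suite asserts the monotonicity that actually
holds. Second, upstream missing-value imputation is out of scope; the
table is taken as given, and the synthetic generator only emulates
left-censored missingness through low detection counts.

`disambiguateGroups()` resolves identifiers occurring in several protein
groups by keeping each identifier only in its highest-occurrence group;
ties break by total group evidence, then lexicographic group id, and
tie-broken rows are flagged — the tie-break is a deterministic choice the
upstream rule leaves open.

## Boolean export

`compileBoolnet()` derives one synchronous update rule per node:
`OR(activators) AND NOT OR(inhibitors)`. The derivation convention is
this package's documented choice (none is prescribed upstream); two
boundary cases are fixed deliberately:

* nodes with no regulators are inputs and hold their state (`A, A`);
* nodes with inhibitors but no activators are constitutively on unless
  inhibited (`!(I)`), rather than constant-off from an empty disjunction.

Undirected edges are omitted (binding without direction has no causal
reading) and reported via attributes; unknown-sign directed edges are
excluded with a warning. The emitted dialect is the `targets, factors`
CSV; `readBoolnet()` parses exactly that restricted grammar, and a small
synchronous simulator (`boolnetStep()`, `boolnetAttractor()`,
`boolnetTransitionTable()`) allows exported files to be re-parsed and
checked against hand-computed transition tables.

## Synthetic fixtures

The generators are pure functions of parameters + seed (caller RNG state
is restored) and plant ground truth **constructively** — layered wiring
with detour padding, not rejection sampling — so test runtimes are
deterministic:

* `generateNetwork()` plants a unique shortest path (noise edges only
  ever *leave* path nodes into decoys with no edges back, so no shorter
  route can arise; a longer detour keeps the instance non-trivial), a
  unique bottleneck cut (one cheap edge behind a wide high-capacity fan),
  and a hub of stated degrees, on disjoint node sets;
* `generateReactionFixture()` is a deterministic stressor → receptor →
  kinase-cluster → transcription factor → responsive-gene cascade with an
  inhibition crosslink, the cluster reused by several reactions;
* `generateOmicsTable()` plants responders (stimulus effect ≈ 2 log2
  units, conditional ≈ 0, both significant only where planted), co-regulated
  decoys removed by the subtraction rule, null rows, and optionally
  low-detection rows removed by the replicate filter.

What the fixtures do *not* emulate: realistic degree distributions,
proteome-scale missingness mechanisms, correlated noise between
contrasts, or biological module structure. Passing tests therefore
demonstrate algorithmic correctness on structurally controlled instances,
not performance claims about real interactomes.

## Problem sizes and verification strategy

Every randomized computation is verified against an independent
brute-force oracle that shares no code with the implementation:
adjacency-list BFS with recursive shortest-path enumeration, exhaustive
edge-subset min-cut search (subsets visited in ascending capacity, first
disconnecting subset is optimal), union-find components, and per-row
predicate scans. The suite runs 1 000 min-cut instances (≤ 8 nodes, ≤ 10
edges — small enough for exact enumeration), 500 path instances (≤ 50
nodes), 200 condensation and filter-nesting fixtures, 100 planted-path
seeds and 100 round-trip fixtures; these sizes keep exhaustive oracles
exact while exercising every code path, and the whole suite completes in
a few minutes on one CPU. `scripts/acceptance.R` re-derives the same
quantities from scratch at comparable sizes under a user-supplied seed.

## Known limitations

* All-shortest-path enumeration is exponential in the worst case; the cap
  plus `truncated` flag make truncation explicit rather than silent.
* The min-cut is reported as the canonical source-side cut; other minimum
  cuts of equal capacity may exist and are not enumerated.
* The boolnet reader accepts only the restricted grammar the writer
  emits; it is an interchange format here, not a general Boolean parser.
* Orthology translation, live resource downloads, SBML/SBGN export and
  graph-database persistence are out of scope by design; adapters are
  expected to deliver pre-fetched tables in the documented TSV/JSON
  shapes.
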