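---
title: "Seed-gene sub-network inference: models, parameters and design choices"
author: "seednet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-gene sub-network inference: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seednet)
```

## The analysis model

`seednet` implements the network stage of a differential-expression study:
gene lists from microarray (or any DEG caller) become *seed genes* on a
background molecular graph, and the analysis asks which seeds are close to
each other, through whom, and what that neighborhood does functionally.

The background is always modeled as an **undirected simple graph** over
normalized gene symbols. This is an assumption, not a convenience: the
distance rule ("a distance of 1 means direct interaction, a distance of 2
means one intermediate gene") is defined once, on an undirected model, so
directed curated-interaction inputs are symmetrized for topology and their
activation/inhibition labels are retained only as edge attributes for
export. Self-loops are dropped and multi-edges collapsed because both
distances and degrees presume a simple graph.

### Sub-network extraction

Given mapped seeds $S$ and shortest-path distance $d(\cdot,\cdot)$:

* qualifying pairs: all $\{a,b\} \subseteq S$ with $d(a,b) \le 2$
  ("distance less than 3" — the distance-3 case is excluded);
* seed nodes: seeds in at least one qualifying pair (an unpaired seed is
  *excluded*, not kept as an isolate, because the sub-network is defined as
  the seeds that are close to one another);
* intermediate nodes: for every qualifying pair at distance exactly 2,
  **all** common neighbors $N(a) \cap N(b)$. A pair at distance 1
  contributes no intermediates even if it has common neighbors;
* edges: the subgraph *induced* on the selected nodes, so seed–seed and
  intermediate–intermediate edges not on any qualifying path are included.

Three of these points were genuinely open design choices and are worth
stating with their rationale:

1. *All common neighbors, not one witness.* The verbal definition of an
   intermediate ("a non-seed gene" between two seeds) does not give a
   selection rule for ties. Including every common neighbor is
   deterministic, tie-break-free, and matches the dense published network
   figures; picking one witness would require an arbitrary order.
2. *Induced edge set.* "Their edges" could mean only the qualifying path
   edges; we take the induced subgraph because it is canonical (no path
   bookkeeping) and again matches the figures.
3. *Seed precedence.* A seed that happens to lie between two other seeds
   stays labeled seed; roles are exclusive.

Distances are computed on the full background, not iteratively on the
growing sub-network, and the result is bit-deterministic for a given input.
`extractSubnetwork()` records the qualifying pairs with their distances so
every inclusion is auditable.

### Hubs and modules

A *hub seed gene* has strictly more than `minNeighbors` (default **14**)
direct neighbors; "more than 14" is a strict inequality, so exactly 14 does
not qualify, and intermediates never qualify regardless of degree. Degree is
counted **within the extracted sub-network** by default — the threshold is
applied "in the sub-network" — but `findHubSeeds(where = "background")`
offers the defensible alternative of counting in the raw background. The
threshold itself is a parameter, not a constant: whether 14 was tuned in the
original study to yield its 10 hubs is unknowable from the text. A module is
the hub's ego network with induced edges.

### Over-representation statistics

For query size $n$, term size $K$, overlap $k$ and universe $N$:

$$p_{\mathrm{Fisher}} = P(X \ge k), \quad X \sim \mathrm{Hypergeom}(N, K, n)$$

computed in log space (log-binomials combined by max-shifted log-sum-exp),
which keeps the tail exact for universes of $10^5$ genes and small queries —
no chi-square approximation anywhere. The EASE score is the same tail at
$k' = \max(k-1, 0)$: a deliberately conservative jackknife that nulls
single-gene overlaps. It is implemented here as a local statistic because
the web service the original analysis used is neither archivable nor
scriptable offline. Its FDR companion is Benjamini–Hochberg step-up
($q_{(i)} = \min_{j \ge i} p_{(j)} m / j$, capped at 1); the original
tooling's "approximated FDR" may have been a different variant, so BH is a
declared substitution. One call to `enrichGeneSets()` is one
multiple-testing family. The significance filter is strict on both sides
(`p < 1e-3` and `q < 0.01`) as those thresholds were stated with strict
inequalities.

The **universe** deserves care: the default is the background network's node
set (the genes that could have entered a sub-network), with the union of
annotated genes as the configurable alternative (`universe_policy`). The
original analysis's universe is population-dependent and unrecoverable,
which is one reason its printed enrichment p-values are not reproduction
targets.

### miRNA bipartite enrichment

The miRNA stage was described in the source analysis only as a bipartite
graph plus a per-miRNA p-value; the published table's pattern (more targets
in the sub-network, generally smaller p) is consistent with a
hypergeometric over-representation test, which is what `enrichMiRNAs()`
implements — an interpretation, stated as such. The default universe is the
union of all target sets in the supplied map (self-contained; a genome-wide
list can be passed instead). Ties are broken by miRNA id so ranks are
deterministic.

### Co-expression backgrounds

Edges are kept when Pearson $r \ge 0.5$, *inclusive* ("equal to or greater
than"), signed by default — the stated rule reads as positive co-expression —
with `mode = "absolute"` available. Pearson matches the convention of the
co-expression databases this input emulates; those databases' native mutual
ranks are out of scope. Matrix input requires at least 3 samples and drops
zero-variance rows with a warning.

## Parameters at a glance

| parameter | default | units / meaning |
|---|---|---|
| `fold_threshold` | 1.6 | linear fold change; filter keeps strictly greater magnitudes |
| `max_distance` | 2 | edges; qualifying seed-pair distance ("less than 3") |
| `hub_min_neighbors` | 14 | neighbors in the sub-network; strict |
| `r_min` | 0.5 | Pearson correlation; inclusive |
| `p_max`, `q_max` | 1e-3, 0.01 | strict enrichment thresholds |
| `top_k_mirnas` | 10 | reported miRNAs |

A note on the fold-change boundary: the shipped DEG-table transcriptions
contain a few entries with magnitude at or below 1.6 exactly as printed
(e.g. 1.52, −1.59, 1.60). The fixtures therefore reproduce the published
record counts *unfiltered*, while `filterDEG()` applies the stated strict
rule to new data. Whether those printed entries reflect a different
per-gene test in the original study is not stated anywhere we could check.

Gene symbols are normalized by whitespace stripping, a fixed Greek
transliteration (α→A, β→B, γ→G) and upper-casing, plus an optional
user-supplied alias map applied after case folding. Aliases are never
guessed: the published tables mix synonyms (e.g. GANP vs MCM3AP) whose
merger the original authors did not document, which is why the
unique-seed totals this package computes from the tables (87 overall, 82
hippocampus, 38 cortex, naive union) differ from the published 81/78/37 and
are reported rather than asserted.

## What the synthetic generator emulates — and what it does not

`makeBundle()` produces every pipeline input with ground truth
(`SyntheticTruth`), all derived from one integer seed through R's RNG, with
no global state leaking between components:

* a preferential-attachment background whose default scale (10^4 nodes,
  m = 4, hence ~4×10^4 edges) matches curated human PPI resources, with the
  heavy-tailed degree distribution the hub analysis presumes;
* a planted seed cluster made pairwise-reachable within distance 2 through
  dedicated bridge intermediates, one cluster seed wired as a hub, and decoy
  seeds held at distance ≥ 3 from every other seed. Planting is
  *assert-at-generation*: the distance properties are recomputed after
  construction and infeasible placements fail loudly rather than silently
  degrading the ground truth;
* gene sets with one planted term covering the expected sub-network, a
  miRNA map with one planted miRNA targeting most of it (default 80%),
  DEG tables with fold magnitudes in [1.7, 3.0] (above the 1.6 filter, so
  synthetic seeds survive filtering), and a disease list half drawn from the
  planted sub-network.

The planted cluster and bridges are *new* nodes attached only to each other,
which is what makes exact recovery provable: no background edge can create
an accidental common neighbor. That is also the generator's main
unrealism — real seed neighborhoods are embedded in the background, so real
extractions contain incidental intermediates and their node sets are not
"exactly the planted truth". Passing the planted-recovery suites therefore
demonstrates the *correctness of the machinery* (the extraction logic, hub
rule, ranking statistics), not that real sub-networks are clean. Other
simplifications: uniform fold-change magnitudes (no intensity-dependent
variance), co-expression r values drawn uniformly rather than from a
correlation null, no symbol aliasing noise, and no miRNA database biases.

## Numerical and degenerate-input choices

* Unreachable distances are `Inf` — an explicit sentinel that propagates
  correctly through comparisons — never a large placeholder integer.
* `fisherOverrep(k = 0, ...)` returns exactly 1 by definition, bypassing
  summation; the log-sum-exp path bounds the result at 1.
* Empty sub-networks, empty GMT files after empty-set dropping, miRNAs with
  zero overlap (p = 1, ranked last) and empty enrichment inputs are all
  valid, tested paths.
* All writers emit canonically sorted rows (edge endpoints sorted within a
  pair, then rows lexicographically), which is what makes rerun artifacts
  hash-identical; the pipeline report embeds a config hash and no
  timestamps.
* Enrichment ties are broken by term/miRNA id; module order is descending
  hub degree, then symbol.

## Problem sizes used in validation

The test suite validates the extraction against a brute-force
all-paths-of-length-≤2 enumerator on 500 random graphs of up to 10 nodes,
the exact test against exhaustive subset enumeration on every contingency
configuration with N ≤ 12, shortest distances against exhaustive simple-path
search on 500 random graphs of up to 8 nodes, and planted recovery on 100
bundles with 500-node backgrounds (20-seed cluster, 2 bridges, degree-21
hub, 5 decoys, 50 random terms and 50 random miRNAs each). The determinism
check runs the full pipeline twice on the default 10^4-node profile. These
sizes keep each oracle exhaustive or exactly checkable while the whole suite
runs in a couple of minutes on one core.

## Known limitations

* The original study's sub-network sizes, hub list, disease-overlap counts
  and miRNA p-values are not reproducible without its proprietary or
  versioned database snapshots; this package reproduces the *procedure*, and
  its fixtures reproduce the *printed tables*.
* No GO-graph traversal: gene sets are flat records, so "highest-level
  term" roll-ups are out of scope.
* No community detection; modules are ego networks by definition.
* No weighted shortest paths and no centrality beyond degree.
* `maxDistance > 2` qualifies more distant seed pairs, but intermediates are
  still collected only from distance-2 pairs (the only case the
  intermediate-gene definition covers).
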