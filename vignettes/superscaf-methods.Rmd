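---
title: "Clustering transcript fragments by shared protein homology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering transcript fragments by shared protein homology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(superscaf)
```

## The problem and the model

A de novo transcriptome assembly of a non-model organism typically ends as
hundreds of thousands of short fragments, because nucleotide overlap and
read pairing alone cannot bridge gaps caused by low coverage, polymorphism
or degraded RNA. `superscaf` closes some of those gaps semantically: two
fragments that align to the same database protein (or to homologous
proteins connected through further fragments) very likely belong to the
same transcript or gene family, even with zero nucleotide overlap between
them.

The data structure is a bipartite graph. A translated BLAST search of all
fragments against a protein database yields hits; each retained hit is an
edge between a fragment vertex and a protein vertex. A **super-contig** is
a connected component of this graph: the set of fragments braced together
by shared homology, annotated by proxy with the component's nearest
homolog — the subject of its lowest-e-value hit.

The component structure is computed the way the original formulation
describes it, as iterative minimum-label propagation over edges:

1. label the $N$ retained edges $1..N$ in input order;
2. sweep the edges; whenever two edges share a vertex, both take the
   smaller of their two current labels;
3. repeat until a sweep changes nothing;
4. renumber the surviving labels consecutively $1..K$.

Labels are bounded below by 1 and never increase, so convergence is
guaranteed; at the fixed point two edges carry equal labels exactly when
they are connected, so the partition equals the graph's connected
components. We keep this formulation (rather than replacing it outright
with a components call) because the label-propagation fixed point *is* the
method; an independent components computation (igraph on the same bipartite
graph, `oracle_components()`) is kept alongside as a verification route,
and the test suite asserts exact agreement between the two on randomized
instances.

One implementation note: the original description compares all edge pairs
per iteration, which is quadratic in $N$. We maintain instead a per-vertex
minimum label and sweep edges in ascending index order, which reaches the
same fixed point at $O(N \log N)$ per sweep. Within a sweep the update is
asynchronous (Gauss–Seidel): a small label can travel along a chain of
shared vertices in a single pass. The converged partition is independent of
sweep order — this is property-tested by permuting input rows — but
intermediate labels and the iteration count are not, so the sweep order is
fixed and documented for reproducibility of `n_iterations`.
`n_iterations` counts every sweep executed, including the final one that
observes no change; it is a data-dependent diagnostic, not a contract.

## Tunable parameters

* **`max_evalue`** (default `0.001`, dimensionless expectation value).
  Hits with larger e-values are mostly low-complexity matches or shared
  short motifs, which would fuse unrelated components. The comparison is
  *inclusive* (`evalue <= max_evalue` is kept): the stated rule excludes
  hits *higher* than the cutoff, so equality stays in.
* **Duplicate collapse** (not tunable). Two hits between the same query and
  the same subject describe different homologous regions of one pair and
  must count as one edge. Which line survives is a genuinely open choice;
  we keep the lowest-e-value representative (ties: larger bit score, then
  first occurrence) because the nearest-homolog annotation downstream is a
  minimum over exactly these e-values, so this choice loses nothing.
* **`workers`** (default 1). Models the equal-share data partitioning of a
  threaded implementation: each of $W$ contiguous shares sweeps against the
  iteration-start vertex labels, and proposals merge by elementwise
  minimum. The contract — and the tested property — is that the final
  partition is identical for every $W$; only the sweep count may differ.
  The package runs the shares sequentially: the point is the partitioning
  contract, not wall-clock parallelism.
* **Edge weight.** "Edge length" from an e-value has no canonical formula;
  we define the weight $-\log_{10} e$, capped at 300 for $e \le 10^{-300}$
  (beneath double-precision underflow), so that per-cluster minimum,
  maximum and mean are finite and read naturally as bits of evidence
  (weight 3 is a hit exactly at the 0.001 cutoff; weight 50 is a strong
  homolog). Reported per cluster as `edge_weight_min/max/mean`.
* **Nearest-homolog tie-break.** Equal minimal e-values resolve by larger
  bit score, then lexicographically smallest subject id, making output
  deterministic across platforms and input orderings.
* **Cluster relabeling.** "Sorted and renumbered" leaves the sort key open;
  distinct converged labels are sorted ascending and mapped to ranks, so
  clusters appear in order of their first edge in the input. Sorting by
  size instead would reorder rows but change no content.
* **Member counts.** "Number of members" can mean edges or fragments; the
  cluster table reports both (`n_edges`, `n_fragments`, plus
  `n_proteins`).

## Quantification

Assemblers such as SOAPdenovo record which read was placed on which contig;
`read_read_matches()` parses these records through a small dialect registry
(`soap`: whitespace-separated read/contig/position; `tsv2col`: two
columns), because the intermediate format varies by assembler and version
and is not otherwise documented. Records are deduplicated so a read counts
at most once per contig. Counts flow contig → (optional) scaffold →
cluster; a cluster's count is the sum over its member fragments. The
estimate is deliberately crude — raw record counts, no length or depth
normalization — intended to separate highly expressed, intermediate and
low-expressed transcripts, not to feed differential expression.

Two accounting rules are made explicit because the original leaves them
open: a read whose records land on contigs in *different* clusters counts
once in each (the total of such reads is reported as an attribute so
inflation can be judged), and mates of a pair are independent records.
Counts on fragments with no retained homology evidence go to a reported
`unassigned` total, so the conservation law
`sum(cluster counts) + unassigned = total records` holds on every input —
it is asserted on every generated fixture.

## What the generator emulates — and what it does not

`simulate_instance()` plants `n_components` vertex-disjoint connected
bipartite components (a random spanning tree over each component's
fragments and proteins, plus extra random within-component hits), then
injects the two artifacts the filter must remove: duplicate lines (same
pair, different coordinates; default rate 0.1) and super-threshold hits
(default rate 0.1), with true e-values log-uniform on $[10^{-50}, 10^{-4}]$
and noise e-values on $[10^{-2}, 1]$ — cleanly separated around the 0.001
cutoff so the planted truth is unambiguous. Default component sizes (2–6
fragments, 1–3 proteins, 0–20 reads per fragment) keep instances at the
scale where exact ground-truth comparison over a hundred seeds stays cheap.
An optional `merge_noise_rate` adds sub-threshold cross-component edges;
since those genuinely change the connected components, tests using it
compare against the igraph oracle instead of the planted partition.

The generator emulates graph topology and filtering artifacts only. It does
not simulate nucleotide sequences, sequencing error, BLAST score
statistics, compositional biases, or the heavy-tailed cluster-size
distributions of real transcriptomes (where one gene family can absorb a
large fraction of all edges). Passing tests therefore demonstrate the
algebraic contracts — partition correctness, conservation, determinism,
order and partition invariance — on clean planted structure; they do not
certify biological accuracy of clusters on real data, which inherits all
the caveats of BLAST annotation transfer.

## Numerical and degenerate-input choices

* E-values parse with `e` or `E` notation; `0.0` is stored as exact zero
  and hits the weight cap.
* An empty input file is an empty edge table, and clustering it yields
  $K = 0$ with a header-only output table — not an error.
* Fragment and protein identifiers must be disjoint namespaces (validated
  at load): an id on both sides would silently merge unrelated vertices.
  Comparison is case-sensitive and exact.
* A cutoff below every e-value is a legal run producing zero clusters.
* Identical configuration and inputs give byte-identical outputs; the only
  randomness in the package sits in the generator, behind a mandatory seed
  that leaves the caller's RNG state untouched.

## Problem sizes used by the checks

The routine suite runs on instances of roughly 1–15 components
(tens-to-hundreds of edges) over a hundred seeds, one instance of about
$10^4$ edges, and one smoke test near $10^5$ edges that must cluster in
well under a minute — sizes chosen so exhaustive ground-truth comparison
stays exact and fast while still guarding against accidental quadratic
behavior in the sweep.

## Known limitations

* Paralogs and splice forms sharing strong homology collapse into one
  cluster by construction; separating them would need expression-aware or
  sequence-level post-processing.
* Only fragments with at least one retained hit are clustered; the output
  covers the homology-supported subset of the transcriptome, and reads on
  unclustered fragments are only totalled, not placed.
* Multi-mapped reads inflate per-cluster counts additively across
  clusters; the reported multi-cluster read total bounds the effect but
  does not correct it.
* The e-value cutoff is global; a database with very uneven annotation
  density may warrant per-query calibration, which is out of scope.
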