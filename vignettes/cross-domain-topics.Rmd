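---
title: "Cross-domain neighborhood patterns and predicate topic discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-domain neighborhood patterns and predicate topic discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdnp)
```

## The problem

Biomedical knowledge is spread over many independently maintained
vocabularies — drug, gene, disease, pathway and trial ontologies each
describe one slice of the same biology. At the schema level each
vocabulary is a set of triples ⟨S, P, O⟩ over concept classes, and the
interesting structure for integration is not inside any one vocabulary but
in how *predicates* (relations) from different vocabularies touch shared
concepts. `cdnp` analyses that structure: it builds one heterogeneous
schema graph over all input vocabularies, enumerates the recurring
predicate-neighborhood motifs, quantifies how strongly predicates are
associated through shared and chained concepts, and clusters the
predicates into *topics* — bounded contexts in which a group of relations
collaborates, usually across several source domains.

## The schema graph

The substrate is a directed graph that strictly alternates concept nodes
and predicate nodes: each schema statement ⟨S, P, O⟩ contributes the edges
S → P and P → O. Every node carries exactly one *domain* label, assigned
by longest-matching namespace prefix from a user-supplied namespace map
(vocabularies are prefix-partitioned, so this is unambiguous; a lenient
mode labels unmatched namespaces `"unknown"` instead of failing).

Three cleaning steps precede node creation:

* predicates in the RDF, RDFS, OWL and XML-Schema namespaces are removed —
  only domain-specific relations form patterns;
* literal-valued and blank-node statements are dropped (counted, not
  traversed): patterns are concept-to-concept;
* an optional concept-normalization table (e.g. mappings onto a shared
  upper ontology) is applied once, before nodes are created, merging the
  images of mapped URIs.

Repeated statements collapse to one schema edge with an occurrence count;
degree-based rankings therefore see the collapsed graph, with counts
retained as metadata.

## The five neighborhood patterns

Write C(P) for the set of concepts adjacent to predicate P in either
direction. Two predicates form a *share* pattern when they touch a common
concept:

* **Provider** — a common *object* (both relations deliver information to
  the shared concept);
* **Consumer** — a common *subject* (both draw from it);
* **Reacher** — an ordered pair where an object of the first is a subject
  of the second, chaining information onward.

*Connectivity* patterns extend Reacher links into chains of at least three
predicates: the **Directional Connector** (DC) respects edge directions,
the **Non-Directional Connector** (NDC) ignores them. A chain of m
predicates is admissible here when its predicates are pairwise distinct,
its m − 1 bridging concepts are pairwise distinct (a simple alternating
path), and the direction-ignoring distance between its end predicates lies
in [2, B], with B the topic boundary below. Share patterns are mined both
within- and cross-domain and flagged — the within-domain counts are part
of the census — while connectivity chains are only emitted when they span
at least two domains, where they are the thing of interest. Since an NDC
chain equals its reversal, the lexicographically smaller orientation is
kept; DC and Reacher are ordered, Provider and Consumer unordered. All
output is sorted by (type, predicate URIs), so mining is independent of
input order.

## Association measures

The *association distance* l(Pi, Pj) is the number of concept nodes on the
shortest undirected alternating path between two predicate nodes: 0 for
identity, 1 when they share a concept, ∞ when disconnected.

The *share association* of a predicate pair is

SA(Pi, Pj) = |C(Pi) ∩ C(Pj)|² / (|C(Pi)| · |C(Pj)|),

with SA = 1 for identical and 0 for unreachable predicates — the product
of the two conditional probabilities of landing in the shared set when
drawing a concept from each neighborhood. For pairs at distance 2 ≤ l ≤ B
the *connectivity association* CA chains share associations
multiplicatively along bridging predicates and takes the maximum over
admissible chains; because subchains of shortest paths are shortest, the
maximum is computed by dynamic programming over split points, exactly as
in chain matrix multiplication. The *predicate association matrix* PA uses
SA for l ≤ 1, CA for 2 ≤ l ≤ B and 0 beyond the boundary; it is symmetric
with unit diagonal, and every entry sits in [0, 1].

Cross-domain links are then up-weighted. With W̄(P) the mean association
between P and its direct neighbors (l = 1), a cross-domain pair with
pairwise weight SW gets the *diversity weight*

DW = max((SW + W̄i)/2, (SW + W̄j)/2)  if SW < (SW + W̄i)/2, else SW,

which never falls below SW and biases the clustering toward topics that
span domains. The printed condition tests only the first predicate's
neighborhood mean, which is order-dependent; to keep the matrix symmetric
the package evaluates it with the larger of the two means in first
position (the worked 0.2/0.5/0.23 → 0.35 example is unchanged either
way). Same-domain entries are never modified.

## Topic discovery

Clustering operates on the element distance d(m, n) = 1 − PA′(m, n), the
complement of the reweighted association — the only pairwise predicate
quantity the model defines, and the reason the diversity weighting exists.

**Phase 1 — merge tree.** Starting from one singleton cluster per
predicate, clusters are agglomerated under average linkage (the mean
element distance over the cross product). Each recorded *level* of the
tree merges every mutual-nearest-neighbour cluster pair at once, with ties
broken lexicographically by sorted member URIs; merging continues until a
single cluster remains. Two properties motivated this level semantics
over the textbook one-merge-per-step recording. First, each level is then
a meaningful resolution of the data rather than an arbitrary prefix of a
merge sequence: with one merge per level the middle level of a tree over n
predicates always holds about n/2 clusters, most of them untouched
singletons, which makes "the topics at the middle level" a vacuous notion
for any realistic vocabulary collection. Second, simultaneous
mutual-nearest-neighbour merging is deterministic and order-free, which
the reproducibility tests rely on. Every merge is still recorded as a
binary pair, so the tree converts to an `hclust` object (`as.hclust`,
`plot`) with the level as merge height.

**Phase 2 — mid-level topics.** With H the tree height, the active
cluster set at level Mid = ⌈H/2⌉ is extracted (stepping down if that level
was not recorded). Multi-member clusters become topics numbered from 2;
clusters still singleton at that level are pooled into the special Topic 1
— relations that had not yet associated with any context at the chosen
resolution.

**Phase 3 — refinement.** Hard partitioning can separate relations that
collaborate through an intermediate: for every in-topic pair at distance
2 the bridging predicates of its cross-domain connectivity chains are
added to the topic, and at distance 3 both intermediates are. The bridges
are derived directly from the distance matrix (every bridge on a shortest
alternating path admits pairwise-distinct anchors, so this is equivalent
to consulting the mined chain table, which `refine_topics()` also
accepts); the step runs to a fixed point, is idempotent, only ever grows
topics, and may place a predicate in several topics — the final topic set
is overlapping by design. The singleton pool is left unrefined.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `boundary` (B) | 3 | maximum direction-ignoring predicate distance inside a topic; bounds chain length (3..B+1 predicates) and cuts PA to 0 beyond it. 3 keeps the matrix sparse while still linking relations two bridges apart; raising it admits ever-weaker multiplicative chains. |
| `top_k` | 40 | predicate-ranking cutoff used when projecting patterns onto the domain-collaboration graph. |
| `balance_tol` | 0.2 | relative in/out-degree tolerance for the Provider / Consumer / Balancer domain roles; the role definitions are qualitative, so a domain within 20% of balance is called balanced. |
| hub threshold | mean + 1 sd | a domain whose total collaboration degree exceeds the across-domain mean by one standard deviation is a Hub ("strongly connected" made operational). |

Domain roles are deliberately non-exclusive (a domain can be Consumer and
Bridger at once). For rankings with cross-domain scope, participation is
judged on share patterns and directed connectors only; the undirected
relaxation reaches nearly every connected predicate and would make the
scope vacuous.

## The synthetic generator

`simulate_vocabulary()` emulates a small multi-vocabulary collection: 4
domains × 10 predicates by default, each predicate anchored by a private
subject concept, with 3 planted topics realized as share-dense blocks.
Within-topic predicate pairs co-attach to one of their topic's hub
concepts (as shared object or shared subject) with probability 0.6;
cross-topic pairs are bridged Reacher-style through a fresh concept with
probability 0.05, giving the refinement step work to do. Requested pattern
motifs are planted verbatim on reserved predicates interleaved across
domains and excluded from the background share process, so every planted
motif is recoverable by the corresponding miner. One seeded RNG drives a
run; the caller's RNG state is restored, and the same seed reproduces the
triple list byte for byte.

What the generator does *not* emulate: the heavy-tailed degree
distributions of real vocabularies, literal-valued annotation predicates,
concept reuse across unrelated domains (e.g. generic `Resource` classes),
and instance-level volume. Tests passing on these fixtures therefore
demonstrate correctness of the mining, association and clustering
machinery and recoverability of clean planted structure — not that a real
vocabulary collection decomposes into equally crisp topics.

Simulation-based checks in the test suite run at 40 predicates over 4
domains with 20 generator seeds, and the miner-versus-enumeration checks
use 50 random graphs of 6–14 predicates — sizes at which the exhaustive
oracles (tuple enumeration and path-product maximization) are still exact
and fast.

## Numerical and degenerate-input choices

Associations are carried in full double precision; values printed at two
decimals elsewhere are compared at that precision only in documentation
examples. All set-valued outputs are sorted (radix order) before use, so
every stage is deterministic and independent of input order. Degenerate
inputs have defined behavior: an empty triple table yields an empty graph
and empty rankings; a single predicate yields a height-0 tree whose only
topic is its singleton; self-loop triples give single-concept
neighborhoods and cannot form Reacher pairs; an isolated predicate has
neighborhood weight 0; density is reported as 0 for subgraphs with fewer
than two nodes.

## Known limitations

* The fixed mid-level heuristic ⌈H/2⌉ under-resolves small numbers of
  large communities: when k planted blocks account for almost all merges,
  nearly every level of the tree lies below the k-cluster resolution, so
  the extracted mid-level topics are subdivisions of the true communities
  plus a singleton pool. The merge tree itself is not the limitation — at
  the level holding exactly k clusters it reproduces the planted partition
  — and consumers needing a specific resolution should cut the tree there
  (`as.hclust()` + `cutree()`) rather than rely on the mid level.
* Eq-style association is defined through shared concepts only; two
  predicates whose concepts are semantically equivalent but not normalized
  to the same URI are unrelated to the model. The concept-normalization
  map is the only lever for this.
* The Turtle and RDF/XML readers cover the node-centric subsets common in
  vocabulary dumps (prefixes, continuation lists, typed nodes, nested
  descriptions), not the full specifications; N-Triples is the canonical
  interchange format and the writers emit sorted N-Triples that reload to
  an isomorphic graph.
* Chain mining is exhaustive over simple alternating paths and is meant
  for schema graphs (hundreds of predicates), not instance graphs.
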