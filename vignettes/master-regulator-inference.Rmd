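---
title: "Inferring master regulators from co-expressed gene lists: methods and design notes"
author: "regmaster package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring master regulators from co-expressed gene lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regmaster)
```

## The problem

A differential-expression experiment yields a list of co-expressed genes —
for instance, genes over-expressed in a diseased tissue compartment. Those
genes do not act independently: subsets of them share cis-regulatory
elements and are driven by common transcription factors (TFs), which in
turn sit inside transcriptional complexes and under the control of
upstream kinases. `regmaster` implements the reverse-engineering chain
from such a seed gene list to (i) enriched regulatory motifs and their
candidate TFs, (ii) hub master regulators of the reconstructed TF–gene
network, (iii) upstream interactors and kinases, and (iv) pathway
associations of each hub's transcriptional cluster. Everything is
validated against a synthetic world with planted ground truth.

## Rank-and-recovery enrichment

The package consumes a precomputed *ranking database*: for each motif (or
ChIP-seq track, treated identically apart from a `T` label prefix), a
total ranking of all $G$ genes with the most likely targets at the top.
Constructing such databases (sequence scanning, cross-species module
detection) is upstream of this package, as it is for the analyses the
package supports; the parameters that govern it (`motif_similarity_fdr`,
`min_orthology_identity`) are accepted and logged for provenance only.

For seed set $S$ and motif $m$, the recovery curve is
$\mathrm{rec}_m(r) = |\{g \in S : \mathrm{rank}_m(g) \le r\}|$, and

$$\mathrm{AUC}_m = \frac{\sum_{r=1}^{r_{\max}} \mathrm{rec}_m(r)}{r_{\max}\,|S|},
\qquad r_{\max} = \max(1, \lfloor \rho G \rfloor),$$

with $\rho = 0.03$ by default. This discrete normalization is bounded by 1
and has clean closed forms (a seed set occupying exactly ranks
$1..r_{\max}$ scores $(r_{\max}+1)/(2 r_{\max})$), which the tests use as
oracles. The tools this emulates do not print their exact normalization;
the divisor above is this package's contract and is not configurable.

AUCs are standardized over the whole collection:
$\mathrm{NES}_m = (\mathrm{AUC}_m - \mu)/\sigma$ with the *population*
standard deviation, so the NES vector always has mean 0 and sd 1. Motifs
pass with $\mathrm{NES} \ge$ `nes_threshold` (default 3.0; 3.5 is the
stricter post-hoc choice) and $\mathrm{AUC} >$ `auc_threshold` (0.06).
Both filters are applied after computing NES on the full collection — the
alternative order (AUC filter before standardization) would change the
null against which NES is measured.

Targets: the *leading edge* of motif $m$ is the rank
$r^\* = \arg\max_{r \le R} (\mathrm{rec}_m(r) - \overline{\mathrm{rec}}(r))$,
where $\overline{\mathrm{rec}}$ is the collection-average curve and $R$
the rank threshold (default 5000, clipped to $G$); ties resolve to the
smallest rank, and predicted targets are the seed genes ranked
$\le r^\*$. The field's tools report "number of targets" without printing
the rule; maximal deviation above the collection mean is this package's
definition, chosen because it is fully testable and reduces to intuitive
answers (a lone seed gene at rank 1 over a flat mean curve gives
$r^\* = 1$ and exactly that gene).

Seed genes absent from the database are dropped with a warning rather
than an error: seed lists are mapped onto the database's gene annotation
and modest losses are normal.

## Motif clusters and TF assignment

Enriched motifs are clustered by single linkage on the Jaccard similarity
of their top-$k$ gene sets (defaults $k = 100$, threshold 0.5). The
field's default clustering is sequence-based on the position weight
matrices themselves; since the package deliberately never touches PWMs,
ranking-space overlap is used instead — the downstream contract (clusters
→ one candidate TF → target union) is unchanged. Clusters are labelled
`M1, M2, …` / `T1, …` in descending order of their representative
(maximum-NES member) NES, motif and track clusters interleaved in that
global order.

TF assignment uses annotation confidence: only `direct` annotations (the
motif was experimentally determined for that TF) qualify; among several,
the one on the highest-NES member wins, then lexicographic order. A
cluster with no direct annotation is flagged and excluded from the
network rather than assigned a low-confidence TF.

## Network topology

The TF→gene network is bipartite and directed, with each TF's out-degree
equal to its cluster's target-union size (a cross-module invariant the
tests assert). For *hub selection* the network is treated as undirected
for distance purposes: in a pure source→sink bipartite digraph every
vertex has either no predecessors or no successors, so directed
betweenness is identically zero — yet published per-TF betweenness values
on such networks are positive and lie in $[0,1]$, which is only
consistent with normalized betweenness over the undirected skeleton. The
extended (hub + interactor + kinase) network, whose edges genuinely carry
regulator→regulated direction, is analysed as directed.

Conventions (all asserted against a simple-path enumeration oracle on
small random graphs):

* distances are unweighted shortest-path lengths; unreachable pairs are
  skipped in sums and maxima, and a node with an empty reachable set
  scores 0 on distance-based indexes;
* betweenness is normalized by $(n-1)(n-2)/2$ (undirected) or
  $(n-1)(n-2)$ (directed); stress is the raw shortest-path count through
  the node; edge betweenness is unnormalized;
* radiality follows the diameter-relative convention
  $\sum_w (\Delta + 1 - d(v,w))/(n-1)$, which yields values slightly
  above the 2–3.5 range on networks of a few hundred nodes, matching how
  the index is reported by the standard network-analysis plugins;
* closeness and eccentricity are reciprocals of the distance sum and
  maximum (higher = more central);
* the centroid value is $\min_w(\gamma_v(w) - \gamma_w(v))$ with
  $\gamma_v(w)$ the number of nodes strictly closer to $v$;
* bridging weights raw betweenness by
  $(1/\deg v) / \sum_{i \in N(v)} 1/\deg i$ over the *distinct* neighbor
  set;
* eigenvector centrality is the non-negative unit-norm principal
  eigenvector of the symmetrized adjacency matrix (symmetrization
  guarantees a well-defined non-negative Perron vector).

Hubs are the TF candidates in the upper tertile — the top
$\lceil n/3 \rceil$ rank positions, values tied with the boundary
included — of *every* index (degree, betweenness, radiality by default),
ordered by degree. With three or fewer candidates the tertile of each
index is a single node and the intersection degenerates to (at most) the
top candidate; the package treats such candidate sets as too small to
rank and returns them whole with a warning, so that downstream stages
still receive every supported regulator. Per-index z-scores (population
sd) tag nodes as very relevant at $z \ge 2$ and near-relevant at
$1.5 \le z < 2$; indexes constant across nodes are flagged degenerate.

## Upstream regulators

PPI expansion is strictly one hop: proteins with a direct interaction
(either orientation, evidence count $\ge$ `min_evidence`) with a hub,
plus all recorded edges among the resulting node set. Kinase enrichment
scores each kinase's substrate set $K$ against the expansion query $q$
within universe $U$ (all substrate proteins) by the hypergeometric upper
tail $P(X \ge k)$, $k = |K \cap q|$ — equivalently a one-sided Fisher
exact test — BH-corrected across kinases. The combined score is
$-\log(p)\,z$ with $z = (k - E[X])/\sqrt{\mathrm{Var}[X]}$ under the same
hypergeometric; the formula behind the published "combined score" is not
printed anywhere, so this definition — monotone in both evidence strength
and effect size, and computed in log space so that extreme p-values do
not overflow — is the package's own, and is flagged as such. Selection
keeps kinases significant after correction (adjusted $p < 0.01$) and
returns the upper tertile by combined score, boundary ties included; the
tertile is taken over the corrected set (with 28 significant kinases that
is $\lceil 28/3 \rceil = 10$).

## Pathway association

Each hub's transcriptional cluster — the hub plus all in- and
out-neighbors across motif, PPI, and kinase edges — is tested against a
GMT collection by the hypergeometric upper tail with population $N$ (the
universe), successes $|$set$|$, draws $|$cluster$|$. Three deliberate
conventions: the universe defaults to the union of all collection members
(the collection defines what is annotatable; a configurable override
exists because the "right" universe is analysis-specific); BH correction
is applied once, jointly across the full cluster × set grid (a single
family of hypotheses per run — a regression test asserts the joint
convention, since per-cluster correction gives different numbers); and
the overlap floor "$\ge 5\%$ of the genes" is read as a fraction of the
*cluster*, $k \ge 0.05\,n$. Cluster symbols missing from the universe
(kinases and proteins without pathway annotation) are dropped with a
logged count, mirroring how mixed gene/protein clusters meet
gene-only annotations.

## The synthetic world

`gen_world()` emulates every input with planted ground truth:

* **Ranking database** — decoy motifs are uniform random permutations
  (the null model; none of the upstream databases publish one, so the
  exchangeable-uniform choice is the package's own); a planted regulon
  up-ranks each of its targets into the top $\lfloor 0.03 G \rfloor$
  window with probability `signal_strength`, uniformly within the
  window. Planted motifs carry a `direct` annotation plus a decoy
  `similarity` annotation so the direct-wins rule is exercised against
  competition; decoys get `similarity`/`orthology` links to decoy TFs.
* **Interactome** — each hub TF receives direct neighbors in both
  orientations; the expansion set is additionally wired densely
  (`complex_edges`, default $15 \times$ neighbors per hub ≈ 120 edges),
  emulating transcriptional-complex neighborhoods, whose published
  density (hundreds of edges over a few dozen nodes) is far above random
  background. This density matters: on sparse digraphs the
  skip-unreachable closeness convention makes low-reach leaves look
  spuriously central, and the expected strong positive correlation among
  out-degree, radiality, and closeness only emerges at realistic
  density.
* **Kinases** — the first kinase's substrates are exactly the expansion
  set, making it the guaranteed minimal-p kinase; decoys draw substrates
  with a mild hub bias.
* **Pathways** — one planted set per hub covering 80% of that hub's
  expected transcriptional cluster (comfortably above the 50% the
  recovery guarantee needs), among random decoy sets; per-set scores
  emulate gene-set-enrichment NES values.

Reference conditions: 172 seed genes among $G = 2000$, $M = 50$ motifs,
3 planted regulons with 30 disjoint targets each, 10 kinases, 25 pathway
sets. These sizes keep the full pipeline under a second per run while
preserving every statistical mechanism; the 172/3-hub/10-kinase layout
mirrors the scale of the analyses the package reproduces.

**Signal strength and the NES ceiling.** Because NES is standardized
within the collection with the population sd, $\sum_m \mathrm{NES}_m^2 =
M$ exactly. With $M = 50$ and three equally strong planted motifs the
ceiling is $\mathrm{NES} = \sqrt{47/3} \approx 3.96$ each — at most
$\lfloor M/9 \rfloor = 5$ motifs can ever clear 3.0. Replicate noise
(window placement, background seed genes) spreads the weakest of the
three by roughly $\pm 0.3$, so the all-three-pass event is reliable only
near full signal: measured over 20 replicates it occurs ~70% of the time
at signal 0.9, ~85% at 0.95, and ~95% at 1.0. The default is therefore
`signal_strength = 1` — the forced-by-construction regime in which every
planted target sits in the top window — and recovery claims should be
read against that reference; a *single* planted regulon, whose NES is not
suppressed by sibling regulons, passes the 3.0 filter in ≥ 95% of
replicates already at signal 0.9 (tested). Real motif collections are two
orders of magnitude larger, which is precisely why published NES values
can exceed 5 while a 50-motif collection cannot.

## What passing tests do and do not show

The synthetic generator reproduces the *statistical structure* the
analysis assumes: exchangeable decoy rankings, up-ranked planted targets,
hub-centered interactomes, covering pathway sets. It does not reproduce
sequence-level motif similarity (clusters in the synthetic world are
singletons unless motifs share targets), correlated decoy motifs (real
motif collections are highly redundant), literature-biased PPI evidence,
or incomplete pathway annotation. Recovery of planted structure therefore
validates the inference machinery, not the biological error rate on real
data. Determinism is contractual: every generator is a pure function of
its seed, the pipeline itself draws no random numbers, and a rerun with
the same inputs writes byte-identical outputs (tested file-by-file).

## Numerical and degenerate-input choices

Tolerances of 1e-9 are asserted for the oracle comparisons and the NES
identities; hypergeometric tails are computed in log space before
exponentiation. Degenerate cases are errors or warnings, never silent:
constant AUC collections (NES undefined), empty effective seed sets,
empty queries after universe restriction, clusters without direct
annotations, isolated hubs, no-significant-kinase and
no-significant-overlap outcomes (both legal, distinct from failure).
Tertile and tie rules are inclusive at the boundary everywhere, and
flagged when ties enlarge a selection.

## Problem sizes used in validation

Tests run the enumeration oracles on graphs of up to 8 nodes (50 seeded
instances) and hypergeometric populations up to 12; brute-force
enrichment checks use $G \le 200$, $M \le 20$; end-to-end recovery uses
the reference world ($G = 2000$, $M = 50$) over 20 seeded replicates.
These sizes were chosen so the complete suite exercises every formula
while remaining fast enough to run on every change.
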