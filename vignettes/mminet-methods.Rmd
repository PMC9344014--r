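---
title: "Methods: microbiota-metabolite-immune network analysis with MMInet"
author: "MMInet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microbiota-metabolite-immune network analysis with MMInet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MMInet)
```

## The model

`MMInet` formalises a chain of influence: microbial taxa produce
metabolites; metabolites bind human gene products; gene sets annotate
immune-system processes (ISPs). The package represents this chain as an
undirected, simple, typed multipartite graph (`LayeredNetwork`) with node
types TAXON, METABOLITE, GENE and GOISP, and derives every downstream
quantity from set operations and standard graph algorithms on it.

Three modelling rules matter:

* **Existential linking.** A metabolite is linked to a significant immune
  term when it targets *at least one* query gene annotated to that term.
  Edges are unweighted; the number of shared genes does not multiply the
  edge. This keeps the tripartite network a simple graph and makes the
  taxon→term projection exactly the boolean product of the
  taxon×metabolite and metabolite×term incidence matrices (a property the
  tests assert).
* **Pruning to the informative core.** Metabolites with no significant-term
  link, and taxa left without metabolites, are dropped. Pruning is a
  monotone contraction, so its fixed point does not depend on order.
* **Sentinel taxa.** Metabolites whose record names a kingdom but no source
  organism are attributed to "Unnamed bacteria"/"Unnamed fungi" sentinel
  entities. Sentinels take part in the multipartite network (so no
  microbially derived metabolite is lost) but are excluded from
  taxon-sourced projections, clustering and the commonality graph, which
  only make sense for named organisms.

## Enrichment and term grouping

Over-representation uses the one-sided hypergeometric upper tail
`P(X >= k)` for overlap `k`, term size `K`, query size `n` and universe
`N`, computed with `stats::phyper`, and Benjamini–Hochberg control via
`stats::p.adjust`. The universe defaults to all genes of the annotation
but can be supplied explicitly; the pipeline passes the full simulated
gene universe so the null model is exact. Terms with no overlap receive
p = 1; results order by adjusted p, then term id, so output is
deterministic.

Significant terms are grouped by Cohen's kappa on the 2×2 contingency of
query-gene membership. Pairs with kappa at or above the threshold (default
0.4, a conventional default for annotation-grouping tools) are linked and
connected components form the groups — a hard partition, which is a
deliberate simplification of the iterative group merging some interactive
tools perform. Each group is led by its smallest-adjusted-p term, with
ties broken by larger term size and then lexicographic id. Degenerate
kappa tables (chance agreement 1) map to kappa 1 when observed agreement
is also 1, else 0.

## Similarity and clustering

Entity profiles are binary incidence rows; distance is Jaccard
(`vegan::vegdist(..., method = "jaccard", binary = TRUE)`). Agglomerative
trees are built for each candidate linkage (average, complete, single,
ward.D2 by default) and the linkage with the highest Pearson correlation
between cophenetic and input distances is selected — the same validation
criterion practitioners use to justify average linkage. Ties go to the
first candidate, so runs are reproducible. With only two entities (one
pairwise distance) the correlation is undefined and defined as 1 for
every method: all linkages describe such data perfectly. The cut is by
requested `k` (or height); the number of clusters is a caller decision,
since no internal criterion is claimed to recover a "true" number on real
data.

## Commonality topology

The taxon–taxon commonality graph joins two taxa when they share at least
`minShared` (default 1) metabolites, weighted by the shared count.
Degree, strength (sum of incident weights), connected-component modules
and articulation points come from igraph; articulation points are the
nodes whose removal disconnects their module, and the tests check the
linear-time answer against a remove-one-node brute force. Rankings break
ties by higher value, then lexicographic name.

## Disease and virus overlays

A disease gene set is the `top_n` highest-scoring genes (boundary ties
resolved lexicographically and reported) with intra-set interactions kept
at confidence ≥ 0.8 by default. Intersection nodes are disease genes
targeted by ≥1 metabolite; the overlay keeps exactly the metabolites that
reach them and the taxa that keep a metabolite, so every retained taxon
reaches an intersection node — an invariant, not an observation. Immune
terms enter an overlay when annotated to an intersection node; the full
significant set is kept separately so term coverage ("how many of the
disease's enriched ISPs are reachable from the targeted genes") is
reported as covered/total.

The virus-host network is bipartite with strain labels on viral proteins;
all strains collapse to one virus entity for similarity analysis. The
enrichment query for the virus is its direct human targets plus their
first human neighbours *in the integrated network* (after merging disease
edges), matching how per-disease target sets grow when disease
interactions are added — integration can only enlarge the set. Joint
clustering appends the virus as an all-ones row over the virus–microbiota
common terms, which is exact by construction: the common terms are the
virus's significant terms restricted to the microbiota's term space.

## Rewiring

Two networks are compared by set algebra on node ids and canonical edge
keys (edge type plus sorted endpoints; attributes and direction ignored).
The scalar score is the Jaccard distance of the edge sets, 0 for
identical and defined as 0 when both edge sets are empty. This score is
this package's own summary statistic — it is *not* the variance-based
multi-network rewiring degree of interactive comparison tools, and output
labels it accordingly. Swap symmetry and the class-conservation
identities (|common| + |left_only| = |left|) are asserted on random pairs.

## The synthetic universe

`generateUniverse()` emulates the five input kinds (metabolite XML,
taxon→metabolite and metabolite→gene tables, GMT annotation, scored
disease gene sets with interactions, virus-host PPI) with planted,
recoverable structure. All draws flow from one seeded RNG stream, so a
config is a complete specification of its bundle.

* **Cluster structure** is a block model on the taxon×metabolite
  incidence: the taxa of a cluster share a disjoint core repertoire
  (default 3 clusters of 20 taxa, 12 metabolites per core out of 120).
  At zero noise, same-cluster rows are identical and different-cluster
  rows disjoint, so Jaccard clustering has an analytic answer (ARI 1).
  Noise flips each membership independently (default rate 0.05).
* **The articulation taxon** ("Pontibacter articulans") shares distinct
  core metabolites with clusters 1 and 2, which are otherwise
  disconnected at zero noise — so it is provably the bridge the
  commonality stage must find. At positive noise random sharing can
  create bypasses, which is why articulation recovery is a zero-noise
  property.
* **Enrichment structure**: metabolite targets are drawn from a coherent
  pool (35% of the 400-gene universe; 75% of metabolites have targets,
  5–12 genes each). Planted terms draw 90% of their genes from the
  realised target set, background terms draw uniformly, so planted terms
  are strongly over-represented and background terms are exact
  hypergeometric nulls — the empirical FDR among them is checked against
  the BH level over repeated random queries.
* **Diseases** overlap the target genes by a configured fraction (default
  0.5 of 40 genes), drawn preferentially from the targeted genes of two
  of the planted terms per disease: the diseases emulated are
  immune-associated, and real disease gene sets concentrate on specific
  processes rather than spreading uniformly over the immune annotation.
  The non-overlapping half comes from never-targeted genes, so the
  planted intersection is exact ground truth.
* **The virus** (one entity, four strain labels) targets disease genes at
  the configured fraction and draws most of the remainder from the
  planted-term genes, emulating a virus that perturbs the same immune
  processes the microbiota reach; this gives the virus–microbiota
  common-term comparison genuine signal.
* **Names** mix genus-only and genus+species forms to exercise taxon-name
  normalisation; gene symbols are synthetic uppercase tokens, so no alias
  resolution is modelled.

What the generator does **not** emulate: database curation biases,
metabolite chemistry, taxonomy, annotation DAG structure (terms are flat
sets, with no ancestor propagation), or correlated noise. Passing the
recovery tests therefore demonstrates algorithmic correctness under the
planted model, not performance on real database extracts.

## Numerical and design choices

* Merge tie-breaks in `hclust` follow the row order of the distance
  matrix; profiles are supplied in deterministic (sorted) order, so runs
  are reproducible, and the label-equivariance test works on distinct
  profiles.
* Duplicate association rows collapse at the pair level with evidence
  tags concatenated; merging is commutative, associative and idempotent.
* Kingdom matching is a case-insensitive token match on
  "bacteria"/"fungi", mirroring substring matching on disposition text.
* Gene identity is the uppercased symbol; taxon names are trimmed,
  whitespace-collapsed and first-letter-capitalised; genus-only and
  genus+species remain distinct entities.
* Problem sizes in the tests and the acceptance script (60 taxa, 120
  metabolites, 400 genes, 30 terms, 20 noisy-recovery seeds, 100 FDR
  queries) were chosen so the planted effects are strong and the whole
  verification completes comfortably on a laptop; they are stated here as
  the package's study conditions and are configurable.

## Known limitations

* The kappa grouping is a hard partition; tools that let one term join
  several groups will differ on overlapping annotations.
* The hard-coded published marginal counts exercised in the accounting
  tests validate identities (partitions summing to totals), not the
  underlying database snapshots, which are not redistributable.
* No default `k` is claimed to reproduce any particular published cluster
  count; the cut is a caller parameter.
* The rewiring score compares presence/absence only; edge weights and
  attributes are deliberately ignored.
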