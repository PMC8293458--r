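---
title: "Mining bioconcept co-occurrence networks from annotated literature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining bioconcept co-occurrence networks from annotated literature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litcooc)
```

## The analysis

litcooc implements a literature-mining workflow over PubMed-derived
corpora whose titles and abstracts have been annotated with named
biomedical entities ("bioconcepts") by a PubTator-style NER service.
Each annotation carries an entity class — one of CellLine, Chemical,
Disease, DNAMutation, Gene, Genus, ProteinMutation, SNP, Species,
Strain — and, usually, a database identifier (an NCBI Gene ID, a MeSH
descriptor, a taxonomy ID). The pair is rendered canonically as
`<class>_<id>`, e.g. `Species_9606` for human or
`Disease_MESH:D009369` for cancer, and that canonical label is the
node identity in every network the package builds.

The workflow has four strands:

1. **Scientometrics** over MEDLINE citation records: publication
   counts per year and journal, MeSH-keyword frequency tables, and a
   keyword co-occurrence network.
2. **Set-intersection profiles**: each MeSH subheading under a search
   term defines a set of PMIDs; a binary PMID-by-subheading membership
   matrix feeds an exclusive (UpSet "distinct"-mode) intersection
   tally.
3. **Co-occurrence knowledge graphs**: a bipartite document-entity
   graph, a one-mode bioconcept co-occurrence graph, class-induced
   subgraphs (typically gene-gene), summary metrics, and ranked
   top-node tables.
4. **A synthetic corpus generator** that emulates the statistical
   structure of such corpora so every stage is testable without live
   downloads.

## Edge-weight conventions

The two graph builders use deliberately different conventions, both
exposed as flags:

* `build_cooccurrence()` gives the edge between concepts $a$ and $b$
  the weight $w_{ab} = 2\,|\{d : a \in d \wedge b \in d\}|$ — each
  shared document contributes **+2**, as if both directed edges were
  created and parallel edges merged by summing. Consequently all
  weights are even, the minimum weight is 2 (one shared article), a
  pair sharing 32 articles has weight 64, and every non-isolated node
  has even weighted degree ≥ 2 at degree ≥ 1. Within-document
  multiplicity does not inflate the weight: a document mentioning $a$
  three times and $b$ twice still contributes +2. `doubled = FALSE`
  yields plain shared-document counts for downstream uses that prefer
  the undoubled convention.
* `build_bipartite()` weights the (PMID, concept) edge by the
  **mention count** of the concept in that document, so the average
  weighted degree of the graph exceeds its average degree whenever
  entities are mentioned repeatedly. `mention_counts = FALSE` gives
  binary weights.
* `keyword_cooccurrence()` counts each shared record **once** — the
  standard link-strength convention of keyword co-occurrence mapping
  tools, independent of the bioconcept convention above.

Annotations lacking an identifier are retained in documents and
counted by `concept_stats()` (they occur only for CellLine, Chemical
and Disease in practice), but they never become graph nodes: identity
across documents is undefined without an ID.

## Network metrics

`graph_summary()` reports node/edge counts, average degree $2E/N$,
average weighted degree (mean strength), the weighted modularity of a
Louvain multilevel partition, and the mean unweighted local
clustering coefficient with degree-<2 nodes counted as 0. Choices
worth stating:

* **Louvain** is seeded (default seed 0, resolution 1.0) and the seed
  is restored around the call, so summaries are reproducible and leave
  the caller's RNG untouched. Modularity values are asserted only on
  closed-form cases (two disjoint triangles at the correct
  2-community partition give exactly
  $\sum_c (e_c/m - (d_c/2m)^2) = 2(\tfrac12 - \tfrac14) = 0.5$),
  because the optimiser is stochastic and different tools' community
  structures differ on large graphs.
* **Clustering coefficient** variants abound; the unweighted local
  average over *all* nodes is used, with isolated and degree-1 nodes
  contributing 0 rather than being dropped.
* `degree_table()` ranks by weighted degree descending with
  deterministic tie-breaks (degree descending, then node id
  ascending); the "most interacting node" column is the neighbour on
  the maximum-weight incident edge, ties again by id.

## Exclusive versus inclusive intersections

`exclusive_intersections()` implements UpSet distinct mode: an
element is counted for the single combination equal to its exact
membership pattern, so counts partition the union. Narrative
statements like "the intersection of physiology and metabolism"
usually mean the *inclusive* pairwise figure, so
`inclusive_pair_counts()` reports that view as well; keeping both
modes labelled side by side avoids guessing which one a given number
refers to. `nonparticipating_sets()` returns the sets none of whose
elements co-occur with any other set — with a single-set matrix the
answer is that set, as no partner exists.

## What the synthetic generator emulates

`corpus_spec()` defaults describe, at desk scale, the corpus shape
the pipeline targets:

* ten bioconcept classes with class mix proportional to observed
  annotation totals in large proteome-literature corpora (Species
  most frequent, then Chemical, Disease, Gene; Strain rarest);
* within-class concept popularity following a Zipf law (exponent 1),
  so a few concepts dominate — the regime in which co-occurrence
  hubs such as human/cancer/p53 arise;
* about 11 annotations per document (negative binomial, size 5), with
  a 15% chance of a repeated mention;
* identifier-less mentions only for CellLine, Chemical and Disease at
  their observed rates (11%, 14.9% and 4.6% of that class's
  mentions);
* publication years 1992–2021 with linearly rising weights, a
  dominant specialist journal, Zipf-weighted MeSH keywords, and
  overlapping subheading memberships with one deliberately rare
  subheading.

`n_docs = 500` is the default problem size; tests use 25–400
documents, chosen so the whole suite and the brute-force oracles run
in minutes. Planted signals (`planted_pairs`) are enforced exactly:
every planted key is first removed from the background, then each
pair is injected into a fresh random sample of exactly `n_shared`
documents, so ground truth is known by construction. The generator
keeps a ledger of everything it drew (per-class tallies, year/journal
tallies, membership patterns, planted co-occurrence counts) that
tests compare against recomputed statistics.

The generator does **not** emulate linguistically realistic prose
(mentions are spliced into placeholder abstracts at recorded
offsets — enough for parser round-trips), NER error modes, offset
conventions of heterogeneous PubTator exports, or correlations
between entity content and keywords/subheadings. Passing tests
therefore demonstrate correctness of parsing, counting and graph
construction under known ground truth — not robustness to the noise
of a real annotation service.

The `CorpusSpec` carries a MeSH keyword vocabulary
(`mesh_vocab_size`, `mesh_per_doc`) so generated MEDLINE records
exercise the keyword analyses; keyword content is drawn independently
of the entity annotations.

## Numerical and degenerate-input choices

* Offsets are 0-based, half-open over title + one separator +
  abstract; the parser preserves them verbatim and validates only
  that spans are ordered and within the combined length — lossless
  I/O beats strict validation across heterogeneous exports.
* Duplicate annotation lines are kept as distinct mentions; graph
  builders, not the parser, decide how multiplicity matters.
* Empty corpora: `concept_stats()` returns an all-zero 10-row table;
  `graph_summary()` refuses an empty graph; an empty membership union
  is an error (nothing to intersect).
* Frequency tables sort by count descending with lexicographic
  tie-break, and percentages are computed over the table's own sum
  *after* min-frequency filtering and top-n truncation (the
  convention used when percentages are reported over a retained
  keyword list).
* Pipeline defaults: minimum keyword frequency 5, keyword cap 1000,
  top-10 concept table — the standard settings of this analysis.

## Limitations

Co-occurrence within a title+abstract is the simplest relation
signal: it carries no direction, no sentence-level context, and
conflates positive and negative statements. Cluster counts from
external visualisation tools are not reproducible here because their
normalisation and clustering algorithms are not part of the published
record; community structure is reported via seeded Louvain instead.
Affiliation/country analyses and BioC XML dialects are out of scope.
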