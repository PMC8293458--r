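# litcooc — bioconcept co-occurrence networks from annotated literature

litcooc is an R toolkit for mining entity-annotated biomedical
literature. Given (a) a PubTator-format annotation export — titles,
abstracts and named-entity annotations with class and database ID for
each mention — (b) MEDLINE citation records, and (c) per-subheading
PMID lists, it computes the standard descriptive layers of a
literature-scale knowledge graph study:

* **Bioconcept statistics** per entity class (total, unique and
  identifier-less mentions across CellLine, Chemical, Disease,
  DNAMutation, Gene, Genus, ProteinMutation, SNP, Species, Strain).
* **Scientometrics**: publication counts per year and journal, MeSH
  keyword frequency tables and a keyword co-occurrence network.
* **Exclusive set intersections** (UpSet distinct mode) over the
  binary PMID × subheading membership matrix, plus the inclusive
  pairwise view and the list of non-participating sets.
* **Co-occurrence knowledge graphs**: the document–entity bipartite
  graph, the bioconcept–bioconcept co-occurrence graph, class-induced
  subgraphs (e.g. gene–gene) and key-node neighborhoods, with
  degree/weighted-degree/modularity/clustering summaries and ranked
  top-node tables.

The core statistic is the co-occurrence edge weight. For bioconcepts
*a*, *b* it is

> w(a,b) = 2 × |{documents containing both a and b}|

— each shared article contributes +2 (both directed edges, merged by
summing), so a pair sharing one article has weight 2 and a pair
sharing 32 articles has weight 64; node identity is the canonical
`<class>_<id>` label (e.g. `Species_9606`, `Disease_MESH:D009369`).
Bipartite document–entity edges are weighted by mention count, and
keyword co-occurrence counts each shared record once. All conventions
are flag-switchable; see the vignette in `vignettes/` for rationale.

A seeded synthetic-corpus generator (`corpus_spec()` /
`generate_corpus()`) emulates the statistical structure of such
corpora — Zipf-skewed concept popularity, class mix, ID-less mention
rates, years, journals, overlapping subheading memberships, planted
co-occurrence pairs with exact shared-document counts — and returns a
ground-truth ledger, so the whole pipeline is testable offline.

## Worked example

```r
library(litcooc)

spec <- corpus_spec(n_docs = 200, seed = 42,
                    planted_pairs = list(list("Gene_2475", "Gene_207", 32)))
corpus <- generate_corpus(spec)

g    <- build_cooccurrence(corpus$documents)   # doubled-weight convention
gene <- class_subgraph(g, "Gene")
graph_summary(gene, seed = 0)
#>   node_count edge_count avg_degree avg_weighted_degree modularity ...
#> 1        104        417       8.02                  24      0.270

degree_table(gene, top_n = 5)
#>   concept_id  weighted_degree degree top_partner top_partner_weight
#> 1 Gene_1001               314     63 Gene_1002                   30
#> 2 Gene_207                190     32 Gene_2475                   64
#> 3 Gene_2475               190     32 Gene_207                    64
#> ...
```

The planted pair `Gene_2475`–`Gene_207` shares exactly 32 documents,
so its edge weight — and each member's "frequency of most interacting
node" — is 64; the background hub `Gene_1001` (the Zipf rank-1 gene)
tops the weighted-degree ranking. Intersections work the same way:

```r
m <- build_membership_matrix(corpus$subheading_lists)
head(exclusive_intersections(m), 3)
#>   combination           degree count
#> 1 physiology                 1    25
#> 2 physiology&metabolism      2    20
#> 3 metabolism                 1    18
nonparticipating_sets(m)
#> [1] "pharmacokinetics"
```

`run_pipeline(run_config(...))` executes every stage on files on disk
and writes CSV/GraphML/plot artifacts plus a report table;
`inst/scripts/litcooc.R` wraps it for shell use
(`Rscript litcooc.R simulate ...`, `Rscript litcooc.R all ...`).

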