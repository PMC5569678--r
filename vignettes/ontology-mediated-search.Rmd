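---
title: "Ontology-mediated semantic search over federated RDF datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-mediated semantic search over federated RDF datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semsearch)
```

## The problem

Life-science Linked Data collections such as Bio2RDF republish dozens of
databases (DrugBank, KEGG, OMIM, Orphanet, ...) as RDF, each behind its own
SPARQL endpoint and — crucially — each with its own vocabulary. One dataset
types its records as `Disease`, a second as `Disorder`, a third splits the
same notion into `Phenotype` and `Predominantly-phenotypes`. A biomedical
user who wants "everything about Alzheimer's, as a disease or phenotype,
from any dataset" would have to know every schema and write one SPARQL query
per dataset.

`semsearch` implements the core of a mediator-based (global-as-view) answer
to this problem:

1. a **constrained keyword query language** — plain keywords plus `C:`
   (class), `P:` (property) and `S:` (dataset) tags;
2. a **linguistic ontology matcher** that aligns every dataset schema to one
   mediating ontology;
3. **mapping-based query rewriting** that turns the user's query into a
   union of per-dataset SPARQL queries and merges the results; and
4. **result organization**: ranking, three-way property grouping, faceted
   filters, and cross-dataset link resolution.

A seeded fixture generator produces miniature heterogeneous dataset bundles
with known ground truth, so every layer is testable without downloading any
external resource.

## The query language and its semantics

A query is a whitespace-separated token sequence. Tokens are classified by
three case-insensitive patterns — `^C:\w+`, `^P:\w+`, `^S:\w+` — and
everything not starting with one of those tags is a plain keyword. A tag
prefix followed by anything other than an alphanumeric name (`C:`,
`C:foo-bar`) is rejected as malformed rather than silently reinterpreted,
which keeps classification total and exclusive and makes render/parse an
exact round trip.

Categories combine with AND, tokens within a category with OR:

```{r}
format(logical_form(parse_ease("alzheimer C:Phenotype C:Disease")))
```

Because within-category OR is permissive, ranking (not filtering) rewards
entities that match several keywords at once; ties are broken by the number
of matched class options, then display label, then IRI, so ordering is total
and independent of input order.

## The matcher

Two linguistic measures score every mediating-term/dataset-term pair of the
same kind (class–class, property–property). Structural matching is
deliberately absent: federated dataset schemas are shallow (mostly flat
class lists plus property declarations), so structure carries almost no
signal.

**Virtual documents.** Each term `t` contributes a bag of words `LD(t)` from
the local name of its IRI and its labels/annotations (purely numeric tokens
are dropped — numeric local names such as `sio:010038` carry their meaning
in labels). The virtual document adds discounted neighbor descriptions:

    VD(t) = LD(t) + gamma_s * sum LD(t') over subject neighbors
                  + gamma_p * sum LD(t') over predicate neighbors
                  + gamma_o * sum LD(t') over object neighbors

with all three weights defaulting to 0.5, the recommended setting for this
family of matchers. A node appearing in several neighbor sets contributes
once per set. Similarity is the cosine of the two weight vectors. Weights
are raw term frequencies without IDF: the alignment task compares two small
schemas, not a retrieval corpus, and raw counts keep the measure exactly
reproducible by a brute-force oracle.

**I-Sub.** A string measure that scores commonality *and* difference:
iteratively remove maximal common substrings; `Comm` is twice the removed
length over the summed lengths; `Diff` combines the unmatched fractions
through a product damped by a difference weight of 0.6; a Winkler-style
bonus `0.1 * min(4, common prefix) * (1 - Comm)` rewards shared prefixes.
The raw score lies in [-1, 1] and is clamped to [0, 1] so the final
combination stays a similarity. I-Sub sees the space-joined token form of a
term's description, with labels preferred over opaque local names.

**Combination and threshold.** The overall score is `max(V-Doc, I-Sub)`, and
every pair at or above the threshold (default **0.9**, chosen for precision)
becomes an equivalence mapping. All pairs above threshold are kept — no
stable-marriage filtering — because real schemas need 1-to-many mappings
(one mediating class covering two disjoint dataset classes).

**Synonyms.** A pluggable provider (a two-column TSV, symmetrically closed
on load) enriches local descriptions before both measures: each description
token found in the provider appends its synonym tokens once, idempotently.
This is what recovers lexically disjoint pairs such as *disease* vs
*Disorder*: after enrichment both sides describe themselves with the same
token set, so both the cosine and the string measure saturate.

Shared built-in vocabulary (RDF, RDFS, OWL, DC/DCTERMS, SKOS, FOAF, VoID) is
excluded from matching by default: both graphs use those IRIs verbatim, so
matching them is vacuous; they instead enter query answering through the
54-property common extension (below) and rewrite by identity.

## Query answering

`build_global_query()` resolves `C:`/`P:` names against the mediating
ontology case-insensitively (local name or label), then expands class
options over the transitive subclass closure — expansion happens on the
mediating side, *before* mapping, which is the natural direction for
global-as-view integration. Property constraints also resolve against a
configurable extension of 54 commonly-used annotation/link properties
(`rdfs:label`, `owl:sameAs`, `dc:title`, `foaf:homepage`, ...), which
datasets share verbatim.

`rewrite_to_local()` substitutes each global class option by each of its
mapped dataset classes and likewise for properties; one local query per
(class pattern x property pattern) combination carries the keyword filter.
The plan's semantics is the union over combinations. Two deliberate
behaviors:

* a dataset lacking a mapping for a required term is *skipped*, not fatal —
  partial coverage is the normal condition of federated schemas, and
  faceted filtering surfaces the dataset-specific remainder;
* keywords filter case-insensitive substrings over an entity's literals
  (all literals by default; restrictable to configured text properties).
  The filter is applied inside each local query, not post-hoc.

Results are entities — instances — never the vocabulary itself, on both the
federated path and the oracle path; rendered SPARQL enforces the same
scoping with `FILTER NOT EXISTS` guards when no class pattern is present.
Per-entity descriptions are the outgoing triples; incoming references
surface only through x-link properties. Execution isolates per-dataset
failures (partial results plus a warning); only a total failure raises.

**The central property.** For every generated query, executing the
rewritten plan over the heterogeneous datasets must return exactly the
entities obtained by evaluating the global query directly over the
*homogenized* merged graph (all vocabulary rewritten to mediating terms via
the ground-truth alignment). The test suite and the acceptance script check
this set equality on 100 generated queries over a 3-dataset bundle.

## Result organization

Each entity's description is partitioned into three groups: *metadata*
(configurable namespace list, defaulting to RDF/RDFS/OWL/DC/DCTERMS/FOAF),
*entity-linking* (property local name matching the `x-<name>` convention,
configurable regex), and *domain-specific* (the rest); groups are sorted
alphabetically by property then value. Facets extract the classes,
properties and datasets of the result entities; a leaf hangs under the
mediating term an alignment connects it to, otherwise under its dataset
bucket, so unmatched dataset-specific vocabulary stays reachable. Facet
counts are computed on the current (refined) result set, and refinement by
a leaf is idempotent; a leaf no current entity carries is reported stale.
X-link values resolve their target dataset from the link property's name,
falling back to the target IRI's namespace, else `"unknown"`.

## The fixture generator

`generate_fixtures()` emulates the heterogeneity the engine exists to
bridge, at toy scale: a mediating ontology of eight classes (an
`Entity` root over `Drug`, `Gene`, `Protein`, `Pathway`, `Disease`, with
`Phenotype` and `Syndrome` under `Disease`) and six domain properties; two
to three datasets whose vocabularies re-express those terms under seeded
perturbations (letter case, delimiter convention, synonym substitution, or
an added qualifier producing a 1-to-2 mapping in the
`Predominantly-phenotypes` style); three entities per class, labelled with
words from a ten-keyword pool embedded verbatim so keyword hits are
enumerable; five x-link triples between datasets; the ground-truth
alignments; and the homogenized oracle graph. Everything is a pure function
of the spec (including its seed).

What the fixtures do *not* emulate: real-data scale (millions of entities),
noisy or multilingual labels, schema drift beyond the four perturbation
modes, endpoint latency and paging, and a live synonym service (the
provider is a static table). Passing tests therefore demonstrate the
*logic* — recovery of known perturbations, semantics preservation of the
rewriting, invariants of presentation — not retrieval quality on real
collections.

## Numerical and degenerate-case choices

* Similarities are clamped to [0, 1]; empty strings or empty documents
  score 0.
* Precision of an empty predicted alignment is reported as 0 (undefined by
  convention), recall of an empty reference likewise; F1 is 0 whenever
  precision + recall is 0.
* Alignment rows, expansion output and canonical N-Triples lines are sorted
  bytewise (`method = "radix"`), so every artifact is deterministic and
  diffable.
* Longest-common-substring ties break to the earliest position in the first
  string, then the second — a fixed choice that makes the dual
  implementations comparable character-for-character.
* Subclass cycles are closed over with a visited set, so expansion always
  terminates.
* Loading deduplicates triples (RDF set semantics); graph equality in tests
  is byte equality of canonical serializations.

## Problem sizes used by the test suite

The suite runs on bundles of 2–3 datasets (8 classes, 6 properties, 3
entities per class), 100 generated queries for the soundness/completeness
property, 10 seeded bundles for the synonym-recall summary, 200 random
virtual documents and 50 random string pairs against the brute-force
oracles, and 1000 random tokens against the grammar oracle — sizes at which
every expected value is independently recomputable, which is the point of
the design.

## Known limitations

* No OWL reasoning beyond explicit triples; only `rdfs:subClassOf` is used,
  and only for class expansion (properties are not expanded over
  sub-property relations).
* Federation is a per-dataset union — no cross-dataset joins in a single
  query, no cost-based source selection.
* The SPARQL endpoint client is a minimal SELECT-over-HTTP helper; the test
  suite exercises in-memory graphs only.
* The Turtle reader covers the pragmatic subset used by federated
  biomedical dumps (prefixes, lists, literals with language/datatype,
  blank nodes); exotic constructs (collections, quoted triples) are out of
  scope.
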