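Package: semsearch
Title: Ontology-Mediated Semantic Search over Federated RDF Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A semantic search engine core for heterogeneous life-science RDF
    datasets. Parses a constrained keyword query language (plain keywords plus
    class, property and dataset tags), aligns each dataset schema to a mediating
    ontology with two linguistic matchers (virtual-document cosine similarity
    and the I-Sub string metric), rewrites queries through the resulting
    equivalence mappings into per-dataset SPARQL under global-as-view
    semantics, executes them federatedly, and organizes results with ranking,
    property grouping and faceted filters. Ships a seeded generator of small
    Bio2RDF-style fixture datasets with ground-truth alignments and a
    homogenized oracle graph so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
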