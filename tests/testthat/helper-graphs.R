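# Small hand-built graphs shared by tests.

EX <- "http://example.org/ex/"

tiny_graph <- function(triples, name = "tiny") {
  # triples: list of c(s, p, o) IRI triples or list(s, p, o, lit = TRUE)
  rows <- lapply(triples, function(t) {
    if (is.list(t)) {
      semsearch:::make_triples(t[[1]], t[[2]], t[[3]], o_lit = TRUE,
                               lang = t$lang %||% NA_character_)
    } else {
      semsearch:::make_triples(t[1], t[2], t[3])
    }
  })
  dataset_graph(name, triples = do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

onto <- function(name) paste0(semsearch:::MEDIATING_NS, name)

rdf_type <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
rdfs_label <- "http://www.w3.org/2000/01/rdf-schema#label"
rdfs_subclassof <- "http://www.w3.org/2000/01/rdf-schema#subClassOf"
owl_class <- "http://www.w3.org/2002/07/owl#Class"

# Brute-force neighbor scan: the oracle for term_neighbors.
neighbors_oracle <- function(iri, graph) {
  tr <- graph$triples
  sn <- character(0); pn <- character(0); on <- character(0)
  for (i in seq_len(nrow(tr))) {
    o_node <- if (tr$o_lit[i]) paste0("\"", semsearch:::nt_escape(tr$o[i]), "\"") else tr$o[i]
    occurs_s <- tr$s[i] == iri
    occurs_p <- tr$p[i] == iri
    occurs_o <- !tr$o_lit[i] && tr$o[i] == iri
    if (occurs_p || occurs_o) sn <- c(sn, tr$s[i])
    if (occurs_s || occurs_o) pn <- c(pn, tr$p[i])
    if (occurs_s || occurs_p) on <- c(on, o_node)
  }
  list(SN = setdiff(unique(sn), iri), PN = setdiff(unique(pn), iri),
       ON = setdiff(unique(on), iri))
}

# Brute-force local-query evaluator used as the oracle for rendered SPARQL.
python_sparql_entities <- function(graph, sparql) {
  nt <- tempfile(fileext = ".nt")
  qf <- tempfile(fileext = ".rq")
  write_ntriples(graph, nt)
  writeLines(sparql, qf)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json",
    "import rdflib",
    "g = rdflib.Graph()",
    "g.parse(sys.argv[1], format='nt')",
    "q = open(sys.argv[2]).read()",
    "res = g.query(q)",
    "print(json.dumps(sorted(str(row[0]) for row in res)))"), script)
  out <- system2("python", c(script, nt, qf), stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("python rdflib oracle failed: ", paste(out, collapse = "\n"))
  }
  as.character(unlist(jsonlite::fromJSON(out[length(out)])))
}

has_python_rdflib <- function() {
  out <- suppressWarnings(system2("python", c("-c", "import rdflib"),
                                  stdout = FALSE, stderr = FALSE))
  identical(out, 0L)
}
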