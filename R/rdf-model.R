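# Graph container, term extraction, local descriptions, neighbor sets.

#' Construct a dataset graph
#'
#' @param dataset_name Unique identifier for the dataset.
#' @param triples Triple data.frame (as produced by the readers).
#' @param source Where the graph came from (file path or endpoint URL).
#' @param graph_iri Optional named-graph IRI.
#' @param endpoint Endpoint URL when the graph is endpoint-backed.
#' @return An object of class `dataset_graph`.
#' @export
dataset_graph <- function(dataset_name, triples = empty_triples(),
                          source = NA_character_, graph_iri = NULL,
                          endpoint = NULL) {
  stopifnot(is.character(dataset_name), length(dataset_name) == 1)
  structure(list(dataset_name = dataset_name,
                 source = source,
                 graph_iri = graph_iri,
                 endpoint = endpoint,
                 triples = dedup_triples(triples)),
            class = "dataset_graph")
}

#' @export
print.dataset_graph <- function(x, ...) {
  cat(sprintf("<dataset_graph> %s: %d triples%s\n", x$dataset_name,
              nrow(x$triples),
              if (!is.null(x$endpoint)) paste0(" (endpoint ", x$endpoint, ")") else ""))
  invisible(x)
}

n_triples <- function(graph) nrow(graph$triples)

#' Extract the schema terms of a graph
#'
#' A term is a class or a property. Classes are IRIs typed as
#' `rdfs:Class`/`owl:Class`, IRIs appearing as the object of a typing triple,
#' or ends of `rdfs:subClassOf` edges; properties are IRIs declared as
#' properties or used in predicate position. Labels and annotations are
#' collected from the configured label-like and comment-like properties.
#'
#' @param graph A `dataset_graph`.
#' @param label_properties,comment_properties Annotation property IRIs whose
#'   literal values feed a term's textual description.
#' @return A named list of `rdf_term` objects (names are term IRIs), each with
#'   fields `iri`, `kind` ("class"/"property"), `labels`, `annotations`.
#' @export
extract_terms <- function(graph,
                          label_properties = default_label_properties(),
                          comment_properties = default_comment_properties()) {
  tr <- graph$triples
  if (nrow(tr) == 0) return(structure(list(), names = character(0)))

  is_iri <- function(x) !startsWith(x, "_:")
  type_tr <- tr[tr$p == RDF_TYPE & !tr$o_lit, , drop = FALSE]
  sub_tr <- tr[tr$p == RDFS_SUBCLASSOF & !tr$o_lit, , drop = FALSE]

  class_iris <- unique(c(
    type_tr$s[type_tr$o %in% c(RDFS_CLASS, OWL_CLASS)],
    type_tr$o,
    sub_tr$s, sub_tr$o))
  class_iris <- class_iris[is_iri(class_iris)]
  class_iris <- setdiff(class_iris,
                        c(RDF_PROPERTY, OWL_OBJECT_PROP, OWL_DATA_PROP, OWL_ANN_PROP))

  prop_iris <- unique(c(
    tr$p,
    type_tr$s[type_tr$o %in% c(RDF_PROPERTY, OWL_OBJECT_PROP, OWL_DATA_PROP,
                               OWL_ANN_PROP)]))
  prop_iris <- prop_iris[is_iri(prop_iris)]

  # Declared property wins over incidental class usage (and vice versa is
  # impossible: typing as a class removes it from the property declarations).
  class_iris <- setdiff(class_iris, prop_iris)

  lab_tr <- tr[tr$o_lit & tr$p %in% label_properties, , drop = FALSE]
  com_tr <- tr[tr$o_lit & tr$p %in% comment_properties, , drop = FALSE]

  build <- function(iri, kind) {
    structure(list(iri = iri, kind = kind,
                   labels = lab_tr$o[lab_tr$s == iri],
                   annotations = com_tr$o[com_tr$s == iri]),
              class = "rdf_term")
  }
  terms <- c(lapply(class_iris, build, kind = "class"),
             lapply(prop_iris, build, kind = "property"))
  names(terms) <- c(class_iris, prop_iris)
  terms
}

#' @export
print.rdf_term <- function(x, ...) {
  cat(sprintf("<rdf_term> %s [%s]%s\n", x$iri, x$kind,
              if (length(x$labels)) paste0(" \"", x$labels[1], "\"") else ""))
  invisible(x)
}

#' Local description of a term
#'
#' The bag of lowercase word tokens drawn from the local name of the term's
#' IRI plus all of its labels and annotations. Purely numeric tokens are
#' dropped, so opaque numeric local names (common in SIO) contribute nothing
#' and the labels carry the signal.
#'
#' @param term An `rdf_term` (or a bare IRI string).
#' @return Character vector of tokens (a multiset: repeats preserved).
#' @export
local_description <- function(term) {
  if (is.character(term)) term <- structure(list(iri = term, labels = character(0),
                                                 annotations = character(0)),
                                            class = "rdf_term")
  c(tokenize(local_name(term$iri)),
    tokenize(term$labels),
    tokenize(term$annotations))
}

# Description tokens for an arbitrary neighbor node (IRI, blank node, or a
# literal passed in its N-Triples form "\"lex\""). A blank node describes
# itself through the literal values it carries in the graph.
node_local_description <- function(node, graph, terms = NULL) {
  if (startsWith(node, "\"")) {
    return(tokenize(nt_unescape(substr(node, 2L, nchar(node) - 1L))))
  }
  if (startsWith(node, "_:")) {
    tr <- graph$triples
    lits <- tr$o[tr$s == node & tr$o_lit]
    return(tokenize(lits))
  }
  if (!is.null(terms) && node %in% names(terms)) {
    return(local_description(terms[[node]]))
  }
  tokenize(local_name(node))
}

# Encode the object column of a triple table as neighbor node strings:
# literals become "\"lex\"" so they remain distinguishable from IRIs.
encode_object_nodes <- function(tr) {
  ifelse(tr$o_lit, paste0("\"", nt_escape(tr$o), "\""), tr$o)
}

#' Neighbor sets of a term
#'
#' Subject neighbors are the subjects of triples in which the term occurs as
#' predicate or object; predicate neighbors the predicates of triples where it
#' occurs as subject or object; object neighbors the objects of triples where
#' it occurs as subject or predicate. The term itself is excluded; literal
#' neighbors are returned in quoted form.
#'
#' @param term An `rdf_term` or IRI string.
#' @param graph A `dataset_graph`.
#' @return `list(SN = , PN = , ON = )` of character vectors (sets).
#' @export
term_neighbors <- function(term, graph) {
  iri <- if (is.character(term)) term else term$iri
  tr <- graph$triples
  obj_is <- !tr$o_lit & tr$o == iri
  sn <- unique(tr$s[tr$p == iri | obj_is])
  pn <- unique(tr$p[tr$s == iri | obj_is])
  on_tr <- tr[tr$s == iri | tr$p == iri, , drop = FALSE]
  on <- unique(encode_object_nodes(on_tr))
  list(SN = setdiff(sn, iri), PN = setdiff(pn, iri), ON = setdiff(on, iri))
}

#' Merge several graphs into one
#'
#' @param graphs List of `dataset_graph` objects.
#' @param dataset_name Name for the merged graph.
#' @return A `dataset_graph` with the union of the triple sets.
#' @export
merge_graphs <- function(graphs, dataset_name = "merged") {
  tr <- do.call(rbind, lapply(graphs, function(g) g$triples))
  dataset_graph(dataset_name, triples = dedup_triples(tr))
}
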