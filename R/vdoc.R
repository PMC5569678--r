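# Virtual documents and the combined linguistic similarity.

#' Matcher configuration
#'
#' Holds the neighbor weighting factors of the virtual-document model, the
#' acceptance threshold of the aligner, and the optional synonym provider.
#' The recommended neighbor weights are 0.5 for all three neighbor kinds, and
#' the threshold defaults to 0.9 for high-precision alignments.
#'
#' @param gamma_s,gamma_p,gamma_o Weights in `[0, 1]` for subject, predicate
#'   and object neighbors.
#' @param threshold Minimum combined similarity for a mapping to be kept.
#' @param synonyms Optional synonym provider: a named list mapping a token to
#'   a character vector of synonym tokens (see [read_synonyms()]).
#' @param include_builtin Match terms from the RDF/RDFS/OWL/DC/SKOS/FOAF
#'   namespaces too? These are shared vocabulary, identical on both sides, so
#'   they are excluded by default.
#' @param label_properties,comment_properties Annotation properties feeding
#'   term descriptions.
#' @return A `match_config` list.
#' @export
match_config <- function(gamma_s = 0.5, gamma_p = 0.5, gamma_o = 0.5,
                         threshold = 0.9, synonyms = NULL,
                         include_builtin = FALSE,
                         label_properties = default_label_properties(),
                         comment_properties = default_comment_properties()) {
  stopifnot(gamma_s >= 0, gamma_s <= 1, gamma_p >= 0, gamma_p <= 1,
            gamma_o >= 0, gamma_o <= 1, threshold >= 0, threshold <= 1)
  structure(list(gamma_s = gamma_s, gamma_p = gamma_p, gamma_o = gamma_o,
                 threshold = threshold, synonyms = synonyms,
                 include_builtin = include_builtin,
                 label_properties = label_properties,
                 comment_properties = comment_properties),
            class = "match_config")
}

#' Enrich a local description with synonyms
#'
#' For every token of the description found in the provider, one copy of each
#' of its synonym tokens is appended unless already present. Applying the
#' enrichment twice with the same provider changes nothing.
#'
#' @param ld Character vector of tokens (a local description).
#' @param config A [match_config()]; with no synonym provider the description
#'   is returned unchanged.
#' @return The enriched token multiset.
#' @export
enrich_with_synonyms <- function(ld, config) {
  provider <- config$synonyms
  if (is.null(provider) || length(ld) == 0) return(ld)
  added <- character(0)
  present <- unique(ld)
  for (tok in unique(ld)) {
    syns <- provider[[tok]]
    if (is.null(syns)) next
    new <- setdiff(syns, c(present, added))
    added <- c(added, new)
  }
  c(ld, added)
}

# token multiset -> named count vector
token_counts <- function(tokens) {
  if (length(tokens) == 0) return(stats::setNames(numeric(0), character(0)))
  tab <- table(tokens)
  stats::setNames(as.numeric(tab), names(tab))
}

add_weights <- function(w, extra, factor = 1) {
  if (length(extra) == 0 || factor == 0) return(w)
  for (tok in names(extra)) {
    w[tok] <- (if (tok %in% names(w)) w[[tok]] else 0) + factor * extra[[tok]]
  }
  w
}

#' Build the virtual document of a term
#'
#' The virtual document is the local description of the term plus, for every
#' node in each of its three neighbor sets, the neighbor's local description
#' discounted by the corresponding weight (`gamma_s`, `gamma_p`, `gamma_o`).
#' A node occurring in several neighbor sets contributes once per set.
#' Synonym enrichment (when configured) applies to each local description
#' before weighting.
#'
#' @param term An `rdf_term`.
#' @param graph The `dataset_graph` the term belongs to.
#' @param config A [match_config()].
#' @param terms Optional pre-extracted term list of `graph` (avoids
#'   re-extraction in loops).
#' @return A `virtual_document`: named numeric vector of positive token
#'   weights.
#' @export
build_virtual_document <- function(term, graph, config = match_config(),
                                   terms = NULL) {
  if (is.null(terms)) terms <- extract_terms(graph, config$label_properties,
                                             config$comment_properties)
  ld <- function(node) {
    token_counts(enrich_with_synonyms(node_local_description(node, graph, terms),
                                      config))
  }
  w <- token_counts(enrich_with_synonyms(local_description(term), config))
  nb <- term_neighbors(term, graph)
  gammas <- c(SN = config$gamma_s, PN = config$gamma_p, ON = config$gamma_o)
  for (set in names(gammas)) {
    g <- gammas[[set]]
    if (g == 0) next
    for (node in nb[[set]]) w <- add_weights(w, ld(node), g)
  }
  w <- w[w > 0]
  structure(w, class = "virtual_document")
}

#' Cosine similarity of two virtual documents
#'
#' Dot product over the union vocabulary divided by the product of the
#' Euclidean norms; 0 when either document is empty.
#'
#' @param vd1,vd2 Virtual documents (named weight vectors).
#' @return Similarity in `[0, 1]`.
#' @export
vdoc_similarity <- function(vd1, vd2) {
  if (length(vd1) == 0 || length(vd2) == 0) return(0)
  shared <- intersect(names(vd1), names(vd2))
  if (length(shared) == 0) return(0)
  dot <- sum(unclass(vd1)[shared] * unclass(vd2)[shared])
  dot / (sqrt(sum(unclass(vd1)^2)) * sqrt(sum(unclass(vd2)^2)))
}

# The string I-Sub sees for a term: labels are preferred over the local name
# (opaque numeric identifiers say nothing), synonym-enriched, space-joined.
term_isub_string <- function(term, config) {
  toks <- c(tokenize(term$labels), tokenize(term$annotations))
  if (length(toks) == 0) toks <- tokenize(local_name(term$iri))
  toks <- enrich_with_synonyms(toks, config)
  paste(toks, collapse = " ")
}

#' Combined similarity of two terms
#'
#' The maximum of the virtual-document cosine similarity and the I-Sub string
#' similarity of the two terms' descriptions. Symmetric; terms must be of the
#' same kind (class with class, property with property).
#'
#' @param ts,tb `rdf_term`s (mediating-ontology side and dataset side).
#' @param graph_s,graph_b Their graphs.
#' @param config A [match_config()].
#' @param vd_s,vd_b Optional precomputed virtual documents.
#' @return Similarity in `[0, 1]`.
#' @export
combined_similarity <- function(ts, tb, graph_s, graph_b,
                                config = match_config(),
                                vd_s = NULL, vd_b = NULL) {
  if (!identical(ts$kind, tb$kind)) {
    stop(sprintf("Incompatible term kinds: %s (%s) vs %s (%s)",
                 ts$iri, ts$kind, tb$iri, tb$kind), call. = FALSE)
  }
  if (is.null(vd_s)) vd_s <- build_virtual_document(ts, graph_s, config)
  if (is.null(vd_b)) vd_b <- build_virtual_document(tb, graph_b, config)
  vdoc <- vdoc_similarity(vd_s, vd_b)
  isub <- isub_similarity(term_isub_string(ts, config),
                          term_isub_string(tb, config))
  max(vdoc, isub)
}
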