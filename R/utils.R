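# Well-known vocabulary IRIs and small shared helpers.

RDF_NS      <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS     <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS      <- "http://www.w3.org/2002/07/owl#"
XSD_NS      <- "http://www.w3.org/2001/XMLSchema#"
DC_NS       <- "http://purl.org/dc/elements/1.1/"
DCTERMS_NS  <- "http://purl.org/dc/terms/"
SKOS_NS     <- "http://www.w3.org/2004/02/skos/core#"
FOAF_NS     <- "http://xmlns.com/foaf/0.1/"
VOID_NS     <- "http://rdfs.org/ns/void#"

RDF_TYPE         <- paste0(RDF_NS, "type")
RDF_PROPERTY     <- paste0(RDF_NS, "Property")
RDFS_CLASS       <- paste0(RDFS_NS, "Class")
RDFS_SUBCLASSOF  <- paste0(RDFS_NS, "subClassOf")
RDFS_LABEL       <- paste0(RDFS_NS, "label")
RDFS_COMMENT     <- paste0(RDFS_NS, "comment")
OWL_CLASS        <- paste0(OWL_NS, "Class")
OWL_OBJECT_PROP  <- paste0(OWL_NS, "ObjectProperty")
OWL_DATA_PROP    <- paste0(OWL_NS, "DatatypeProperty")
OWL_ANN_PROP     <- paste0(OWL_NS, "AnnotationProperty")
DC_TITLE         <- paste0(DC_NS, "title")
DC_DESCRIPTION   <- paste0(DC_NS, "description")
DCTERMS_TITLE    <- paste0(DCTERMS_NS, "title")
SKOS_PREFLABEL   <- paste0(SKOS_NS, "prefLabel")

BUILTIN_NAMESPACES <- c(RDF_NS, RDFS_NS, OWL_NS, XSD_NS, DC_NS, DCTERMS_NS,
                        SKOS_NS, FOAF_NS, VOID_NS)

#' Default label-like annotation properties
#'
#' Properties whose literal values are treated as human-readable names of a
#' term or entity. Used when collecting term descriptions and when matching
#' keyword filters against entity text.
#' @return Character vector of property IRIs.
#' @export
default_label_properties <- function() {
  c(RDFS_LABEL, DC_TITLE, DCTERMS_TITLE, SKOS_PREFLABEL)
}

#' Default comment-like annotation properties
#' @return Character vector of property IRIs.
#' @export
default_comment_properties <- function() {
  c(RDFS_COMMENT, DC_DESCRIPTION)
}

is_builtin_iri <- function(iri) {
  res <- rep(FALSE, length(iri))
  for (ns in BUILTIN_NAMESPACES) {
    res <- res | startsWith(iri, ns)
  }
  res
}

#' Local name of an IRI
#'
#' The fragment after the last '/', '#' or ':' — the shape used by Bio2RDF
#' and SIO identifiers (e.g. `.../sio/010038` or `kegg:Drug`).
#' @param iri Character vector of IRIs.
#' @return Character vector of local names ("" when the IRI ends in a
#'   separator).
#' @export
local_name <- function(iri) {
  sub("^.*[/#:]", "", iri)
}

namespace_of <- function(iri) {
  m <- regexpr("^.*[/#:]", iri)
  ifelse(m > 0, substr(iri, 1L, attr(m, "match.length")), "")
}

# Split camelCase boundaries, then any non-alphanumeric run; lowercase;
# drop empty and purely numeric tokens (opaque numeric local names carry no
# lexical signal — their meaning lives in labels).
tokenize <- function(x, drop_numeric = TRUE) {
  if (length(x) == 0) return(character(0))
  x <- gsub("([[:lower:][:digit:]])([[:upper:]])", "\\1 \\2", x)
  x <- gsub("([[:upper:]])([[:upper:]][[:lower:]])", "\\1 \\2", x)
  toks <- unlist(strsplit(tolower(x), "[^[:alnum:]]+"))
  toks <- toks[nzchar(toks)]
  if (drop_numeric) toks <- toks[!grepl("^[[:digit:]]+$", toks)]
  toks
}

`%||%` <- function(a, b) if (is.null(a)) b else a
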