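# The EASE query language: plain keywords plus C:/P:/S: semantic tags.
#
# Token classification follows the interface definition exactly:
#   plain text          ^(?![CPS]:)\w+
#   class constraint    ^C:\w+
#   property constraint ^P:\w+
#   dataset constraint  ^S:\w+
# with \w case-insensitive alphanumerics and the tag letters themselves
# case-insensitive. A token that starts with a tag but carries no well-formed
# name (e.g. "C:" or "C:foo-bar") is malformed rather than silently reparsed.

EASE_TAG_RE <- "^[CcPpSs]:"

#' Parse an EASE query string
#'
#' Splits the text on whitespace and classifies each token as a plain
#' keyword or a class (`C:`), property (`P:`) or dataset (`S:`) constraint.
#' Tag letters are case-insensitive; the tag prefix is stripped from
#' constraint names.
#'
#' @param text Query string.
#' @return An `ease_query` with fields `plain`, `classes`, `properties`,
#'   `datasets` (character vectors, input order preserved).
#' @export
#' @examples
#' parse_ease("Alzheimer C:Disease C:Phenotype")
parse_ease <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  tokens <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0) {
    stop("Empty query: the text contains no tokens", call. = FALSE)
  }
  q <- list(plain = character(0), classes = character(0),
            properties = character(0), datasets = character(0))
  for (tok in tokens) {
    if (grepl(EASE_TAG_RE, tok)) {
      name <- substr(tok, 3L, nchar(tok))
      if (!grepl("^[[:alnum:]_]+$", name)) {
        stop(sprintf("Malformed semantic tag '%s': expected %s:<name> with an alphanumeric name",
                     tok, toupper(substr(tok, 1L, 1L))), call. = FALSE)
      }
      slot <- switch(toupper(substr(tok, 1L, 1L)),
                     C = "classes", P = "properties", S = "datasets")
      q[[slot]] <- c(q[[slot]], name)
    } else {
      q$plain <- c(q$plain, tok)
    }
  }
  structure(q, class = "ease_query")
}

#' Render an EASE query back to text
#'
#' @param query An `ease_query`.
#' @return The query string (plain keywords first, then C:, P:, S: tags).
#' @export
render_ease <- function(query) {
  paste(c(query$plain,
          if (length(query$classes)) paste0("C:", query$classes),
          if (length(query$properties)) paste0("P:", query$properties),
          if (length(query$datasets)) paste0("S:", query$datasets)),
        collapse = " ")
}

#' @export
print.ease_query <- function(x, ...) {
  cat("<ease_query>", render_ease(x), "\n")
  invisible(x)
}

#' Logical form of an EASE query
#'
#' AND logic combines the four keyword categories; OR logic combines multiple
#' keywords within one category. Rendering the form reproduces the bracketed
#' notation, e.g. `(alzheimer) AND (C:Phenotype OR C:Disease)`.
#'
#' @param query An `ease_query`.
#' @return An `ease_logical_form`: a list of groups, each
#'   `list(category = , leaves = )` with leaves keeping the original token
#'   text (tag included for constraints).
#' @export
logical_form <- function(query) {
  groups <- list()
  add <- function(category, tokens, tag = NULL) {
    if (length(tokens) == 0) return()
    leaves <- if (is.null(tag)) tokens else paste0(tag, tokens)
    groups[[length(groups) + 1L]] <<- list(category = category, leaves = leaves)
  }
  add("plain", query$plain)
  add("class", query$classes, "C:")
  add("property", query$properties, "P:")
  add("dataset", query$datasets, "S:")
  structure(groups, class = "ease_logical_form")
}

#' @export
format.ease_logical_form <- function(x, ...) {
  paste(vapply(x, function(g) paste0("(", paste(g$leaves, collapse = " OR "), ")"),
               character(1)),
        collapse = " AND ")
}

#' @export
print.ease_logical_form <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Auto-complete a semantic tag prefix
#'
#' After `C:` or `P:` offers mediating-ontology class/property names whose
#' name (or a label) starts with the typed fragment, case-insensitively;
#' after `S:` offers registered dataset names.
#'
#' @param prefix The typed text, beginning with a tag (e.g. `"C:Dr"`).
#' @param registry A `dataset_registry` (for `S:`).
#' @param ontology The mediating `dataset_graph` (for `C:`/`P:`).
#' @return Sorted character vector of candidate completions (names only,
#'   without the tag).
#' @export
autocomplete <- function(prefix, registry = NULL, ontology = NULL) {
  if (!grepl(EASE_TAG_RE, prefix)) return(character(0))
  tag <- toupper(substr(prefix, 1L, 1L))
  frag <- tolower(substr(prefix, 3L, nchar(prefix)))
  if (tag == "S") {
    cands <- if (is.null(registry)) character(0) else names(registry)
  } else {
    if (is.null(ontology)) return(character(0))
    terms <- extract_terms(ontology)
    kind <- if (tag == "C") "class" else "property"
    terms <- Filter(function(t) t$kind == kind, terms)
    cands <- unique(unlist(lapply(terms, function(t) {
      c(local_name(t$iri), t$labels)
    })))
    cands <- cands[nzchar(cands)]
  }
  hits <- cands[startsWith(tolower(cands), frag)]
  sort(unique(hits), method = "radix")
}
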