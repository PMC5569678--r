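# Mapping-based query answering: EASE query -> global query against the
# mediating ontology -> per-dataset local SPARQL via the alignments (GAV
# rewriting) -> federated execution -> merged result set.

#' The common-property extension of the mediating ontology
#'
#' 54 commonly-used properties from RDF(S), OWL, DC/DCTERMS, FOAF, SKOS and
#' VoID that datasets share verbatim. Property constraints resolve against
#' these in addition to the mediating ontology's own properties, and they are
#' rewritten by identity (no mapping needed).
#'
#' @return Character vector of property IRIs.
#' @export
common_properties <- function() {
  c(paste0(RDF_NS, c("type", "value")),
    paste0(RDFS_NS, c("label", "comment", "seeAlso", "isDefinedBy")),
    paste0(OWL_NS, c("sameAs", "differentFrom", "versionInfo")),
    paste0(DC_NS, c("title", "creator", "subject", "description", "publisher",
                    "contributor", "date", "type", "format", "identifier",
                    "source", "language", "relation", "coverage", "rights")),
    paste0(DCTERMS_NS, c("title", "description", "identifier", "alternative",
                         "abstract", "created", "modified", "issued",
                         "license", "bibliographicCitation")),
    paste0(FOAF_NS, c("name", "homepage", "page", "depiction", "img", "logo",
                      "mbox", "nick")),
    paste0(SKOS_NS, c("prefLabel", "altLabel", "hiddenLabel", "definition",
                      "note", "notation", "broader", "narrower", "related",
                      "exactMatch", "closeMatch")),
    paste0(VOID_NS, "inDataset"))
}

#' Search configuration
#'
#' @param text_properties Property IRIs whose literals the keyword filter
#'   scans; `NULL` (default) means any literal of the entity.
#' @param metadata_namespaces Namespaces whose properties belong to the
#'   metadata display group.
#' @param xlink_regex Pattern (on the property local name, case-insensitive)
#'   identifying cross-dataset link properties.
#' @return A `search_config` list.
#' @export
search_config <- function(text_properties = NULL,
                          metadata_namespaces = c(RDF_NS, RDFS_NS, OWL_NS,
                                                  DC_NS, DCTERMS_NS, FOAF_NS,
                                                  VOID_NS),
                          xlink_regex = "^x-") {
  structure(list(text_properties = text_properties,
                 metadata_namespaces = metadata_namespaces,
                 xlink_regex = xlink_regex),
            class = "search_config")
}

# ---- Class expansion --------------------------------------------------------

#' Expand classes over the subclass hierarchy
#'
#' Returns the input classes plus the full transitive closure of their
#' subclasses in the mediating ontology. Terminates on cycles.
#'
#' @param classes Character vector of class IRIs.
#' @param mediating The mediating `dataset_graph`.
#' @return Sorted character vector of class IRIs (superset of the input).
#' @export
expand_classes <- function(classes, mediating) {
  tr <- mediating$triples
  sub_tr <- tr[tr$p == RDFS_SUBCLASSOF & !tr$o_lit, , drop = FALSE]
  known <- unique(c(tr$s[tr$p == RDF_TYPE & tr$o %in% c(RDFS_CLASS, OWL_CLASS)],
                    sub_tr$s, sub_tr$o))
  unknown <- setdiff(classes, known)
  if (length(unknown) > 0) {
    stop("Unknown class in mediating ontology: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  seen <- character(0)
  frontier <- classes
  while (length(frontier) > 0) {
    seen <- union(seen, frontier)
    children <- unique(sub_tr$s[sub_tr$o %in% frontier])
    frontier <- setdiff(children, seen)
  }
  sort(seen, method = "radix")
}

# ---- Global query -----------------------------------------------------------

resolve_names <- function(names_, terms, kind) {
  kinds <- vapply(terms, function(t) t$kind, character(1))
  cand <- terms[kinds == kind]
  hits <- lapply(names_, function(nm) {
    key <- tolower(nm)
    iris <- names(cand)[vapply(cand, function(t) {
      tolower(local_name(t$iri)) == key ||
        any(tolower(gsub("[^[:alnum:]]", "", t$labels)) == key)
    }, logical(1))]
    if (length(iris) == 0) {
      stop(sprintf("Unknown %s name in mediating ontology: '%s'", kind, nm),
           call. = FALSE)
    }
    iris
  })
  unique(unlist(hits))
}

#' Build the global query for an EASE query
#'
#' Class constraints are resolved against the mediating ontology
#' (case-insensitive match on local name or label) and expanded over the
#' subclass hierarchy; property constraints resolve against the mediating
#' properties plus the common-property extension; plain keywords become
#' keyword filters; dataset constraints fix the federation scope.
#'
#' @param query An `ease_query`.
#' @param mediating The mediating `dataset_graph`.
#' @param registry A `dataset_registry`.
#' @param config A [search_config()].
#' @return A `global_query` with fields `classes` (expanded IRI set),
#'   `class_seeds`, `properties`, `keywords`, `datasets` (empty = all).
#' @export
build_global_query <- function(query, mediating, registry,
                               config = search_config()) {
  terms <- extract_terms(mediating)
  class_seeds <- character(0)
  classes <- character(0)
  if (length(query$classes) > 0) {
    class_seeds <- resolve_names(query$classes, terms, "class")
    classes <- expand_classes(class_seeds, mediating)
  }
  properties <- character(0)
  if (length(query$properties) > 0) {
    common <- common_properties()
    common_terms <- lapply(common, function(iri) {
      structure(list(iri = iri, kind = "property", labels = character(0),
                     annotations = character(0)), class = "rdf_term")
    })
    names(common_terms) <- common
    all_props <- c(terms, common_terms[setdiff(common, names(terms))])
    properties <- resolve_names(query$properties, all_props, "property")
  }
  datasets <- character(0)
  if (length(query$datasets) > 0) {
    datasets <- vapply(query$datasets, function(nm) {
      hit <- names(registry)[tolower(names(registry)) == tolower(nm)]
      if (length(hit) == 0) {
        stop("Unknown dataset: '", nm, "'", call. = FALSE)
      }
      hit[1]
    }, character(1), USE.NAMES = FALSE)
    datasets <- unique(datasets)
  }
  structure(list(classes = classes, class_seeds = class_seeds,
                 properties = properties, keywords = query$plain,
                 datasets = datasets),
            class = "global_query")
}

# ---- Rewriting --------------------------------------------------------------

local_query <- function(dataset_name, class_iri = NA_character_,
                        property_iri = NA_character_, keywords = character(0),
                        graph_iri = NULL, global_class = NA_character_,
                        global_property = NA_character_) {
  structure(list(dataset_name = dataset_name, class_iri = class_iri,
                 property_iri = property_iri, keywords = keywords,
                 graph_iri = graph_iri, global_class = global_class,
                 global_property = global_property),
            class = "local_query")
}

#' Rewrite a global query into per-dataset local queries
#'
#' For each dataset in scope, every global class option is substituted by
#' each of its mapped local classes and every global property option by each
#' of its mapped local properties (1-to-many mappings fan out). One local
#' query is produced per combination of one class pattern and one property
#' pattern, carrying the keyword filter. Common-extension properties rewrite
#' by identity. Combinations whose required term has no mapping for a dataset
#' are skipped for that dataset; a dataset expressing no combination
#' contributes nothing.
#'
#' @param global A `global_query`.
#' @param alignments Named list (dataset name -> `alignment`).
#' @param registry A `dataset_registry`.
#' @return A `query_plan`: list with `local_queries` and, per query, the
#'   provenance (`global_class`, `global_property`) of the substitutions.
#' @export
rewrite_to_local <- function(global, alignments, registry) {
  scope <- if (length(global$datasets) > 0) global$datasets else names(registry)
  common <- common_properties()
  queries <- list()
  for (ds in scope) {
    al <- alignments[[ds]]
    mp <- if (is.null(al)) NULL else al$mappings
    graph_iri <- registry[[ds]]$graph_iri

    class_pairs <- NULL   # (global, local) substitutions
    if (length(global$classes) > 0) {
      hits <- mp[mp$source %in% global$classes, , drop = FALSE]
      if (is.null(hits) || nrow(hits) == 0) {
        message(sprintf("Dataset %s: no mapping for any class option; skipped", ds))
        next
      }
      class_pairs <- hits[c("source", "target")]
    }
    prop_pairs <- NULL
    if (length(global$properties) > 0) {
      hits <- mp[mp$source %in% global$properties, , drop = FALSE]
      idty <- intersect(global$properties, common)
      prop_pairs <- rbind(
        if (!is.null(hits) && nrow(hits) > 0) hits[c("source", "target")],
        if (length(idty)) data.frame(source = idty, target = idty,
                                     stringsAsFactors = FALSE))
      if (is.null(prop_pairs) || nrow(prop_pairs) == 0) {
        message(sprintf("Dataset %s: no mapping for any property option; skipped", ds))
        next
      }
      prop_pairs <- prop_pairs[!duplicated(prop_pairs), , drop = FALSE]
    }

    ci <- seq_len(max(1L, if (is.null(class_pairs)) 0L else nrow(class_pairs)))
    pi <- seq_len(max(1L, if (is.null(prop_pairs)) 0L else nrow(prop_pairs)))
    for (i in ci) {
      for (j in pi) {
        queries[[length(queries) + 1L]] <- local_query(
          dataset_name = ds,
          class_iri = if (is.null(class_pairs)) NA_character_ else class_pairs$target[i],
          property_iri = if (is.null(prop_pairs)) NA_character_ else prop_pairs$target[j],
          keywords = global$keywords,
          graph_iri = graph_iri,
          global_class = if (is.null(class_pairs)) NA_character_ else class_pairs$source[i],
          global_property = if (is.null(prop_pairs)) NA_character_ else prop_pairs$source[j])
      }
    }
  }
  if (length(queries) == 0) {
    warning("Empty query plan: no dataset in scope can express the query")
  }
  structure(list(local_queries = queries), class = "query_plan")
}

#' @export
print.query_plan <- function(x, ...) {
  cat(sprintf("<query_plan> %d local queries over %d dataset(s)\n",
              length(x$local_queries),
              length(unique(vapply(x$local_queries,
                                   function(q) q$dataset_name, character(1))))))
  invisible(x)
}

# ---- SPARQL rendering -------------------------------------------------------

escape_regex_literal <- function(x) {
  gsub("([.\\\\+*?\\[\\]^$(){}=!<>|:#-])", "\\\\\\1", x, perl = TRUE)
}

escape_sparql_string <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  gsub("\"", "\\\"", x, fixed = TRUE)
}

#' Render a local query as SPARQL 1.1
#'
#' `SELECT DISTINCT ?s` over the query's triple patterns; plain keywords
#' become a case-insensitive regex filter over the entity's literals,
#' OR-combined across keywords. The named-graph dialect wraps the patterns in
#' the dataset's `GRAPH` clause.
#'
#' @param local A `local_query`.
#' @param dialect `"portable"` or `"named-graph"`.
#' @param config A [search_config()]; restricting `text_properties` narrows
#'   which literals the filter scans.
#' @return A SPARQL SELECT string.
#' @export
render_sparql <- function(local, dialect = c("portable", "named-graph"),
                          config = search_config()) {
  dialect <- match.arg(dialect)
  pat <- character(0)
  if (!is.na(local$class_iri)) {
    pat <- c(pat, sprintf("?s a <%s> .", local$class_iri))
  } else {
    # without a class pattern, keep schema terms out of the entity results,
    # mirroring the in-memory evaluator
    pat <- c(pat, "?s ?p0 ?o0 .",
             "FILTER NOT EXISTS { ?i0 a ?s . }",
             "FILTER NOT EXISTS { ?x0 ?s ?y0 . }",
             sprintf("FILTER NOT EXISTS { ?s a ?m0 . VALUES ?m0 { %s } }",
                     paste(sprintf("<%s>", c(RDFS_CLASS, OWL_CLASS,
                                             RDF_PROPERTY, OWL_OBJECT_PROP,
                                             OWL_DATA_PROP, OWL_ANN_PROP)),
                           collapse = " ")),
             sprintf("FILTER NOT EXISTS { ?s <%s> ?c0 . }", RDFS_SUBCLASSOF),
             sprintf("FILTER NOT EXISTS { ?c1 <%s> ?s . }", RDFS_SUBCLASSOF))
  }
  if (!is.na(local$property_iri)) {
    pat <- c(pat, sprintf("?s <%s> ?pv .", local$property_iri))
  }
  if (length(local$keywords) > 0) {
    pat <- c(pat, "?s ?tp ?txt .")
    flt <- paste(sprintf("REGEX(STR(?txt), \"%s\", \"i\")",
                         escape_sparql_string(escape_regex_literal(local$keywords))),
                 collapse = " || ")
    guards <- "isLiteral(?txt)"
    if (!is.null(config$text_properties)) {
      guards <- c(guards,
                  paste0("?tp IN (",
                         paste(sprintf("<%s>", config$text_properties),
                               collapse = ", "), ")"))
    }
    pat <- c(pat, sprintf("FILTER(%s && (%s))",
                          paste(guards, collapse = " && "), flt))
  }
  body <- paste0("  ", pat, collapse = "\n")
  if (dialect == "named-graph" && !is.null(local$graph_iri)) {
    body <- paste0("  GRAPH <", local$graph_iri, "> {\n",
                   gsub("(?m)^", "  ", body, perl = TRUE), "\n  }")
  }
  paste0("SELECT DISTINCT ?s WHERE {\n", body, "\n}")
}

# ---- In-memory evaluation ---------------------------------------------------

iri_subjects <- function(tr) unique(tr$s[!startsWith(tr$s, "_:")])

# IRIs playing a schema role: predicates, typing objects, declared
# classes/properties, subclass ends. Query results are entities (instances),
# never the vocabulary itself, on both the federated and the oracle side.
schema_iris <- function(tr) {
  type_tr <- tr[tr$p == RDF_TYPE & !tr$o_lit, , drop = FALSE]
  meta <- c(RDFS_CLASS, OWL_CLASS, RDF_PROPERTY, OWL_OBJECT_PROP,
            OWL_DATA_PROP, OWL_ANN_PROP)
  sub_tr <- tr[tr$p == RDFS_SUBCLASSOF & !tr$o_lit, , drop = FALSE]
  unique(c(tr$p, type_tr$o, type_tr$s[type_tr$o %in% meta],
           sub_tr$s, sub_tr$o))
}

entity_candidates <- function(tr) {
  setdiff(iri_subjects(tr), schema_iris(tr))
}

# Matched keywords per entity: named list entity -> character vector.
keyword_hits <- function(tr, entities, keywords, config) {
  lit <- tr[tr$o_lit & tr$s %in% entities, , drop = FALSE]
  if (!is.null(config$text_properties)) {
    lit <- lit[lit$p %in% config$text_properties, , drop = FALSE]
  }
  res <- lapply(stats::setNames(entities, entities), function(e) character(0))
  if (nrow(lit) == 0 || length(keywords) == 0) return(res)
  low <- tolower(lit$o)
  for (kw in keywords) {
    hit_s <- unique(lit$s[grepl(tolower(kw), low, fixed = TRUE)])
    for (e in hit_s) res[[e]] <- c(res[[e]], kw)
  }
  res
}

evaluate_local_query <- function(local, graph, config = search_config()) {
  tr <- graph$triples
  cand <- entity_candidates(tr)
  if (!is.na(local$class_iri)) {
    cand <- intersect(cand, tr$s[tr$p == RDF_TYPE & !tr$o_lit &
                                   tr$o == local$class_iri])
  }
  if (!is.na(local$property_iri)) {
    cand <- intersect(cand, tr$s[tr$p == local$property_iri])
  }
  if (length(local$keywords) > 0) {
    hits <- keyword_hits(tr, cand, local$keywords, config)
    cand <- names(hits)[vapply(hits, length, integer(1)) > 0]
    return(list(entities = cand, matched = hits[cand]))
  }
  list(entities = cand,
       matched = lapply(stats::setNames(cand, cand), function(e) character(0)))
}

# ---- Result sets ------------------------------------------------------------

result_set <- function(entity = character(0), dataset = character(0),
                       matched_keywords = list(), matched_classes = list(),
                       descriptions = list()) {
  structure(list(entity = entity, dataset = dataset,
                 matched_keywords = matched_keywords,
                 matched_classes = matched_classes,
                 descriptions = descriptions),
            class = "result_set")
}

#' @export
print.result_set <- function(x, ...) {
  cat(sprintf("<result_set> %d entities from %d dataset(s)\n",
              length(x$entity), length(unique(x$dataset))))
  invisible(x)
}

#' @export
length.result_set <- function(x) length(x$entity)

result_subset <- function(results, idx) {
  result_set(results$entity[idx], results$dataset[idx],
             results$matched_keywords[idx], results$matched_classes[idx],
             results$descriptions[idx])
}

#' Execute a query plan federatedly
#'
#' Runs each local query against its dataset, merges and deduplicates per
#' (entity, dataset), and attaches each entity's description (its outgoing
#' triples). A failing dataset is isolated: its results are dropped with a
#' warning; only when every dataset fails is an error raised.
#'
#' @param plan A `query_plan`.
#' @param registry A `dataset_registry` (graphs in memory or loadable).
#' @param config A [search_config()].
#' @return A `result_set`.
#' @export
execute_plan <- function(plan, registry, config = search_config()) {
  by_ds <- split(plan$local_queries,
                 vapply(plan$local_queries, function(q) q$dataset_name,
                        character(1)))
  out <- result_set()
  failures <- character(0)
  for (ds in names(by_ds)) {
    res <- tryCatch({
      graph <- registry_graph(registry, ds)
      tr <- graph$triples
      ents <- character(0)
      kw <- list(); cls <- list()
      for (lq in by_ds[[ds]]) {
        ev <- evaluate_local_query(lq, graph, config)
        for (e in ev$entities) {
          if (!e %in% ents) {
            ents <- c(ents, e)
            kw[[e]] <- character(0)
            cls[[e]] <- character(0)
          }
          kw[[e]] <- unique(c(kw[[e]], ev$matched[[e]]))
          if (!is.na(lq$global_class)) {
            cls[[e]] <- unique(c(cls[[e]], lq$global_class))
          }
        }
      }
      desc <- lapply(ents, function(e) {
        d <- tr[tr$s == e, , drop = FALSE]
        rownames(d) <- NULL
        d
      })
      list(entities = ents, kw = kw, cls = cls, desc = desc)
    }, error = function(e) {
      warning(sprintf("Dataset %s failed: %s", ds, conditionMessage(e)),
              call. = FALSE)
      failures <<- c(failures, sprintf("%s: %s", ds, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) next
    out$entity <- c(out$entity, res$entities)
    out$dataset <- c(out$dataset, rep(ds, length(res$entities)))
    out$matched_keywords <- c(out$matched_keywords, unname(res$kw[res$entities]))
    out$matched_classes <- c(out$matched_classes, unname(res$cls[res$entities]))
    out$descriptions <- c(out$descriptions, res$desc)
  }
  if (length(by_ds) > 0 && length(failures) == length(by_ds)) {
    stop("Federated execution failed for every dataset:\n  ",
         paste(failures, collapse = "\n  "), call. = FALSE)
  }
  out
}

#' Evaluate a global query directly on one graph
#'
#' Applies the global query's class options (any-of), property options
#' (any-of) and keyword filter (any-of) to a single graph that already speaks
#' the mediating vocabulary — the oracle counterpart of federated execution
#' over a homogenized merged graph.
#'
#' @param global A `global_query`.
#' @param graph A `dataset_graph` in mediating vocabulary.
#' @param config A [search_config()].
#' @return Character vector of entity IRIs satisfying the query.
#' @export
evaluate_global_query <- function(global, graph, config = search_config()) {
  tr <- graph$triples
  cand <- entity_candidates(tr)
  if (length(global$classes) > 0) {
    cand <- intersect(cand, tr$s[tr$p == RDF_TYPE & !tr$o_lit &
                                   tr$o %in% global$classes])
  }
  if (length(global$properties) > 0) {
    cand <- intersect(cand, tr$s[tr$p %in% global$properties])
  }
  if (length(global$keywords) > 0) {
    hits <- keyword_hits(tr, cand, global$keywords, config)
    cand <- names(hits)[vapply(hits, length, integer(1)) > 0]
  }
  sort(cand, method = "radix")
}

#' End-to-end search
#'
#' Parses an EASE string, builds and expands the global query, rewrites it
#' through the alignments, executes the plan and ranks the results.
#'
#' @param text EASE query string.
#' @param mediating Mediating `dataset_graph`.
#' @param registry A `dataset_registry`.
#' @param alignments Named list of `alignment`s.
#' @param config A [search_config()].
#' @return Ranked list of `entity_card`s (see [rank_results()]).
#' @export
semantic_search <- function(text, mediating, registry, alignments,
                            config = search_config()) {
  q <- parse_ease(text)
  global <- build_global_query(q, mediating, registry, config)
  plan <- rewrite_to_local(global, alignments, registry)
  results <- execute_plan(plan, registry, config)
  rank_results(results, q, config)
}
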