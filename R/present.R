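# Result presentation: entity cards, property grouping, ranking, faceted
# filters, and cross-dataset link resolution.

display_label <- function(desc, iri) {
  labs <- desc$o[desc$o_lit & desc$p %in% default_label_properties()]
  if (length(labs) > 0) labs[1] else local_name(iri)
}

#' Group an entity's description properties
#'
#' Three display groups partition the description pairs: *metadata*
#' (properties from the configured metadata namespaces — RDF(S), OWL,
#' DC/DCTERMS, FOAF by default), *entity_linking* (properties whose local
#' name matches the x-link pattern, the Bio2RDF `x-<dataset>` convention),
#' and *domain_specific* (everything else). Pairs within each group are
#' sorted alphabetically by property, then value.
#'
#' @param desc Triple data.frame of the entity's outgoing triples.
#' @param config A [search_config()].
#' @return `list(metadata =, domain_specific =, entity_linking =)` of
#'   data.frames with columns `property`, `value`, `is_iri`.
#' @export
group_properties <- function(desc, config = search_config()) {
  pairs <- data.frame(property = desc$p, value = desc$o,
                      is_iri = !desc$o_lit & !startsWith(desc$o, "_:"),
                      stringsAsFactors = FALSE)
  is_xlink <- grepl(config$xlink_regex, local_name(pairs$property),
                    ignore.case = TRUE)
  is_meta <- rep(FALSE, nrow(pairs))
  for (ns in config$metadata_namespaces) {
    is_meta <- is_meta | startsWith(pairs$property, ns)
  }
  is_meta <- is_meta & !is_xlink
  pick <- function(keep) {
    g <- pairs[keep, , drop = FALSE]
    g <- g[order(g$property, g$value, method = "radix"), , drop = FALSE]
    rownames(g) <- NULL
    g
  }
  list(metadata = pick(is_meta),
       domain_specific = pick(!is_meta & !is_xlink),
       entity_linking = pick(is_xlink))
}

entity_card <- function(iri, dataset, desc, matched_keywords,
                        matched_classes, config) {
  structure(list(iri = iri, dataset_name = dataset,
                 display_label = display_label(desc, iri),
                 matched_keywords = matched_keywords,
                 matched_classes = matched_classes,
                 groups = group_properties(desc, config),
                 description = desc),
            class = "entity_card")
}

#' @export
print.entity_card <- function(x, ...) {
  cat(sprintf("<entity_card> %s [%s] \"%s\" (%d keyword hits)\n", x$iri,
              x$dataset_name, x$display_label, length(x$matched_keywords)))
  invisible(x)
}

#' Rank search results
#'
#' Entities that simultaneously contain more of the query's plain keywords
#' rank higher. Ties are broken by the number of matched class options, then
#' display label, then IRI — a total, deterministic order independent of
#' input order.
#'
#' @param results A `result_set`.
#' @param query The originating `ease_query`.
#' @param config A [search_config()].
#' @return Ordered list of `entity_card`s.
#' @export
rank_results <- function(results, query, config = search_config()) {
  n <- length(results$entity)
  if (n == 0) return(list())
  cards <- lapply(seq_len(n), function(i) {
    entity_card(results$entity[i], results$dataset[i],
                results$descriptions[[i]],
                results$matched_keywords[[i]] %||% character(0),
                results$matched_classes[[i]] %||% character(0),
                config)
  })
  nkw <- vapply(cards, function(c) length(unique(c$matched_keywords)), integer(1))
  ncl <- vapply(cards, function(c) length(unique(c$matched_classes)), integer(1))
  lab <- vapply(cards, function(c) c$display_label, character(1))
  iri <- vapply(cards, function(c) c$iri, character(1))
  cards[order(-nkw, -ncl, lab, iri, method = "radix")]
}

# ---- Facets -----------------------------------------------------------------

#' Build the faceted filter tree
#'
#' Extracts the classes and properties of the result entities as leaves with
#' distinct-entity counts. A leaf hangs under a mediating-ontology term when
#' an alignment mapping connects them, otherwise under its dataset's bucket
#' (so dataset-specific vocabulary is not lost). A third facet counts
#' entities per dataset.
#'
#' @param results A `result_set`.
#' @param alignments Named list of `alignment`s.
#' @param mediating The mediating `dataset_graph` (reserved for labelling;
#'   attachment needs only the alignments).
#' @param config A [search_config()].
#' @return A `facet_tree` with data.frames `classes`, `properties` (columns
#'   `leaf`, `dataset`, `parent`, `parent_type`, `count`) and `datasets`
#'   (columns `dataset`, `count`).
#' @export
build_facets <- function(results, alignments, mediating = NULL,
                         config = search_config()) {
  n <- length(results$entity)
  leaf_rows <- function(extract) {
    rows <- list()
    for (i in seq_len(n)) {
      for (leaf in extract(results$descriptions[[i]])) {
        rows[[length(rows) + 1L]] <- data.frame(
          leaf = leaf, dataset = results$dataset[i],
          entity = results$entity[i], stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0) {
      return(data.frame(leaf = character(0), dataset = character(0),
                        parent = character(0), parent_type = character(0),
                        count = integer(0), stringsAsFactors = FALSE))
    }
    df <- unique(do.call(rbind, rows))
    agg <- stats::aggregate(entity ~ leaf + dataset, data = df, FUN = length)
    names(agg)[names(agg) == "entity"] <- "count"
    parent <- character(nrow(agg)); ptype <- character(nrow(agg))
    for (k in seq_len(nrow(agg))) {
      al <- alignments[[agg$dataset[k]]]
      src <- if (is.null(al)) character(0) else
        al$mappings$source[al$mappings$target == agg$leaf[k]]
      if (length(src) > 0) {
        parent[k] <- sort(src, method = "radix")[1]
        ptype[k] <- "mediating"
      } else {
        parent[k] <- agg$dataset[k]
        ptype[k] <- "dataset"
      }
    }
    agg$parent <- parent
    agg$parent_type <- ptype
    agg <- agg[order(agg$leaf, agg$dataset, method = "radix"), ,
               drop = FALSE]
    rownames(agg) <- NULL
    agg[c("leaf", "dataset", "parent", "parent_type", "count")]
  }
  classes <- leaf_rows(function(desc) {
    unique(desc$o[desc$p == RDF_TYPE & !desc$o_lit])
  })
  properties <- leaf_rows(function(desc) unique(desc$p))
  ds <- if (n == 0) {
    data.frame(dataset = character(0), count = integer(0),
               stringsAsFactors = FALSE)
  } else {
    tab <- table(results$dataset)
    data.frame(dataset = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE)
  }
  structure(list(classes = classes, properties = properties, datasets = ds),
            class = "facet_tree")
}

#' @export
print.facet_tree <- function(x, ...) {
  cat(sprintf("<facet_tree> %d class leaves, %d property leaves, %d datasets\n",
              nrow(x$classes), nrow(x$properties), nrow(x$datasets)))
  invisible(x)
}

#' A facet leaf
#'
#' @param type `"class"`, `"property"` or `"dataset"`.
#' @param value Class/property IRI, or the dataset name.
#' @param dataset For class/property leaves, optionally restrict to one
#'   dataset's leaf.
#' @return A `facet_leaf`.
#' @export
facet_leaf <- function(type = c("class", "property", "dataset"), value,
                       dataset = NULL) {
  type <- match.arg(type)
  structure(list(type = type, value = value, dataset = dataset),
            class = "facet_leaf")
}

#' Refine results by a facet leaf
#'
#' Keeps the entities carrying the leaf's class/property (optionally within
#' one dataset) or belonging to the leaf's dataset. Applying the same leaf
#' twice is a no-op; a leaf matched by no current entity is stale and raises
#' an error.
#'
#' @param results A `result_set`.
#' @param leaf A [facet_leaf()].
#' @return The refined `result_set`.
#' @export
apply_facet <- function(results, leaf) {
  n <- length(results$entity)
  keep <- vapply(seq_len(n), function(i) {
    if (!is.null(leaf$dataset) && results$dataset[i] != leaf$dataset) {
      return(FALSE)
    }
    desc <- results$descriptions[[i]]
    switch(leaf$type,
           dataset = results$dataset[i] == leaf$value,
           class = any(desc$p == RDF_TYPE & !desc$o_lit & desc$o == leaf$value),
           property = any(desc$p == leaf$value))
  }, logical(1))
  if (n > 0 && !any(keep)) {
    stop(sprintf("Unknown facet: no current result carries %s '%s'",
                 leaf$type, leaf$value), call. = FALSE)
  }
  result_subset(results, keep)
}

# ---- Cross-dataset links ----------------------------------------------------

#' Resolve an entity's cross-dataset links
#'
#' For every pair in the entity-linking group whose value is an IRI, the
#' target dataset is inferred from the `x-<name>` link property or, failing
#' that, from the target IRI's namespace; unresolvable targets are reported
#' with dataset `"unknown"`.
#'
#' @param card An `entity_card`.
#' @param registry A `dataset_registry`.
#' @param config A [search_config()].
#' @return data.frame with columns `property`, `target`, `target_dataset`.
#' @export
resolve_xlinks <- function(card, registry, config = search_config()) {
  links <- card$groups$entity_linking
  links <- links[links$is_iri, , drop = FALSE]
  if (nrow(links) == 0) {
    return(data.frame(property = character(0), target = character(0),
                      target_dataset = character(0), stringsAsFactors = FALSE))
  }
  reg_names <- names(registry)
  infer <- function(prop, target) {
    ln <- local_name(prop)
    m <- regmatches(ln, regexec(paste0(config$xlink_regex, "(.*)$"), ln,
                                ignore.case = TRUE))[[1]]
    if (length(m) >= 2 && nzchar(m[2])) {
      hit <- reg_names[tolower(reg_names) == tolower(m[2])]
      if (length(hit) > 0) return(hit[1])
    }
    for (nm in reg_names) {
      if (grepl(paste0("/", tolower(nm), "/"), tolower(target), fixed = TRUE)) {
        return(nm)
      }
    }
    "unknown"
  }
  data.frame(property = links$property, target = links$value,
             target_dataset = vapply(seq_len(nrow(links)), function(i) {
               infer(links$property[i], links$value[i])
             }, character(1)),
             stringsAsFactors = FALSE)
}

# ---- JSON serialization -----------------------------------------------------

card_to_list <- function(card) {
  list(iri = card$iri, dataset = card$dataset_name,
       label = card$display_label,
       matched_keywords = as.list(card$matched_keywords),
       grouped_properties = lapply(card$groups, function(g) {
         lapply(seq_len(nrow(g)), function(i) {
           list(property = g$property[i], value = g$value[i],
                is_iri = g$is_iri[i])
         })
       }))
}

#' Serialize ranked results (and optional facets) to JSON
#'
#' @param cards List of `entity_card`s.
#' @param facets Optional `facet_tree`.
#' @return A JSON string.
#' @export
results_to_json <- function(cards, facets = NULL) {
  doc <- list(entities = lapply(cards, card_to_list))
  if (!is.null(facets)) {
    doc$facets <- list(classes = facets$classes,
                       properties = facets$properties,
                       datasets = facets$datasets)
  }
  jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
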