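# Alignment extraction, evaluation, and the TSV interchange format.

#' Construct an alignment
#'
#' @param dataset_name The dataset the mappings target.
#' @param mappings data.frame with columns `source` (mediating term IRI),
#'   `target` (dataset term IRI), `score`, `relation`.
#' @return An `alignment` object.
#' @export
alignment <- function(dataset_name,
                      mappings = data.frame(source = character(0),
                                            target = character(0),
                                            score = numeric(0),
                                            relation = character(0),
                                            stringsAsFactors = FALSE)) {
  mappings <- mappings[!duplicated(mappings[c("source", "target")]), , drop = FALSE]
  ord <- order(mappings$source, mappings$target, method = "radix")
  mappings <- mappings[ord, , drop = FALSE]
  rownames(mappings) <- NULL
  structure(list(dataset_name = dataset_name, mappings = mappings),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> %s: %d mappings\n", x$dataset_name, nrow(x$mappings)))
  invisible(x)
}

#' Match a dataset schema against the mediating ontology
#'
#' Scores every class–class and property–property pair with the combined
#' linguistic similarity and keeps every pair at or above the configured
#' threshold as an equivalence mapping. One mediating term may map to several
#' dataset terms. Output rows are ordered by source IRI, then target IRI.
#'
#' @param mediating The mediating-ontology `dataset_graph`.
#' @param dataset A dataset `dataset_graph`.
#' @param config A [match_config()].
#' @return An `alignment` for `dataset`.
#' @export
match_ontologies <- function(mediating, dataset, config = match_config()) {
  terms_m <- extract_terms(mediating, config$label_properties,
                           config$comment_properties)
  terms_d <- extract_terms(dataset, config$label_properties,
                           config$comment_properties)
  if (!config$include_builtin) {
    terms_m <- terms_m[!is_builtin_iri(names(terms_m))]
    terms_d <- terms_d[!is_builtin_iri(names(terms_d))]
  }
  if (length(terms_m) == 0 || length(terms_d) == 0) {
    warning("Empty term set: nothing to match for dataset ",
            dataset$dataset_name)
    return(alignment(dataset$dataset_name))
  }
  vds_m <- lapply(terms_m, build_virtual_document, graph = mediating,
                  config = config, terms = terms_m)
  vds_d <- lapply(terms_d, build_virtual_document, graph = dataset,
                  config = config, terms = terms_d)
  rows <- list()
  for (im in names(terms_m)) {
    for (id in names(terms_d)) {
      if (terms_m[[im]]$kind != terms_d[[id]]$kind) next
      sc <- combined_similarity(terms_m[[im]], terms_d[[id]], mediating,
                                dataset, config,
                                vd_s = vds_m[[im]], vd_b = vds_d[[id]])
      if (sc >= config$threshold) {
        rows[[length(rows) + 1L]] <- data.frame(source = im, target = id,
                                                score = sc,
                                                relation = "equivalence",
                                                stringsAsFactors = FALSE)
      }
    }
  }
  mp <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(mp)) return(alignment(dataset$dataset_name))
  alignment(dataset$dataset_name, mp)
}

#' Precision, recall and F1 of an alignment against a reference
#'
#' Computed on the sets of (source, target) pairs. Empty-set conventions: an
#' empty prediction has precision 0 (its precision is undefined; 0 is
#' reported), an empty reference has recall 0; F1 is 0 whenever precision +
#' recall is 0.
#'
#' @param predicted,truth `alignment` objects for the same dataset.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
score_alignment <- function(predicted, truth) {
  pk <- paste(predicted$mappings$source, predicted$mappings$target, sep = "\r")
  tk <- paste(truth$mappings$source, truth$mappings$target, sep = "\r")
  tp <- length(intersect(pk, tk))
  precision <- if (length(pk) == 0) 0 else tp / length(unique(pk))
  recall <- if (length(tk) == 0) 0 else tp / length(unique(tk))
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Coverage of a dataset's vocabulary by an alignment
#'
#' The fraction of the dataset's class terms (and, separately, property
#' terms) that appear as the target of some mapping.
#'
#' @param align An `alignment`.
#' @param dataset The dataset's `dataset_graph`.
#' @param config A [match_config()] (controls whether built-in vocabulary
#'   counts toward the denominator).
#' @return Named numeric vector `c(class_coverage, property_coverage)`.
#' @export
coverage_rate <- function(align, dataset, config = match_config()) {
  terms <- extract_terms(dataset, config$label_properties,
                         config$comment_properties)
  if (!config$include_builtin) terms <- terms[!is_builtin_iri(names(terms))]
  kinds <- vapply(terms, function(t) t$kind, character(1))
  cls <- names(terms)[kinds == "class"]
  prp <- names(terms)[kinds == "property"]
  matched <- unique(align$mappings$target)
  c(class_coverage = if (length(cls) == 0) 0 else mean(cls %in% matched),
    property_coverage = if (length(prp) == 0) 0 else mean(prp %in% matched))
}

#' Write an alignment as TSV
#'
#' Columns `source_iri`, `target_iri`, `score`, `relation`; rows in the
#' alignment's deterministic order.
#'
#' @param align An `alignment`.
#' @param path Output path.
#' @export
write_alignment <- function(align, path) {
  df <- align$mappings
  names(df) <- c("source_iri", "target_iri", "score", "relation")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an alignment TSV
#'
#' @param path File written by [write_alignment()].
#' @param dataset_name Dataset the alignment targets; defaults to the file
#'   stem.
#' @return An `alignment`.
#' @export
read_alignment <- function(path, dataset_name = NULL) {
  if (is.null(dataset_name)) dataset_name <- tools::file_path_sans_ext(basename(path))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  alignment(dataset_name,
            data.frame(source = df$source_iri, target = df$target_iri,
                       score = df$score, relation = df$relation,
                       stringsAsFactors = FALSE))
}

#' Read a synonym table
#'
#' Two-column TSV (token, synonym), no header required. The symmetric closure
#' is applied: if a maps to b then b maps to a.
#'
#' @param path TSV path.
#' @return Named list token -> character vector of synonyms, usable as the
#'   `synonyms` field of [match_config()].
#' @export
read_synonyms <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          col.names = c("token", "synonym"))
  synonym_table(df$token, df$synonym)
}

#' Build a synonym provider from token pairs
#'
#' @param token,synonym Equal-length character vectors of synonymous token
#'   pairs (lowercased on load); the symmetric closure is applied.
#' @return Named list token -> synonyms.
#' @export
synonym_table <- function(token, synonym) {
  a <- tolower(c(token, synonym))
  b <- tolower(c(synonym, token))
  out <- split(b, a)
  lapply(out, unique)
}
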