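# Seeded generator of small Bio2RDF-style fixture bundles: a mini mediating
# ontology, heterogeneous datasets whose vocabularies are known perturbations
# of the mediating terms, ground-truth alignments, cross-dataset x-links, and
# a homogenized merged graph serving as the query-answering oracle.

MEDIATING_NS <- "http://example.org/onto/"

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

default_class_tree <- function() {
  data.frame(
    name = c("Entity", "Drug", "Gene", "Protein", "Pathway", "Disease",
             "Phenotype", "Syndrome"),
    parent = c(NA, "Entity", "Entity", "Entity", "Entity", "Entity",
               "Disease", "Disease"),
    stringsAsFactors = FALSE)
}

default_synonym_pairs <- function() {
  data.frame(
    token = c("disease", "drug", "gene", "phenotype", "protein", "pathway"),
    synonym = c("disorder", "medication", "locus", "trait", "polypeptide",
                "cascade"),
    stringsAsFactors = FALSE)
}

#' Specification of a fixture bundle
#'
#' The defaults describe the study conditions the test-suite fixtures use:
#' two datasets, an eight-class hierarchy of the three recurring biomedical
#' entity kinds (drug, disease/phenotype, gene) plus supporting concepts, six
#' domain properties, three entities per class, case and delimiter
#' perturbations, and five cross-dataset links. The seed fully determines the
#' output.
#'
#' @param n_datasets Number of heterogeneous datasets.
#' @param classes data.frame with columns `name`, `parent` (NA for roots).
#' @param properties Character vector of domain property names.
#' @param n_entities_per_class Entities generated per class per dataset.
#' @param perturbation_modes Subset of `c("case", "delimiter", "synonym",
#'   "affix")` applied to dataset vocabularies.
#' @param synonym_pairs data.frame (`token`, `synonym`) backing the synonym
#'   mode and the matcher's synonym provider.
#' @param n_xlinks Number of cross-dataset link triples.
#' @param keyword_pool Words embedded verbatim in entity labels and property
#'   values, so keyword hits are enumerable by construction.
#' @param affix_classes Class names receiving a second, affixed class variant
#'   (a 1-to-2 mapping); `NULL` lets the generator pick ~30% of classes when
#'   the affix mode is active.
#' @param dataset_names Names for the datasets.
#' @param seed Integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_datasets = 2,
                         classes = default_class_tree(),
                         properties = c("dosage", "indication", "encodes",
                                        "severity", "prevalence", "halfLife"),
                         n_entities_per_class = 3,
                         perturbation_modes = c("case", "delimiter"),
                         synonym_pairs = default_synonym_pairs(),
                         n_xlinks = 5,
                         keyword_pool = c("alzheimer", "penicillin",
                                          "tuberculosis", "malaria",
                                          "warfarin", "insulin", "aspirin",
                                          "fibrosis", "anemia", "migraine"),
                         affix_classes = NULL,
                         dataset_names = NULL,
                         seed = 1) {
  perturbation_modes <- match.arg(perturbation_modes,
                                  c("case", "delimiter", "synonym", "affix"),
                                  several.ok = TRUE)
  if ("synonym" %in% perturbation_modes &&
      (is.null(synonym_pairs) || nrow(synonym_pairs) == 0)) {
    stop("Synonym perturbation mode requires a synonym table", call. = FALSE)
  }
  if (is.null(dataset_names)) {
    pool <- c("DrugBank", "KEGG", "OMIM", "Orphanet", "PharmGKB", "MeSH",
              "InterPro", "NCBIGene")
    if (n_datasets > length(pool)) {
      pool <- c(pool, paste0("Dataset", seq_len(n_datasets - length(pool))))
    }
    dataset_names <- pool[seq_len(n_datasets)]
  }
  structure(list(n_datasets = n_datasets, classes = classes,
                 properties = properties,
                 n_entities_per_class = n_entities_per_class,
                 perturbation_modes = perturbation_modes,
                 synonym_pairs = synonym_pairs, n_xlinks = n_xlinks,
                 keyword_pool = keyword_pool, affix_classes = affix_classes,
                 dataset_names = dataset_names, seed = seed),
            class = "fixture_spec")
}

# spaced word form of a camelCase name, e.g. "SmallMolecule" -> tokens
name_tokens <- function(name) tokenize(name)

camel_join <- function(tokens) {
  paste(vapply(tokens, function(t) {
    paste0(toupper(substr(t, 1, 1)), substr(t, 2, nchar(t)))
  }, character(1)), collapse = "")
}

#' Perturb a term name
#'
#' Applies one heterogeneity mode to a vocabulary name, emulating how
#' independently published dataset schemas drift from a mediating ontology:
#' letter-case changes, delimiter-convention swaps (camelCase vs hyphens vs
#' underscores), synonym substitution, or an added qualifier token (the
#' "Predominantly-phenotypes" pattern). Token identity is recoverable, which
#' is what ground-truth alignments record. Uses the current RNG stream.
#'
#' @param name Term name (camelCase words).
#' @param mode One of `"case"`, `"delimiter"`, `"synonym"`, `"affix"`.
#' @param synonyms Named list token -> synonyms (required for
#'   `mode = "synonym"`).
#' @return The perturbed name.
#' @export
perturb_term_name <- function(name, mode, synonyms = NULL) {
  toks <- name_tokens(name)
  switch(mode,
    case = {
      style <- sample(c("lower", "upper", "title"), 1)
      switch(style,
             lower = tolower(name),
             upper = toupper(name),
             title = camel_join(toks))
    },
    delimiter = {
      delim <- sample(c("-", "_", "camel"), 1)
      if (delim == "camel") camel_join(toks) else paste(toks, collapse = delim)
    },
    synonym = {
      hit <- FALSE
      out <- vapply(toks, function(t) {
        syn <- synonyms[[t]]
        if (is.null(syn)) return(t)
        hit <<- TRUE
        syn[1]
      }, character(1))
      if (!hit) {
        message(sprintf("No synonym for any token of '%s'; name unchanged", name))
        return(name)
      }
      camel_join(out)
    },
    affix = {
      qualifier <- sample(c("Predominantly", "Primary", "Related", "Atypical"), 1)
      paste0(qualifier, "-", tolower(paste(toks, collapse = "-")), "s")
    },
    stop("Unknown perturbation mode: ", mode, call. = FALSE))
}

term_iri <- function(ns, name) paste0(ns, "vocabulary/", name)
mediating_iri <- function(name) paste0(MEDIATING_NS, name)

build_mediating_graph <- function(spec) {
  tr <- empty_triples()
  for (i in seq_len(nrow(spec$classes))) {
    iri <- mediating_iri(spec$classes$name[i])
    tr <- rbind(tr,
                make_triples(iri, RDF_TYPE, OWL_CLASS),
                make_triples(iri, RDFS_LABEL, spec$classes$name[i], o_lit = TRUE))
    if (!is.na(spec$classes$parent[i])) {
      tr <- rbind(tr, make_triples(iri, RDFS_SUBCLASSOF,
                                   mediating_iri(spec$classes$parent[i])))
    }
  }
  for (p in spec$properties) {
    iri <- mediating_iri(p)
    tr <- rbind(tr,
                make_triples(iri, RDF_TYPE, RDF_PROPERTY),
                make_triples(iri, RDFS_LABEL, p, o_lit = TRUE))
  }
  dataset_graph("mediating", triples = tr, source = "generated")
}

#' Generate a fixture bundle
#'
#' Produces the mediating ontology, `n_datasets` heterogeneous datasets whose
#' class/property vocabularies are seeded perturbations of the mediating
#' terms, entities with keyword-bearing labels, cross-dataset x-link triples,
#' the ground-truth alignments, and the homogenized oracle graph. Calling
#' twice with the same spec yields byte-identical serializations.
#'
#' @param spec A [fixture_spec()].
#' @return A `fixture_bundle` with fields `mediating`, `datasets` (named
#'   list), `truth_alignments` (named list), `xlink_table`, `homogenized`,
#'   `synonyms`, `spec`.
#' @export
generate_fixtures <- function(spec = fixture_spec()) {
  with_seed(spec$seed, {
    syn_provider <- synonym_table(spec$synonym_pairs$token,
                                  spec$synonym_pairs$synonym)
    mediating <- build_mediating_graph(spec)
    modes <- spec$perturbation_modes
    base_modes <- setdiff(modes, "affix")
    if (length(base_modes) == 0) base_modes <- "case"

    datasets <- list()
    truths <- list()
    for (d in seq_len(spec$n_datasets)) {
      ds_name <- spec$dataset_names[d]
      ns <- paste0("http://example.org/", tolower(ds_name), "/")
      tr <- empty_triples()
      map_rows <- list()

      affixed <- if ("affix" %in% modes) {
        if (!is.null(spec$affix_classes)) {
          spec$affix_classes
        } else {
          cls <- spec$classes$name
          cls[stats::runif(length(cls)) < 0.3]
        }
      } else character(0)

      class_variants <- list()
      for (i in seq_len(nrow(spec$classes))) {
        nm <- spec$classes$name[i]
        base <- suppressMessages(
          perturb_term_name(nm, sample(base_modes, 1), syn_provider))
        variants <- base
        if (nm %in% affixed) {
          variants <- c(variants, perturb_term_name(nm, "affix", syn_provider))
        }
        class_variants[[nm]] <- variants
        for (v in variants) {
          iri <- term_iri(ns, v)
          tr <- rbind(tr,
                      make_triples(iri, RDF_TYPE, OWL_CLASS),
                      make_triples(iri, RDFS_LABEL, v, o_lit = TRUE))
          map_rows[[length(map_rows) + 1L]] <-
            data.frame(source = mediating_iri(nm), target = iri, score = 1,
                       relation = "equivalence", stringsAsFactors = FALSE)
        }
      }
      prop_variants <- character(0)
      for (p in spec$properties) {
        v <- suppressMessages(
          perturb_term_name(p, sample(base_modes, 1), syn_provider))
        prop_variants[p] <- v
        iri <- term_iri(ns, v)
        tr <- rbind(tr,
                    make_triples(iri, RDF_TYPE, RDF_PROPERTY),
                    make_triples(iri, RDFS_LABEL, v, o_lit = TRUE))
        map_rows[[length(map_rows) + 1L]] <-
          data.frame(source = mediating_iri(p), target = iri, score = 1,
                     relation = "equivalence", stringsAsFactors = FALSE)
      }
      vocab <- c(unlist(class_variants), prop_variants)
      if (anyDuplicated(tolower(vocab))) {
        stop("Perturbation collision within dataset ", ds_name, ": ",
             paste(vocab[duplicated(tolower(vocab))], collapse = ", "),
             call. = FALSE)
      }

      np <- length(spec$properties)
      for (i in seq_len(nrow(spec$classes))) {
        nm <- spec$classes$name[i]
        variants <- class_variants[[nm]]
        for (k in seq_len(spec$n_entities_per_class)) {
          v <- variants[((k - 1L) %% length(variants)) + 1L]
          ent <- paste0(ns, "entity/", tolower(nm), "_", k)
          kw <- sample(spec$keyword_pool, 1)
          kw2 <- sample(spec$keyword_pool, 1)
          prop_nm <- spec$properties[((i + k - 2L) %% np) + 1L]
          tr <- rbind(tr,
                      make_triples(ent, RDF_TYPE, term_iri(ns, v)),
                      make_triples(ent, RDFS_LABEL,
                                   paste(kw, tolower(paste(name_tokens(nm),
                                                           collapse = " ")), k),
                                   o_lit = TRUE),
                      make_triples(ent, term_iri(ns, prop_variants[prop_nm]),
                                   kw2, o_lit = TRUE))
        }
      }
      datasets[[ds_name]] <- dataset_graph(ds_name, triples = tr,
                                           source = "generated",
                                           graph_iri = paste0(ns, "graph"))
      truths[[ds_name]] <- alignment(ds_name, do.call(rbind, map_rows))
    }

    xlink_rows <- list()
    if (spec$n_datasets >= 2 && spec$n_xlinks > 0) {
      for (k in seq_len(spec$n_xlinks)) {
        ab <- sample(spec$dataset_names, 2)
        ga <- datasets[[ab[1]]]; gb <- datasets[[ab[2]]]
        ents_a <- grep("/entity/", iri_subjects(ga$triples), value = TRUE)
        ents_b <- grep("/entity/", iri_subjects(gb$triples), value = TRUE)
        ea <- sample(ents_a, 1); eb <- sample(ents_b, 1)
        prop <- paste0("http://example.org/", tolower(ab[1]), "/x-",
                       tolower(ab[2]))
        ga$triples <- dedup_triples(rbind(ga$triples,
                                          make_triples(ea, prop, eb)))
        datasets[[ab[1]]] <- ga
        xlink_rows[[k]] <- data.frame(source_entity = ea, property = prop,
                                      target_entity = eb,
                                      source_dataset = ab[1],
                                      target_dataset = ab[2],
                                      stringsAsFactors = FALSE)
      }
    }

    bundle <- structure(list(mediating = mediating, datasets = datasets,
                             truth_alignments = truths,
                             xlink_table = if (length(xlink_rows))
                               do.call(rbind, xlink_rows) else NULL,
                             homogenized = NULL,
                             synonyms = syn_provider, spec = spec),
                        class = "fixture_bundle")
    bundle$homogenized <- homogenize(bundle)
    bundle
  })
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("<fixture_bundle> %d datasets (%s), mediating ontology of %d triples\n",
              length(x$datasets), paste(names(x$datasets), collapse = ", "),
              nrow(x$mediating$triples)))
  invisible(x)
}

#' Homogenize a fixture bundle
#'
#' Merges the (selected) datasets into one graph in which every dataset
#' vocabulary term is rewritten to its mediating term via the ground-truth
#' alignments. Entity IRIs already live in per-dataset namespaces, so no
#' collision arises. The result is the oracle against which federated
#' query answering is checked. Unmapped vocabulary other than shared built-in
#' properties and x-link properties is an error listing the offending terms.
#'
#' @param bundle A `fixture_bundle`.
#' @param datasets Dataset names to include (default: all).
#' @return A `dataset_graph` in mediating vocabulary.
#' @export
homogenize <- function(bundle, datasets = NULL) {
  if (is.null(datasets)) datasets <- names(bundle$datasets)
  pieces <- lapply(datasets, function(ds) {
    g <- bundle$datasets[[ds]]
    map <- bundle$truth_alignments[[ds]]$mappings
    lut <- stats::setNames(map$source, map$target)
    tr <- g$triples
    vocab <- unique(c(tr$p, tr$o[!tr$o_lit & tr$p == RDF_TYPE]))
    unmapped <- vocab[!vocab %in% names(lut) & !is_builtin_iri(vocab) &
                        !grepl("/x-", vocab)]
    if (length(unmapped) > 0) {
      stop("Homogenization: unmapped vocabulary in ", ds, ": ",
           paste(unmapped, collapse = ", "), call. = FALSE)
    }
    swap <- function(x) ifelse(x %in% names(lut), lut[x], x)
    tr$s <- swap(tr$s)
    tr$p <- swap(tr$p)
    tr$o[!tr$o_lit] <- swap(tr$o[!tr$o_lit])
    tr
  })
  dataset_graph("homogenized", triples = dedup_triples(do.call(rbind, pieces)))
}

#' Generate random well-formed EASE query strings for a bundle
#'
#' Mixes keywords from the bundle's pool with `C:`/`P:`/`S:` tags naming the
#' bundle's mediating terms and datasets. Every string is guaranteed to
#' parse; every fifth query populates all four categories.
#'
#' @param bundle A `fixture_bundle`.
#' @param n Number of queries.
#' @param seed Integer seed.
#' @return Character vector of EASE strings.
#' @export
generate_queries <- function(bundle, n, seed = 1) {
  if (n == 0) return(character(0))
  spec <- bundle$spec
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      full <- (i %% 5L == 0L)
      nkw <- if (full) sample(1:2, 1) else sample(0:2, 1)
      ncl <- if (full) sample(1:2, 1) else sample(0:2, 1)
      npr <- if (full) 1L else sample(0:1, 1)
      nds <- if (full) 1L else sample(0:1, 1)
      if (nkw + ncl + npr + nds == 0L) nkw <- 1L
      toks <- c(sample(spec$keyword_pool, nkw),
                if (ncl > 0) paste0("C:", sample(spec$classes$name, ncl)),
                if (npr > 0) paste0("P:", sample(spec$properties, npr)),
                if (nds > 0) paste0("S:", sample(names(bundle$datasets), nds)))
      paste(sample(toks), collapse = " ")
    }, character(1))
  })
}

#' Write a fixture bundle to disk
#'
#' Canonical Turtle-compatible triple files, alignment TSVs, the synonym
#' table, the x-link table, and a registry/manifest YAML.
#'
#' @param bundle A `fixture_bundle`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ntriples(bundle$mediating, file.path(dir, "mediating.ttl"))
  reg <- list()
  for (ds in names(bundle$datasets)) {
    f <- paste0(ds, ".ttl")
    write_ntriples(bundle$datasets[[ds]], file.path(dir, f))
    write_alignment(bundle$truth_alignments[[ds]],
                    file.path(dir, paste0(ds, ".alignment.tsv")))
    reg[[ds]] <- list(source = f, format = "turtle",
                      graph_iri = bundle$datasets[[ds]]$graph_iri)
  }
  sp <- bundle$spec$synonym_pairs
  utils::write.table(sp, file.path(dir, "synonyms.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(bundle$xlink_table)) {
    utils::write.table(bundle$xlink_table, file.path(dir, "xlinks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  yaml::write_yaml(list(mediating = "mediating.ttl", datasets = reg),
                   file.path(dir, "registry.yml"))
  invisible(dir)
}
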