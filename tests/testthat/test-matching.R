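# Virtual documents, I-Sub, synonym enrichment, alignment extraction and
# alignment evaluation.

test_that("virtual documents weight neighbor descriptions by gamma", {
  # isolated term: the document is just the local description
  g0 <- tiny_graph(list(c(paste0(EX, "other"), paste0(EX, "q"), paste0(EX, "z"))))
  t0 <- structure(list(iri = paste0(EX, "drug"), labels = character(0),
                       annotations = character(0)), class = "rdf_term")
  expect_equal(unclass(build_virtual_document(t0, g0)), c(drug = 1))

  # single-triple graph <alpha, p, beta>, all gammas 0.5
  g1 <- tiny_graph(list(c(paste0(EX, "alpha"), paste0(EX, "p"), paste0(EX, "beta"))))
  tp <- extract_terms(g1)[[paste0(EX, "p")]]
  vd <- build_virtual_document(tp, g1)
  expect_equal(unclass(vd)[order(names(vd))],
               c(alpha = 0.5, beta = 0.5, p = 1.0))

  # gamma = 0 degenerates to the local description counts
  cfg0 <- match_config(gamma_s = 0, gamma_p = 0, gamma_o = 0)
  vd0 <- build_virtual_document(tp, g1, cfg0)
  expect_equal(unclass(vd0), c(p = 1))
})

test_that("virtual-document similarity is the cosine over the union vocabulary", {
  vd <- function(...) {
    w <- c(...)
    if (is.null(w)) w <- stats::setNames(numeric(0), character(0))
    structure(w, class = "virtual_document")
  }
  expect_equal(vdoc_similarity(vd(a = 2, b = 1), vd(a = 2, b = 1)), 1)
  expect_equal(vdoc_similarity(vd(a = 1), vd(b = 1)), 0)
  expect_equal(vdoc_similarity(vd(a = 1, b = 1), vd(a = 1)), 1 / sqrt(2))
  expect_equal(vdoc_similarity(vd(), vd(a = 1)), 0)
})

test_that("I-Sub scores identity, case-folding and empty strings as specified", {
  expect_equal(isub_similarity("drug", "drug"), 1)
  expect_equal(isub_similarity("drug", "Drug"), 1)   # sio "drug" vs kegg:Drug
  expect_equal(isub_similarity("", "drug"), 0)
  expect_equal(isub_similarity("drug", ""), 0)
})

test_that("I-Sub matches the independent transcription on random pairs", {
  set.seed(123)
  for (i in 1:20) {
    s1 <- random_word(1, 10); s2 <- random_word(1, 10)
    expect_equal(isub_similarity(s1, s2), isub_oracle(s1, s2),
                 tolerance = 1e-12, info = paste(s1, s2))
  }
})

test_that("similarities are symmetric and within [0, 1]", {
  set.seed(99)
  for (i in 1:30) {
    s1 <- random_word(0, 8); s2 <- random_word(0, 8)
    v <- isub_similarity(s1, s2)
    expect_identical(v, isub_similarity(s2, s1))
    expect_gte(v, 0); expect_lte(v, 1)
    w1 <- random_vdoc(); w2 <- random_vdoc()
    c1 <- vdoc_similarity(w1, w2)
    expect_equal(c1, vdoc_similarity(w2, w1))
    expect_gte(c1, 0); expect_lte(c1, 1 + 1e-12)
  }
})

test_that("synonym enrichment adds one copy per provided synonym, idempotently", {
  cfg <- match_config(synonyms = synonym_table("disorder", "disease"))
  expect_setequal(enrich_with_synonyms(c("disorder"), cfg),
                  c("disorder", "disease"))
  once <- enrich_with_synonyms(c("disorder", "disorder"), cfg)
  expect_equal(sort(once), c("disease", "disorder", "disorder"))
  expect_equal(sort(enrich_with_synonyms(once, cfg)), sort(once))

  no_provider <- match_config()
  expect_equal(enrich_with_synonyms(c("disorder"), no_provider), "disorder")
})

test_that("combined similarity is the max of the two matchers and needs same kinds", {
  b <- generate_fixtures(fixture_spec(seed = 4))
  g <- b$datasets[[1]]
  terms_m <- extract_terms(b$mediating)
  terms_m <- terms_m[!semsearch:::is_builtin_iri(names(terms_m))]
  cfg <- match_config()
  t_drug <- terms_m[[paste0(semsearch:::MEDIATING_NS, "Drug")]]
  expect_equal(combined_similarity(t_drug, t_drug, b$mediating, b$mediating, cfg), 1)

  t_prop <- terms_m[[paste0(semsearch:::MEDIATING_NS, "dosage")]]
  expect_error(combined_similarity(t_drug, t_prop, b$mediating, b$mediating, cfg),
               "[Ii]ncompatible")
})

test_that("combined similarity equals the max of independently computed parts", {
  b <- generate_fixtures(fixture_spec(seed = 8))
  cfg <- match_config()
  tm <- extract_terms(b$mediating)
  tm <- tm[!semsearch:::is_builtin_iri(names(tm))]
  td <- extract_terms(b$datasets[[2]])
  td <- td[!semsearch:::is_builtin_iri(names(td))]
  set.seed(8)
  for (i in 1:40) {
    a <- tm[[sample(length(tm), 1)]]
    d <- td[[sample(length(td), 1)]]
    if (a$kind != d$kind) next
    got <- combined_similarity(a, d, b$mediating, b$datasets[[2]], cfg)
    vd <- vdoc_similarity(build_virtual_document(a, b$mediating, cfg),
                          build_virtual_document(d, b$datasets[[2]], cfg))
    is <- isub_similarity(semsearch:::term_isub_string(a, cfg),
                          semsearch:::term_isub_string(d, cfg))
    expect_identical(got, max(vd, is))
  }
})

test_that("matching identical ontologies yields the identity alignment", {
  b <- generate_fixtures(fixture_spec(seed = 6))
  al <- match_ontologies(b$mediating, b$mediating)
  terms <- extract_terms(b$mediating)
  terms <- terms[!semsearch:::is_builtin_iri(names(terms))]
  ident <- al$mappings[al$mappings$source == al$mappings$target, ]
  expect_equal(nrow(ident), length(terms))
})

test_that("case/delimiter-perturbed fixtures are recovered exactly at 0.9", {
  b <- generate_fixtures(fixture_spec(seed = 10))
  for (ds in names(b$datasets)) {
    al <- match_ontologies(b$mediating, b$datasets[[ds]])
    sc <- score_alignment(al, b$truth_alignments[[ds]])
    expect_equal(unname(sc), c(1, 1, 1))
  }
})

test_that("a synonym provider recovers lexically divergent mappings", {
  spec <- fixture_spec(perturbation_modes = "synonym", seed = 12)
  b <- generate_fixtures(spec)
  with_syn <- match_config(synonyms = b$synonyms)
  without <- match_config()
  for (ds in names(b$datasets)) {
    r1 <- score_alignment(match_ontologies(b$mediating, b$datasets[[ds]], with_syn),
                          b$truth_alignments[[ds]])["recall"]
    r0 <- score_alignment(match_ontologies(b$mediating, b$datasets[[ds]], without),
                          b$truth_alignments[[ds]])["recall"]
    expect_gt(r1, r0)
  }
})

test_that("raising the threshold never adds a mapping", {
  b <- generate_fixtures(fixture_spec(seed = 14))
  keys <- function(al) paste(al$mappings$source, al$mappings$target)
  prev <- NULL
  for (th in c(0.5, 0.7, 0.9, 0.99)) {
    al <- match_ontologies(b$mediating, b$datasets[[1]],
                           match_config(threshold = th))
    if (!is.null(prev)) expect_true(all(keys(al) %in% prev))
    prev <- keys(al)
  }
})

test_that("alignment scoring applies the documented conventions", {
  mk <- function(pairs) {
    alignment("D", data.frame(source = vapply(pairs, `[`, "", 1),
                              target = vapply(pairs, `[`, "", 2),
                              score = 1, relation = "equivalence",
                              stringsAsFactors = FALSE))
  }
  truth <- mk(list(c("a", "1"), c("b", "2"), c("c", "3"), c("d", "4")))
  expect_equal(unname(score_alignment(truth, truth)), c(1, 1, 1))
  expect_equal(unname(score_alignment(alignment("D"), truth)), c(0, 0, 0))
  pred <- mk(list(c("a", "1"), c("b", "2"), c("c", "3"), c("e", "9")))
  expect_equal(unname(score_alignment(pred, truth)), c(0.75, 0.75, 0.75))
})

test_that("coverage rates count matched targets per kind", {
  b <- generate_fixtures(fixture_spec(seed = 15))
  ds <- names(b$datasets)[1]
  truth <- b$truth_alignments[[ds]]

  # an identity alignment over the dataset's own vocabulary covers everything
  terms_all <- extract_terms(b$datasets[[ds]])
  terms_all <- terms_all[!semsearch:::is_builtin_iri(names(terms_all))]
  ident <- alignment(ds, data.frame(source = names(terms_all),
                                    target = names(terms_all), score = 1,
                                    relation = "equivalence",
                                    stringsAsFactors = FALSE))
  expect_equal(unname(coverage_rate(ident, b$datasets[[ds]])), c(1, 1))

  # the truth alignment covers all classes; x-link properties stay uncovered
  n_xl <- sum(grepl("/x-", names(terms_all)))
  n_prop <- sum(vapply(terms_all, function(t) t$kind, character(1)) == "property")
  cov_truth <- coverage_rate(truth, b$datasets[[ds]])
  expect_equal(unname(cov_truth["class_coverage"]), 1)
  expect_equal(unname(cov_truth["property_coverage"]),
               (n_prop - n_xl) / n_prop)
  expect_equal(unname(coverage_rate(alignment(ds), b$datasets[[ds]])), c(0, 0))

  # partial: keep class mappings for 4 of the classes only
  cls <- truth$mappings[grepl("/vocabulary/", truth$mappings$target), ]
  terms <- extract_terms(b$datasets[[ds]])
  kinds <- vapply(terms, function(t) t$kind, character(1))
  class_targets <- intersect(cls$target, names(kinds)[kinds == "class"])
  part <- alignment(ds, truth$mappings[truth$mappings$target %in%
                                         class_targets[1:4], ])
  cov <- coverage_rate(part, b$datasets[[ds]])
  expect_equal(unname(cov["class_coverage"]), 4 / length(class_targets))
})

test_that("alignments and synonym tables round-trip through TSV", {
  b <- generate_fixtures(fixture_spec(seed = 16))
  al <- b$truth_alignments[[1]]
  f <- withr::local_tempfile(fileext = ".tsv")
  write_alignment(al, f)
  al2 <- read_alignment(f, dataset_name = al$dataset_name)
  expect_equal(al2$mappings, al$mappings)

  fs <- withr::local_tempfile(fileext = ".tsv")
  writeLines("disease\tdisorder", fs)
  syn <- read_synonyms(fs)
  expect_equal(syn$disease, "disorder")
  expect_equal(syn$disorder, "disease")   # symmetric closure
})
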