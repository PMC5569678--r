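# Global query construction, class expansion, GAV rewriting, SPARQL
# rendering, and federated execution.

onto <- function(name) paste0(semsearch:::MEDIATING_NS, name)

test_that("class expansion returns the transitive subclass closure", {
  b <- generate_fixtures(fixture_spec(seed = 1))
  m <- b$mediating
  expect_equal(expand_classes(onto("Phenotype"), m), onto("Phenotype"))
  expect_setequal(expand_classes(onto("Disease"), m),
                  onto(c("Disease", "Phenotype", "Syndrome")))
  expect_setequal(expand_classes(onto("Entity"), m),
                  onto(c("Entity", "Drug", "Gene", "Protein", "Pathway",
                         "Disease", "Phenotype", "Syndrome")))
  expect_error(expand_classes(onto("Nonexistent"), m), "Unknown class")
})

test_that("class expansion terminates on subclass cycles", {
  g <- tiny_graph(list(c(paste0(EX, "A"), rdfs_subclassof, paste0(EX, "B")),
                       c(paste0(EX, "B"), rdfs_subclassof, paste0(EX, "A"))))
  expect_setequal(expand_classes(paste0(EX, "A"), g),
                  paste0(EX, c("A", "B")))
})

test_that("a chain A <- B <- C expands from the root", {
  g <- tiny_graph(list(c(paste0(EX, "B"), rdfs_subclassof, paste0(EX, "A")),
                       c(paste0(EX, "C"), rdfs_subclassof, paste0(EX, "B"))))
  expect_setequal(expand_classes(paste0(EX, "A"), g), paste0(EX, c("A", "B", "C")))
})

test_that("global queries resolve constraints and expand classes", {
  b <- generate_fixtures(fixture_spec(seed = 2))
  reg <- registry_from_graphs(b$datasets)

  g <- build_global_query(parse_ease("Alzheimer C:Disease C:Phenotype"),
                          b$mediating, reg)
  expect_equal(g$keywords, "Alzheimer")
  expect_true(all(onto(c("Disease", "Phenotype", "Syndrome")) %in% g$classes))
  expect_true(all(g$class_seeds %in% g$classes))

  g2 <- build_global_query(parse_ease("penicillin"), b$mediating, reg)
  expect_length(g2$classes, 0)
  expect_length(g2$properties, 0)
  expect_length(g2$datasets, 0)

  # property from the common extension set
  g3 <- build_global_query(parse_ease("x P:label"), b$mediating, reg)
  expect_true(paste0("http://www.w3.org/2000/01/rdf-schema#label") %in%
                g3$properties)

  # mediating-ontology property, case-insensitively
  g4 <- build_global_query(parse_ease("x P:Dosage"), b$mediating, reg)
  expect_equal(g4$properties, onto("dosage"))

  expect_error(build_global_query(parse_ease("C:Nope"), b$mediating, reg),
               "Unknown class")
  expect_error(build_global_query(parse_ease("S:Nope"), b$mediating, reg),
               "Unknown dataset")
})

test_that("rewriting substitutes synonym-divergent classes (Disorder pattern)", {
  spec <- fixture_spec(n_datasets = 1, perturbation_modes = "synonym",
                       dataset_names = "Orphanet", seed = 21)
  b <- generate_fixtures(spec)
  reg <- registry_from_graphs(b$datasets)
  g <- build_global_query(parse_ease("alzheimer C:Disease"), b$mediating, reg)
  plan <- rewrite_to_local(g, b$truth_alignments, reg)
  targets <- vapply(plan$local_queries, function(q) q$class_iri, character(1))
  expect_true(any(grepl("/vocabulary/Disorder$", targets)))
})

test_that("a 1-to-2 class mapping fans out into two local queries", {
  spec <- fixture_spec(n_datasets = 1, perturbation_modes = c("case", "affix"),
                       affix_classes = "Phenotype", dataset_names = "OMIM",
                       seed = 22)
  b <- generate_fixtures(spec)
  reg <- registry_from_graphs(b$datasets)
  g <- build_global_query(parse_ease("alzheimer C:Phenotype"), b$mediating, reg)
  plan <- rewrite_to_local(g, b$truth_alignments, reg)
  expect_length(plan$local_queries, 2)
  expect_setequal(vapply(plan$local_queries, function(q) q$dataset_name,
                         character(1)), "OMIM")
  expect_length(unique(vapply(plan$local_queries, function(q) q$class_iri,
                              character(1))), 2)
})

test_that("plan size equals sum over datasets of class pairs x property pairs", {
  b <- generate_fixtures(fixture_spec(n_datasets = 3, seed = 23))
  reg <- registry_from_graphs(b$datasets)
  g <- build_global_query(parse_ease("x C:Disease P:dosage"), b$mediating, reg)
  plan <- rewrite_to_local(g, b$truth_alignments, reg)
  expected <- 0L
  for (ds in names(b$datasets)) {
    mp <- b$truth_alignments[[ds]]$mappings
    ncls <- sum(mp$source %in% g$classes)
    nprp <- sum(mp$source %in% g$properties)
    if (ncls > 0) expected <- expected + ncls * max(1L, nprp)
  }
  expect_length(plan$local_queries, expected)
})

test_that("an inexpressible query yields an empty plan with a warning", {
  b <- generate_fixtures(fixture_spec(seed = 24))
  reg <- registry_from_graphs(b$datasets)
  g <- build_global_query(parse_ease("x C:Disease"), b$mediating, reg)
  empty_al <- lapply(b$truth_alignments, function(a) alignment(a$dataset_name))
  expect_warning(plan <- rewrite_to_local(g, empty_al, reg), "[Ee]mpty")
  expect_length(plan$local_queries, 0)
  expect_length(execute_plan(plan, reg)$entity, 0)
})

test_that("rendered SPARQL returns exactly the in-memory evaluation results", {
  b <- generate_fixtures(fixture_spec(seed = 25))
  reg <- registry_from_graphs(b$datasets)
  queries <- c("alzheimer C:Disease", "P:dosage", "malaria", "S:KEGG")
  for (txt in queries) {
    g <- build_global_query(parse_ease(txt), b$mediating, reg)
    plan <- rewrite_to_local(g, b$truth_alignments, reg)
    for (lq in plan$local_queries[seq_len(min(2, length(plan$local_queries)))]) {
      graph <- reg[[lq$dataset_name]]$graph
      mem <- sort(semsearch:::evaluate_local_query(lq, graph)$entities)
      sparql <- render_sparql(lq)
      expect_equal(python_sparql_entities(graph, sparql), mem, info = txt)
    }
  }
})

test_that("named-graph dialect wraps the pattern in a GRAPH clause", {
  lq <- semsearch:::local_query("D", class_iri = paste0(EX, "Drug"),
                                keywords = "aspirin",
                                graph_iri = paste0(EX, "graph"))
  s <- render_sparql(lq, dialect = "named-graph")
  expect_match(s, "GRAPH <http://example.org/ex/graph>", fixed = TRUE)
  expect_match(s, "REGEX\\(STR\\(\\?txt\\), \"aspirin\", \"i\"\\)")
})

test_that("multiple keywords render as OR-combined regex alternatives", {
  lq <- semsearch:::local_query("D", class_iri = paste0(EX, "Drug"),
                                keywords = c("aspirin", "warfarin"))
  s <- render_sparql(lq)
  expect_equal(lengths(regmatches(s, gregexpr("REGEX", s))), 2)
  expect_match(s, "\\|\\|")
})

test_that("execution deduplicates entities matched by several combinations", {
  b <- generate_fixtures(fixture_spec(seed = 26))
  reg <- registry_from_graphs(b$datasets)
  g <- build_global_query(parse_ease("C:Disease"), b$mediating, reg)
  plan <- rewrite_to_local(g, b$truth_alignments, reg)
  plan$local_queries <- c(plan$local_queries, plan$local_queries)
  res <- execute_plan(plan, reg)
  expect_false(any(duplicated(paste(res$entity, res$dataset))))
})

test_that("a failing dataset is isolated; all failing is an error", {
  b <- generate_fixtures(fixture_spec(seed = 27))
  good <- b$datasets[[1]]
  reg <- structure(list(
    Good = list(dataset_name = "Good", graph = good),
    Bad = list(dataset_name = "Bad", source = "/nonexistent/file.ttl",
               format = "turtle")), class = "dataset_registry")
  plan <- structure(list(local_queries = list(
    semsearch:::local_query("Good"), semsearch:::local_query("Bad"))),
    class = "query_plan")
  expect_warning(res <- execute_plan(plan, reg), "Bad")
  expect_setequal(unique(res$dataset), "Good")

  plan2 <- structure(list(local_queries = list(semsearch:::local_query("Bad"))),
                     class = "query_plan")
  expect_error(suppressWarnings(execute_plan(plan2, reg)), "every dataset")
})

test_that("restricting the dataset scope never adds results", {
  b <- generate_fixtures(fixture_spec(n_datasets = 3, seed = 28))
  reg <- registry_from_graphs(b$datasets)
  full <- semantic_search("alzheimer C:Disease", b$mediating, reg,
                          b$truth_alignments)
  part <- semantic_search(paste("alzheimer C:Disease S:", names(b$datasets)[1],
                                sep = ""), b$mediating, reg,
                          b$truth_alignments)
  expect_true(all(vapply(part, function(c) c$iri, character(1)) %in%
                    vapply(full, function(c) c$iri, character(1))))
})

test_that("adding a subclass edge never shrinks a query's result set", {
  b <- generate_fixtures(fixture_spec(seed = 29))
  reg <- registry_from_graphs(b$datasets)
  res1 <- semantic_search("C:Disease", b$mediating, reg, b$truth_alignments)
  m2 <- b$mediating
  m2$triples <- semsearch:::dedup_triples(rbind(
    m2$triples,
    semsearch:::make_triples(onto("Drug"), rdfs_subclassof, onto("Disease"))))
  res2 <- semantic_search("C:Disease", m2, reg, b$truth_alignments)
  iris1 <- vapply(res1, function(c) c$iri, character(1))
  iris2 <- vapply(res2, function(c) c$iri, character(1))
  expect_true(all(iris1 %in% iris2))
  expect_gt(length(iris2), length(iris1))
})
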