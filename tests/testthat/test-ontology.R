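test_that("OBO parsing keeps is_a edges, SMILES and non-obsolete terms only", {
  path <- oboLines(
    termStanza("T:A", "alpha"),
    termStanza("T:B", "beta", parents = "T:A"),
    termStanza("T:C", "gamma", parents = "T:B", smiles = "CCO",
               extra = "relationship: has_part T:A"),
    termStanza("T:OLD", "gone", parents = "T:A", obsolete = TRUE))
  g <- loadOntology(path)
  expect_equal(nrow(g@nodes), 3L)
  expect_equal(nrow(g@edges), 2L)  # has_part dropped, obsolete dropped
  expect_equal(g@nodes$smiles[g@nodes$id == "T:C"], "CCO")
  expect_false("T:OLD" %in% g@nodes$id)
})

test_that("class/member distinction follows leaf + SMILES", {
  # alanine is a class with L-alanine (structure-bearing leaf) as member
  path <- oboLines(
    termStanza("T:ALA", "alanine"),
    termStanza("T:LALA", "L-alanine", parents = "T:ALA",
               smiles = "C[C@@H](C(O)=O)N"),
    termStanza("T:NOSTRUCT", "leaf without structure", parents = "T:ALA"))
  g <- loadOntology(path)
  expect_setequal(leafMembers(g), "T:LALA")
})

test_that("root restriction prunes other branches before leaf status", {
  path <- oboLines(
    termStanza("T:TOP"),
    termStanza("T:MOL", parents = "T:TOP"),
    termStanza("T:ROLE", parents = "T:TOP"),
    termStanza("T:X", parents = "T:MOL", smiles = "CC"),
    termStanza("T:Y", parents = "T:ROLE", smiles = "CO"))
  g <- loadOntology(path, root = "T:MOL")
  expect_setequal(g@nodes$id, c("T:MOL", "T:X"))
  expect_equal(g@root, "T:MOL")
  expect_setequal(leafMembers(g), "T:X")
  expect_error(loadOntology(path, root = "T:ABSENT"), "root term")
})

test_that("malformed input fails loudly", {
  bad <- oboLines("[Term]", "name: no id here", "")
  expect_error(loadOntology(bad), "stanza")
  expect_error(loadOntology(tempfile()), "not found")
  # a cyclic is_a structure violates the DAG invariant
  cyc <- oboLines(
    termStanza("T:A", parents = "T:B"),
    termStanza("T:B", parents = "T:A"))
  expect_error(loadOntology(cyc), "cycle")
})

test_that("multiple SMILES values use the first with a warning", {
  path <- oboLines(
    termStanza("T:A"),
    c("[Term]", "id: T:M", "name: m", "is_a: T:A",
      "property_value: http://x/smiles \"CC\" xsd:string",
      "property_value: http://x/smiles \"CO\" xsd:string", ""))
  expect_warning(g <- loadOntology(path), "SMILES")
  expect_equal(g@nodes$smiles[g@nodes$id == "T:M"], "CC")
})

test_that("leaf members require both leaf status and structure", {
  g <- chainGraph()
  expect_setequal(leafMembers(g), "C")
  empty <- OntologyGraph(data.frame(id = character(), name = character(),
                                    smiles = character()),
                         data.frame(child = character(),
                                    parent = character()))
  expect_length(leafMembers(empty), 0L)
})

test_that("ancestors follow child-to-parent closure", {
  g <- chainGraph()
  expect_setequal(termAncestors(g, "C"), c("A", "B"))
  expect_length(termAncestors(g, "A"), 0L)
  d <- diamondGraph()
  expect_setequal(termAncestors(d, "D"), c("A", "B", "C"))
  expect_error(termAncestors(g, "Z"), "unknown term")
})

test_that("condense returns an antichain and is idempotent", {
  g <- chainGraph()
  expect_equal(condenseClasses(g, c("A", "B")), "B")
  d <- diamondGraph()
  expect_setequal(condenseClasses(d, c("B", "C")), c("B", "C"))
  # a specific prediction plus a top-level root: root removed
  expect_equal(condenseClasses(d, c("D", "A")), "D")
  withr::with_seed(42, {
    for (i in 1:20) {
      dag <- randomDag(sample(5:30, 1), seed = i)
      sub <- sample(dag@nodes$id, sample(2:5, 1))
      once <- condenseClasses(dag, sub)
      expect_identical(sort(condenseClasses(dag, once)), sort(once))
      for (a in once)
        for (b in setdiff(once, a))
          expect_false(a %in% termAncestors(dag, b))
    }
  })
})

test_that("path length matches the printed conventions", {
  g <- chainGraph()
  expect_identical(pathLength(g, "B", "B"), 0L)   # identical -> 0
  expect_identical(pathLength(g, "A", "B"), 1L)   # direct parent -> 1
  expect_identical(pathLength(g, "A", "C"), 2L)
  # symmetric under the undirected convention
  expect_identical(pathLength(g, "C", "A"), 2L)
  disconnected <- OntologyGraph(
    data.frame(id = c("A", "B", "X"), name = c("A", "B", "X"), smiles = NA),
    data.frame(child = "B", parent = "A"))
  expect_true(is.na(pathLength(disconnected, "X", "A")))
  expect_error(pathLength(g, "A", "Z"), "unknown term")
})

test_that("path length equals an independent BFS oracle on random DAGs", {
  withr::with_seed(99, {
    for (i in 1:25) {
      dag <- randomDag(sample(5:50, 1), seed = 1000 + i)
      pair <- sample(dag@nodes$id, 2)
      expect_identical(pathLength(dag, pair[1], pair[2]),
                       igraphPathOracle(dag, pair[1], pair[2]))
    }
  })
})

test_that("write + reload round-trips a graph, edge list exports as TSV", {
  fx <- fixtureSpec(nClasses = 3, membersPerClass = 4, hierarchyDepth = 4,
                    overlapFraction = 0.3, seed = 21)
  g <- makeToyOntology(fx)
  path <- tempfile(fileext = ".obo")
  writeOntology(g, path)
  g2 <- loadOntology(path)
  o1 <- order(g@nodes$id); o2 <- order(g2@nodes$id)
  expect_equal(g@nodes[o1, ], g2@nodes[o2, ], ignore_attr = TRUE)
  expect_setequal(paste(g@edges$child, g@edges$parent),
                  paste(g2@edges$child, g2@edges$parent))

  tsv <- tempfile(fileext = ".tsv")
  exportEdgeList(g, tsv)
  ed <- read.delim(tsv)
  expect_named(ed, c("child_id", "parent_id"))
  expect_equal(nrow(ed), nrow(g@edges))
})
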