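test_that("balanced selection returns N x M disjoint members from closures", {
  fx <- fixtureSpec(nClasses = 4, membersPerClass = 6, overlapFraction = 0.2,
                    seed = 3)
  g <- makeToyOntology(fx)
  ds <- selectBalanced(g, 3, 4, seed = 5)
  tab <- datasetTable(ds)
  expect_equal(length(unique(tab$class_id)), 3L)
  expect_true(all(table(tab$class_id) == 4L))
  expect_false(anyDuplicated(tab$member_id) > 0)
  closures <- chemont:::.leafClosures(g)
  for (i in seq_len(nrow(tab)))
    expect_true(tab$member_id[i] %in% closures[[tab$class_id[i]]])
})

test_that("selection is deterministic in (graph, spec, seed)", {
  g <- makeToyOntology(fixtureSpec(3, 5, seed = 9))
  a <- datasetTable(selectBalanced(g, 2, 4, seed = 11))
  b <- datasetTable(selectBalanced(g, 2, 4, seed = 11))
  c <- datasetTable(selectBalanced(g, 2, 4, seed = 12))
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("tiny problems and infeasible requests behave per contract", {
  # single class, single member
  one <- OntologyGraph(
    nodes = data.frame(id = c("CL", "M1", "M2"), name = c("cl", "m1", "m2"),
                       smiles = c(NA, "CC", "CO")),
    edges = data.frame(child = c("M1", "M2"), parent = "CL"))
  ds <- selectBalanced(one, 1, 1, seed = 1)
  expect_equal(nrow(datasetTable(ds)), 1L)

  # two classes over the same 5 leaves cannot fill 2 x 3 disjointly
  leaves <- sprintf("L%d", 1:5)
  shared <- OntologyGraph(
    nodes = data.frame(id = c("A", "B", leaves),
                       name = c("A", "B", leaves),
                       smiles = c(NA, NA, rep("CC", 5))),
    edges = rbind(data.frame(child = leaves, parent = "A"),
                  data.frame(child = leaves, parent = "B")))
  expect_error(selectBalanced(shared, 2, 3, seed = 1),
               "only 1 class")
})

test_that("smallest-first ordering serves nested classes that a
           largest-first greedy starves", {
  g <- nestedClassOntology(m = 5L)
  for (seed in 1:5) {
    ds <- selectBalanced(g, 2, 5, seed = seed)
    tab <- datasetTable(ds)
    expect_true("SMALL" %in% tab$class_id)
    expect_false(anyDuplicated(tab$member_id) > 0)
  }
  # a greedy that serves the largest classes first exhausts the nested
  # small class's members before it is reached
  for (seed in 1:5)
    expect_false("SMALL" %in% largestFirstSelect(g, 2, 5, seed))
})

test_that("feasibility is monotone in N", {
  g <- makeToyOntology(fixtureSpec(5, 6, overlapFraction = 0.3, seed = 17))
  for (n in 5:1) {
    ds <- selectBalanced(g, n, 5, seed = 2)
    expect_equal(ds@nClasses, as.integer(n))
  }
})

test_that("stratified split honours fractions within 1 per class", {
  g <- makeToyOntology(fixtureSpec(3, 10, seed = 4))
  ds <- selectBalanced(g, 3, 10, seed = 4)
  sp <- splitDataset(ds, c(0.7, 0.1, 0.2), seed = 8)
  expect_setequal(sp$member_id, datasetTable(ds)$member_id)
  for (cl in unique(sp$class_id)) {
    counts <- table(factor(sp$split[sp$class_id == cl],
                           levels = c("train", "validation", "test")))
    expect_true(all(abs(counts - c(7, 1, 2)) <= 1))
    expect_equal(sum(counts), 10L)
  }
})

test_that("split is reproducible and validates fractions", {
  g <- makeToyOntology(fixtureSpec(2, 8, seed = 6))
  ds <- selectBalanced(g, 2, 6, seed = 6)
  a <- splitDataset(ds, c(0.5, 0.25, 0.25), seed = 3)
  b <- splitDataset(ds, c(0.5, 0.25, 0.25), seed = 3)
  expect_identical(a, b)
  # two-way split: empty validation is valid
  tw <- splitDataset(ds, c(0.8, 0, 0.2), seed = 3)
  expect_equal(sum(tw$split == "validation"), 0L)
  expect_error(splitDataset(ds, c(0.7, 0.2, 0.2), seed = 1), "sum to 1")
  expect_error(splitDataset(ds, c(1, 0, 0), seed = 1), "test fraction")
})

test_that("dataset TSV round-trips", {
  g <- makeToyOntology(fixtureSpec(2, 5, seed = 14))
  sp <- splitDataset(selectBalanced(g, 2, 4, seed = 14), seed = 14)
  path <- tempfile(fileext = ".tsv")
  writeDatasetTsv(sp, path)
  back <- readDatasetTsv(path)
  expect_equal(back$member_id, sp$member_id)
  expect_equal(back$smiles, sp$smiles)
  expect_equal(back$split, sp$split)
})
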