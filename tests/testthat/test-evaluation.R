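test_that("precision/recall/F1 follow the defining formulas", {
  expect_equal(precisionScore(1, 1), 0.5)
  expect_equal(recallScore(1, 0), 1.0)
  expect_equal(f1Score(1, 1, 0), 2 / 3)
  # harmonic mean bounded by its arguments
  withr::with_seed(10, {
    for (i in 1:50) {
      tp <- sample(0:20, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
      p <- precisionScore(tp, fp); r <- recallScore(tp, fn)
      f <- f1Score(tp, fp, fn)
      expect_equal(unclass(p), if (tp + fp == 0) 0 else tp / (tp + fp),
                   ignore_attr = TRUE)
      expect_equal(unclass(r), if (tp + fn == 0) 0 else tp / (tp + fn),
                   ignore_attr = TRUE)
      if (p > 0 && r > 0) {
        expect_equal(unclass(f), 2 * p * r / (p + r), ignore_attr = TRUE)
        expect_true(f >= min(p, r) - 1e-12 && f <= max(p, r) + 1e-12)
      }
    }
  })
})

test_that("zero denominators yield 0 with a flag", {
  p <- precisionScore(0, 0)
  expect_equal(unclass(p), 0, ignore_attr = TRUE)
  expect_true(attr(p, "zeroDenominator"))
  expect_equal(unclass(f1Score(0, 0, 0)), 0, ignore_attr = TRUE)
})

test_that("single-label scoring matches a brute-force counter", {
  withr::with_seed(20, {
    for (i in 1:10) {
      classes <- paste0("c", 1:4)
      n <- 40
      truth <- setNames(sample(classes, n, TRUE), paste0("m", 1:n))
      pred <- setNames(sample(classes, n, TRUE), names(truth))
      rep <- scoreSingleLabel(pred, truth, classes)
      for (j in seq_along(classes)) {
        bc <- bruteCounts(pred, truth, classes[j])
        expect_equal(unlist(rep[j, c("tp", "fp", "fn")]), bc,
                     ignore_attr = TRUE)
      }
      expect_equal(unname(attr(rep, "macro")["f1"]), mean(rep$f1))
      expect_equal(sum(rep$tp), sum(pred == truth))
    }
  })
})

test_that("single-label scoring covers the printed counting cases", {
  truth <- setNames(rep(c("a", "b"), each = 2), paste0("m", 1:4))
  perfect <- truth
  rep <- scoreSingleLabel(perfect, truth)
  expect_true(all(rep$f1 == 1))
  # everything predicted 'a' on a balanced 2-class set
  allA <- setNames(rep("a", 4), names(truth))
  rep2 <- scoreSingleLabel(allA, truth)
  expect_equal(rep2$precision[rep2$class_id == "a"], 0.5)
  expect_equal(rep2$recall[rep2$class_id == "a"], 1.0)
  expect_equal(rep2$f1[rep2$class_id == "b"], 0)
  expect_error(scoreSingleLabel(allA[1:3], truth), "different member sets")
})

test_that("multi-label scoring yields per-molecule F1 and abstentions", {
  truth <- list(m1 = "a", m2 = "a", m3 = c("a", "b"))
  pred <- list(m1 = "a", m2 = character(), m3 = c("a", "b", "c"))
  out <- scoreMultiLabel(pred, truth, classes = c("a", "b", "c"))
  expect_equal(unname(out$perMoleculeF1["m1"]), 1)
  expect_equal(unname(out$perMoleculeF1["m2"]), 0)
  expect_equal(unname(out$perMoleculeF1["m3"]), 0.8)  # 2*2/(3+2)
  expect_equal(out$abstentions, "m2")
  # predicted {a,b} vs truth {a}
  out2 <- scoreMultiLabel(list(m = c("a", "b")), list(m = "a"),
                          classes = c("a", "b"))
  expect_equal(unname(out2$perMoleculeF1["m"]), 2 / 3)
})

test_that("reports are invariant under member permutation", {
  withr::with_seed(30, {
    classes <- c("x", "y", "z")
    truth <- setNames(sample(classes, 30, TRUE), paste0("m", 1:30))
    pred <- setNames(sample(classes, 30, TRUE), names(truth))
    a <- scoreSingleLabel(pred, truth, classes)
    perm <- sample(names(truth))
    b <- scoreSingleLabel(pred[perm], truth[perm], classes)
    expect_equal(a, b)
  })
})

test_that("path-length report covers match, chain and pair-count cases", {
  g <- chainGraph()
  # predicted identical to asserted: all zero
  r0 <- pathLengthReport(g, asserted = list(m1 = "B"),
                         predicted = list(m1 = "B"))
  expect_equal(r0$mean, 0)
  expect_equal(r0$perMolecule$max, 0)
  # asserted B, predicted its parent A: single length 1
  r1 <- pathLengthReport(g, asserted = list(m1 = "B"),
                         predicted = list(m1 = "A"))
  expect_equal(r1$pairs$length, 1L)
  expect_equal(r1$perMolecule$min, 1)
  expect_equal(r1$perMolecule$max, 1)
  expect_equal(r1$mean, 1)
  # 2 asserted x 3 predicted = 6 pairwise lengths
  d <- makeToyOntology(fixtureSpec(5, 3, seed = 44))
  cls <- sprintf("TOY:C%06d", 1:5)
  r2 <- pathLengthReport(d, asserted = list(m = cls[1:2]),
                         predicted = list(m = cls[3:5]))
  expect_equal(nrow(r2$pairs), 6L)
  expect_true(all(r2$perMolecule$min <= r2$perMolecule$mean &
                  r2$perMolecule$mean <= r2$perMolecule$max))
  expect_error(pathLengthReport(g, list(m = "B"), list(m = "ZZ")),
               "unknown term")
})

test_that("disconnected pairs are excluded from means but counted", {
  g <- OntologyGraph(
    data.frame(id = c("A", "B", "X"), name = c("A", "B", "X"), smiles = NA),
    data.frame(child = "B", parent = "A"))
  r <- pathLengthReport(g, asserted = list(m = "X"),
                        predicted = list(m = c("A", "X")))
  expect_equal(r$noPathCount, 1L)
  expect_equal(r$mean, 0)  # only the exact match contributes
})

test_that("mean parent count condenses before counting", {
  g <- chainGraph()
  expect_equal(meanParentCount(list(m1 = "A", m2 = "B"), g), 1)
  # one class plus its ancestor counts as one
  expect_equal(meanParentCount(list(m1 = c("B", "A")), g), 1)
  d <- diamondGraph()
  expect_equal(meanParentCount(list(m1 = "B", m2 = c("B", "C"),
                                    m3 = c("B", "C", "D")), d),
               mean(c(1, 2, 1)))  # D subsumed by none; B,C above D condense away
})

test_that("evaluation report files are written as JSON and TSV", {
  truth <- setNames(c("a", "b"), c("m1", "m2"))
  rep <- scoreSingleLabel(truth, truth)
  base <- tempfile()
  writeEvalReport(rep, base)
  expect_true(file.exists(paste0(base, ".json")))
  js <- jsonlite::read_json(paste0(base, ".json"))
  expect_equal(js$macro$f1, 1)
  tsv <- read.delim(paste0(base, ".tsv"))
  expect_equal(nrow(tsv), 2L)
})
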