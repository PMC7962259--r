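# Unit tests run a deliberately tiny network; learning power at the study's
# problem size is covered by the acceptance suite.

tinyTask <- function(n = 60, seed = 2) {
  # two token "motifs": sequences containing X belong to K1, Y to K2,
  # some to both
  withr::with_seed(seed, {
    seqs <- lapply(seq_len(n), function(i) {
      base <- sample(c("C", "O", "N"), sample(4:8, 1), replace = TRUE)
      cls <- sample(c("K1", "K2", "both"), 1)
      ins <- switch(cls, K1 = "X", K2 = "Y", both = c("X", "Y"))
      c(ins, base)
    })
    truth <- lapply(seqs, function(s)
      c(if ("X" %in% s) "K1", if ("Y" %in% s) "K2"))
    list(seqs = seqs, truth = truth)
  })
}

tinyModel <- function(task, epochs = 15, seed = 1) {
  vocab <- buildVocabulary(task$seqs)
  x <- encodeSequences(task$seqs, vocab)
  y <- matrix(0, length(task$truth), 2, dimnames = list(NULL, c("K1", "K2")))
  for (i in seq_along(task$truth)) y[i, task$truth[[i]]] <- 1
  cfg <- networkConfig(embeddingDim = 8, lstmUnits = 16, denseUnits = 16,
                       epochs = epochs, batchSize = 16, seed = seed)
  list(model = trainLstm(cfg, x, y, classLabels = c("K1", "K2"),
                         vocabulary = vocab),
       x = x, y = y)
}

test_that("config validation rejects out-of-range values", {
  expect_error(networkConfig(dropoutRate = 0), "dropoutRate")
  expect_error(networkConfig(threshold = 1), "threshold")
  expect_error(networkConfig(epochs = 0), "epochs")
})

test_that("history holds one record per epoch and training loss decreases", {
  fit <- tinyModel(tinyTask(), epochs = 10)
  h <- trainingHistory(fit$model)
  expect_equal(nrow(h), 10L)
  expect_equal(h$epoch, 1:10)
  # early epochs improve on the toy (no strict monotonicity required late)
  expect_lt(h$train_loss[10], h$train_loss[1])
})

test_that("analytic gradients match finite differences", {
  withr::with_seed(6, {
    w <- chemont:::.lstm_create(7L, 3L, 4L, 5L, 2L, 60L)
    X <- matrix(sample(0:6, 12, replace = TRUE), 3, 4)
    X[2, 3:4] <- 0L  # right padding
    storage.mode(X) <- "integer"
    Y <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE)
    g <- chemont:::.lstm_grad(w, X, Y)
    eps <- 1e-5
    for (nm in names(w)) {
      for (i in sample(length(w[[nm]]), min(8, length(w[[nm]])))) {
        wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
        wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
        num <- (chemont:::.lstm_loss(wp, X, Y) -
                chemont:::.lstm_loss(wm, X, Y)) / (2 * eps)
        expect_true(abs(num - g[[nm]][i]) <
                      1e-4 * max(1, abs(num)) + 1e-7,
                    label = paste("gradient of", nm))
      }
    }
  })
})

test_that("scores lie in [0,1], are deterministic, one vector per input", {
  task <- tinyTask()
  fit <- tinyModel(task, epochs = 5)
  sc <- predictScores(fit$model, fit$x)
  expect_equal(nrow(sc), nrow(fit$x))
  expect_true(all(sc >= 0 & sc <= 1))
  expect_identical(sc, predictScores(fit$model, fit$x))
  expect_error(predictScores(fit$model, fit$x[, 1:3]), "padded")
})

test_that("training is reproducible from the config seed", {
  task <- tinyTask()
  f1 <- tinyModel(task, epochs = 4, seed = 9)
  f2 <- tinyModel(task, epochs = 4, seed = 9)
  expect_identical(predictScores(f1$model, f1$x),
                   predictScores(f2$model, f2$x))
})

test_that("thresholding is strict and reports abstentions", {
  sc <- matrix(c(0.6, 0.4,
                 0.5, 0.5,
                 0.2, 0.9), 3, 2, byrow = TRUE,
               dimnames = list(NULL, c("K1", "K2")))
  pred <- predictClasses(sc, 0.5)
  expect_equal(pred[[1]], "K1")
  expect_length(pred[[2]], 0L)          # exactly 0.5 is excluded
  expect_equal(pred[[3]], "K2")
  expect_equal(attr(pred, "abstained"), 2L)
})

test_that("the network can predict several classes per molecule", {
  task <- tinyTask(n = 120, seed = 4)
  fit <- tinyModel(task, epochs = 25, seed = 3)
  pred <- predictClasses(predictScores(fit$model, fit$x), 0.5)
  sizes <- lengths(pred)
  both <- vapply(task$truth, length, integer(1)) == 2L
  expect_gt(mean(sizes[both] == 2L), 0.5)
})

test_that("label matrices support single-hot and ancestor-closure modes", {
  g <- chainGraph()
  single <- labelMatrix(c("C", "B"), classLabels = c("A", "B", "C"))
  expect_equal(single, rbind(c(0, 0, 1), c(0, 1, 0)), ignore_attr = TRUE)
  multi <- labelMatrix(c("C", "B"), classLabels = c("A", "B", "C"),
                       graph = g, multiHot = TRUE)
  expect_equal(multi, rbind(c(1, 1, 1), c(1, 1, 0)), ignore_attr = TRUE)
  expect_error(labelMatrix("C", c("A", "C"), multiHot = TRUE), "graph")
})

test_that("history CSV export is long-format per split", {
  fit <- tinyModel(tinyTask(), epochs = 3)
  path <- tempfile(fileext = ".csv")
  writeHistoryCsv(fit$model, path)
  h <- read.csv(path)
  expect_equal(nrow(h), 6L)
  expect_setequal(unique(h$split), c("train", "validation"))
})
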