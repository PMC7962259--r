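#' Sequence-network configuration
#'
#' Hyperparameters of the multi-label recurrent classifier: token embedding
#' -> unidirectional LSTM -> dense (ReLU) -> dropout -> per-class sigmoid,
#' trained with binary cross-entropy.
#'
#' @param embeddingDim Embedding width per token (default 64).
#' @param lstmUnits LSTM state size (default 128).
#' @param denseUnits Width of the dense layer after the last LSTM cell
#'   (default 128).
#' @param dropoutRate Dropout fraction applied after the dense layer,
#'   in (0, 1) (default 0.2).
#' @param epochs Training epochs (default 100).
#' @param threshold Class-membership cut-off on the sigmoid scores, in
#'   (0, 1) (default 0.5); membership is \emph{strictly} greater than the
#'   threshold.
#' @param batchSize Minibatch size (default 32).
#' @param learningRate Adam learning rate (default 1e-3).
#' @param seed Integer seed for weight initialisation, shuffling and dropout.
#' @return Validated configuration list.
#' @export
networkConfig <- function(embeddingDim = 64L, lstmUnits = 128L,
                          denseUnits = 128L, dropoutRate = 0.2,
                          epochs = 100L, threshold = 0.5, batchSize = 32L,
                          learningRate = 1e-3, seed = 1L) {
  stopifnot(embeddingDim >= 1, lstmUnits >= 1, denseUnits >= 1,
            epochs >= 1, batchSize >= 1, learningRate > 0)
  if (dropoutRate <= 0 || dropoutRate >= 1)
    stop("dropoutRate must lie in (0, 1)", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  list(embeddingDim = as.integer(embeddingDim),
       lstmUnits = as.integer(lstmUnits),
       denseUnits = as.integer(denseUnits),
       dropoutRate = dropoutRate, epochs = as.integer(epochs),
       threshold = threshold, batchSize = as.integer(batchSize),
       learningRate = learningRate, seed = as.integer(seed))
}

#' Build class label matrices
#'
#' Converts per-molecule class assignments into the 0/1 label matrix the
#' network is trained against.  By default labels are single-hot: the
#' positive label is the class the molecule was sampled for, since
#' predictions are scored against the sampled classes.  With
#' \code{multiHot = TRUE} and an ontology, all ancestors of the sampled
#' class that are themselves in \code{classLabels} are also set positive
#' (ancestor-closure labelling).
#'
#' @param classes Character vector, one sampled class per molecule.
#' @param classLabels Ordered label set (matrix columns).
#' @param graph Optional [OntologyGraph-class], required for
#'   \code{multiHot}.
#' @param multiHot Logical; include ancestor classes as positives.
#' @return 0/1 numeric matrix, \code{length(classes)} rows.
#' @export
labelMatrix <- function(classes, classLabels, graph = NULL,
                        multiHot = FALSE) {
  Y <- matrix(0, nrow = length(classes), ncol = length(classLabels),
              dimnames = list(NULL, classLabels))
  for (i in seq_along(classes)) {
    pos <- classes[[i]]
    if (multiHot) {
      if (is.null(graph))
        stop("multiHot labelling requires the ontology graph", call. = FALSE)
      pos <- c(pos, intersect(termAncestors(graph, pos), classLabels))
    }
    Y[i, intersect(pos, classLabels)] <- 1
  }
  Y
}

#' Train the multi-label LSTM classifier
#'
#' Trains embedding -> LSTM -> dense -> dropout -> sigmoid against binary
#' cross-entropy for \code{config$epochs} epochs with Adam, recording loss
#' and micro-averaged precision/recall on the training and validation sets
#' after every epoch.  All stochastic pieces (weight initialisation,
#' shuffling, dropout masks) are keyed to \code{config$seed}.
#'
#' @param config A [networkConfig()].
#' @param x Integer matrix of encoded, right-padded token sequences from
#'   [encodeSequences()].
#' @param y 0/1 label matrix from [labelMatrix()]; one column per class.
#' @param xVal,yVal Optional validation set in the same encoding; pass
#'   \code{NULL} to train without validation tracking.
#' @param classLabels Class identifiers naming the columns of \code{y}.
#' @param vocabulary The [TokenVocabulary-class] the sequences were encoded
#'   with (stored for later encoding of test data).
#' @return A [LstmClassifier-class].
#' @export
trainLstm <- function(config, x, y, xVal = NULL, yVal = NULL,
                      classLabels = colnames(y), vocabulary) {
  stopifnot(is.matrix(x), is.matrix(y), nrow(x) == nrow(y))
  if (is.null(classLabels))
    stop("classLabels must be given (or y must have column names)",
         call. = FALSE)
  if (ncol(y) != length(classLabels))
    stop("label matrix has ", ncol(y), " columns for ",
         length(classLabels), " classes", call. = FALSE)
  stopifnot(is(vocabulary, "TokenVocabulary"))
  storage.mode(x) <- "integer"
  if (is.null(xVal)) {
    xVal <- matrix(0L, 0L, ncol(x))
    yVal <- matrix(0, 0L, ncol(y))
  }
  stopifnot(nrow(xVal) == nrow(yVal))
  if (nrow(xVal) > 0 && ncol(yVal) != ncol(y))
    stop("validation labels have a different class dimension",
         call. = FALSE)
  storage.mode(xVal) <- "integer"

  vocabRows <- length(vocabulary@index) + 2L  # + reserved pad/unknown
  weights <- .lstm_create(vocabRows, config$embeddingDim, config$lstmUnits,
                          config$denseUnits, length(classLabels),
                          config$seed)
  fit <- .lstm_fit(weights, x, y, xVal, yVal, config$epochs,
                   config$batchSize, config$learningRate,
                   config$dropoutRate, config$threshold, config$seed)
  history <- data.frame(
    epoch = seq_len(config$epochs),
    train_loss = fit$train_loss, train_precision = fit$train_precision,
    train_recall = fit$train_recall, val_loss = fit$val_loss,
    val_precision = fit$val_precision, val_recall = fit$val_recall)
  new("LstmClassifier", weights = fit$params, config = config,
      classLabels = as.character(classLabels), vocabulary = vocabulary,
      padTo = ncol(x), history = history)
}

#' Per-class membership scores
#'
#' Runs the trained network over encoded sequences; each molecule receives
#' one score per class, each in [0, 1].  Inference is deterministic (dropout
#' is inactive).
#'
#' @param model A [LstmClassifier-class].
#' @param x Integer matrix of sequences encoded with the model's vocabulary
#'   and padded to the model's training length.
#' @return Numeric matrix, one row per molecule, one column per class.
#' @export
predictScores <- function(model, x) {
  stopifnot(is(model, "LstmClassifier"), is.matrix(x))
  if (ncol(x) != model@padTo)
    stop("sequences padded to ", ncol(x), " but the model was trained at ",
         model@padTo, call. = FALSE)
  storage.mode(x) <- "integer"
  scores <- .lstm_scores(model@weights, x)
  colnames(scores) <- model@classLabels
  scores
}

#' Threshold scores into predicted class sets
#'
#' A class is predicted when its score is \emph{strictly} greater than the
#' threshold; a molecule whose scores all fall at or below the threshold
#' receives the empty set, i.e. the network abstains.
#'
#' @param scores Score matrix from [predictScores()] (or one score vector).
#' @param threshold Membership cut-off in (0, 1); default 0.5.
#' @return List of character vectors of predicted class identifiers (empty
#'   = abstention); attribute \code{"abstained"} holds the row indices with
#'   empty predictions.
#' @export
predictClasses <- function(scores, threshold = 0.5) {
  if (is.vector(scores)) scores <- matrix(scores, nrow = 1,
                                          dimnames = list(NULL, names(scores)))
  stopifnot(threshold > 0, threshold < 1)
  labels <- colnames(scores)
  out <- lapply(seq_len(nrow(scores)), function(i)
    labels[scores[i, ] > threshold])
  attr(out, "abstained") <- which(vapply(out, length, integer(1)) == 0L)
  out
}

#' Per-epoch training history
#'
#' @param model A [LstmClassifier-class].
#' @return data.frame with columns \code{epoch}, \code{train_loss},
#'   \code{train_precision}, \code{train_recall} and their validation
#'   counterparts (NA when trained without a validation set).
#' @export
trainingHistory <- function(model) {
  stopifnot(is(model, "LstmClassifier"))
  model@history
}

#' Export a training history as CSV
#'
#' Long format: epoch, split, loss, precision, recall.
#'
#' @param model A [LstmClassifier-class].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeHistoryCsv <- function(model, path) {
  h <- trainingHistory(model)
  long <- rbind(
    data.frame(epoch = h$epoch, split = "train", loss = h$train_loss,
               precision = h$train_precision, recall = h$train_recall),
    data.frame(epoch = h$epoch, split = "validation", loss = h$val_loss,
               precision = h$val_precision, recall = h$val_recall))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
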