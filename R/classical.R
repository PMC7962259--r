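# Uniform fit/predict surface over the eight classical algorithms operating
# on fingerprint vectors: one-vs-rest ridge logistic regression, K-nearest
# neighbours, a single decision tree, random forest, naive Bayes, linear
# discriminant analysis and support vector machines with linear, RBF and
# sigmoid kernels.  All are multi-class single-label: exactly one predicted
# class per molecule, never an abstention.

.algorithms <- c("LR", "KNN", "CART", "RF", "NB", "LDA", "SVM")
.svmKernels <- c("linear", "rbf", "sigmoid")

#' Specify a classical classifier
#'
#' @param algorithm One of \code{"LR"} (one-vs-rest logistic regression),
#'   \code{"KNN"}, \code{"CART"} (decision tree), \code{"RF"} (random
#'   forest), \code{"NB"} (naive Bayes), \code{"LDA"} or \code{"SVM"}.
#' @param kernel For SVM only: \code{"linear"}, \code{"rbf"} or
#'   \code{"sigmoid"}.
#' @param hyperparameters Named list of backend hyperparameters; recognised
#'   keys are \code{k} (KNN neighbours, default 5), \code{ntree} (forest
#'   size, default 500), \code{lambda} (LR ridge penalty, default 1e-3) and
#'   \code{cost} (SVM C, default 1).  Unstated values are the backends'
#'   defaults.
#' @param seed Integer seed driving any stochastic fitting (RF bootstrap,
#'   tie-breaks).
#' @return Validated spec list.
#' @export
classifierSpec <- function(algorithm, kernel = NULL,
                           hyperparameters = list(), seed = 1L) {
  algorithm <- match.arg(algorithm, .algorithms)
  if (algorithm == "SVM") {
    if (is.null(kernel)) kernel <- "linear"
    kernel <- match.arg(kernel, .svmKernels)
  } else if (!is.null(kernel)) {
    stop("kernel may only be set for SVM", call. = FALSE)
  }
  if (!is.null(hyperparameters$k) && hyperparameters$k < 1)
    stop("k must be >= 1", call. = FALSE)
  list(algorithm = algorithm, kernel = kernel,
       hyperparameters = hyperparameters, seed = as.integer(seed))
}

.hp <- function(spec, key, default) {
  v <- spec$hyperparameters[[key]]
  if (is.null(v)) default else v
}

# fingerprint bits as two-level factors, so naive Bayes models them as
# Bernoulli features rather than degenerate Gaussians
.asBitFactors <- function(X) {
  out <- data.frame(lapply(seq_len(ncol(X)), function(j)
    factor(X[, j], levels = c(0, 1))))
  names(out) <- colnames(X)
  out
}

#' Train a classical classifier on fingerprint vectors
#'
#' Fits the algorithm named in \code{spec} on a 0/1 fingerprint matrix.  For
#' logistic regression a separate one-vs-rest ridge-penalised discriminator
#' is fitted per class and prediction takes the class whose discriminator
#' scores highest (ties broken towards the lowest class index).  LDA drops
#' columns with zero variance before fitting (they carry no discriminative
#' information and break the covariance estimate); the retained columns are
#' stored with the model.  Fitting is deterministic given \code{spec$seed}.
#'
#' @param spec A [classifierSpec()].
#' @param X Numeric 0/1 matrix, one fingerprint per row.
#' @param y Character/factor vector of class labels, \code{length(y) ==
#'   nrow(X)}; at least two distinct labels.
#' @return A [ClassicalModel-class].
#' @export
trainClassical <- function(spec, X, y) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (nrow(X) != length(y))
    stop("X and y lengths differ (", nrow(X), " vs ", length(y), ")",
         call. = FALSE)
  if (nrow(X) == 0L) stop("empty training set", call. = FALSE)
  labels <- sort(unique(y))
  if (length(labels) < 2L)
    stop("training requires at least two distinct class labels",
         call. = FALSE)
  colnames(X) <- paste0("b", seq_len(ncol(X)))
  yf <- factor(y, levels = labels)
  keep <- seq_len(ncol(X))
  trainX <- NULL; trainY <- NULL

  fit <- withr::with_seed(spec$seed, switch(spec$algorithm,
    LR = lapply(labels, function(cl) {
      glmnet::glmnet(X, as.numeric(y == cl), family = "binomial",
                     alpha = 0, lambda = .hp(spec, "lambda", 1e-3),
                     standardize = FALSE)
    }),
    KNN = {
      trainX <- X; trainY <- y
      NULL  # lazy learner: data retained, no fitting
    },
    CART = rpart::rpart(cls ~ ., data = data.frame(cls = yf, X),
                        method = "class"),
    RF = randomForest::randomForest(X, yf,
                                    ntree = .hp(spec, "ntree", 500)),
    NB = e1071::naiveBayes(.asBitFactors(X), yf, laplace = 1),
    LDA = {
      # lda rejects variables with (near-)zero pooled within-group variance
      withinVar <- Reduce(`+`, lapply(split(seq_len(nrow(X)), yf),
        function(rows) {
          xs <- X[rows, , drop = FALSE]
          colSums(sweep(xs, 2, colMeans(xs))^2)
        })) / nrow(X)
      keep <- which(withinVar > 1e-8)
      if (length(keep) < 1L)
        stop("no informative fingerprint columns for LDA", call. = FALSE)
      suppressWarnings(MASS::lda(X[, keep, drop = FALSE], grouping = yf))
    },
    SVM = {
      kern <- switch(spec$kernel, linear = "linear", rbf = "radial",
                     sigmoid = "sigmoid")
      e1071::svm(X, yf, kernel = kern, cost = .hp(spec, "cost", 1),
                 scale = FALSE)
    }))

  if (spec$algorithm == "LR") names(fit) <- labels
  new("ClassicalModel", spec = spec, classLabels = labels, fit = fit,
      keepColumns = as.integer(keep), nFeatures = ncol(X),
      trainX = trainX, trainY = trainY)
}

#' One-vs-rest discriminator scores of a logistic-regression model
#'
#' Per-class membership probabilities from each one-vs-rest discriminator;
#' [predict()][ClassicalModel-class] takes the row-wise argmax of these.
#'
#' @param model A [ClassicalModel-class] with algorithm \code{"LR"}.
#' @param X Fingerprint matrix.
#' @return Numeric matrix, one column per class.
#' @export
ovrScores <- function(model, X) {
  stopifnot(is(model, "ClassicalModel"), model@spec$algorithm == "LR")
  X <- as.matrix(X)
  colnames(X) <- paste0("b", seq_len(ncol(X)))
  scores <- vapply(model@classLabels, function(cl) {
    as.numeric(stats::predict(model@fit[[cl]], X, type = "response"))
  }, numeric(nrow(X)))
  matrix(scores, nrow = nrow(X),
         dimnames = list(NULL, model@classLabels))
}

#' @describeIn ClassicalModel-class Predict exactly one class label per
#'   fingerprint row; never abstains.  Argmax ties resolve to the lowest
#'   class index.
#' @param object A [ClassicalModel-class].
#' @param newdata Fingerprint matrix with the training dimensionality.
#' @export
setMethod("predict", "ClassicalModel", function(object, newdata) {
  X <- as.matrix(newdata)
  if (ncol(X) != object@nFeatures)
    stop("fingerprint length differs from training dimensionality (",
         ncol(X), " vs ", object@nFeatures, ")", call. = FALSE)
  colnames(X) <- paste0("b", seq_len(ncol(X)))
  spec <- object@spec
  labels <- object@classLabels

  out <- withr::with_seed(spec$seed, switch(spec$algorithm,
    LR = {
      sc <- ovrScores(object, X)
      labels[max.col(sc, ties.method = "first")]
    },
    KNN = as.character(class::knn(object@trainX, X, object@trainY,
                                  k = .hp(spec, "k", 5))),
    CART = {
      p <- stats::predict(object@fit, data.frame(X), type = "prob")
      labels[max.col(p, ties.method = "first")]
    },
    RF = as.character(stats::predict(object@fit, X)),
    NB = as.character(stats::predict(object@fit, .asBitFactors(X))),
    LDA = {
      as.character(stats::predict(
        object@fit, X[, object@keepColumns, drop = FALSE])$class)
    },
    SVM = as.character(stats::predict(object@fit, X))))
  unname(out)
})

#' Save / load a fitted model
#'
#' Round-trips any chemont model object (classical or LSTM) to an on-disk
#' artifact.
#'
#' @param model Model object.
#' @param path File path.
#' @return \code{saveModel}: invisibly, \code{path}; \code{loadModel}: the
#'   model.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) readRDS(path)
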