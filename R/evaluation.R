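# Scoring: per-class precision/recall/F1 from confusion counts, per-molecule
# F1 and abstention reporting for multi-label predictions, and the
# ontology-aware path-length comparison between predicted and asserted
# parent classes.

#' Precision, recall and F1 from confusion counts
#'
#' \code{precision = TP / (TP + FP)}, \code{recall = TP / (TP + FN)}, and F1
#' is their harmonic mean \code{2 P R / (P + R)}.  A zero denominator yields
#' 0 by convention (so macro averages stay total); the returned value then
#' carries attribute \code{"zeroDenominator" = TRUE}.
#'
#' @param tp,fp,fn Non-negative confusion counts.
#' @return Numeric in [0, 1].
#' @examples
#' precisionScore(1, 1)   # 0.5
#' recallScore(1, 0)      # 1
#' f1Score(1, 1, 0)       # 2/3
#' @export
precisionScore <- function(tp, fp) .safeRatio(tp, tp + fp)

#' @rdname precisionScore
#' @export
recallScore <- function(tp, fn) .safeRatio(tp, tp + fn)

#' @rdname precisionScore
#' @export
f1Score <- function(tp, fp, fn) {
  p <- precisionScore(tp, fp)
  r <- recallScore(tp, fn)
  .safeRatio(2 * p * r, p + r)
}

.safeRatio <- function(num, den) {
  stopifnot(num >= 0, den >= 0)
  if (den == 0) structure(0, zeroDenominator = TRUE) else unname(num / den)
}

.classReport <- function(counts) {
  # counts: data.frame(class_id, tp, fp, fn)
  counts$precision <- mapply(precisionScore, counts$tp, counts$fp)
  counts$recall <- mapply(recallScore, counts$tp, counts$fn)
  counts$f1 <- mapply(f1Score, counts$tp, counts$fp, counts$fn)
  counts
}

#' Score single-label predictions
#'
#' Per-class confusion counts for a multi-class single-label classifier:
#' for class c, TP = members of c predicted c, FP = members of other classes
#' predicted c, FN = members of c predicted otherwise.  Predictions are
#' scored against the classes the molecules were sampled from.
#'
#' @param predictions Named character vector, member id -> predicted class.
#' @param truth Named character vector, member id -> sampled (true) class.
#'   Must cover the same member ids as \code{predictions}.
#' @param classes Class label set; defaults to the union of truth labels.
#' @return data.frame with one row per class (\code{class_id}, \code{tp},
#'   \code{fp}, \code{fn}, \code{precision}, \code{recall}, \code{f1});
#'   attribute \code{"macro"} holds the macro-averaged precision/recall/F1.
#' @export
scoreSingleLabel <- function(predictions, truth, classes = NULL) {
  if (!setequal(names(predictions), names(truth)))
    stop("predictions and truth cover different member sets",
         call. = FALSE)
  predictions <- predictions[names(truth)]
  if (is.null(classes)) classes <- sort(unique(truth))
  counts <- do.call(rbind, lapply(classes, function(cl) {
    data.frame(class_id = cl,
               tp = sum(truth == cl & predictions == cl),
               fp = sum(truth != cl & predictions == cl),
               fn = sum(truth == cl & predictions != cl))
  }))
  rep <- .classReport(counts)
  attr(rep, "macro") <- c(precision = mean(rep$precision),
                          recall = mean(rep$recall), f1 = mean(rep$f1))
  rep
}

#' Score multi-label predictions
#'
#' Per-class confusion counts over set membership, the distribution of
#' per-molecule F1 scores (F1 between each molecule's predicted and true
#' class sets), and the abstention set: molecules with an empty predicted
#' set.  An abstaining molecule with non-empty truth scores a per-molecule
#' F1 of 0, which is what makes abstention detrimental to overall recall.
#'
#' @param predictions Named list, member id -> character vector of predicted
#'   classes (may be empty).
#' @param truth Named list, member id -> character vector of true classes.
#' @param classes Class label set; defaults to the union of truth labels.
#' @return list with elements \code{classReport} (as in
#'   [scoreSingleLabel()], incl. the \code{"macro"} attribute),
#'   \code{perMoleculeF1} (named numeric) and \code{abstentions}
#'   (character vector of member ids).
#' @export
scoreMultiLabel <- function(predictions, truth, classes = NULL) {
  if (!setequal(names(predictions), names(truth)))
    stop("predictions and truth cover different member sets",
         call. = FALSE)
  predictions <- predictions[names(truth)]
  if (is.null(classes))
    classes <- sort(unique(unlist(truth, use.names = FALSE)))
  counts <- do.call(rbind, lapply(classes, function(cl) {
    inPred <- vapply(predictions, function(s) cl %in% s, logical(1))
    inTrue <- vapply(truth, function(s) cl %in% s, logical(1))
    data.frame(class_id = cl,
               tp = sum(inPred & inTrue),
               fp = sum(inPred & !inTrue),
               fn = sum(!inPred & inTrue))
  }))
  rep <- .classReport(counts)
  attr(rep, "macro") <- c(precision = mean(rep$precision),
                          recall = mean(rep$recall), f1 = mean(rep$f1))
  perMol <- vapply(names(truth), function(id) {
    p <- predictions[[id]]
    t <- truth[[id]]
    tp <- length(intersect(p, t))
    f1Score(tp, length(setdiff(p, t)), length(setdiff(t, p)))
  }, numeric(1))
  abstained <- names(predictions)[
    vapply(predictions, length, integer(1)) == 0L]
  list(classReport = rep, perMoleculeF1 = perMol, abstentions = abstained)
}

#' Path-length report between predicted and asserted parents
#'
#' For every molecule, every (asserted, predicted) class pair contributes
#' one path length via [pathLength()]: 0 when the predicted class is one of
#' the asserted parents, otherwise the number of subsumption edges between
#' the two.  Reports the full pairwise list, per-molecule minimum/maximum/
#' mean, the overall mean over all pairs (each pair weighted equally), and
#' the count of disconnected (no-path) pairs, which are excluded from all
#' means.
#'
#' Predicted sets should already be condensed ([condenseClasses()]) so that
#' redundant superclasses do not dilute the statistics.
#'
#' @param graph An [OntologyGraph-class].
#' @param asserted Named list, member id -> character vector of asserted
#'   (ground-truth) parent classes; either ChEBI-asserted direct parents or
#'   the sampled training classes.
#' @param predicted Named list, member id -> character vector of predicted
#'   classes; molecules with empty predictions contribute no pairs.
#' @return list with \code{pairs} (data.frame member_id, asserted,
#'   predicted, length), \code{perMolecule} (data.frame member_id, min, max,
#'   mean), \code{mean} (overall pairwise mean), \code{noPathCount}.
#' @export
pathLengthReport <- function(graph, asserted, predicted) {
  stopifnot(is(graph, "OntologyGraph"))
  if (!setequal(names(asserted), names(predicted)))
    stop("asserted and predicted cover different member sets",
         call. = FALSE)
  allIds <- unique(c(unlist(asserted, use.names = FALSE),
                     unlist(predicted, use.names = FALSE)))
  .checkIds(graph, allIds)

  # one BFS per distinct asserted class, reused across molecules
  distFrom <- list()
  for (a in unique(unlist(asserted, use.names = FALSE)))
    distFrom[[a]] <- .bfsDistances(graph, a)

  pairs <- do.call(rbind, lapply(names(asserted), function(id) {
    av <- asserted[[id]]
    pv <- predicted[[id]]
    if (!length(av) || !length(pv)) return(NULL)
    grid <- expand.grid(asserted = av, predicted = pv,
                        stringsAsFactors = FALSE)
    grid$length <- mapply(function(a, p) {
      if (a == p) 0L else unname(distFrom[[a]][p])
    }, grid$asserted, grid$predicted)
    cbind(member_id = id, grid)
  }))
  if (is.null(pairs))
    pairs <- data.frame(member_id = character(), asserted = character(),
                        predicted = character(), length = integer())

  ok <- !is.na(pairs$length)
  perMol <- do.call(rbind, lapply(split(pairs[ok, , drop = FALSE],
                                        pairs$member_id[ok]), function(df) {
    data.frame(member_id = df$member_id[[1L]], min = min(df$length),
               max = max(df$length), mean = mean(df$length))
  }))
  if (is.null(perMol))
    perMol <- data.frame(member_id = character(), min = integer(),
                         max = integer(), mean = numeric())
  rownames(perMol) <- NULL
  list(pairs = pairs,
       perMolecule = perMol,
       mean = if (any(ok)) mean(pairs$length[ok]) else NA_real_,
       noPathCount = sum(!ok))
}

#' Mean number of (non-redundant) predicted parent classes
#'
#' Condenses each molecule's predicted class set to an antichain (dropping
#' any prediction that is a superclass of another prediction) and returns
#' the average set size per molecule.
#'
#' @param predictions Named list, member id -> character vector of predicted
#'   classes.
#' @param graph An [OntologyGraph-class].
#' @return Mean condensed parent count per molecule.
#' @export
meanParentCount <- function(predictions, graph) {
  stopifnot(is(graph, "OntologyGraph"))
  sizes <- vapply(predictions, function(p)
    length(condenseClasses(graph, p)), integer(1))
  mean(sizes)
}

#' Write an evaluation report as JSON and TSV
#'
#' @param report list from [scoreSingleLabel()]/[scoreMultiLabel()] or a
#'   per-class report data.frame.
#' @param path Output path without extension; writes \code{path.json} and a
#'   per-class \code{path.tsv}.
#' @return Invisibly, the JSON path.
#' @export
writeEvalReport <- function(report, path) {
  classReport <- if (is.data.frame(report)) report else report$classReport
  payload <- if (is.data.frame(report)) {
    list(classReport = report, macro = as.list(attr(report, "macro")))
  } else {
    c(report, list(macro = as.list(attr(report$classReport, "macro"))))
  }
  jsonlite::write_json(payload, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  utils::write.table(classReport, paste0(path, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paste0(path, ".json"))
}
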