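#' @import methods
NULL

#' OntologyGraph: a subsumption DAG over chemical terms
#'
#' Directed acyclic graph of ontology terms connected by \code{is_a}
#' (subsumption) edges, as parsed from an OBO file.  Each node carries a term
#' identifier, a display name and, optionally, a SMILES string describing a
#' fully defined molecular structure.  Terms that are leaves of the hierarchy
#' *and* carry a SMILES annotation are the "leaf members" used as
#' classification instances; all other terms act as classes.
#'
#' @slot nodes data.frame with columns \code{id}, \code{name}, \code{smiles}
#'   (\code{NA} when the term has no structure annotation).
#' @slot edges data.frame with columns \code{child}, \code{parent}; one row
#'   per \code{is_a} assertion.
#' @slot root character of length 0 or 1; the designated root term, when the
#'   graph was restricted to a branch (e.g. ChEBI's 'molecular entity').
#'
#' @seealso [loadOntology()], [leafMembers()], [pathLength()]
#' @export
setClass("OntologyGraph",
  representation(nodes = "data.frame", edges = "data.frame",
                 root = "character"),
  prototype(
    nodes = data.frame(id = character(), name = character(),
                       smiles = character(), stringsAsFactors = FALSE),
    edges = data.frame(child = character(), parent = character(),
                       stringsAsFactors = FALSE),
    root = character()
  )
)

setValidity("OntologyGraph", function(object) {
  nd <- object@nodes
  ed <- object@edges
  msgs <- character()
  if (!all(c("id", "name", "smiles") %in% names(nd)))
    msgs <- c(msgs, "nodes must have columns id, name, smiles")
  else {
    if (anyDuplicated(nd$id))
      msgs <- c(msgs, "duplicated term identifiers")
    bad <- !is.na(nd$smiles) & !nzchar(nd$smiles)
    if (any(bad))
      msgs <- c(msgs, "empty SMILES annotation present")
  }
  if (!all(c("child", "parent") %in% names(ed)))
    msgs <- c(msgs, "edges must have columns child, parent")
  else if (length(msgs) == 0L) {
    if (!all(ed$child %in% nd$id) || !all(ed$parent %in% nd$id))
      msgs <- c(msgs, "edge endpoint not present in nodes")
    else if (is.null(.topologicalOrder(nd$id, ed)))
      msgs <- c(msgs, "subsumption graph contains a cycle")
  }
  if (length(object@root) > 1L)
    msgs <- c(msgs, "root must have length 0 or 1")
  if (length(object@root) == 1L && !(object@root %in% nd$id))
    msgs <- c(msgs, "root term not present in nodes")
  if (length(msgs)) msgs else TRUE
})

#' Construct an OntologyGraph
#'
#' @param nodes data.frame with columns \code{id}, \code{name} and optionally
#'   \code{smiles}.
#' @param edges data.frame with columns \code{child}, \code{parent}.
#' @param root optional root term identifier.
#' @return An [OntologyGraph-class] object.
#' @examples
#' g <- OntologyGraph(
#'   nodes = data.frame(id = c("T:1", "T:2"), name = c("acid", "formic acid"),
#'                      smiles = c(NA, "OC=O")),
#'   edges = data.frame(child = "T:2", parent = "T:1"))
#' leafMembers(g)
#' @export
OntologyGraph <- function(nodes, edges, root = character()) {
  if (is.null(nodes$smiles)) nodes$smiles <- NA_character_
  nodes <- data.frame(id = as.character(nodes$id),
                      name = as.character(nodes$name),
                      smiles = as.character(nodes$smiles),
                      stringsAsFactors = FALSE)
  edges <- data.frame(child = as.character(edges$child),
                      parent = as.character(edges$parent),
                      stringsAsFactors = FALSE)
  if (is.null(root)) root <- character()
  new("OntologyGraph", nodes = nodes, edges = edges,
      root = as.character(root))
}

setMethod("show", "OntologyGraph", function(object) {
  nmem <- length(leafMembers(object))
  cat("OntologyGraph with", nrow(object@nodes), "terms and",
      nrow(object@edges), "is_a edges\n")
  if (length(object@root))
    cat("  root:", object@root, "\n")
  cat("  leaf members (structure-bearing leaves):", nmem, "\n")
})

#' SampledDataset: a balanced N-by-M labelled set
#'
#' Result of the smallest-first non-overlapping sampling strategy: exactly
#' \code{nClasses} ontology classes, each assigned exactly
#' \code{membersPerClass} distinct leaf members (with their SMILES), no member
#' shared between classes.
#'
#' @slot assignments named list; one element per selected class, each a
#'   data.frame with columns \code{member_id}, \code{smiles}.
#' @slot nClasses integer, the problem's N.
#' @slot membersPerClass integer, the problem's M.
#' @slot seed integer seed the selection was drawn with.
#' @seealso [selectBalanced()], [splitDataset()]
#' @export
setClass("SampledDataset",
  representation(assignments = "list", nClasses = "integer",
                 membersPerClass = "integer", seed = "integer"))

setValidity("SampledDataset", function(object) {
  msgs <- character()
  if (length(object@assignments) != object@nClasses)
    msgs <- c(msgs, "number of classes differs from nClasses")
  sizes <- vapply(object@assignments, nrow, integer(1))
  if (length(sizes) && any(sizes != object@membersPerClass))
    msgs <- c(msgs, "a class does not hold exactly membersPerClass members")
  ids <- unlist(lapply(object@assignments, `[[`, "member_id"),
                use.names = FALSE)
  if (anyDuplicated(ids))
    msgs <- c(msgs, "a member is assigned to more than one class")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SampledDataset", function(object) {
  cat(sprintf("SampledDataset: %d x %d (N classes x M members), seed %d\n",
              object@nClasses, object@membersPerClass, object@seed))
  cat("  classes:", paste(utils::head(names(object@assignments), 5),
                          collapse = ", "),
      if (length(object@assignments) > 5) "...\n" else "\n")
})

#' TokenVocabulary: token to integer index map
#'
#' Maps each distinct SMILES token to an integer index used by the embedding
#' layer of the sequence network.  Indices 0 (padding) and 1 (unknown token)
#' are reserved; real tokens are numbered contiguously from 2 in first
#' occurrence order.
#'
#' @slot index named integer vector, token -> index (indices >= 2).
#' @seealso [buildVocabulary()], [encodeSequences()]
#' @export
setClass("TokenVocabulary", representation(index = "integer"))

setValidity("TokenVocabulary", function(object) {
  idx <- object@index
  msgs <- character()
  if (length(idx)) {
    if (is.null(names(idx)) || any(!nzchar(names(idx))))
      msgs <- c(msgs, "all indices must be named by their token")
    if (anyDuplicated(names(idx)))
      msgs <- c(msgs, "duplicated token")
    if (!identical(sort(unname(idx)), seq.int(2L, length.out = length(idx))))
      msgs <- c(msgs, "indices must be contiguous from 2 (0/1 are reserved)")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TokenVocabulary", function(object) {
  cat("TokenVocabulary with", length(object@index),
      "tokens (+ reserved 0 = pad, 1 = unknown)\n")
})

#' ClassicalModel: a fitted classical classifier
#'
#' Uniform wrapper around the eight classical algorithms (LR, KNN, CART, RF,
#' NB, LDA and SVM with three kernels) operating on fingerprint vectors.  All
#' wrapped models are multi-class single-label: prediction emits exactly one
#' class per molecule and never abstains.
#'
#' @slot spec list as returned by [classifierSpec()].
#' @slot classLabels character, the ordered training label set.
#' @slot fit fitted backend object (opaque; for LR a list of one-vs-rest fits).
#' @slot keepColumns integer columns of the fingerprint matrix retained at
#'   training time (LDA drops zero-variance columns).
#' @slot trainX matrix or NULL; retained for the lazy-learning KNN backend.
#' @slot trainY character or NULL.
#' @seealso [trainClassical()]
#' @export
setClass("ClassicalModel",
  representation(spec = "list", classLabels = "character", fit = "ANY",
                 keepColumns = "integer", nFeatures = "integer",
                 trainX = "ANY", trainY = "ANY"))

setMethod("show", "ClassicalModel", function(object) {
  cat("ClassicalModel:", object@spec$algorithm,
      if (!is.null(object@spec$kernel)) paste0("(", object@spec$kernel,
                                               " kernel)") else "",
      "-", length(object@classLabels), "classes\n")
})

#' LstmClassifier: a trained multi-label sequence network
#'
#' Token embedding -> unidirectional LSTM -> dense (ReLU) -> dropout ->
#' per-class sigmoid, trained with binary cross-entropy.  Scores are
#' per-class membership values in [0, 1]; thresholding may yield zero, one or
#' several predicted classes per molecule (the empty set is an abstention).
#'
#' @slot weights named list of weight matrices/vectors.
#' @slot config list as returned by [networkConfig()].
#' @slot classLabels character, ordered class label set.
#' @slot vocabulary [TokenVocabulary-class] used for encoding.
#' @slot padTo integer, common padded sequence length.
#' @slot history data.frame with per-epoch loss/precision/recall on the
#'   training and validation sets.
#' @seealso [trainLstm()], [predictScores()], [predictClasses()]
#' @export
setClass("LstmClassifier",
  representation(weights = "list", config = "list",
                 classLabels = "character", vocabulary = "TokenVocabulary",
                 padTo = "integer", history = "data.frame"))

setMethod("show", "LstmClassifier", function(object) {
  cfg <- object@config
  cat(sprintf(
    "LstmClassifier: %d classes, embed %d -> LSTM %d -> dense %d -> dropout %.2f -> sigmoid\n",
    length(object@classLabels), cfg$embeddingDim, cfg$lstmUnits,
    cfg$denseUnits, cfg$dropoutRate))
  cat("  trained", nrow(object@history), "epochs, padded length",
      object@padTo, "\n")
})
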