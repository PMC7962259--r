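# Synthetic toy ontologies with motif-bearing SMILES leaves.  Class identity
# is encoded by injecting one distinctive SMILES fragment per class into
# otherwise random decoration, so every pipeline stage (parsing, sampling,
# encoding, learning, evaluation) is testable offline with a learnable
# signal.  Decorations come from a small grammar of acyclic C/O/N chains,
# optional branches and one optional ring, so syntactic validity is
# guaranteed by construction rather than by rejection sampling.

# terminal fragments that stay valid when prefixed to a carbon chain
.defaultMotifPool <- c("Cl", "Br", "I", "F", "S", "P", "N#C", "O=C",
                       "C#C", "[Se]", "B", "Cl/C=C/", "FC(F)(F)",
                       "O=S(=O)", "ON=C", "SC(=S)")

#' Default class motifs
#'
#' A pool of distinctive SMILES fragments (halogens, hetero groups,
#' triple-bond groups) used to mark class identity in toy ontologies.  None
#' of them can occur in the random C/O/N decoration, so each class's leaves
#' are recognisable by fragment containment.
#'
#' @param n Number of motifs required (max 16).
#' @return Character vector of n SMILES fragments.
#' @export
defaultMotifs <- function(n) {
  if (n > length(.defaultMotifPool))
    stop("only ", length(.defaultMotifPool),
         " distinct default motifs are available", call. = FALSE)
  .defaultMotifPool[seq_len(n)]
}

#' Fixture specification for a toy ontology
#'
#' @param nClasses Number of mid-level classes.
#' @param membersPerClass Leaf members generated under each class.
#' @param hierarchyDepth Levels from root to leaves (>= 3: root, classes,
#'   leaves; deeper values insert chain terms between root and classes).
#' @param overlapFraction Fraction of leaves in [0, 1) additionally attached
#'   under a second class, emulating the diamond-shaped overlap of real
#'   chemical ontologies.
#' @param motifs One distinctive SMILES fragment per class; defaults to
#'   [defaultMotifs()].
#' @param seed Integer seed.
#' @return Validated spec list.
#' @export
fixtureSpec <- function(nClasses, membersPerClass, hierarchyDepth = 3L,
                        overlapFraction = 0, motifs = defaultMotifs(nClasses),
                        seed = 1L) {
  stopifnot(nClasses >= 1, membersPerClass >= 1, hierarchyDepth >= 3)
  if (overlapFraction < 0 || overlapFraction >= 1)
    stop("overlapFraction must lie in [0, 1)", call. = FALSE)
  if (length(motifs) != nClasses)
    stop("need exactly one motif per class", call. = FALSE)
  if (!all(validSmiles(paste0(motifs, "CC"))))
    stop("motif not embeddable into valid SMILES", call. = FALSE)
  list(nClasses = as.integer(nClasses),
       membersPerClass = as.integer(membersPerClass),
       hierarchyDepth = as.integer(hierarchyDepth),
       overlapFraction = overlapFraction,
       motifs = as.character(motifs), seed = as.integer(seed))
}

# random decoration: acyclic C/O/N chain, optional branch, optional ring;
# always starts with C so any terminal motif prefix stays valid
.randomDecoration <- function(minLen = 3L, maxLen = 10L) {
  len <- sample(seq.int(minLen, maxLen), 1L)
  atoms <- c("C", sample(c("C", "C", "C", "O", "N"), len - 1L,
                         replace = TRUE))
  s <- paste(atoms, collapse = "")
  if (stats::runif(1) < 0.3)  # branch after the first atom
    s <- paste0(substr(s, 1, 1), "(C)", substr(s, 2, nchar(s)))
  if (stats::runif(1) < 0.25)  # one optional ring
    s <- paste0(s, "C1CCCC1")
  s
}

#' Generate random syntactically valid SMILES
#'
#' Draws strings from the decoration grammar (acyclic C/O/N chains, optional
#' branch and ring, occasionally a two-letter halogen prefix), guaranteeing
#' syntactic validity by construction.  Deterministic per seed.
#'
#' @param n Number of strings.
#' @param seed Integer seed.
#' @param lengthRange Two integers: approximate min/max chain length.
#' @return Character vector of n SMILES strings.
#' @export
randomValidSmiles <- function(n, seed = 1L, lengthRange = c(3L, 10L)) {
  withr::with_seed(as.integer(seed), {
    vapply(seq_len(n), function(i) {
      s <- .randomDecoration(lengthRange[1], lengthRange[2])
      if (stats::runif(1) < 0.3)
        s <- paste0(sample(c("Cl", "Br", "F", "I"), 1L), s)
      s
    }, character(1))
  })
}

#' Generate a toy ontology with motif-bearing leaves
#'
#' Builds a single-rooted DAG: root, \code{hierarchyDepth - 3} chain terms,
#' one mid-level class per motif, and \code{membersPerClass} leaf members
#' under each class whose SMILES embed the class motif inside random valid
#' decoration.  A fraction of leaves is additionally attached under a second
#' class, so the non-overlap constraint of balanced sampling becomes
#' binding, as in real chemical ontologies.  Optionally serialised to OBO
#' (round-trippable by [loadOntology()]) with a TSV leaf manifest.
#'
#' @param spec A [fixtureSpec()].
#' @param oboPath Optional path; when given the ontology is written there
#'   and a leaf manifest (\code{member_id}, \code{smiles},
#'   \code{parent_ids}) next to it as \code{<path>.manifest.tsv}.
#' @return An [OntologyGraph-class] with root \code{"TOY:0000001"}.
#' @export
makeToyOntology <- function(spec, oboPath = NULL) {
  n <- spec$nClasses
  m <- spec$membersPerClass
  rootId <- "TOY:0000001"
  chainN <- spec$hierarchyDepth - 3L
  chainIds <- if (chainN > 0)
    sprintf("TOY:%07d", 1L + seq_len(chainN)) else character()
  classIds <- sprintf("TOY:C%06d", seq_len(n))
  leafIds <- sprintf("TOY:L%06d", seq_len(n * m))

  withr::with_seed(spec$seed, {
    smiles <- character(n * m)
    edges <- list()
    above <- if (chainN > 0) chainIds[chainN] else rootId
    prev <- rootId
    for (ch in chainIds) {
      edges[[length(edges) + 1L]] <- data.frame(child = ch, parent = prev)
      prev <- ch
    }
    for (k in seq_len(n)) {
      edges[[length(edges) + 1L]] <-
        data.frame(child = classIds[k], parent = above)
      for (j in seq_len(m)) {
        idx <- (k - 1L) * m + j
        smiles[idx] <- paste0(spec$motifs[k], .randomDecoration())
        edges[[length(edges) + 1L]] <-
          data.frame(child = leafIds[idx], parent = classIds[k])
        if (n > 1L && stats::runif(1) < spec$overlapFraction) {
          other <- sample(setdiff(seq_len(n), k), 1L)
          edges[[length(edges) + 1L]] <-
            data.frame(child = leafIds[idx], parent = classIds[other])
        }
      }
    }
  })

  nodes <- data.frame(
    id = c(rootId, chainIds, classIds, leafIds),
    name = c("toy root",
             if (chainN > 0) paste("chain level", seq_len(chainN)),
             paste("toy class", seq_len(n)),
             paste("toy leaf", seq_len(n * m))),
    smiles = c(rep(NA_character_, 1L + chainN + n), smiles),
    stringsAsFactors = FALSE)
  graph <- OntologyGraph(nodes, do.call(rbind, edges), root = rootId)

  if (!is.null(oboPath)) {
    writeOntology(graph, oboPath)
    parentOf <- split(graph@edges$parent, graph@edges$child)
    manifest <- data.frame(
      member_id = leafIds,
      smiles = smiles,
      parent_ids = vapply(leafIds, function(id)
        paste(sort(parentOf[[id]]), collapse = ";"), character(1)))
    utils::write.table(manifest, paste0(oboPath, ".manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  graph
}
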