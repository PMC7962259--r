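# Graph queries on the subsumption DAG: leaf members, ancestors/descendants,
# antichain condensation and the undirected shortest-path metric used by the
# ontology-aware evaluation.

# Kahn topological order over child->parent edges; NULL when cyclic.
.topologicalOrder <- function(ids, edges) {
  n <- length(ids)
  if (n == 0L) return(character())
  idx <- seq_len(n)
  names(idx) <- ids
  from <- idx[edges$child]
  to <- idx[edges$parent]
  outAdj <- split(to, factor(from, levels = idx))   # child -> parents
  indeg <- tabulate(to, nbins = n)
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    order <- c(order, v)
    for (w in outAdj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order) < n) return(NULL)
  ids[order]
}

.checkIds <- function(graph, ids) {
  missing <- setdiff(ids, graph@nodes$id)
  if (length(missing))
    stop("unknown term identifier(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

# adjacency list keyed by id; direction "up" = child->parents,
# "down" = parent->children, "both" = undirected neighbours
.adjacency <- function(graph, direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  ids <- graph@nodes$id
  ed <- graph@edges
  adj <- switch(direction,
    up = split(ed$parent, factor(ed$child, levels = ids)),
    down = split(ed$child, factor(ed$parent, levels = ids)),
    both = split(c(ed$parent, ed$child),
                 factor(c(ed$child, ed$parent), levels = ids)))
  adj
}

.reachable <- function(graph, id, direction) {
  adj <- .adjacency(graph, direction)
  seen <- character()
  frontier <- adj[[id]]
  while (length(frontier)) {
    frontier <- setdiff(unique(frontier), seen)
    if (!length(frontier)) break
    seen <- c(seen, frontier)
    frontier <- unlist(adj[frontier], use.names = FALSE)
  }
  seen
}

#' Leaf members of an ontology
#'
#' A *leaf member* is a term with no \code{is_a} children and an associated
#' SMILES structure annotation; these are the classification instances.
#' Terms failing either condition act as classes.
#'
#' @param graph An [OntologyGraph-class].
#' @return Character vector of term identifiers.
#' @examples
#' g <- OntologyGraph(
#'   nodes = data.frame(id = c("T:1", "T:2"), name = c("a", "b"),
#'                      smiles = c(NA, "CCO")),
#'   edges = data.frame(child = "T:2", parent = "T:1"))
#' leafMembers(g)  # "T:2"
#' @export
leafMembers <- function(graph) {
  stopifnot(is(graph, "OntologyGraph"))
  hasChild <- graph@nodes$id %in% graph@edges$parent
  hasSmiles <- !is.na(graph@nodes$smiles)
  graph@nodes$id[!hasChild & hasSmiles]
}

#' Ancestors of a term
#'
#' All terms reachable from \code{id} by repeatedly following child-to-parent
#' \code{is_a} edges; the term itself is excluded.
#'
#' @param graph An [OntologyGraph-class].
#' @param id Term identifier present in the graph.
#' @return Character vector of ancestor identifiers (possibly empty).
#' @export
termAncestors <- function(graph, id) {
  stopifnot(is(graph, "OntologyGraph"), length(id) == 1L)
  .checkIds(graph, id)
  .reachable(graph, id, "up")
}

#' Descendants of a term
#'
#' All terms whose ancestor set contains \code{id}; the term itself is
#' excluded.
#'
#' @inheritParams termAncestors
#' @return Character vector of descendant identifiers.
#' @export
termDescendants <- function(graph, id) {
  stopifnot(is(graph, "OntologyGraph"), length(id) == 1L)
  .checkIds(graph, id)
  .reachable(graph, id, "down")
}

#' Condense a class set to an antichain
#'
#' Removes every class that is a (strict) ancestor of another class in the
#' set, so that no retained class subsumes another.  Used to strip redundant
#' high-level predictions (e.g. 'molecular entity') before counting parents
#' or measuring path lengths.  Idempotent.
#'
#' @param graph An [OntologyGraph-class].
#' @param classes Character vector of term identifiers.
#' @return Character vector: the subsumption-free subset, in input order.
#' @export
condenseClasses <- function(graph, classes) {
  stopifnot(is(graph, "OntologyGraph"))
  classes <- unique(as.character(classes))
  .checkIds(graph, classes)
  if (length(classes) <= 1L) return(classes)
  drop <- vapply(classes, function(cl) {
    any(vapply(setdiff(classes, cl),
               function(other) cl %in% termAncestors(graph, other),
               logical(1)))
  }, logical(1))
  classes[!drop]
}

# undirected BFS distances from `from` to every node; NA when unreachable
.bfsDistances <- function(graph, from) {
  adj <- .adjacency(graph, "both")
  dist <- rep(NA_integer_, nrow(graph@nodes))
  names(dist) <- graph@nodes$id
  dist[from] <- 0L
  frontier <- from
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Path length between a predicted and an asserted class
#'
#' Number of subsumption (\code{is_a}) edges that must be traversed to get
#' from the predicted parent to the asserted parent: 0 when they coincide, 1
#' when one is the direct parent of the other, and so on.  The subsumption
#' graph is treated as undirected, so predictions in sibling branches still
#' receive a finite distance; \code{NA} marks disconnected pairs.
#'
#' @param graph An [OntologyGraph-class].
#' @param predicted,asserted Term identifiers present in the graph.
#' @return Non-negative integer, or \code{NA} when no path exists.
#' @examples
#' g <- OntologyGraph(
#'   nodes = data.frame(id = c("A", "B", "C"), name = c("A", "B", "C"),
#'                      smiles = NA),
#'   edges = data.frame(child = c("B", "C"), parent = c("A", "B")))
#' pathLength(g, "A", "C")  # 2
#' @export
pathLength <- function(graph, predicted, asserted) {
  stopifnot(is(graph, "OntologyGraph"),
            length(predicted) == 1L, length(asserted) == 1L)
  .checkIds(graph, c(predicted, asserted))
  if (predicted == asserted) return(0L)
  unname(.bfsDistances(graph, predicted)[asserted])
}
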