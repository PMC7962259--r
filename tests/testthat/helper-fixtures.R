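# Shared fixture builders: hand-written OBO snippets, small graphs, and a
# random-DAG generator with an igraph-based shortest-path oracle.

oboLines <- function(...) {
  path <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", ...), path)
  path
}

termStanza <- function(id, name = id, parents = character(),
                       smiles = NULL, obsolete = FALSE, extra = character()) {
  c("[Term]",
    paste0("id: ", id),
    paste0("name: ", name),
    paste0("is_a: ", parents),
    if (!is.null(smiles))
      paste0("property_value: http://purl.obolibrary.org/obo/chebi/smiles \"",
             smiles, "\" xsd:string"),
    if (obsolete) "is_obsolete: true",
    extra,
    "")
}

# chain A <- B <- C with a SMILES only on C
chainGraph <- function() {
  OntologyGraph(
    nodes = data.frame(id = c("A", "B", "C"), name = c("A", "B", "C"),
                       smiles = c(NA, NA, "CCO")),
    edges = data.frame(child = c("B", "C"), parent = c("A", "B")))
}

# diamond: A <- B, A <- C, B <- D, C <- D
diamondGraph <- function() {
  OntologyGraph(
    nodes = data.frame(id = c("A", "B", "C", "D"),
                       name = c("A", "B", "C", "D"), smiles = NA),
    edges = data.frame(child = c("B", "C", "D", "D"),
                       parent = c("A", "A", "B", "C")))
}

# random DAG: nodes 1..n, each non-root node gets 1-2 parents among
# earlier nodes, so acyclicity holds by construction
randomDag <- function(n, seed) {
  withr::with_seed(seed, {
    ids <- sprintf("N%03d", seq_len(n))
    edges <- do.call(rbind, lapply(2:n, function(i) {
      k <- sample(1:2, 1)
      parents <- sample(i - 1L, min(k, i - 1L))
      data.frame(child = ids[i], parent = ids[parents])
    }))
    OntologyGraph(data.frame(id = ids, name = ids, smiles = NA), edges)
  })
}

# independent shortest-path oracle on the undirected is_a graph
igraphPathOracle <- function(graph, from, to) {
  ig <- igraph::graph_from_data_frame(
    graph@edges, directed = FALSE,
    vertices = data.frame(name = graph@nodes$id))
  d <- igraph::distances(ig, v = from, to = to)[1, 1]
  if (is.infinite(d)) NA_integer_ else as.integer(d)
}

# greedy balanced sampler that processes classes LARGEST first; used as the
# contrast showing why the smallest-first ordering matters; returns the
# class ids it managed to fill
largestFirstSelect <- function(graph, nClasses, membersPerClass, seed) {
  closures <- chemont:::.leafClosures(graph)
  sizes <- lengths(closures)
  candidates <- names(closures)[sizes >= 2L]
  candidates <- candidates[order(-sizes[candidates], candidates)]
  used <- character()
  filled <- character()
  withr::with_seed(seed, {
    for (cl in candidates) {
      if (length(filled) == nClasses) break
      avail <- setdiff(closures[[cl]], used)
      if (length(avail) < membersPerClass) next
      used <- c(used, sample(avail, membersPerClass))
      filled <- c(filled, cl)
    }
  })
  filled
}

# brute-force confusion counter used as the independent oracle for the
# precision/recall/F1 formulas
bruteCounts <- function(pred, truth, cl) {
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == cl && pred[i] == cl) tp <- tp + 1
    if (truth[i] != cl && pred[i] == cl) fp <- fp + 1
    if (truth[i] == cl && pred[i] != cl) fn <- fn + 1
  }
  c(tp = tp, fp = fp, fn = fn)
}

# nested-class ontology: the smallest class's leaves are a subset of the
# largest's, with just enough spare leaves that a disjoint 2 x M selection
# exists only if the small class is served first
nestedClassOntology <- function(m = 5L) {
  small <- sprintf("S%02d", seq_len(m))
  extra <- sprintf("E%02d", seq_len(m))
  nodes <- data.frame(
    id = c("ROOT", "BIG", "SMALL", small, extra),
    name = c("root", "big", "small", small, extra),
    smiles = c(NA, NA, NA, rep("CCO", 2L * m)))
  edges <- rbind(
    data.frame(child = c("BIG", "SMALL"), parent = c("ROOT", "ROOT")),
    data.frame(child = small, parent = "SMALL"),
    data.frame(child = c(small, extra), parent = "BIG"))
  OntologyGraph(nodes, edges, root = "ROOT")
}
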