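# OBO 1.2/1.4 flat-file reading and writing, restricted to the subset a
# subsumption analysis needs: [Term] stanzas with id, name, is_a,
# is_obsolete and a SMILES structure annotation carried as a property_value
# (ChEBI style: property_value: http://.../chebi/smiles "CCO" xsd:string).

.parseOboStanzas <- function(lines) {
  starts <- grep("^\\[", lines)
  termStarts <- starts[lines[starts] == "[Term]"]
  ends <- c(starts[-1L] - 1L, length(lines))
  endFor <- ends[match(termStarts, starts)]
  Map(function(s, e) lines[seq.int(s + 1L, length.out = max(0L, e - s))],
      termStarts, endFor)
}

.tagValues <- function(stanza, tag) {
  hits <- grep(paste0("^", tag, ":"), stanza, value = TRUE)
  sub("\\s*!.*$", "", sub(paste0("^", tag, ":\\s*"), "", hits))
}

.smilesFromStanza <- function(stanza, stanzaId) {
  pv <- .tagValues(stanza, "property_value")
  hits <- pv[grepl("smiles", pv, ignore.case = TRUE)]
  if (!length(hits)) return(NA_character_)
  vals <- regmatches(hits, regexpr('"[^"]*"', hits))
  vals <- gsub('"', "", vals)
  vals <- vals[nzchar(vals)]
  if (!length(vals)) return(NA_character_)
  if (length(vals) > 1L)
    warning("term ", stanzaId, " carries ", length(vals),
            " SMILES values; using the first", call. = FALSE)
  vals[[1L]]
}

#' Load an OBO ontology as a subsumption graph
#'
#' Parses an OBO 1.2/1.4 flat file into an [OntologyGraph-class].  Only
#' hierarchical \code{is_a} relationships are retained (\code{relationship:}
#' tags such as \code{has_part} are dropped); obsolete terms are removed; a
#' SMILES structure annotation is read from the term's
#' \code{property_value} when present.  When \code{root} is given the graph
#' is restricted to that term and its descendants (the ChEBI use case
#' restricts to the 'molecular entity' branch); leaf status is determined
#' after this restriction.
#'
#' @param path Path to an OBO file.
#' @param root Optional term identifier to restrict the graph to.
#' @return An [OntologyGraph-class].
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("format-version: 1.2", "", "[Term]", "id: T:1", "name: acid",
#'   "", "[Term]", "id: T:2", "name: formic acid", "is_a: T:1",
#'   "property_value: http://example.org/smiles \"OC=O\" xsd:string"), obo)
#' g <- loadOntology(obo)
#' leafMembers(g)
#' @export
loadOntology <- function(path, root = NULL) {
  if (!file.exists(path))
    stop("OBO file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE), which = "right")
  stanzas <- .parseOboStanzas(lines)
  if (!length(stanzas))
    stop("malformed OBO file (no [Term] stanza found): ", path,
         call. = FALSE)

  recs <- lapply(seq_along(stanzas), function(i) {
    st <- stanzas[[i]]
    id <- .tagValues(st, "id")
    if (length(id) != 1L || !nzchar(id))
      stop("malformed OBO [Term] stanza #", i,
           ": expected exactly one id tag", call. = FALSE)
    obsolete <- any(.tagValues(st, "is_obsolete") == "true")
    name <- .tagValues(st, "name")
    list(id = id,
         name = if (length(name)) name[[1L]] else id,
         smiles = .smilesFromStanza(st, id),
         parents = .tagValues(st, "is_a"),
         obsolete = obsolete)
  })
  recs <- Filter(function(r) !r$obsolete, recs)
  ids <- vapply(recs, `[[`, character(1), "id")
  nodes <- data.frame(
    id = ids,
    name = vapply(recs, `[[`, character(1), "name"),
    smiles = vapply(recs, `[[`, character(1), "smiles"),
    stringsAsFactors = FALSE)
  edges <- do.call(rbind, lapply(recs, function(r) {
    parents <- intersect(r$parents, ids)  # ignore links to obsolete/missing
    if (!length(parents)) return(NULL)
    data.frame(child = r$id, parent = parents, stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(child = character(), parent = character(),
                        stringsAsFactors = FALSE)

  if (!is.null(root)) {
    if (!(root %in% ids))
      stop("root term not present in ontology: ", root, call. = FALSE)
    g0 <- OntologyGraph(nodes, edges)
    keep <- c(root, termDescendants(g0, root))
    nodes <- nodes[nodes$id %in% keep, , drop = FALSE]
    edges <- edges[edges$child %in% keep & edges$parent %in% keep,
                   , drop = FALSE]
    rownames(nodes) <- rownames(edges) <- NULL
    return(OntologyGraph(nodes, edges, root = root))
  }
  OntologyGraph(nodes, edges)
}

#' Write an ontology back to OBO format
#'
#' Serialises the graph as OBO \code{[Term]} stanzas (id, name, \code{is_a},
#' SMILES as a \code{property_value}), round-trippable by [loadOntology()].
#'
#' @param graph An [OntologyGraph-class].
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeOntology <- function(graph, path) {
  stopifnot(is(graph, "OntologyGraph"))
  nd <- graph@nodes[order(graph@nodes$id), , drop = FALSE]
  parentOf <- split(graph@edges$parent, graph@edges$child)
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(nd))) {
    st <- c("[Term]",
            paste0("id: ", nd$id[i]),
            paste0("name: ", nd$name[i]))
    for (p in sort(parentOf[[nd$id[i]]]))
      st <- c(st, paste0("is_a: ", p))
    if (!is.na(nd$smiles[i]))
      st <- c(st, paste0("property_value: http://purl.obolibrary.org/obo/",
                         "chebi/smiles \"", nd$smiles[i], "\" xsd:string"))
    out <- c(out, st, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Export the subsumption edges as a TSV edge list
#'
#' @param graph An [OntologyGraph-class].
#' @param path Output file path; columns \code{child_id}, \code{parent_id}.
#' @return Invisibly, \code{path}.
#' @export
exportEdgeList <- function(graph, path) {
  stopifnot(is(graph, "OntologyGraph"))
  ed <- graph@edges[order(graph@edges$child, graph@edges$parent), ,
                    drop = FALSE]
  utils::write.table(
    data.frame(child_id = ed$child, parent_id = ed$parent),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
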