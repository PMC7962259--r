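# Balanced N x M dataset construction.  Candidate classes are processed from
# the smallest leaf-membership to the largest so that small, specific classes
# are not starved of members by large general ones, and every leaf member is
# used for at most one class.

# descendant leaf-member closure for every term, as a named list of
# character vectors; computed in one bottom-up pass over topological order
.leafClosures <- function(graph) {
  ids <- graph@nodes$id
  members <- leafMembers(graph)
  downAdj <- .adjacency(graph, "down")
  ord <- .topologicalOrder(ids, graph@edges)  # children before parents
  closures <- vector("list", length(ids))
  names(closures) <- ids
  for (id in ord) {
    kids <- downAdj[[id]]
    if (!length(kids)) {
      closures[[id]] <- if (id %in% members) id else character()
    } else {
      closures[[id]] <- unique(unlist(closures[kids], use.names = FALSE))
    }
  }
  closures
}

#' Select a balanced N-by-M dataset from an ontology
#'
#' Implements the smallest-first, non-overlapping sampling strategy.
#' Candidate classes are terms with at least two leaf members in their
#' descendant closure (restricted to the designated root branch when the
#' graph carries one), sorted by ascending leaf-member count with ties broken
#' by term identifier.  Iterating in that order, a class is filled with
#' \code{membersPerClass} members drawn uniformly at random without
#' replacement from its still-unused leaf members when enough remain, and
#' skipped otherwise; selection stops after \code{nClasses} classes.  No leaf
#' member is assigned to more than one class, which keeps train/test splits
#' cleanly separable despite the heavily overlapping ("diamond-shaped")
#' class structure of real chemical ontologies.
#'
#' @param graph An [OntologyGraph-class].
#' @param nClasses Number of classes N to select.
#' @param membersPerClass Number of members M per class.
#' @param seed Integer seed; the same (graph, N, M, seed) always reproduces
#'   the same dataset.
#' @return A [SampledDataset-class].
#' @export
selectBalanced <- function(graph, nClasses, membersPerClass, seed = 1L) {
  stopifnot(is(graph, "OntologyGraph"),
            nClasses >= 1L, membersPerClass >= 1L)
  nClasses <- as.integer(nClasses)
  membersPerClass <- as.integer(membersPerClass)
  seed <- as.integer(seed)

  closures <- .leafClosures(graph)
  sizes <- lengths(closures)
  candidates <- names(closures)[sizes >= 2L]
  candidates <- candidates[order(sizes[candidates], candidates)]

  smilesOf <- stats::setNames(graph@nodes$smiles, graph@nodes$id)
  assignments <- list()
  used <- character()
  withr::with_seed(seed, {
    for (cl in candidates) {
      if (length(assignments) == nClasses) break
      avail <- setdiff(closures[[cl]], used)
      if (length(avail) < membersPerClass) next
      picked <- sample(avail, membersPerClass)
      used <- c(used, picked)
      assignments[[cl]] <- data.frame(
        member_id = picked,
        smiles = unname(smilesOf[picked]),
        stringsAsFactors = FALSE)
    }
  })
  if (length(assignments) < nClasses)
    stop(sprintf(paste0("infeasible dataset: requested %d classes x %d ",
                        "members but only %d class(es) could be filled ",
                        "disjointly"),
                 nClasses, membersPerClass, length(assignments)),
         call. = FALSE)
  new("SampledDataset", assignments = assignments, nClasses = nClasses,
      membersPerClass = membersPerClass, seed = seed)
}

#' Flatten a SampledDataset to a table
#'
#' @param dataset A [SampledDataset-class].
#' @return data.frame with columns \code{member_id}, \code{smiles},
#'   \code{class_id}, one row per member.
#' @export
datasetTable <- function(dataset) {
  stopifnot(is(dataset, "SampledDataset"))
  out <- do.call(rbind, lapply(names(dataset@assignments), function(cl) {
    df <- dataset@assignments[[cl]]
    df$class_id <- cl
    df
  }))
  rownames(out) <- NULL
  out
}

#' Stratified train/validation/test split
#'
#' Randomly partitions a balanced dataset, stratified by class so that every
#' class contributes (up to integer rounding by largest remainder, hence
#' within 1 of exact proportionality) the same share to each partition.  The
#' validation fraction may be zero: classical classifiers use a two-way
#' train/test split, the network a three-way split.
#'
#' @param dataset A [SampledDataset-class] or a data.frame as produced by
#'   [datasetTable()].
#' @param fractions Numeric triple (train, validation, test); must sum to 1.
#' @param seed Integer seed; identical seeds give identical partitions.
#' @return data.frame with columns \code{member_id}, \code{smiles},
#'   \code{class_id}, \code{split} (\code{"train"}, \code{"validation"} or
#'   \code{"test"}); the fractions are attached as attribute
#'   \code{"fractions"}.
#' @export
splitDataset <- function(dataset, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  tab <- if (is(dataset, "SampledDataset")) datasetTable(dataset) else dataset
  stopifnot(is.data.frame(tab), all(c("member_id", "class_id") %in% names(tab)))
  if (length(fractions) != 3L || any(fractions < 0))
    stop("fractions must be a non-negative triple", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1", call. = FALSE)
  if (fractions[1] <= 0 || fractions[3] <= 0)
    stop("train and test fractions must be positive", call. = FALSE)

  splitNames <- c("train", "validation", "test")
  tab$split <- NA_character_
  withr::with_seed(as.integer(seed), {
    for (cl in unique(tab$class_id)) {
      rows <- which(tab$class_id == cl)
      m <- length(rows)
      exact <- fractions * m
      counts <- floor(exact)
      short <- m - sum(counts)
      if (short > 0) {
        give <- order(exact - counts, decreasing = TRUE)[seq_len(short)]
        counts[give] <- counts[give] + 1
      }
      shuffled <- sample(rows)
      tab$split[shuffled] <- rep(splitNames, times = counts)
    }
  })
  attr(tab, "fractions") <- stats::setNames(fractions, splitNames)
  tab
}

#' Write a split dataset as TSV
#'
#' Columns \code{member_id}, \code{smiles}, \code{class_id}, \code{split}.
#'
#' @param split data.frame from [splitDataset()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeDatasetTsv <- function(split, path) {
  utils::write.table(split, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a split dataset TSV
#'
#' @param path Path written by [writeDatasetTsv()].
#' @return data.frame with the dataset columns.
#' @export
readDatasetTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = "character", quote = "")
}
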