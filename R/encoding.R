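# SMILES encodings: 1024-bit hashed topological path fingerprints (OpenBabel
# FP2 via ChemmineOB, a hash of linear paths of length 1-7 through the
# molecular graph) for the fixed-length classifiers, and character-level /
# atom-grouped token sequences for the recurrent network.

# Two-letter element symbols of the periodic table; greedy case-sensitive
# matching (uppercase + lowercase letter) turns these into single tokens.
.twoLetterElements <- c(
  "He", "Li", "Be", "Ne", "Na", "Mg", "Al", "Si", "Cl", "Ar", "Ca", "Sc",
  "Ti", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se",
  "Br", "Kr", "Rb", "Sr", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag",
  "Cd", "In", "Sn", "Sb", "Te", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf",
  "Ta", "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At",
  "Rn", "Fr", "Ra", "Ac", "Th", "Pa", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og")

# symbols like "Sc" or "Os" that could equally read as a one-letter atom
# followed by an aromatic atom; grouped greedily as the two-letter element,
# with a warning, because bare scandium-vs-sulfur+aromatic-carbon cases are
# vanishingly rare in practice
.ambiguousTwoLetter <- local({
  singles <- c("B", "C", "N", "O", "P", "S", "F", "I", "H")
  aromatic <- c("b", "c", "n", "o", "s", "p")
  sym <- .twoLetterElements
  sym[substr(sym, 1, 1) %in% singles & substr(sym, 2, 2) %in% aromatic]
})

#' Fingerprint configuration
#'
#' The fingerprint is a fixed-length bit string hashing all linear
#' topological paths (walks) of length 1 to \code{maxWalk} through the
#' molecular graph, covering atom types, bond types and branches.  The
#' backend (OpenBabel FP2) hashes paths up to length 7 into 1024 bits; other
#' lengths are obtained by XOR-folding the 1024-bit string, the standard
#' fingerprint densification operation.
#'
#' @param length Bit count; must divide 1024 (default 1024).
#' @param maxWalk Maximum path length hashed (default and backend maximum 7).
#' @return list with elements \code{length}, \code{maxWalk}.
#' @export
fingerprintConfig <- function(length = 1024L, maxWalk = 7L) {
  length <- as.integer(length)
  maxWalk <- as.integer(maxWalk)
  if (length <= 0L || 1024L %% length != 0L)
    stop("fingerprint length must be a positive divisor of 1024",
         call. = FALSE)
  if (maxWalk != 7L)
    stop("the path-fingerprint backend hashes walks of length 1-7; ",
         "maxWalk must be 7", call. = FALSE)
  list(length = length, maxWalk = maxWalk)
}

#' Syntactic SMILES validation
#'
#' Checks that a string is well-formed SMILES: non-empty, only legal
#' characters, balanced parentheses and brackets, every ring-bond digit
#' opened and closed, and no dangling bond symbol.  This is a syntax check,
#' not a valence model; it is applied before fingerprinting because the
#' OpenBabel reader silently repairs strings such as \code{"C("}.
#'
#' @param smiles Character vector.
#' @return Logical vector, \code{TRUE} for well-formed strings.
#' @export
validSmiles <- function(smiles) {
  vapply(as.character(smiles), .validSmilesOne, logical(1), USE.NAMES = FALSE)
}

.validSmilesOne <- function(s) {
  if (is.na(s) || !nzchar(s)) return(FALSE)
  chars <- strsplit(s, "")[[1]]
  legalSet <- c(LETTERS, letters, as.character(0:9), "(", ")", "[", "]",
                "=", "#", "$", ":", "/", "\\", ".", "%", "@", "+", "-")
  if (!all(chars %in% legalSet)) return(FALSE)
  depth <- 0L; inBracket <- FALSE
  ringOpen <- integer()
  i <- 1L; n <- length(chars)
  lastWasAtomish <- FALSE
  while (i <= n) {
    ch <- chars[i]
    if (inBracket) {
      if (ch == "[") return(FALSE)
      if (ch == "]") inBracket <- FALSE
      i <- i + 1L
      next
    }
    if (ch == "[") { inBracket <- TRUE; lastWasAtomish <- TRUE }
    else if (ch == "]") return(FALSE)
    else if (ch == "(") { if (!lastWasAtomish) return(FALSE); depth <- depth + 1L }
    else if (ch == ")") { depth <- depth - 1L; if (depth < 0L) return(FALSE) }
    else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9][0-9]$",
                               paste0(chars[i + 1L], chars[i + 2L])))
        return(FALSE)
      num <- as.integer(paste0(chars[i + 1L], chars[i + 2L]))
      ringOpen <- .toggleRing(ringOpen, num)
      i <- i + 3L
      next
    }
    else if (ch %in% as.character(0:9)) {
      if (!lastWasAtomish &&
          !(chars[max(1L, i - 1L)] %in% c("=", "#", "/", "\\")))
        return(FALSE)
      ringOpen <- .toggleRing(ringOpen, as.integer(ch))
    }
    else if (grepl("^[A-Za-z]$", ch)) lastWasAtomish <- TRUE
    i <- i + 1L
  }
  if (inBracket || depth != 0L || length(ringOpen)) return(FALSE)
  # trailing bond or branch symbol dangles
  !(chars[n] %in% c("=", "#", "/", "\\", ".", "+", "-"))
}

.toggleRing <- function(open, num) {
  if (num %in% open) setdiff(open, num) else c(open, num)
}

#' Compute topological path fingerprints for SMILES
#'
#' Encodes each molecule as a fixed-length bit vector (default 1024 bits)
#' hashing its topological paths; the same SMILES and configuration always
#' produce the same bits.  Strings failing [validSmiles()] raise a condition
#' of class \code{"chemont_smiles_error"} whose \code{smiles} field carries
#' the offending strings, so callers may catch, log and skip them.
#'
#' @param smiles Character vector of SMILES.
#' @param config A [fingerprintConfig()].
#' @return 0/1 integer matrix, one row per molecule, \code{config$length}
#'   columns; rownames are the input SMILES' names when present.
#' @export
smilesFingerprint <- function(smiles, config = fingerprintConfig()) {
  smiles <- as.character(smiles)
  ok <- validSmiles(smiles)
  if (!all(ok)) {
    bad <- smiles[!ok]
    cond <- structure(
      class = c("chemont_smiles_error", "error", "condition"),
      list(message = paste0("unparseable SMILES: ",
                            paste(utils::head(bad, 5), collapse = ", "),
                            if (length(bad) > 5) " ..."),
           call = sys.call(-1), smiles = bad))
    stop(cond)
  }
  obm <- ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
                                identity)
  fp <- ChemmineOB::fingerprint_OB(obm, "FP2")
  fp <- matrix(as.integer(fp), nrow = length(smiles))
  if (config$length < 1024L) {  # XOR-fold to the requested width
    while (ncol(fp) > config$length) {
      half <- ncol(fp) / 2L
      fp <- (fp[, seq_len(half), drop = FALSE] +
             fp[, half + seq_len(half), drop = FALSE]) %% 2L
    }
  }
  rownames(fp) <- names(smiles)
  fp
}

#' Tokenise SMILES strings
#'
#' Two tokenisation modes are supported.  \code{"character"} emits one token
#' per character.  \code{"atom"} additionally groups the two-letter element
#' symbols of the periodic table (Cl, Br, Si, Na, ...) into single tokens,
#' matched greedily left to right and case-sensitively (an uppercase letter
#' followed by the matching lowercase letter), inside or outside bracket
#' atoms; everything else - bonds, branch parentheses, ring-closure digits
#' (multi-digit ring indices stay split into separate digit tokens),
#' \code{\%}, charges, stereo marks, aromatic lowercase atoms - remains a
#' single-character token.  Concatenating the tokens of either mode
#' reproduces the input exactly.
#'
#' @param smiles Character vector.
#' @param mode \code{"character"} or \code{"atom"}.
#' @return List of character vectors (one token sequence per input), with
#'   attribute \code{"mode"}.
#' @examples
#' tokenizeSmiles("ClC(=O)C1=CC=CC=C1", mode = "atom")[[1]]
#' @export
tokenizeSmiles <- function(smiles, mode = c("character", "atom")) {
  mode <- match.arg(mode)
  smiles <- as.character(smiles)
  out <- if (mode == "character") {
    strsplit(smiles, "", fixed = FALSE)
  } else {
    lapply(smiles, .tokenizeAtomsOne)
  }
  attr(out, "mode") <- mode
  out
}

.tokenizeAtomsOne <- function(s) {
  if (!nzchar(s) || is.na(s)) return(character())
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  tokens <- character(0)
  i <- 1L
  while (i <= n) {
    if (i < n) {
      pair <- paste0(chars[i], chars[i + 1L])
      if (pair %in% .twoLetterElements) {
        if (pair %in% .ambiguousTwoLetter)
          warning("ambiguous symbol '", pair,
                  "' grouped as a two-letter element", call. = FALSE)
        tokens <- c(tokens, pair)
        i <- i + 2L
        next
      }
    }
    tokens <- c(tokens, chars[i])
    i <- i + 1L
  }
  tokens
}

#' Build a token vocabulary
#'
#' Assigns each distinct token an integer index starting at 2, in first
#' occurrence order; indices 0 and 1 are reserved for padding and unknown
#' tokens respectively.
#'
#' @param sequences List of token sequences (character vectors), e.g. from
#'   [tokenizeSmiles()].
#' @return A [TokenVocabulary-class].
#' @export
buildVocabulary <- function(sequences) {
  if (!length(sequences))
    stop("cannot build a vocabulary from an empty collection",
         call. = FALSE)
  toks <- unique(unlist(sequences, use.names = FALSE))
  new("TokenVocabulary",
      index = stats::setNames(seq.int(2L, length.out = length(toks)), toks))
}

#' Number of distinct tokens in a vocabulary
#' @param vocab A [TokenVocabulary-class].
#' @return Integer count (excluding the two reserved indices).
#' @export
vocabularySize <- function(vocab) length(vocab@index)

#' Encode token sequences as padded integer matrices
#'
#' Maps tokens through the vocabulary (unseen tokens to the reserved unknown
#' index 1) and right-pads with the reserved padding index 0 to a common
#' length, as consumed by the network's embedding layer.
#'
#' @param sequences List of token sequences.
#' @param vocab A [TokenVocabulary-class].
#' @param padTo Common length; defaults to the longest sequence.  Sequences
#'   longer than \code{padTo} are an error.
#' @return Integer matrix, one row per sequence, \code{padTo} columns.
#' @export
encodeSequences <- function(sequences, vocab, padTo = NULL) {
  stopifnot(is(vocab, "TokenVocabulary"))
  lens <- lengths(sequences)
  if (is.null(padTo)) padTo <- max(lens, 1L)
  padTo <- as.integer(padTo)
  if (any(lens > padTo))
    stop("sequence of length ", max(lens),
         " exceeds pad_to = ", padTo, call. = FALSE)
  idx <- vocab@index
  mat <- matrix(0L, nrow = length(sequences), ncol = padTo)
  for (i in seq_along(sequences)) {
    s <- sequences[[i]]
    if (!length(s)) next
    v <- unname(idx[s])
    v[is.na(v)] <- 1L
    mat[i, seq_along(v)] <- v
  }
  mat
}
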