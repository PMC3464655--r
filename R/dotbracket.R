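#' Secondary structures and dot-bracket notation
#'
#' A secondary structure is a set of base pairs over sequence positions; in
#' dot-bracket text a dot is an unpaired position and an opening parenthesis
#' pairs with its matching closing parenthesis. Positions are 1-based and
#' pairs are stored with `i < j`, each position in at most one pair.
#'
#' @param length number of positions.
#' @param pairs two-column integer matrix of (i, j) pairs, `i < j`, 1-based;
#'   may have zero rows.
#' @return An object of class `rna_structure`.
#' @export
rna_structure <- function(length, pairs = matrix(integer(), 0, 2)) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) > 0) {
    if (any(pairs[, 1] >= pairs[, 2]))
      stop("pairs must satisfy i < j")
    if (any(pairs < 1) || any(pairs > length))
      stop("pair index out of range")
    if (anyDuplicated(as.vector(pairs)))
      stop("a position occurs in more than one pair")
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  }
  colnames(pairs) <- c("i", "j")
  structure(list(length = as.integer(length), pairs = pairs),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("RNA structure, length", x$length, "with", nrow(x$pairs), "pairs:",
      to_dotbracket(x), "\n")
  invisible(x)
}

#' Parse dot-bracket text into a structure
#'
#' Matching uses a stack; unbalanced text errors with the offending position.
#'
#' @param text a single string over `(`, `)`, `.`.
#' @return An `rna_structure`.
#' @examples
#' parse_dotbracket("((..))")$pairs
#' @export
parse_dotbracket <- function(text) {
  ch <- strsplit(text, "")[[1]]
  bad <- which(!(ch %in% c("(", ")", ".")))
  if (length(bad) > 0)
    stop(sprintf("invalid character '%s' at position %d", ch[bad[1]], bad[1]))
  stack <- integer()
  pairs <- matrix(integer(), 0, 2)
  for (k in seq_along(ch)) {
    if (ch[k] == "(") stack <- c(stack, k)
    else if (ch[k] == ")") {
      if (length(stack) == 0)
        stop(sprintf("unbalanced ')' at position %d", k))
      pairs <- rbind(pairs, c(stack[length(stack)], k))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0)
    stop(sprintf("unbalanced '(' at position %d", stack[1]))
  rna_structure(length(ch), pairs)
}

#' Render a structure as dot-bracket text
#'
#' Only valid for non-crossing (pseudoknot-free) structures, which is all the
#' single-bracket alphabet can encode.
#'
#' @param structure an `rna_structure`.
#' @return A single string.
#' @export
to_dotbracket <- function(structure) {
  if (nrow(structure$pairs) > 0 && detect_pseudoknot(structure$pairs))
    stop("structure has crossing pairs; dot-bracket cannot encode pseudoknots")
  ch <- rep(".", structure$length)
  ch[structure$pairs[, 1]] <- "("
  ch[structure$pairs[, 2]] <- ")"
  paste(ch, collapse = "")
}

#' Detect crossing base pairs (pseudoknots)
#'
#' @param pairs a two-column matrix of (i, j) pairs (or an `rna_structure`).
#' @return `TRUE` iff two pairs (i, j), (k, l) cross: i < k < j < l.
#' @export
detect_pseudoknot <- function(pairs) {
  if (inherits(pairs, "rna_structure")) pairs <- pairs$pairs
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (anyDuplicated(as.vector(pairs)))
    stop("a position occurs in more than one pair")
  n <- nrow(pairs)
  if (n < 2) return(FALSE)
  for (a in seq_len(n - 1)) {
    i <- pairs[a, 1]; j <- pairs[a, 2]
    k <- pairs[(a + 1):n, 1]; l <- pairs[(a + 1):n, 2]
    if (any((i < k & k < j & j < l) | (k < i & i < l & l < j)))
      return(TRUE)
  }
  FALSE
}

#' Minimum hairpin loop length of a structure
#'
#' A hairpin-closing pair is a pair enclosing no other pair; its loop length
#' is the number of enclosed (necessarily unpaired) positions. Grammar
#' completeness is judged against structures whose hairpins are all of length
#' at least two.
#'
#' @param structure an `rna_structure`.
#' @return The minimum loop length over hairpin-closing pairs, or `Inf` when
#'   the structure has no pairs.
#' @export
min_hairpin_length <- function(structure) {
  p <- structure$pairs
  if (nrow(p) == 0) return(Inf)
  loops <- vapply(seq_len(nrow(p)), function(a) {
    i <- p[a, 1]; j <- p[a, 2]
    encloses <- any(p[, 1] > i & p[, 2] < j)
    if (encloses) NA_real_ else j - i - 1
  }, numeric(1))
  min(loops, na.rm = TRUE)
}

# ---------------------------------------------------------------------------
# Vienna-style records: ">id" / sequence / structure

#' Construct a structured-sequence record
#'
#' @param id record identifier.
#' @param sequence string over `A`, `C`, `G`, `U` (a `T` is normalised to `U`
#'   at read time, not here).
#' @param structure an `rna_structure` of the same length.
#' @return An object of class `structured_seq`.
#' @export
structured_seq <- function(id, sequence, structure) {
  if (nchar(sequence) != structure$length)
    stop(sprintf("record %s: sequence length %d != structure length %d",
                 id, nchar(sequence), structure$length))
  if (grepl("[^ACGU]", sequence))
    stop(sprintf("record %s: sequence has characters outside ACGU", id))
  structure(list(id = id, sequence = sequence, structure = structure),
            class = "structured_seq")
}

#' Read dot-bracket records
#'
#' Reads Vienna-style records (`>id`, sequence line, structure line).
#' `T` is normalised to `U`; lower case is upper-cased; any other letter
#' (ambiguity codes such as `N`, `R`, `Y` included) is rejected — predictions
#' from ambiguous nucleotides are unreliable and such sequences are excluded
#' from training and evaluation.
#'
#' @param path file path.
#' @return A list of `structured_seq` records.
#' @seealso [write_records()], [filter_dataset()]
#' @export
read_records <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) %% 3 != 0)
    stop("expected records of three lines: >id, sequence, structure")
  out <- vector("list", length(lines) %/% 3)
  for (k in seq_along(out)) {
    hdr <- lines[3 * k - 2]
    if (!startsWith(hdr, ">"))
      stop(sprintf("record %d: header '%s' does not start with '>'", k, hdr))
    id <- trimws(substring(hdr, 2))
    seq <- chartr("acgut", "ACGUU", toupper(lines[3 * k - 1]))
    seq <- chartr("T", "U", seq)
    if (grepl("[^ACGU]", seq))
      stop(sprintf("record %s: invalid sequence characters", id))
    st <- tryCatch(parse_dotbracket(lines[3 * k]),
                   error = function(e) stop(sprintf("record %s: %s", id,
                                                    conditionMessage(e)),
                                            call. = FALSE))
    if (nchar(seq) != st$length)
      stop(sprintf("record %s: sequence and structure lengths differ", id))
    out[[k]] <- structured_seq(id, seq, st)
  }
  out
}

#' Write dot-bracket records
#'
#' @param records list of `structured_seq`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  out <- unlist(lapply(records, function(r)
    c(paste0(">", r$id), r$sequence, to_dotbracket(r$structure))))
  writeLines(out, path)
  invisible(path)
}

#' Base-pair similarity between two structures
#'
#' The fraction of shared pairs relative to the larger pair set:
#' `|shared| / max(|pairs1|, |pairs2|)` — conservative, symmetric and
#' parameter-free. Comparison is only defined for equal-length structures;
#' unequal lengths score 0, as does one empty pair set against a non-empty
#' one. Two empty pair sets on equal lengths score 1 (identical
#' structures).
#'
#' @param s1,s2 `rna_structure` objects.
#' @return Similarity in `[0, 1]`.
#' @export
bp_similarity <- function(s1, s2) {
  if (s1$length != s2$length) return(0)
  n1 <- nrow(s1$pairs); n2 <- nrow(s2$pairs)
  if (n1 == 0 && n2 == 0) return(1)
  if (n1 == 0 || n2 == 0) return(0)
  k1 <- paste(s1$pairs[, 1], s1$pairs[, 2])
  k2 <- paste(s2$pairs[, 1], s2$pairs[, 2])
  length(intersect(k1, k2)) / max(n1, n2)
}

#' Filter a dataset of structured sequences
#'
#' Applies, in input order and deterministically (first occurrence kept):
#' removal of records with pseudoknotted structures, removal of duplicate
#' sequences, and removal of any record whose base-pair similarity to an
#' already retained record exceeds `max_bp_similarity`.
#'
#' @param records list of `structured_seq`.
#' @param max_bp_similarity similarity threshold in `[0, 1]`; default 0.8,
#'   the conventional 80 percent redundancy cutoff.
#' @return The filtered list, input order preserved.
#' @export
filter_dataset <- function(records, max_bp_similarity = 0.8) {
  stopifnot(max_bp_similarity >= 0, max_bp_similarity <= 1)
  kept <- list()
  seqs <- character()
  for (r in records) {
    if (detect_pseudoknot(r$structure)) next
    if (r$sequence %in% seqs) next
    sim_ok <- all(vapply(kept, function(k)
      bp_similarity(r$structure, k$structure) <= max_bp_similarity,
      logical(1)))
    if (!sim_ok) next
    kept[[length(kept) + 1]] <- r
    seqs <- c(seqs, r$sequence)
  }
  kept
}
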