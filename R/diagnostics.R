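# Heuristic ambiguity and completeness testing. Both properties are
# undecidable in general; the checks here enumerate or sample structures up
# to a length bound and report either a verified witness (POSITIVE) or
# NEGATIVE_UP_TO_BOUND — never a proof of absence.

#' Enumerate all dot-bracket structures of a given length
#'
#' Generates every valid structure of length `n`. With `min_hairpin = 1`
#' (the least any normal-form grammar can emit: a pair must enclose at least
#' one position) this is all derivable-shaped strings; with
#' `min_hairpin = 2` it is the completeness universe: structures with no
#' hairpin loop shorter than two.
#'
#' @param n structure length.
#' @param min_hairpin minimum hairpin loop length (1 or 2).
#' @return Character vector of structures.
#' @export
enumerate_structures <- function(n, min_hairpin = 1) {
  memo <- new.env(parent = emptyenv())
  gen <- function(n) {
    key <- as.character(n)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (n == 0) return(memo[[key]] <- "")
    out <- paste0(".", gen(n - 1))
    for (k in seq_len(n)) {       # pair from position 1 to k
      if (k - 2 < min_hairpin) next
      for (inner in gen(k - 2))
        out <- c(out, paste0("(", inner, ")", gen(n - k)))
    }
    memo[[key]] <- out
  }
  gen(n)
}

diagnosis_report <- function(property, verdict, witnesses, bound, samples) {
  structure(list(property = property, verdict = verdict,
                 witnesses = witnesses, bound = bound, samples = samples),
            class = "scfg_diagnosis")
}

#' @export
print.scfg_diagnosis <- function(x, ...) {
  cat(sprintf("%s: %s (tested up to length %d, %d sampled)\n", x$property,
              x$verdict, x$bound, x$samples))
  if (length(x$witnesses) > 0)
    cat("  witnesses:", paste(head(x$witnesses, 5), collapse = " "), "\n")
  invisible(x)
}

#' Heuristic ambiguity check
#'
#' A grammar is ambiguous if some structure has more than one derivation.
#' The check enumerates every structure up to length `min(max_len, 10)`
#' exhaustively, then draws structures from the grammar itself (uniform rule
#' choice, over-length rejections) up to `max_len`, counting derivations of
#' each candidate. Returns `POSITIVE` with verified witnesses, or
#' `NEGATIVE_UP_TO_BOUND` — absence of a witness is not a proof of
#' unambiguity.
#'
#' Uses R's RNG for the sampling phase; call `set.seed()` for
#' reproducibility.
#'
#' @param grammar a valid `scfg_grammar`.
#' @param max_len largest structure length examined (default 30).
#' @param sample_budget number of sampled structures beyond the exhaustive
#'   phase (default 1000).
#' @return An `scfg_diagnosis`.
#' @export
check_ambiguity <- function(grammar, max_len = 30, sample_budget = 1000) {
  witnesses <- character()
  exh <- min(max_len, 10)
  for (n in seq_len(exh)) {
    for (s in enumerate_structures(n, 1)) {
      if (count_derivations(grammar, s, cap = 2) >= 2) {
        witnesses <- c(witnesses, s)
        if (length(witnesses) >= 3)
          return(diagnosis_report("AMBIGUITY", "POSITIVE", witnesses, n, 0L))
      }
    }
    if (length(witnesses) > 0)
      return(diagnosis_report("AMBIGUITY", "POSITIVE", witnesses, n, 0L))
  }
  sampled <- 0L
  if (max_len > exh && sample_budget > 0) {
    up <- uniform_params(grammar)
    for (k in seq_len(sample_budget)) {
      s <- sample_structure(grammar, up, max_len = max_len)
      sampled <- sampled + 1L
      if (is.null(s)) next
      if (count_derivations(grammar, s, cap = 2) >= 2)
        return(diagnosis_report("AMBIGUITY", "POSITIVE", s, max_len, sampled))
    }
  }
  diagnosis_report("AMBIGUITY", "NEGATIVE_UP_TO_BOUND", character(),
                   max_len, sampled)
}

#' Heuristic completeness check
#'
#' A grammar is complete if it derives every structure with no hairpin loop
#' shorter than two. The check enumerates all such structures with lengths
#' from `min_len` to `max_len` and reports any without a derivation
#' (`POSITIVE` means *incompleteness* was witnessed). Lengths below three are
#' excluded by default: no legal hairpin pair fits in fewer than three
#' positions, so those strings only probe whether the start symbol happens to
#' carry a direct unpaired rule — a notational property, not structural
#' coverage.
#'
#' @param grammar a valid `scfg_grammar`.
#' @param max_len largest length enumerated (default 14; capped at 18, above
#'   which the enumeration explodes combinatorially).
#' @param min_len smallest length enumerated (default 3).
#' @return An `scfg_diagnosis` (property `"COMPLETENESS"`; `POSITIVE` =
#'   incomplete with witnesses, `NEGATIVE_UP_TO_BOUND` = no failure found).
#' @export
check_completeness <- function(grammar, max_len = 14, min_len = 3) {
  if (max_len > 18)
    stop("max_len above 18 is rejected: the structure universe explodes combinatorially")
  witnesses <- character()
  for (n in seq(min_len, max_len)) {
    for (s in enumerate_structures(n, 2)) {
      if (count_derivations(grammar, s, cap = 1) == 0) {
        witnesses <- c(witnesses, s)
        if (length(witnesses) >= 3)
          return(diagnosis_report("COMPLETENESS", "POSITIVE", witnesses, n, 0L))
      }
    }
    if (length(witnesses) > 0)
      return(diagnosis_report("COMPLETENESS", "POSITIVE", witnesses, n, 0L))
  }
  diagnosis_report("COMPLETENESS", "NEGATIVE_UP_TO_BOUND", character(),
                   max_len, 0L)
}

#' Ambiguity/completeness table for a set of grammars
#'
#' Runs both heuristic checks on each named bundled grammar and tabulates
#' the verdicts as yes/no flags (`ambiguous` = ambiguity witnessed;
#' `complete` = no incompleteness witness up to the bound).
#'
#' @param grammar_names names resolvable by [builtin_grammar()] (default:
#'   all seven bundled grammars).
#' @param max_len length bound passed to both checks.
#' @return A data frame with columns `grammar`, `ambiguous`, `complete`.
#' @export
ambiguity_completeness_table <- function(grammar_names = c("KH99p",
                                                           paste0("GG", 1:6)),
                                         max_len = 14) {
  rows <- lapply(grammar_names, function(nm) {
    g <- builtin_grammar(nm)
    amb <- check_ambiguity(g, max_len = max(max_len, 10), sample_budget = 200)
    cmp <- check_completeness(g, max_len = max_len)
    data.frame(grammar = nm,
               ambiguous = amb$verdict == "POSITIVE",
               complete = cmp$verdict != "POSITIVE")
  })
  do.call(rbind, rows)
}
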