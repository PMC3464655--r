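#' Empty count table for a grammar
#'
#' @param grammar an `scfg_grammar`.
#' @return A list of class `count_table` with `rule_counts` (one per grammar
#'   rule), `unpaired_counts` (4) and `paired_counts` (16), all zero.
#' @export
count_table <- function(grammar) {
  structure(list(rule_counts = numeric(nrow(grammar$rules)),
                 unpaired_counts = setNames(numeric(4), NUCS),
                 paired_counts = setNames(numeric(16), PAIR_NAMES)),
            class = "count_table")
}

#' Normalise counts into parameters
#'
#' Multinomial maximum-likelihood estimation with an optional additive
#' pseudocount: each non-terminal's rule counts and each emission table are
#' normalised to probability distributions. A non-terminal with zero total
#' count and zero pseudocount gets the uniform distribution over its rules
#' (with a message), as does an all-zero emission table.
#'
#' @param grammar an `scfg_grammar`.
#' @param counts a `count_table`.
#' @param pseudocount nonnegative additive smoothing constant (default 0).
#' @param quiet suppress the zero-count messages.
#' @return An `scfg_params`.
#' @export
params_from_counts <- function(grammar, counts, pseudocount = 0, quiet = FALSE) {
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  if (any(!is.finite(counts$rule_counts)) || any(counts$rule_counts < 0))
    stop("rule counts must be finite and nonnegative")
  r <- grammar$rules
  p <- counts$rule_counts + pseudocount
  for (nt in unique(r$lhs)) {
    idx <- which(r$lhs == nt)
    tot <- sum(p[idx])
    if (tot == 0) {
      if (!quiet)
        message("non-terminal ", nt, " has zero counts; using uniform rule probabilities")
      p[idx] <- 1 / length(idx)
    } else p[idx] <- p[idx] / tot
  }
  norm_emit <- function(x, k) {
    x <- x + pseudocount
    if (sum(x) == 0) {
      if (!quiet)
        message("empty emission table; using uniform")
      rep(1 / k, k)
    } else x / sum(x)
  }
  scfg_params(grammar, p,
              setNames(norm_emit(unname(counts$unpaired_counts), 4), NUCS),
              setNames(norm_emit(unname(counts$paired_counts), 16), PAIR_NAMES))
}

#' Supervised parameter training from trusted structures
#'
#' For each record, one derivation of its trusted structure is obtained —
#' the unique derivation for unambiguous grammars, a uniformly sampled one
#' otherwise (the derivation that actually produced the structure cannot be
#' known for ambiguous grammars, so one is randomly selected). Rule usages
#' accumulate into rule counts; nucleotide emissions accumulate from the
#' sequence according to the structure's paired/unpaired status. Records whose
#' structure the grammar cannot derive are skipped (their number is reported
#' in the `n_skipped` attribute, with a warning).
#'
#' Uses R's RNG for derivation sampling: call `set.seed()` for
#' reproducibility on ambiguous grammars.
#'
#' @param grammar an `scfg_grammar`.
#' @param records list of `structured_seq`.
#' @param pseudocount nonnegative smoothing constant (default 0).
#' @return An `scfg_params` with attribute `n_skipped`.
#' @export
supervised_train <- function(grammar, records, pseudocount = 0) {
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  ct <- count_table(grammar)
  cg <- compile_grammar(grammar)
  skipped <- 0L
  for (rec in records) {
    scodes <- encode_structure(to_dotbracket(rec$structure))
    m <- cpp_sample_derivation(cg, scodes)
    if (is.null(m)) { skipped <- skipped + 1L; next }
    ct$rule_counts <- ct$rule_counts + tabulate(m[, 1] + 1L,
                                                nbins = nrow(grammar$rules))
    ch <- strsplit(rec$sequence, "")[[1]]
    p <- rec$structure$pairs
    unp <- setdiff(seq_len(rec$structure$length), as.vector(p))
    for (x in ch[unp])
      ct$unpaired_counts[x] <- ct$unpaired_counts[x] + 1
    if (nrow(p) > 0) {
      for (a in seq_len(nrow(p))) {
        key <- paste0(ch[p[a, 1]], ch[p[a, 2]])
        ct$paired_counts[key] <- ct$paired_counts[key] + 1
      }
    }
  }
  if (skipped == length(records))
    stop("no record's structure is derivable by this grammar")
  if (skipped > 0)
    warning(skipped, " of ", length(records),
            " records had underivable structures and were skipped")
  out <- params_from_counts(grammar, ct, pseudocount, quiet = TRUE)
  attr(out, "n_skipped") <- skipped
  out
}

#' Expectation-maximisation (inside-outside) training
#'
#' Trains rule and emission probabilities on the record *sequences* alone:
#' the trusted structures are ignored, and each iteration computes expected
#' rule and emission usage counts with the inside-outside algorithm, then
#' renormalises. The log-likelihood trace is non-decreasing (standard EM
#' monotonicity); iteration stops after `max_iters` rounds or when the
#' improvement drops below `tol`.
#'
#' Sequences outside the grammar's support at initialisation are excluded
#' with a warning; if all are excluded, an error is raised.
#'
#' @param grammar an `scfg_grammar`.
#' @param records list of `structured_seq` (or plain sequence strings).
#' @param init an `scfg_params`, or `"uniform"` for uniform initialisation
#'   with a small symmetry-breaking jitter (+/-1 percent, via the current
#'   RNG state).
#' @param max_iters maximum EM iterations (default 100).
#' @param tol stop when the total log-likelihood improves by less than this
#'   (default 1e-4).
#' @return A list with `params` (the final `scfg_params`) and `trace`
#'   (per-iteration total log-likelihood).
#' @export
em_train <- function(grammar, records, init = "uniform", max_iters = 100,
                     tol = 1e-4) {
  if (length(records) == 0) stop("records must be non-empty")
  seqs <- vapply(records, function(r)
    if (is.character(r)) r else r$sequence, character(1))
  params <- if (identical(init, "uniform"))
    uniform_params(grammar, jitter = 0.01) else init
  codes <- lapply(seqs, encode_sequence)
  cg0 <- compile_grammar(grammar, params)
  e0 <- log_emissions(params)
  keep <- vapply(codes, function(x)
    is.finite(cpp_inside(cg0, x, e0$lup, e0$lpp)$loglik), logical(1))
  if (!any(keep)) stop("no sequence is in the grammar's support")
  if (!all(keep))
    warning(sum(!keep), " sequences outside the grammar's support were excluded")
  codes <- codes[keep]
  trace <- numeric()
  for (it in seq_len(max_iters)) {
    cg <- compile_grammar(grammar, params)
    e <- log_emissions(params)
    ct <- count_table(grammar)
    ll <- 0
    for (x in codes) {
      res <- cpp_inside_outside(cg, x, e$lup, e$lpp)
      ll <- ll + res$loglik
      ct$rule_counts <- ct$rule_counts + res$rule_exp
      ct$unpaired_counts <- ct$unpaired_counts + res$unpaired_exp
      ct$paired_counts <- ct$paired_counts + res$paired_exp
    }
    trace <- c(trace, ll)
    params <- params_from_counts(grammar, ct, 0, quiet = TRUE)
    if (it > 1 && trace[it] - trace[it - 1] < tol) break
  }
  list(params = params, trace = trace)
}
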