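# Thin R layer over the compiled dynamic programs. compile_grammar() turns an
# scfg_grammar (+ optional params) into the integer form the C++ side expects:
# 0-based non-terminal indices, rule kinds 0/1/2, log rule probabilities
# (all zero for unweighted parsing).

KIND_CODE <- c(BRANCH = 0L, UNPAIRED = 1L, PAIR = 2L)

compile_grammar <- function(grammar, params = NULL) {
  nts <- grammar$nonterminals
  r <- grammar$rules
  idx <- function(sym) {
    i <- match(sym, nts)
    ifelse(is.na(i), -1L, i - 1L)
  }
  logp <- if (is.null(params)) rep(0, nrow(r)) else log(params$rule_prob)
  list(n_nt = length(nts), start = idx(grammar$start),
       lhs = idx(r$lhs), kind = unname(KIND_CODE[r$kind]),
       c1 = as.integer(idx(r$c1)), c2 = as.integer(idx(r$c2)),
       logp = logp)
}

encode_structure <- function(text) {
  m <- match(strsplit(text, "")[[1]], c(".", "(", ")")) - 1L
  if (anyNA(m)) stop("structure text must be over '.', '(', ')'")
  m
}

encode_sequence <- function(sequence) {
  m <- match(strsplit(sequence, "")[[1]], NUCS) - 1L
  if (anyNA(m)) stop("sequence must be over A, C, G, U")
  m
}

log_emissions <- function(params) {
  list(lup = log(unname(params$unpaired_emit)),
       lpp = log(unname(params$paired_emit)))
}

deriv_df <- function(m) {
  # C++ derivation rows are (0-based rule, i, j) over half-open spans;
  # user-facing: 1-based rule index and closed spans [start, end]
  data.frame(rule = m[, 1] + 1L, start = m[, 2] + 1L, end = m[, 3])
}

#' Most probable derivation of a dot-bracket string
#'
#' CYK over the structure string: finds the derivation of the exact string
#' with maximum probability under the grammar's rule probabilities (or any
#' one derivation when `params` is `NULL`, in which case the reported
#' log-probability is 0 for derivable strings — an existence check).
#'
#' @param grammar an `scfg_grammar`.
#' @param structure_text dot-bracket string.
#' @param params optional `scfg_params`.
#' @return `NULL` when the string has no derivation; otherwise a list with
#'   `logp` and `deriv`, a data frame of rule applications in pre-order with
#'   columns `rule` (row index into `grammar$rules`), `start`, `end`
#'   (1-based closed span).
#' @export
structure_cyk <- function(grammar, structure_text, params = NULL) {
  res <- cpp_structure_cyk(compile_grammar(grammar, params),
                           encode_structure(structure_text))
  if (!is.finite(res$logp)) return(NULL)
  list(logp = res$logp, deriv = deriv_df(res$deriv))
}

#' Count derivations of a dot-bracket string
#'
#' Runs the CYK recurrences with (sum, product) in place of (max, product),
#' i.e. counts distinct derivation trees of the exact string. A grammar is
#' ambiguous when some structure has two or more derivations. Counts saturate
#' at `cap` to avoid overflow on highly ambiguous grammars.
#'
#' @param grammar an `scfg_grammar`.
#' @param structure_text dot-bracket string.
#' @param cap saturation bound (default `1e15`; exact below `2^53`).
#' @return The derivation count (0 for underivable strings), as a double.
#' @export
count_derivations <- function(grammar, structure_text, cap = 1e15) {
  cpp_count_derivations(compile_grammar(grammar),
                        encode_structure(structure_text), cap)
}

#' Sample a derivation of a dot-bracket string uniformly at random
#'
#' Draws uniformly among all derivations of the string, by backtracking
#' through the derivation-count tables (kept in log space, so astronomically
#' ambiguous grammars sample correctly). Uses R's RNG: `set.seed()` gives
#' reproducible draws. Used by supervised training on ambiguous grammars,
#' where the derivation that produced a trusted structure cannot be known.
#'
#' @param grammar an `scfg_grammar`.
#' @param structure_text dot-bracket string; must be derivable.
#' @return A derivation data frame (see [structure_cyk()]).
#' @export
sample_derivation <- function(grammar, structure_text) {
  m <- cpp_sample_derivation(compile_grammar(grammar),
                             encode_structure(structure_text))
  if (is.null(m)) stop("string has no derivation under this grammar")
  deriv_df(m)
}

#' Inside algorithm: total sequence likelihood
#'
#' Sums, over all derivations yielding any structure of the sequence's
#' length, the product of rule probabilities and emission probabilities
#' (unpaired positions emit from the 4-way table, pair rules emit the two
#' partners jointly from the 16-way table). Computed in log space; a sequence
#' outside the grammar's support has log-likelihood `-Inf`.
#'
#' @param grammar an `scfg_grammar`.
#' @param params an `scfg_params`.
#' @param sequence string over `A`, `C`, `G`, `U`.
#' @return A list with `loglik` and `inside`, the inside table as an
#'   `(n+1) x (n+1) x m` array: `inside[i, j, t]` is the inside log-value of
#'   non-terminal `t` on the half-open span from position `i` to `j - 1`.
#' @export
sequence_inside <- function(grammar, params, sequence) {
  e <- log_emissions(params)
  res <- cpp_inside(compile_grammar(grammar, params),
                    encode_sequence(sequence), e$lup, e$lpp)
  dimnames(res$inside) <- list(NULL, NULL, grammar$nonterminals)
  res
}

#' Most probable joint derivation and structure of a sequence
#'
#' CYK over the sequence: maximises the joint probability of a derivation and
#' its emitted nucleotides; the yield of the best derivation is the predicted
#' structure. Ties are broken deterministically (rule order as listed in the
#' grammar, then lowest split point).
#'
#' @inheritParams sequence_inside
#' @return `NULL` when no derivation exists; otherwise a list with `logp`,
#'   `deriv` (see [structure_cyk()]) and `structure` (an `rna_structure`).
#' @export
sequence_cyk <- function(grammar, params, sequence) {
  e <- log_emissions(params)
  res <- cpp_sequence_cyk(compile_grammar(grammar, params),
                          encode_sequence(sequence), e$lup, e$lpp)
  if (!is.finite(res$logp)) return(NULL)
  list(logp = res$logp, deriv = deriv_df(res$deriv),
       structure = partner_to_structure(res$partner))
}

partner_to_structure <- function(partner) {
  n <- length(partner)
  i <- which(partner >= 0)            # 0-based partners from C++
  i <- i[partner[i] + 1 > i]          # keep each pair once (i < j)
  rna_structure(n, cbind(i, partner[i] + 1L))
}

#' Posterior base-pairing probabilities of a sequence
#'
#' Runs the inside and outside algorithms and returns, for every position
#' pair, the posterior probability that the two positions are base-paired in
#' a derivation, plus the posterior probability of each position being
#' unpaired. For any position, the unpaired probability plus its row/column
#' pair probabilities sum to 1 (up to numerical tolerance).
#'
#' @inheritParams sequence_inside
#' @return A list of class `posterior_matrix` with `pair_prob` (an `n x n`
#'   matrix, upper triangle meaningful), `unpaired_prob` (length `n`) and
#'   `loglik`.
#' @export
sequence_outside_posteriors <- function(grammar, params, sequence) {
  e <- log_emissions(params)
  res <- cpp_inside_outside(compile_grammar(grammar, params),
                            encode_sequence(sequence), e$lup, e$lpp)
  if (!is.finite(res$loglik))
    stop("sequence not in the grammar's support")
  structure(list(pair_prob = res$pair_prob,
                 unpaired_prob = res$unpaired_prob,
                 loglik = res$loglik),
            class = "posterior_matrix")
}

# inside-outside expected counts for one sequence; internal, used by EM
expected_counts <- function(cg, seqcodes, lup, lpp) {
  cpp_inside_outside(cg, seqcodes, lup, lpp)
}
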