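#' Predict a structure by maximum-likelihood (CYK) decoding
#'
#' Finds the most probable joint derivation of the sequence and reports its
#' emitted structure. When the sequence has no derivation (the grammar's
#' yields cannot cover its length), the prediction fails: the all-unpaired
#' structure is returned with `failed = TRUE` and score `-Inf`.
#'
#' @param grammar an `scfg_grammar`.
#' @param params an `scfg_params`.
#' @param sequence string over `A`, `C`, `G`, `U`.
#' @return A list of class `scfg_prediction` with `structure`
#'   (an `rna_structure`), `method = "CYK"`, `score` (log-probability) and
#'   `failed`.
#' @export
predict_cyk <- function(grammar, params, sequence) {
  res <- sequence_cyk(grammar, params, sequence)
  n <- nchar(sequence)
  if (is.null(res))
    return(structure(list(structure = rna_structure(n), method = "CYK",
                          gamma = NA_real_, score = -Inf, failed = TRUE),
                     class = "scfg_prediction"))
  structure(list(structure = res$structure, method = "CYK",
                 gamma = NA_real_, score = res$logp, failed = FALSE),
            class = "scfg_prediction")
}

#' Predict a structure by gamma-weighted posterior (MEA) decoding
#'
#' Computes the posterior base-pairing probability matrix via inside-outside,
#' then finds the non-crossing structure maximising the expected-accuracy
#' objective: `sum over pairs of gamma * p(i, j) + sum over unpaired i of
#' q(i)`. `gamma` trades correctly predicted base pairs against correctly
#' predicted unpaired positions; `gamma = 2` weights a pair by its two
#' positions, maximising the expected number of correctly predicted
#' positions. The decoded structure need not be derivable by the grammar.
#'
#' @inheritParams predict_cyk
#' @param gamma positive trade-off weight (default 2).
#' @param min_hairpin minimum hairpin loop length imposed on the decoded
#'   structure (default 0: no constraint).
#' @return An `scfg_prediction` with `method = "MEA"`, `gamma`, `score` (the
#'   objective value; 0 with `failed = TRUE` when the sequence is outside the
#'   grammar's support).
#' @export
predict_mea <- function(grammar, params, sequence, gamma = 2,
                        min_hairpin = 0) {
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be positive")
  n <- nchar(sequence)
  post <- tryCatch(sequence_outside_posteriors(grammar, params, sequence),
                   error = function(e) NULL)
  if (is.null(post))
    return(structure(list(structure = rna_structure(n), method = "MEA",
                          gamma = gamma, score = 0, failed = TRUE),
                     class = "scfg_prediction"))
  mea_from_posterior(post, gamma, min_hairpin)
}

#' MEA decoding of a precomputed posterior matrix
#'
#' Useful when several `gamma` values are decoded from one inside-outside
#' pass, as in [gamma_sweep()]. Ties in the objective prefer fewer pairs.
#'
#' @param posterior a `posterior_matrix` (or a list with `pair_prob` and
#'   `unpaired_prob`).
#' @param gamma positive trade-off weight.
#' @param min_hairpin minimum hairpin loop length (default 0).
#' @return An `scfg_prediction` with `method = "MEA"`.
#' @export
mea_from_posterior <- function(posterior, gamma = 2, min_hairpin = 0) {
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be positive")
  partner <- cpp_mea(posterior$pair_prob, posterior$unpaired_prob,
                     gamma, as.integer(min_hairpin))
  st <- partner_to_structure(partner)
  structure(list(structure = st, method = "MEA", gamma = gamma,
                 score = mea_objective(st, posterior, gamma), failed = FALSE),
            class = "scfg_prediction")
}

#' Expected-accuracy objective of a structure under a posterior
#'
#' @param structure an `rna_structure`.
#' @param posterior a `posterior_matrix`.
#' @param gamma positive trade-off weight.
#' @return `sum(gamma * p(i,j)) + sum(q(i))` over the structure's pairs and
#'   unpaired positions.
#' @export
mea_objective <- function(structure, posterior, gamma) {
  p <- structure$pairs
  unp <- setdiff(seq_len(structure$length), as.vector(p))
  s <- sum(posterior$unpaired_prob[unp])
  if (nrow(p) > 0)
    s <- s + gamma * sum(posterior$pair_prob[p])
  s
}

#' @export
print.scfg_prediction <- function(x, ...) {
  cat(sprintf("%s prediction%s (score %.4f%s): %s\n", x$method,
              if (x$method == "MEA") sprintf(", gamma=%g", x$gamma) else "",
              x$score, if (x$failed) ", FAILED" else "",
              to_dotbracket(x$structure)))
  invisible(x)
}
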