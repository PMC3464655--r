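#' SCFG parameters: rule probabilities and emission distributions
#'
#' Parameters attach probabilities to a grammar: one multinomial over each
#' non-terminal's rules, one global 4-way distribution over unpaired
#' nucleotides and one global 16-way distribution over ordered nucleotide
#' pairs. Emissions are global rather than per-rule: the generative model
#' allocates nucleotides to sites by the frequency of occurrence at paired and
#' unpaired positions. The paired table is over ordered pairs; symmetry is up
#' to the trainer, not enforced here.
#'
#' @param grammar the `scfg_grammar` the parameters belong to.
#' @param rule_prob numeric vector aligned with `grammar$rules` rows; for each
#'   non-terminal with at least one rule, its entries must sum to 1 (within
#'   1e-9 tolerance at validation).
#' @param unpaired_emit named numeric of length 4 (`A`, `C`, `G`, `U`).
#' @param paired_emit named numeric of length 16 (`AA`, `AC`, ..., `UU`).
#' @return An object of class `scfg_params`.
#' @export
scfg_params <- function(grammar, rule_prob, unpaired_emit, paired_emit) {
  p <- structure(list(rule_prob = as.numeric(rule_prob),
                      unpaired_emit = unpaired_emit[NUCS],
                      paired_emit = paired_emit[PAIR_NAMES]),
                 class = "scfg_params")
  validate_params(grammar, p)
  p
}

#' Validate an scfg_params object against its grammar
#'
#' Checks non-negativity, per-non-terminal rule-probability sums and emission
#' sums, all within a tolerance of 1e-9 (scaled slightly for long vectors).
#'
#' @param grammar an `scfg_grammar`.
#' @param params an `scfg_params`.
#' @return `TRUE`, invisibly; errors on violation.
#' @export
validate_params <- function(grammar, params) {
  tol <- 1e-9
  if (length(params$rule_prob) != nrow(grammar$rules))
    stop("rule_prob length does not match the grammar's rule count")
  if (any(!is.finite(params$rule_prob)) || any(params$rule_prob < -tol))
    stop("rule probabilities must be finite and non-negative")
  for (nt in unique(grammar$rules$lhs)) {
    s <- sum(params$rule_prob[grammar$rules$lhs == nt])
    if (abs(s - 1) > 1e-9 * max(1, length(params$rule_prob)))
      stop(sprintf("rule probabilities of %s sum to %.12f, not 1", nt, s))
  }
  for (nm in c("unpaired_emit", "paired_emit")) {
    e <- params[[nm]]
    if (anyNA(e) || any(e < -tol)) stop(nm, " has missing or negative entries")
    if (abs(sum(e) - 1) > 1e-8) stop(nm, " does not sum to 1")
  }
  invisible(TRUE)
}

#' Uniform parameters for a grammar
#'
#' Each non-terminal's rules get equal probability; emissions are uniform
#' (1/4 unpaired, 1/16 per ordered pair). The standard initialiser for EM and
#' for unweighted parsing checks.
#'
#' @param grammar an `scfg_grammar`.
#' @param jitter optional multiplicative jitter half-width (e.g. `0.01` for
#'   +/-1 percent) applied to rule probabilities before renormalisation, to
#'   break EM symmetry; uses the current RNG state.
#' @return An `scfg_params`.
#' @export
uniform_params <- function(grammar, jitter = 0) {
  r <- grammar$rules
  p <- numeric(nrow(r))
  for (nt in unique(r$lhs)) {
    idx <- which(r$lhs == nt)
    w <- rep(1, length(idx))
    if (jitter > 0) w <- w * (1 + runif(length(idx), -jitter, jitter))
    p[idx] <- w / sum(w)
  }
  scfg_params(grammar, p,
              setNames(rep(0.25, 4), NUCS),
              setNames(rep(1 / 16, 16), PAIR_NAMES))
}

#' @export
print.scfg_params <- function(x, ...) {
  cat("SCFG parameters:", length(x$rule_prob), "rule probabilities;",
      "unpaired emissions", paste(sprintf("%s=%.3f", NUCS, x$unpaired_emit),
                                  collapse = " "), "\n")
  invisible(x)
}
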