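# Synthetic (sequence, structure) data drawn from an SCFG with known
# parameters, so that training, prediction, evaluation and grammar search can
# be exercised and benchmarked without any external dataset.

# guaranteed minimal terminal yield of each non-terminal (Inf when a symbol
# cannot terminate); fixed-point over the rule shapes
min_yields <- function(grammar) {
  nts <- grammar$nonterminals
  r <- grammar$rules
  y <- setNames(rep(Inf, length(nts)), nts)
  repeat {
    y0 <- y
    for (i in seq_len(nrow(r))) {
      cand <- switch(r$kind[i],
                     UNPAIRED = 1,
                     PAIR = 2 + y[r$c1[i]],
                     BRANCH = y[r$c1[i]] + y[r$c2[i]])
      if (cand < y[r$lhs[i]]) y[r$lhs[i]] <- cand
    }
    if (identical(y, y0)) break
  }
  y
}

#' Sample a structure from an SCFG
#'
#' Performs a leftmost stochastic derivation: the leftmost non-terminal of
#' the sentential form is repeatedly rewritten by a rule drawn from its
#' probability distribution. The derivation is abandoned (`NULL` returned)
#' as soon as the guaranteed minimal yield of the sentential form exceeds
#' `max_len` — SCFG derivations need not terminate, and rejection keeps the
#' sampling distribution correct conditional on the yield fitting.
#'
#' Uses R's RNG; call `set.seed()` for reproducibility.
#'
#' @param grammar an `scfg_grammar`.
#' @param params an `scfg_params`.
#' @param max_len maximum structure length.
#' @return A dot-bracket string, or `NULL` when the draw was rejected.
#' @export
sample_structure <- function(grammar, params, max_len) {
  r <- grammar$rules
  my <- min_yields(grammar)
  if (!is.finite(my[grammar$start]) || my[grammar$start] > max_len)
    return(NULL)
  rules_of <- split(seq_len(nrow(r)), r$lhs)
  # sentential form: character vector of terminals and non-terminal names
  form <- grammar$start
  min_total <- my[grammar$start]
  repeat {
    nt_pos <- which(form %in% grammar$nonterminals)
    if (length(nt_pos) == 0) return(paste(form, collapse = ""))
    pos <- nt_pos[1]
    sym <- form[pos]
    idx <- rules_of[[sym]]
    if (is.null(idx)) return(NULL)      # dead-end non-terminal
    i <- idx[sample.int(length(idx), 1, prob = params$rule_prob[idx])]
    repl <- switch(r$kind[i],
                   UNPAIRED = ".",
                   PAIR = c("(", r$c1[i], ")"),
                   BRANCH = c(r$c1[i], r$c2[i]))
    new_min <- switch(r$kind[i],
                      UNPAIRED = 0,
                      PAIR = 2 + my[r$c1[i]] - my[sym],
                      BRANCH = my[r$c1[i]] + my[r$c2[i]] - my[sym])
    min_total <- min_total + new_min
    if (min_total > max_len) return(NULL)
    form <- append(form[-pos], repl, after = pos - 1)
  }
}

#' Sample structured-sequence records from an SCFG
#'
#' Structures come from [sample_structure()] (rejected draws are retried up
#' to `max_attempts` times per record); nucleotides are then allocated per
#' site — unpaired sites from the 4-way unpaired emission distribution,
#' paired sites jointly from the 16-way ordered-pair distribution. The
#' output is deterministic for a fixed RNG seed.
#'
#' @param grammar an `scfg_grammar`.
#' @param params an `scfg_params`.
#' @param n_records number of records to generate.
#' @param max_len maximum structure length (default 60).
#' @param max_attempts rejected-draw retries per record (default 1000).
#' @param prefix record id prefix.
#' @return A list of `structured_seq` records.
#' @export
sample_records <- function(grammar, params, n_records, max_len = 60,
                           max_attempts = 1000, prefix = "synth") {
  stopifnot(n_records >= 1, max_len >= 1)
  out <- vector("list", n_records)
  for (k in seq_len(n_records)) {
    s <- NULL
    for (a in seq_len(max_attempts)) {
      s <- sample_structure(grammar, params, max_len)
      if (!is.null(s)) break
    }
    if (is.null(s))
      stop("sampling failed after ", max_attempts,
           " attempts; increase max_len or max_attempts")
    st <- parse_dotbracket(s)
    ch <- character(st$length)
    unp <- setdiff(seq_len(st$length), as.vector(st$pairs))
    if (length(unp) > 0)
      ch[unp] <- sample(NUCS, length(unp), replace = TRUE,
                        prob = params$unpaired_emit)
    if (nrow(st$pairs) > 0) {
      pk <- sample(PAIR_NAMES, nrow(st$pairs), replace = TRUE,
                   prob = params$paired_emit)
      ch[st$pairs[, 1]] <- substring(pk, 1, 1)
      ch[st$pairs[, 2]] <- substring(pk, 2, 2)
    }
    out[[k]] <- structured_seq(paste0(prefix, k), paste(ch, collapse = ""), st)
  }
  out
}

#' Reference parameters for the bundled KH99p grammar
#'
#' A hand-set, branch-light and unpaired-heavy parameterisation of the
#' Knudsen-Hein grammar used as the default synthetic-data source: expected
#' structure length stays well below typical `max_len` settings, so
#' rejection rates are low, and the emission tables favour Watson-Crick
#' pairs with A/U-rich unpaired sites, loosely mimicking real RNA
#' composition.
#'
#' @return An `scfg_params` for `builtin_grammar("KH99p")`.
#' @export
kh99p_reference_params <- function() {
  g <- builtin_grammar("KH99p")
  lab <- rule_labels(g$rules)
  p <- numeric(nrow(g$rules))
  p[lab == "A -> B A"] <- 0.40
  p[lab == "A -> ."] <- 0.45
  p[lab == "A -> ( C )"] <- 0.15
  p[lab == "B -> ."] <- 0.80
  p[lab == "B -> ( C )"] <- 0.20
  p[lab == "C -> B A"] <- 0.35
  p[lab == "C -> ( C )"] <- 0.65
  up <- c(A = 0.32, C = 0.20, G = 0.20, U = 0.28)
  pp <- setNames(rep(0.01, 16), PAIR_NAMES)
  pp[c("AU", "UA")] <- 0.23
  pp[c("CG", "GC")] <- 0.20
  pp[c("GU", "UG")] <- 0.02
  pp <- pp / sum(pp)
  scfg_params(g, p, up, pp)
}
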