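# Brute-force derivation enumerator used as an independent oracle for the
# dynamic programs, plus shared toy fixtures. The oracle enumerates complete
# derivation trees recursively (no shared DP machinery with the package).

uniform_emit4 <- setNames(rep(0.25, 4), c("A", "C", "G", "U"))
uniform_emit16 <- setNames(rep(1 / 16, 16),
                           paste0(rep(c("A", "C", "G", "U"), each = 4),
                                  c("A", "C", "G", "U")))

make_params <- function(grammar, rule_prob, up = uniform_emit4,
                        pp = uniform_emit16) {
  scfg_params(grammar, rule_prob, up, pp)
}

# toy grammar 1: S -> (B) 0.6 | . 0.4 ; B -> . (unambiguous, finite language)
toy1 <- function() {
  g <- scfg_grammar(c("S", "B"), "S",
                    rule_df(c("S", "S", "B"), c("PAIR", "UNPAIRED", "UNPAIRED"),
                            c("B", NA, NA)))
  list(grammar = g, params = make_params(g, c(0.6, 0.4, 1)))
}

# toy grammar 2: S -> SS 0.3 | . 0.5 | (S) 0.2 (ambiguous, infinite language)
toy2 <- function() {
  g <- scfg_grammar("S", "S",
                    rule_df(c("S", "S", "S"), c("BRANCH", "UNPAIRED", "PAIR"),
                            c("S", NA, "S"), c("S", NA, NA)))
  list(grammar = g, params = make_params(g, c(0.3, 0.5, 0.2)))
}

# KH99p with its reference parameters (unambiguous, three non-terminals)
toy_kh <- function() {
  list(grammar = builtin_grammar("KH99p"), params = kh99p_reference_params())
}

oracle_toys <- function() list(toy1 = toy1(), toy2 = toy2(), kh = toy_kh())

# --- derivation enumeration ------------------------------------------------

# all derivations of `sym` yielding exactly n terminals; each derivation is
# list(str = yield, rules = rule indices in pre-order)
oracle_derivations <- function(grammar, n, sym = grammar$start,
                               memo = new.env(parent = emptyenv())) {
  key <- paste(sym, n)
  if (!is.null(memo[[key]])) return(memo[[key]])
  memo[[key]] <- list()   # guard (no epsilon/unit rules -> no real cycles)
  r <- grammar$rules
  out <- list()
  for (i in which(r$lhs == sym)) {
    if (r$kind[i] == "UNPAIRED") {
      if (n == 1) out[[length(out) + 1]] <- list(str = ".", rules = i)
    } else if (r$kind[i] == "PAIR") {
      if (n >= 3)
        for (d in oracle_derivations(grammar, n - 2, r$c1[i], memo))
          out[[length(out) + 1]] <-
            list(str = paste0("(", d$str, ")"), rules = c(i, d$rules))
    } else {
      if (n >= 2)
        for (k in 1:(n - 1))
          for (da in oracle_derivations(grammar, k, r$c1[i], memo))
            for (db in oracle_derivations(grammar, n - k, r$c2[i], memo))
              out[[length(out) + 1]] <-
                list(str = paste0(da$str, db$str),
                     rules = c(i, da$rules, db$rules))
    }
  }
  memo[[key]] <- out
  out
}

oracle_deriv_logp <- function(deriv, params) {
  sum(log(params$rule_prob[deriv$rules]))
}

# joint emission log-probability of a sequence given a derivation's structure
oracle_emission_logp <- function(structure_str, sequence, params) {
  st <- parse_dotbracket(structure_str)
  ch <- strsplit(sequence, "")[[1]]
  lp <- 0
  unp <- setdiff(seq_len(st$length), as.vector(st$pairs))
  for (i in unp) lp <- lp + log(params$unpaired_emit[[ch[i]]])
  if (nrow(st$pairs) > 0)
    for (a in seq_len(nrow(st$pairs)))
      lp <- lp + log(params$paired_emit[[paste0(ch[st$pairs[a, 1]],
                                                ch[st$pairs[a, 2]])]])
  lp
}

logsumexp <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# oracle quantities for one sequence: inside total, CYK max (+ structure),
# posterior pair probabilities
oracle_sequence <- function(grammar, params, sequence, memo = NULL) {
  n <- nchar(sequence)
  ders <- oracle_derivations(grammar, n)
  if (length(ders) == 0)
    return(list(total = -Inf, best = -Inf, best_structure = NA, pair = NULL))
  lp <- vapply(ders, function(d)
    oracle_deriv_logp(d, params) +
      oracle_emission_logp(d$str, sequence, params), numeric(1))
  total <- logsumexp(lp)
  pair <- matrix(0, n, n)
  for (q in seq_along(ders)) {
    st <- parse_dotbracket(ders[[q]]$str)
    if (nrow(st$pairs) > 0)
      pair[st$pairs] <- pair[st$pairs] + exp(lp[q] - total)
  }
  best <- which.max(lp)
  list(total = total, best = max(lp), best_structure = ders[[best]]$str,
       pair = pair)
}

# all non-crossing pair sets over n positions with loop length >= min_hairpin
oracle_all_matchings <- function(n, min_hairpin = 0) {
  if (n <= 0) return(list(matrix(integer(), 0, 2)))
  # position 1 unpaired: shift a matching of n-1 positions up by one
  res <- lapply(oracle_all_matchings(n - 1, min_hairpin), function(m) m + 1L)
  for (k in seq_len(n)) {
    if (k - 2 < min_hairpin) next
    inner <- oracle_all_matchings(k - 2, min_hairpin)
    rest <- oracle_all_matchings(n - k, min_hairpin)
    for (mi in inner) for (mr in rest) {
      m <- rbind(c(1L, k), mi + 1L, if (nrow(mr) > 0) mr + k else mr)
      res[[length(res) + 1]] <- matrix(as.integer(m), ncol = 2)
    }
  }
  res
}

oracle_best_mea <- function(pair_prob, q, gamma, min_hairpin = 0) {
  n <- length(q)
  best <- -Inf
  for (m in oracle_all_matchings(n, min_hairpin)) {
    unp <- setdiff(seq_len(n), as.vector(m))
    s <- sum(q[unp])
    if (nrow(m) > 0) s <- s + gamma * sum(pair_prob[m])
    if (s > best) best <- s
  }
  best
}

# quick record builder
rec <- function(sequence, structure_str, id = "r") {
  structured_seq(id, sequence, parse_dotbracket(structure_str))
}

random_sequence <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                            replace = TRUE), collapse = "")
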