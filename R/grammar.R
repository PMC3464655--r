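#' Construct an SCFG grammar in the double emission normal form
#'
#' A grammar is a set of non-terminal symbols with production rules restricted
#' to three shapes: `T -> U V` (branch), `T -> .` (unpaired emission) and
#' `T -> ( U )` (paired emission, producing both partners of a base pair in a
#' single production). The terminal alphabet is fixed to `(`, `)` and `.`.
#' Epsilon rules (`T -> ""`) and unit rules (`T -> U`) are outside the normal
#' form: they permit cyclic productions and countably infinite derivation sets.
#'
#' @param nonterminals character vector of non-terminal symbol names.
#' @param start the start symbol; must be one of `nonterminals`.
#' @param rules a data frame with columns `lhs`, `kind` (one of `"BRANCH"`,
#'   `"UNPAIRED"`, `"PAIR"`), `c1` and `c2` (child symbols; `NA` where unused:
#'   both for `UNPAIRED`, `c2` for `PAIR`).
#' @return An object of class `scfg_grammar` with elements `nonterminals`,
#'   `start` and `rules`.
#' @seealso [validate_normal_form()], [builtin_grammar()], [read_grammar()]
#' @examples
#' g <- scfg_grammar(c("S", "B"), "S",
#'                   rule_df(c("S", "S", "B"), c("PAIR", "UNPAIRED", "UNPAIRED"),
#'                           c("B", NA, NA)))
#' validate_normal_form(g)
#' @export
scfg_grammar <- function(nonterminals, start, rules) {
  stopifnot(is.character(nonterminals), length(nonterminals) >= 1,
            is.character(start), length(start) == 1)
  rules <- as.data.frame(rules, stringsAsFactors = FALSE)
  need <- c("lhs", "kind", "c1", "c2")
  if (!all(need %in% names(rules)))
    stop("rules must have columns lhs, kind, c1, c2")
  rules <- rules[need]
  rownames(rules) <- NULL
  g <- structure(list(nonterminals = nonterminals, start = start,
                      rules = rules),
                 class = "scfg_grammar")
  viol <- validate_normal_form(g)
  if (length(viol) > 0)
    stop("invalid grammar: ", paste(viol, collapse = "; "))
  g
}

#' Build a rule data frame
#'
#' Convenience constructor for the `rules` argument of [scfg_grammar()].
#'
#' @param lhs,kind,c1,c2 vectors recycled to a common length.
#' @return A data frame with columns `lhs`, `kind`, `c1`, `c2`.
#' @export
rule_df <- function(lhs = character(), kind = character(), c1 = NA_character_,
                    c2 = NA_character_) {
  data.frame(lhs = as.character(lhs), kind = as.character(kind),
             c1 = as.character(c1), c2 = as.character(c2),
             stringsAsFactors = FALSE)
}

rule_labels <- function(rules) {
  ifelse(rules$kind == "BRANCH",
         paste(rules$lhs, "->", rules$c1, rules$c2),
         ifelse(rules$kind == "PAIR",
                paste(rules$lhs, "-> (", rules$c1, ")"),
                paste(rules$lhs, "-> .")))
}

#' @export
print.scfg_grammar <- function(x, ...) {
  cat("SCFG grammar (double emission normal form)\n")
  cat("  start:", x$start, "  non-terminals:",
      paste(x$nonterminals, collapse = " "), "\n")
  for (nt in x$nonterminals) {
    sub <- x$rules[x$rules$lhs == nt, , drop = FALSE]
    if (nrow(sub) == 0) next
    alts <- ifelse(sub$kind == "BRANCH", paste(sub$c1, sub$c2),
                   ifelse(sub$kind == "PAIR", paste0("( ", sub$c1, " )"), "."))
    cat(" ", nt, "->", paste(alts, collapse = " | "), "\n")
  }
  invisible(x)
}

#' Check conformance with the double emission normal form
#'
#' Returns a character vector of violation descriptions; an empty vector means
#' the grammar is valid. Checked: the start symbol and all rule symbols are
#' declared non-terminals; every rule is exactly one of the three normal-form
#' shapes; no duplicate rules; the start symbol has at least one rule.
#'
#' @param grammar an `scfg_grammar` (or a bare list with the same fields, so
#'   that malformed candidates can be diagnosed rather than rejected upstream).
#' @return Character vector of human-readable violations (empty if valid).
#' @export
validate_normal_form <- function(grammar) {
  v <- character()
  nts <- grammar$nonterminals
  r <- grammar$rules
  if (anyDuplicated(nts))
    v <- c(v, "duplicate non-terminal names")
  if (!(grammar$start %in% nts))
    v <- c(v, sprintf("start symbol %s not among non-terminals", grammar$start))
  bad_kind <- !(r$kind %in% c("BRANCH", "UNPAIRED", "PAIR"))
  for (i in which(bad_kind))
    v <- c(v, sprintf("rule %d has unknown kind %s (epsilon and unit rules are outside the normal form)",
                      i, r$kind[i]))
  ok <- !bad_kind
  for (i in which(ok)) {
    k <- r$kind[i]
    if (!(r$lhs[i] %in% nts))
      v <- c(v, sprintf("rule lhs %s is not a declared non-terminal", r$lhs[i]))
    if (k == "UNPAIRED") {
      if (!is.na(r$c1[i]) || !is.na(r$c2[i]))
        v <- c(v, sprintf("unpaired rule %s has children", r$lhs[i]))
    } else if (k == "PAIR") {
      if (is.na(r$c1[i]) || !is.na(r$c2[i]))
        v <- c(v, sprintf("pair rule of %s must have exactly one child", r$lhs[i]))
      else if (!(r$c1[i] %in% nts))
        v <- c(v, sprintf("rule child %s is not a declared non-terminal", r$c1[i]))
    } else {
      if (is.na(r$c1[i]) || is.na(r$c2[i]))
        v <- c(v, sprintf("branch rule of %s must have two children", r$lhs[i]))
      else {
        if (!(r$c1[i] %in% nts))
          v <- c(v, sprintf("rule child %s is not a declared non-terminal", r$c1[i]))
        if (!(r$c2[i] %in% nts))
          v <- c(v, sprintf("rule child %s is not a declared non-terminal", r$c2[i]))
      }
    }
  }
  if (anyDuplicated(rule_labels(r)))
    v <- c(v, sprintf("duplicate rule %s",
                      rule_labels(r)[duplicated(rule_labels(r))][1]))
  if (grammar$start %in% nts && sum(r$lhs == grammar$start) == 0)
    v <- c(v, "unproductive start: the start symbol has no production rules")
  v
}

#' Size of the grammar space for m non-terminals
#'
#' Over `m` non-terminal variables the normal form admits `m^3` branch rules,
#' `m^2` pair rules and `m` unpaired rules; every subset of these is a grammar,
#' so the space holds `2^(m^3 + m^2 + m)` grammars. The value is returned as a
#' double; powers of two are exactly representable up to exponent 1023
#' (`m <= 9`), beyond which `Inf` is returned.
#'
#' @param m number of non-terminal variables (positive integer).
#' @return `2^(m^3 + m^2 + m)` as a double.
#' @examples
#' count_grammar_space(2) # 16384: small enough for brute-force search
#' count_grammar_space(3) # ~5.5e11: already out of exhaustive reach
#' @export
count_grammar_space <- function(m) {
  if (!is.numeric(m) || length(m) != 1 || is.na(m) || m < 1 || m != round(m))
    stop("m must be a positive integer")
  2^(m^3 + m^2 + m)
}

#' All normal-form rules over a symbol set
#'
#' @param nonterminals character vector of symbols.
#' @return A rule data frame holding every `T -> U V`, `T -> .` and
#'   `T -> ( U )` over the given symbols (`m^3 + m^2 + m` rows).
#' @export
all_normal_form_rules <- function(nonterminals) {
  nts <- nonterminals
  br <- expand.grid(lhs = nts, c1 = nts, c2 = nts, stringsAsFactors = FALSE,
                    KEEP.OUT.ATTRS = FALSE)
  pr <- expand.grid(lhs = nts, c1 = nts, stringsAsFactors = FALSE,
                    KEEP.OUT.ATTRS = FALSE)
  rbind(rule_df(br$lhs, "BRANCH", br$c1, br$c2),
        rule_df(pr$lhs, "PAIR", pr$c1),
        rule_df(nts, "UNPAIRED"))
}

#' Rules that can be added to a grammar
#'
#' All normal-form rules over the grammar's existing non-terminals that are
#' not already present. The count is always `m^3 + m^2 + m - |rules|`.
#'
#' @param grammar a valid `scfg_grammar`.
#' @return A rule data frame of addable rules.
#' @examples
#' nrow(addable_rules(builtin_grammar("KH99p"))) # 32
#' @export
addable_rules <- function(grammar) {
  viol <- validate_normal_form(grammar)
  if (length(viol) > 0)
    stop("invalid grammar: ", viol[1])
  all <- all_normal_form_rules(grammar$nonterminals)
  all[!(rule_labels(all) %in% rule_labels(grammar$rules)), , drop = FALSE]
}

#' Order-insensitive grammar equality
#'
#' Two grammars are equal when they have the same start symbol, the same set
#' of non-terminal names and the same set of rules; the order of rules and of
#' the non-terminal list is ignored, but symbol names matter.
#'
#' @param g1,g2 `scfg_grammar` objects.
#' @return Logical scalar.
#' @export
grammar_equal <- function(g1, g2) {
  identical(g1$start, g2$start) &&
    setequal(g1$nonterminals, g2$nonterminals) &&
    setequal(rule_labels(g1$rules), rule_labels(g2$rules))
}

# ---------------------------------------------------------------------------

#' Bundled reference grammars
#'
#' Returns one of the bundled grammars by name: `"KH99p"`, the Knudsen-Hein
#' grammar (used by Pfold) rewritten in the double emission normal form, or
#' `"GG1"` to `"GG6"`, grammars discovered by evolutionary search over the
#' normal-form grammar space. All use start symbol `A`. They are stored as
#' plain-text fixtures under `inst/extdata/grammars` in the package's grammar
#' file format and parsed on access.
#'
#' @param name one of `"KH99p"`, `"GG1"`, ..., `"GG6"`.
#' @return An `scfg_grammar`.
#' @examples
#' builtin_grammar("KH99p")
#' @export
builtin_grammar <- function(name) {
  known <- c("KH99p", paste0("GG", 1:6))
  if (!(is.character(name) && length(name) == 1 && name %in% known))
    stop("unknown grammar name; expected one of: ", paste(known, collapse = ", "))
  path <- system.file("extdata", "grammars", paste0(name, ".txt"),
                      package = "rnascfg", mustWork = TRUE)
  read_grammar(path)$grammar
}

# ---------------------------------------------------------------------------
# Grammar text format:
#   # comment
#   start: A
#   A -> B A [0.5] | . [0.2] | ( C ) [0.3]
#   ...
#   unpaired: A 0.25 C 0.25 G 0.25 U 0.25
#   paired: AA 0.01 AC 0.02 ... UU 0.03
# Probability suffixes and the emission blocks are optional; tokens are
# whitespace-separated.

#' Read a grammar (and optional parameters) from a text file
#'
#' The format has an optional leading comment block (`#` lines), a
#' `start: <sym>` line, one `"<sym> -> alt | alt | ..."` line per
#' non-terminal (alternatives are `U V`, `.`, or `( U )`, tokens
#' whitespace-separated, each optionally followed by a `[p]` probability),
#' and optional `unpaired:` / `paired:` emission lines. When any probability
#' is present, a full parameter set is required and each non-terminal's rule
#' probabilities must sum to 1 within 1e-6.
#'
#' @param path file path.
#' @return A list with elements `grammar` (an `scfg_grammar`) and `params`
#'   (an `scfg_params`, or `NULL` when the file carries no probabilities).
#' @seealso [write_grammar()]
#' @export
read_grammar <- function(path) {
  lines <- readLines(path)
  start <- NULL
  lhs <- kind <- c1 <- c2 <- character()
  probs <- numeric()
  unpaired <- paired <- NULL
  seen_lhs <- character()
  for (ln in seq_along(lines)) {
    line <- sub("#.*$", "", lines[ln])
    if (grepl("^\\s*$", line)) next
    if (grepl("^\\s*start\\s*:", line)) {
      start <- trimws(sub("^\\s*start\\s*:", "", line))
      if (!grepl("^\\S+$", start))
        stop(sprintf("line %d: start symbol must be a single token", ln))
      next
    }
    if (grepl("^\\s*unpaired\\s*:", line)) {
      unpaired <- parse_emission_line(line, ln, NUCS)
      next
    }
    if (grepl("^\\s*paired\\s*:", line)) {
      paired <- parse_emission_line(line, ln, PAIR_NAMES)
      next
    }
    if (!grepl("->", line, fixed = TRUE))
      stop(sprintf("line %d: expected a production line containing '->'", ln))
    parts <- strsplit(line, "->", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop(sprintf("line %d: malformed production line", ln))
    sym <- trimws(parts[1])
    if (!grepl("^\\S+$", sym))
      stop(sprintf("line %d: left-hand side must be a single token", ln))
    if (sym %in% seen_lhs)
      stop(sprintf("line %d: duplicate production line for %s", ln, sym))
    seen_lhs <- c(seen_lhs, sym)
    for (alt in strsplit(parts[2], "|", fixed = TRUE)[[1]]) {
      p <- NA_real_
      m <- regmatches(alt, regexec("\\[\\s*([0-9.eE+-]+)\\s*\\]\\s*$", alt))[[1]]
      if (length(m) == 2) {
        p <- as.numeric(m[2])
        alt <- sub("\\[[^]]*\\]\\s*$", "", alt)
      }
      toks <- strsplit(trimws(alt), "\\s+")[[1]]
      toks <- toks[nzchar(toks)]
      if (length(toks) == 1 && toks == ".") {
        lhs <- c(lhs, sym); kind <- c(kind, "UNPAIRED")
        c1 <- c(c1, NA_character_); c2 <- c(c2, NA_character_)
      } else if (length(toks) == 3 && toks[1] == "(" && toks[3] == ")") {
        lhs <- c(lhs, sym); kind <- c(kind, "PAIR")
        c1 <- c(c1, toks[2]); c2 <- c(c2, NA_character_)
      } else if (length(toks) == 2 && !any(toks %in% c("(", ")", "."))) {
        lhs <- c(lhs, sym); kind <- c(kind, "BRANCH")
        c1 <- c(c1, toks[1]); c2 <- c(c2, toks[2])
      } else {
        stop(sprintf(
          "line %d: alternative '%s' of %s is not a normal-form rule (expected 'U V', '.', or '( U )')",
          ln, trimws(alt), sym))
      }
      probs <- c(probs, p)
    }
  }
  if (is.null(start)) stop("missing 'start:' line")
  g <- scfg_grammar(seen_lhs, start, rule_df(lhs, kind, c1, c2))
  params <- NULL
  if (any(!is.na(probs)) || !is.null(unpaired) || !is.null(paired)) {
    if (any(is.na(probs)))
      stop("probabilities must be given for all rules or none")
    if (is.null(unpaired) || is.null(paired))
      stop("files with rule probabilities must also give unpaired: and paired: emissions")
    for (nt in unique(lhs)) {
      s <- sum(probs[lhs == nt])
      if (abs(s - 1) > 1e-6)
        stop(sprintf("rule probabilities of %s sum to %.8f, not 1", nt, s))
    }
    params <- scfg_params(g, probs, unpaired, paired)
  }
  list(grammar = g, params = params)
}

parse_emission_line <- function(line, ln, expected_names) {
  body <- sub("^[^:]*:", "", line)
  toks <- strsplit(trimws(body), "\\s+")[[1]]
  if (length(toks) != 2 * length(expected_names))
    stop(sprintf("line %d: expected %d name/probability pairs", ln,
                 length(expected_names)))
  nm <- toks[seq(1, length(toks), by = 2)]
  val <- as.numeric(toks[seq(2, length(toks), by = 2)])
  if (!setequal(nm, expected_names) || anyNA(val))
    stop(sprintf("line %d: malformed emission table", ln))
  setNames(val, nm)[expected_names]
}

#' Write a grammar (and optional parameters) to a text file
#'
#' @param grammar an `scfg_grammar`.
#' @param path output file path.
#' @param params optional `scfg_params`; when given, `[p]` suffixes and the
#'   emission blocks are written with 15 significant digits so that a
#'   read/write round trip preserves probabilities.
#' @return `path`, invisibly.
#' @export
write_grammar <- function(grammar, path, params = NULL) {
  out <- c(paste("start:", grammar$start))
  r <- grammar$rules
  for (nt in grammar$nonterminals) {
    idx <- which(r$lhs == nt)
    if (length(idx) == 0) next
    alts <- vapply(idx, function(i) {
      a <- switch(r$kind[i],
                  BRANCH = paste(r$c1[i], r$c2[i]),
                  PAIR = paste0("( ", r$c1[i], " )"),
                  UNPAIRED = ".")
      if (!is.null(params))
        a <- sprintf("%s [%.15g]", a, params$rule_prob[i])
      a
    }, character(1))
    out <- c(out, paste(nt, "->", paste(alts, collapse = " | ")))
  }
  if (!is.null(params)) {
    out <- c(out,
             paste("unpaired:", paste(sprintf("%s %.15g", NUCS,
                                              params$unpaired_emit),
                                      collapse = " ")),
             paste("paired:", paste(sprintf("%s %.15g", PAIR_NAMES,
                                            params$paired_emit),
                                    collapse = " ")))
  }
  writeLines(out, path)
  invisible(path)
}
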