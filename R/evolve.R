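# Search over grammar space: an evolutionary algorithm (mutation, breeding,
# stochastic-elimination selection with single-champion elitism), brute-force
# enumeration of two-non-terminal grammars, and local add/delete search
# around a grammar. All randomness flows through R's RNG: set.seed() (or the
# config seed) makes runs fully reproducible.

WORST_FITNESS <- 1e12   # sentinel for grammars that cannot be trained at all

#' Configuration for the evolutionary search
#'
#' @param population_size grammars kept after each selection step
#'   (default 16).
#' @param generations number of generations.
#' @param offspring_per_generation new grammars created per generation
#'   (default 8).
#' @param mutation_weights nonnegative weights over the five mutation types:
#'   start change, rule addition, rule deletion, new non-terminal (fresh or
#'   duplicated), rule rewiring — see [mutate_grammar()].
#' @param breed_fraction probability that an offspring is bred from two
#'   parents rather than mutated from one (default 0.25).
#' @param fitness one of `"MOUNTAIN"`, `"SENSITIVITY"`, `"PPV"`, `"FSCORE"`,
#'   `"COMPOSITE"`; lower fitness is always better (score-type metrics are
#'   negated).
#' @param composite_terms for `"COMPOSITE"`: named weights `longest` (reward
#'   per position of the longest fully correctly predicted structure),
#'   `failure` (penalty per failed prediction) and `complexity` (cost per
#'   production rule).
#' @param training_method `"CYK"` (supervised counting on the trusted
#'   structures) or `"IO"` (inside-outside EM on the sequences).
#' @param prediction_method `"CYK"` or `"MEA"`.
#' @param gamma MEA trade-off weight (default 2, maximising the expected
#'   number of correctly predicted positions).
#' @param seed integer RNG seed for the whole run.
#' @return A list of class `evolution_config`.
#' @export
evolution_config <- function(population_size = 16, generations = 50,
                             offspring_per_generation = 8,
                             mutation_weights = c(start = 0.05, add = 0.4,
                                                  delete = 0.1, new_nt = 0.25,
                                                  rewire = 0.2),
                             breed_fraction = 0.25,
                             fitness = c("FSCORE", "MOUNTAIN", "SENSITIVITY",
                                         "PPV", "COMPOSITE"),
                             composite_terms = c(longest = 0, failure = 0.1,
                                                 complexity = 0.01),
                             training_method = c("CYK", "IO"),
                             prediction_method = c("CYK", "MEA"),
                             gamma = 2, seed = 1L) {
  fitness <- match.arg(fitness)
  stopifnot(population_size >= 2, length(mutation_weights) == 5,
            all(mutation_weights >= 0), sum(mutation_weights) > 0,
            breed_fraction >= 0, breed_fraction <= 1, gamma > 0)
  structure(list(population_size = population_size, generations = generations,
                 offspring_per_generation = offspring_per_generation,
                 mutation_weights = mutation_weights,
                 breed_fraction = breed_fraction, fitness = fitness,
                 composite_terms = composite_terms,
                 training_method = match.arg(training_method),
                 prediction_method = match.arg(prediction_method),
                 gamma = gamma, seed = as.integer(seed)),
            class = "evolution_config")
}

#' The sixteen-grammar initial population
#'
#' Small two-symbol grammars built from the template
#' `S -> SS | SB | BS | BB | (S) | .` with `B -> .`, where every subset of
#' the four branch rules (from none to all four) is excluded — 2^4 = 16
#' distinct grammars. The population starts small and grows non-terminals
#' and rules through mutation and breeding.
#'
#' @return A list of 16 `scfg_grammar` objects.
#' @export
initial_population <- function() {
  branches <- list(c("S", "S"), c("S", "B"), c("B", "S"), c("B", "B"))
  subsets <- expand.grid(rep(list(c(TRUE, FALSE)), 4))
  lapply(seq_len(nrow(subsets)), function(k) {
    keep <- branches[as.logical(subsets[k, ])]
    rules <- rbind(rule_df("S", "PAIR", "S"),
                   rule_df(c("S", "B"), "UNPAIRED"))
    if (length(keep) > 0)
      rules <- rbind(rule_df("S", "BRANCH",
                             vapply(keep, `[`, character(1), 1),
                             vapply(keep, `[`, character(1), 2)),
                     rules)
    scfg_grammar(c("S", "B"), "S", rules)
  })
}

fresh_symbol <- function(grammar) {
  pool <- c(setdiff(LETTERS, c(grammar$nonterminals)),
            paste0("V", 1:999))
  setdiff(pool, grammar$nonterminals)[1]
}

#' Mutate a grammar
#'
#' Applies one stochastic mutation, drawn from five types with the given
#' weights:
#' \enumerate{
#'   \item start change: another non-terminal becomes the start symbol;
#'   \item rule addition: a rule from [addable_rules()] is inserted;
#'   \item rule deletion: a rule is removed (never `B -> .`, and never the
#'     last rule of a non-terminal);
#'   \item new non-terminal: either a fresh symbol added with two new rules
#'     guaranteeing it is reachable from the start and has a non-empty rule
#'     set, or a duplicate of an existing non-terminal's rule set;
#'   \item rewiring: one child symbol of a branch or pair rule is replaced.
#' }
#' The helper rule `B -> .` is kept constant throughout the evolutionary
#' process. Inapplicable draws (e.g. deletion on a minimal grammar) are
#' resampled among the remaining types; an error is raised only when no type
#' applies. The output is always a valid normal-form grammar.
#'
#' @param grammar a valid `scfg_grammar` containing the rule `B -> .`.
#' @param weights nonnegative weights (start, add, delete, new_nt, rewire).
#' @return A mutated `scfg_grammar`.
#' @export
mutate_grammar <- function(grammar,
                           weights = c(start = 0.05, add = 0.4, delete = 0.1,
                                       new_nt = 0.25, rewire = 0.2)) {
  stopifnot(length(weights) == 5, all(weights >= 0), sum(weights) > 0)
  types <- c("start", "add", "delete", "new_nt", "rewire")
  w <- as.numeric(weights)
  tried <- logical(5)
  repeat {
    avail <- which(!tried & w > 0)
    if (length(avail) == 0)
      stop("no applicable mutation for this grammar")
    t <- avail[sample.int(length(avail), 1, prob = w[avail])]
    out <- switch(types[t],
                  start = mut_start(grammar),
                  add = mut_add(grammar),
                  delete = mut_delete(grammar),
                  new_nt = mut_new_nt(grammar),
                  rewire = mut_rewire(grammar))
    if (!is.null(out)) return(out)
    tried[t] <- TRUE
  }
}

mut_start <- function(g) {
  # candidates: non-terminals with at least one rule, other than the start
  cand <- setdiff(unique(g$rules$lhs), g$start)
  if (length(cand) == 0) return(NULL)
  g$start <- cand[sample.int(length(cand), 1)]
  g
}

mut_add <- function(g) {
  add <- addable_rules(g)
  if (nrow(add) == 0) return(NULL)
  g$rules <- rbind(g$rules, add[sample.int(nrow(add), 1), ])
  rownames(g$rules) <- NULL
  g
}

mut_delete <- function(g) {
  r <- g$rules
  protected <- r$lhs == "B" & r$kind == "UNPAIRED"
  # a deletion may not leave any non-terminal with an empty rule set
  last_of_nt <- vapply(seq_len(nrow(r)), function(i)
    sum(r$lhs == r$lhs[i]) == 1, logical(1))
  cand <- which(!protected & !last_of_nt)
  if (length(cand) == 0) return(NULL)
  g$rules <- r[-cand[sample.int(length(cand), 1)], , drop = FALSE]
  rownames(g$rules) <- NULL
  g
}

mut_new_nt <- function(g) {
  v <- fresh_symbol(g)
  if (runif(1) < 0.5) {
    # duplicate: new symbol with rules identical to an existing one's
    src <- unique(g$rules$lhs)
    src <- src[sample.int(length(src), 1)]
    new_rules <- g$rules[g$rules$lhs == src, , drop = FALSE]
    new_rules$lhs <- v
    g$nonterminals <- c(g$nonterminals, v)
    g$rules <- rbind(g$rules, new_rules)
  } else {
    # fresh symbol: one rule making v reachable from an existing productive
    # non-terminal, one rule giving v a non-empty rule set
    g$nonterminals <- c(g$nonterminals, v)
    host <- unique(g$rules$lhs)
    host <- host[sample.int(length(host), 1)]
    reach <- switch(sample.int(3, 1),
                    rule_df(host, "BRANCH", v,
                            g$nonterminals[sample.int(length(g$nonterminals), 1)]),
                    rule_df(host, "BRANCH",
                            g$nonterminals[sample.int(length(g$nonterminals), 1)], v),
                    rule_df(host, "PAIR", v))
    own_kind <- sample(c("BRANCH", "UNPAIRED", "PAIR"), 1)
    own <- switch(own_kind,
                  UNPAIRED = rule_df(v, "UNPAIRED"),
                  PAIR = rule_df(v, "PAIR",
                                 g$nonterminals[sample.int(length(g$nonterminals), 1)]),
                  BRANCH = rule_df(v, "BRANCH",
                                   g$nonterminals[sample.int(length(g$nonterminals), 1)],
                                   g$nonterminals[sample.int(length(g$nonterminals), 1)]))
    g$rules <- rbind(g$rules, reach, own)
  }
  rownames(g$rules) <- NULL
  if (anyDuplicated(rule_labels(g$rules))) return(NULL)
  g
}

mut_rewire <- function(g) {
  r <- g$rules
  cand <- which(r$kind %in% c("BRANCH", "PAIR"))
  if (length(cand) == 0) return(NULL)
  # try a few times to find a rewiring that does not duplicate a rule
  for (a in 1:10) {
    i <- cand[sample.int(length(cand), 1)]
    r2 <- r
    nts <- g$nonterminals
    if (r$kind[i] == "PAIR") {
      r2$c1[i] <- nts[sample.int(length(nts), 1)]
    } else if (runif(1) < 0.5) {
      r2$c1[i] <- nts[sample.int(length(nts), 1)]
    } else {
      r2$c2[i] <- nts[sample.int(length(nts), 1)]
    }
    if (!anyDuplicated(rule_labels(r2))) {
      g$rules <- r2
      return(g)
    }
  }
  NULL
}

#' Breed two grammars
#'
#' Produces a grammar able to derive every string either parent derives: the
#' child's start symbol `S` takes the union of both parents' start rules
#' (with each parent's start symbol renamed to `S`), the parents' remaining
#' non-terminals are namespaced apart (except the shared helper `B`), and
#' their rule sets carried over with the same start-symbol substitution.
#'
#' @param g1,g2 valid `scfg_grammar` objects.
#' @param start_symbol name of the child's start symbol (default `"S"`).
#' @return An `scfg_grammar`.
#' @export
breed_grammars <- function(g1, g2, start_symbol = "S") {
  rename <- function(g, suffix) {
    keep <- c(g$start, "B")
    map <- setNames(g$nonterminals, g$nonterminals)
    map[g$start] <- start_symbol
    others <- setdiff(g$nonterminals, keep)
    map[others] <- paste0(others, suffix)
    r <- g$rules
    r$lhs <- unname(map[r$lhs])
    r$c1 <- ifelse(is.na(r$c1), NA_character_, unname(map[r$c1]))
    r$c2 <- ifelse(is.na(r$c2), NA_character_, unname(map[r$c2]))
    list(nts = unname(map), rules = r)
  }
  a <- rename(g1, "1")
  b <- rename(g2, "2")
  rules <- rbind(a$rules, b$rules)
  rules <- rules[!duplicated(rule_labels(rules)), , drop = FALSE]
  rownames(rules) <- NULL
  nts <- unique(c(start_symbol, a$nts, b$nts))
  scfg_grammar(nts, start_symbol, rules)
}

#' Fitness of a grammar on a training set
#'
#' Trains parameters on the records (per `config$training_method`), predicts
#' each record's structure (per `config$prediction_method`), and scores the
#' predictions against the trusted structures. Fitness is oriented so that
#' lower is better: `MOUNTAIN` is the summed mountain-metric distance;
#' `SENSITIVITY`, `PPV` and `FSCORE` are negated micro-averaged metrics;
#' `COMPOSITE` is the negated F-score plus a failure penalty, a complexity
#' cost of `complexity * |rules|`, and minus `longest * (longest fully
#' correct structure length)`. A grammar that can parse no training
#' structure at all receives a worst-case sentinel fitness rather than an
#' error.
#'
#' @param grammar an `scfg_grammar`.
#' @param train_records list of `structured_seq`.
#' @param config an `evolution_config`.
#' @return A single fitness value (lower is better).
#' @export
evaluate_fitness <- function(grammar, train_records, config) {
  stopifnot(length(train_records) > 0)
  params <- tryCatch(
    suppressWarnings(
      if (config$training_method == "CYK")
        supervised_train(grammar, train_records)
      else
        em_train(grammar, train_records, max_iters = 10)$params),
    error = function(e) NULL)
  if (is.null(params)) return(WORST_FITNESS)
  preds <- lapply(train_records, function(rec) {
    if (config$prediction_method == "CYK")
      predict_cyk(grammar, params, rec$sequence)
    else
      predict_mea(grammar, params, rec$sequence, gamma = config$gamma)
  })
  fitness_from_predictions(grammar, train_records, preds, config)
}

fitness_from_predictions <- function(grammar, records, preds, config) {
  if (config$fitness == "MOUNTAIN") {
    return(sum(mapply(function(rec, pr)
      mountain_distance(pr$structure, rec$structure), records, preds)))
  }
  m <- aggregate_metrics(records, preds)
  base <- switch(config$fitness,
                 SENSITIVITY = -m$sensitivity,
                 PPV = -m$ppv,
                 FSCORE = -m$fscore,
                 COMPOSITE = -m$fscore)
  if (config$fitness == "COMPOSITE") {
    ct <- config$composite_terms
    failed <- sum(vapply(preds, `[[`, logical(1), "failed"))
    correct_len <- mapply(function(rec, pr) {
      r <- compare_structures(pr$structure, rec$structure)
      if (r$fp == 0 && r$fn == 0) rec$structure$length else 0
    }, records, preds)
    base <- base + ct[["failure"]] * failed +
      ct[["complexity"]] * nrow(grammar$rules) -
      ct[["longest"]] * max(c(0, correct_len))
  }
  base
}

#' Stochastic-elimination selection
#'
#' Repeatedly eliminates one grammar until `target_size` remain. The
#' single-step elimination probability is proportional to
#' `fitness - best_fitness + epsilon` (lower fitness is better, so worse
#' grammars are removed preferentially; the shift makes the rule scale-free
#' and never stalls on equal fitness). The current best grammar is protected
#' from elimination (elitism of size one; ties resolved to the first).
#'
#' @param population list of elements `list(grammar =, fitness =)`.
#' @param target_size size after selection.
#' @param epsilon additive floor on elimination weights (default 1e-6).
#' @return The surviving population, input order preserved.
#' @export
select_population <- function(population, target_size, epsilon = 1e-6) {
  stopifnot(length(population) >= target_size)
  while (length(population) > target_size) {
    f <- vapply(population, `[[`, numeric(1), "fitness")
    best <- which.min(f)
    w <- f - min(f) + epsilon
    w[best] <- 0
    victim <- sample.int(length(population), 1, prob = w)
    population <- population[-victim]
  }
  population
}

#' Run the evolutionary search over grammar space
#'
#' Starts from [initial_population()] (or a supplied one), and per
#' generation creates `offspring_per_generation` new grammars — each bred
#' from two random parents with probability `breed_fraction`, otherwise
#' mutated from one — evaluates their fitness on `train_records`, and pares
#' the population back to `population_size` by [select_population()]. The
#' champion (best grammar ever evaluated) and per-generation history are
#' tracked; the champion fitness sequence is non-increasing by construction.
#' Fully reproducible given `config$seed`.
#'
#' @param train_records list of `structured_seq` used for training and
#'   fitness.
#' @param config an `evolution_config`.
#' @param population optional starting population (list of `scfg_grammar`).
#' @return A list of class `search_state` with `population` (list of
#'   `list(grammar, fitness)`), `champion`, and `history` (data frame with
#'   `generation`, `mean_fitness`, `champion_fitness`).
#' @export
run_evolution <- function(train_records, config, population = NULL) {
  if (config$generations < 1) stop("generations must be >= 1")
  set.seed(config$seed)
  grams <- if (is.null(population)) initial_population() else population
  pop <- lapply(grams, function(g)
    list(grammar = g, fitness = evaluate_fitness(g, train_records, config)))
  champ <- pop[[which.min(vapply(pop, `[[`, numeric(1), "fitness"))]]
  hist <- data.frame(generation = integer(), mean_fitness = numeric(),
                     champion_fitness = numeric())
  for (gen in seq_len(config$generations)) {
    for (o in seq_len(config$offspring_per_generation)) {
      child <- NULL
      if (runif(1) < config$breed_fraction && length(pop) >= 2) {
        pick <- sample.int(length(pop), 2)
        child <- tryCatch(breed_grammars(pop[[pick[1]]]$grammar,
                                         pop[[pick[2]]]$grammar),
                          error = function(e) NULL)
      } else {
        parent <- pop[[sample.int(length(pop), 1)]]$grammar
        child <- tryCatch(mutate_grammar(parent, config$mutation_weights),
                          error = function(e) NULL)
      }
      if (is.null(child)) next
      fit <- evaluate_fitness(child, train_records, config)
      pop[[length(pop) + 1]] <- list(grammar = child, fitness = fit)
      if (fit < champ$fitness)
        champ <- list(grammar = child, fitness = fit)
    }
    pop <- select_population(pop, config$population_size)
    hist <- rbind(hist, data.frame(
      generation = gen,
      mean_fitness = mean(vapply(pop, `[[`, numeric(1), "fitness")),
      champion_fitness = champ$fitness))
  }
  structure(list(population = pop, champion = champ, history = hist,
                 config = config),
            class = "search_state")
}

#' @export
print.search_state <- function(x, ...) {
  cat(sprintf("SCFG search state: %d grammars, %d generations, champion fitness %.4f\n",
              length(x$population), nrow(x$history), x$champion$fitness))
  invisible(x)
}

# ---------------------------------------------------------------------------

#' Enumerate the two-non-terminal grammar space
#'
#' The normal form admits 14 rules over two non-terminals (8 branch, 4 pair,
#' 2 unpaired); every one of the 2^14 = 16384 subsets, together with the
#' fixed helper rule `B -> .` (whose symbol the enumerated rules never
#' reference), is a candidate grammar with start symbol `S`.
#'
#' @param symbols the two variable non-terminal names (default `S`, `T`).
#' @return A list of 16384 rule data frames (the subsets, excluding
#'   `B -> .`); subsets whose start symbol has no rule yield grammars that
#'   derive nothing and are still included.
#' @export
two_nonterminal_rulesets <- function(symbols = c("S", "T")) {
  all <- all_normal_form_rules(symbols)
  stopifnot(nrow(all) == 14)
  lapply(0:(2^14 - 1), function(mask) {
    all[bitwAnd(mask, bitwShiftL(1L, 0:13)) != 0, , drop = FALSE]
  })
}

#' Brute-force search over two-non-terminal grammars
#'
#' Builds every grammar from [two_nonterminal_rulesets()] plus the fixed
#' `B -> .`, trains and evaluates each on the given records, and returns
#' them ranked by sensitivity. Grammars whose start symbol cannot derive any
#' training structure get zero metrics without training. `budget` caps the
#' number of candidate grammars evaluated (in enumeration order) so that
#' partial sweeps are possible.
#'
#' @param train_records records used for training and evaluation.
#' @param config an `evolution_config` (training/prediction settings).
#' @param budget number of grammars from the enumeration to process
#'   (default all 16384).
#' @return A data frame with columns `index`, `n_rules`, `sensitivity`,
#'   `ppv`, `fscore` sorted by decreasing sensitivity, with the grammar list
#'   as attribute `grammars`.
#' @export
brute_force_space <- function(train_records, config = evolution_config(),
                              budget = 16384) {
  sets <- two_nonterminal_rulesets()
  sets <- sets[seq_len(min(budget, length(sets)))]
  grams <- vector("list", length(sets))
  rows <- vector("list", length(sets))
  for (k in seq_along(sets)) {
    rules <- rbind(sets[[k]], rule_df("B", "UNPAIRED"))
    rownames(rules) <- NULL
    # constructed directly: subsets without any start rule are legitimate
    # members of the enumeration (they derive nothing and score zero)
    g <- structure(list(nonterminals = c("S", "T", "B"), start = "S",
                        rules = rules),
                   class = "scfg_grammar")
    grams[[k]] <- g
    m <- evaluate_grammar_on(g, train_records, config)
    rows[[k]] <- data.frame(index = k, n_rules = nrow(sets[[k]]),
                            sensitivity = m$sensitivity, ppv = m$ppv,
                            fscore = m$fscore)
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$sensitivity)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "grammars") <- grams[ord]
  out
}

# train + predict + aggregate; zero metrics when the grammar trains on
# nothing (start derives no training structure)
evaluate_grammar_on <- function(grammar, records, config) {
  if (sum(grammar$rules$lhs == grammar$start) == 0)
    return(metric_report(0, 0, sum(vapply(records, function(r)
      nrow(r$structure$pairs), numeric(1)))))
  params <- tryCatch(
    suppressWarnings(
      if (config$training_method == "CYK") supervised_train(grammar, records)
      else em_train(grammar, records, max_iters = 10)$params),
    error = function(e) NULL)
  if (is.null(params)) {
    fn <- sum(vapply(records, function(r) nrow(r$structure$pairs), numeric(1)))
    return(metric_report(0, 0, fn))
  }
  preds <- lapply(records, function(rec) {
    if (config$prediction_method == "CYK")
      predict_cyk(grammar, params, rec$sequence)
    else predict_mea(grammar, params, rec$sequence, gamma = config$gamma)
  })
  aggregate_metrics(records, preds)
}

#' Local search around a grammar
#'
#' Enumerates the one-rule-added (`"add1"`), two-rules-added (`"add2"`,
#' unordered pairs of distinct addable rules) or one-rule-deleted (`"del1"`,
#' `B -> .` protected) neighbourhood of a grammar. With `evaluate = TRUE`
#' each neighbour is trained and evaluated on the records.
#'
#' @param grammar a valid `scfg_grammar`.
#' @param depth `"add1"`, `"add2"` or `"del1"`.
#' @param train_records records for training/evaluation (only used when
#'   `evaluate = TRUE`).
#' @param config an `evolution_config`.
#' @param evaluate train and score each neighbour (default `TRUE`).
#' @return A list of `list(grammar, metrics)` (metrics `NULL` when
#'   `evaluate = FALSE`).
#' @export
local_search <- function(grammar, depth = c("add1", "add2", "del1"),
                         train_records = NULL, config = evolution_config(),
                         evaluate = TRUE) {
  depth <- match.arg(depth)
  grams <- local_search_grammars(grammar, depth)
  lapply(grams, function(g) {
    m <- if (evaluate) evaluate_grammar_on(g, train_records, config) else NULL
    list(grammar = g, metrics = m)
  })
}

#' Neighbourhood grammars for local search
#'
#' @inheritParams local_search
#' @return A list of `scfg_grammar` objects: one per addable rule
#'   (`"add1"`), one per unordered pair of distinct addable rules
#'   (`"add2"`), or one per deletable rule (`"del1"`; `B -> .` is
#'   protected and the last rule of a non-terminal cannot be deleted).
#' @export
local_search_grammars <- function(grammar, depth = c("add1", "add2", "del1")) {
  depth <- match.arg(depth)
  add <- addable_rules(grammar)
  with_rules <- function(extra) {
    g <- grammar
    g$rules <- rbind(g$rules, extra)
    rownames(g$rules) <- NULL
    g
  }
  if (depth == "add1") {
    lapply(seq_len(nrow(add)), function(i) with_rules(add[i, ]))
  } else if (depth == "add2") {
    pairs <- combn(nrow(add), 2)
    lapply(seq_len(ncol(pairs)), function(k)
      with_rules(add[pairs[, k], ]))
  } else {
    r <- grammar$rules
    protected <- r$lhs == "B" & r$kind == "UNPAIRED"
    last_of_nt <- vapply(seq_len(nrow(r)), function(i)
      sum(r$lhs == r$lhs[i]) == 1, logical(1))
    cand <- which(!protected & !last_of_nt)
    lapply(cand, function(i) {
      g <- grammar
      g$rules <- r[-i, , drop = FALSE]
      rownames(g$rules) <- NULL
      g
    })
  }
}
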