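make_train_set <- function(n = 12, max_len = 25, seed = 99) {
  kh <- toy_kh()
  set.seed(seed)
  sample_records(kh$grammar, kh$params, n, max_len = max_len)
}

test_that("the initial population holds the sixteen template grammars", {
  pop <- initial_population()
  expect_length(pop, 16)
  labs <- lapply(pop, function(g) rnascfg:::rule_labels(g$rules))
  # all distinct, all valid, all contain the fixed core
  expect_equal(length(unique(lapply(labs, sort))), 16)
  for (g in pop) {
    expect_length(validate_normal_form(g), 0)
    l <- rnascfg:::rule_labels(g$rules)
    expect_true(all(c("S -> ( S )", "S -> .", "B -> .") %in% l))
    expect_true(all(g$rules$kind != "BRANCH" |
                      (g$rules$lhs == "S" &
                         g$rules$c1 %in% c("S", "B") &
                         g$rules$c2 %in% c("S", "B"))))
  }
  n_branch <- vapply(pop, function(g) sum(g$rules$kind == "BRANCH"),
                     numeric(1))
  expect_equal(sort(n_branch), rep(0:4, choose(4, 0:4)))
  expect_equal(sum(n_branch == 0), 1)
})

test_that("every mutation preserves validity and the fixed B -> . rule", {
  kh <- builtin_grammar("KH99p")
  set.seed(21)
  for (k in 1:400) {
    m <- mutate_grammar(kh)
    expect_length(validate_normal_form(m), 0)
    expect_true("B -> ." %in% rnascfg:::rule_labels(m$rules))
  }
  # targeted mutations
  set.seed(22)
  added <- mutate_grammar(kh, weights = c(0, 1, 0, 0, 0))
  expect_equal(nrow(added$rules), nrow(kh$rules) + 1)
  new_rule <- setdiff(rnascfg:::rule_labels(added$rules),
                      rnascfg:::rule_labels(kh$rules))
  expect_true(new_rule %in% rnascfg:::rule_labels(addable_rules(kh)))

  deleted <- mutate_grammar(kh, weights = c(0, 0, 1, 0, 0))
  expect_equal(nrow(deleted$rules), nrow(kh$rules) - 1)
  expect_true("B -> ." %in% rnascfg:::rule_labels(deleted$rules))

  set.seed(30)
  for (k in 1:40) {
    nn <- mutate_grammar(kh, weights = c(0, 0, 0, 1, 0))
    expect_equal(length(nn$nonterminals), 4)
    v <- setdiff(nn$nonterminals, kh$nonterminals)
    expect_gte(sum(nn$rules$lhs == v), 1)
  }

  sw <- mutate_grammar(kh, weights = c(1, 0, 0, 0, 0))
  expect_true(sw$start %in% c("B", "C"))
})

test_that("a duplicated non-terminal mirrors its source's rule set", {
  kh <- builtin_grammar("KH99p")
  set.seed(77)
  found <- FALSE
  for (k in 1:60) {
    m <- mutate_grammar(kh, weights = c(0, 0, 0, 1, 0))
    v <- setdiff(m$nonterminals, kh$nonterminals)
    dup_rules <- m$rules[m$rules$lhs == v, c("kind", "c1", "c2")]
    for (src in kh$nonterminals) {
      src_rules <- kh$rules[kh$rules$lhs == src, c("kind", "c1", "c2")]
      if (nrow(dup_rules) == nrow(src_rules) &&
          all(rnascfg:::rule_labels(cbind(lhs = "X", dup_rules)) %in%
              rnascfg:::rule_labels(cbind(lhs = "X", src_rules))))
        found <- TRUE
    }
    if (found) break
  }
  expect_true(found)
})

test_that("breeding unions the parents' start rules and preserves their languages", {
  g1 <- scfg_grammar(c("S1", "B"), "S1",
                     rule_df(c("S1", "S1", "B"),
                             c("PAIR", "UNPAIRED", "UNPAIRED"),
                             c("S1", NA, NA)))
  g2 <- scfg_grammar(c("S2", "B"), "S2",
                     rule_df(c("S2", "S2", "B"),
                             c("BRANCH", "UNPAIRED", "UNPAIRED"),
                             c("S2", NA, NA), c("B", NA, NA)))
  child <- breed_grammars(g1, g2)
  labs <- rnascfg:::rule_labels(child$rules)
  expect_true(all(c("S -> ( S )", "S -> .", "S -> S B", "B -> .") %in% labs))
  expect_length(validate_normal_form(child), 0)

  # the child derives samples from both parents
  set.seed(3)
  kh <- builtin_grammar("KH99p")
  gg4 <- builtin_grammar("GG4")
  bred <- breed_grammars(kh, gg4)
  expect_length(validate_normal_form(bred), 0)
  up_kh <- uniform_params(kh)
  draws <- unique(unlist(replicate(100, sample_structure(kh, kh99p_reference_params(), 20))))
  draws <- draws[!vapply(draws, is.null, logical(1))]
  for (s in draws)
    expect_gte(count_derivations(bred, s), 1)
  # breed(g, g) keeps g's language on samples
  self <- breed_grammars(kh, kh)
  for (s in draws)
    expect_gte(count_derivations(self, s), 1)
})

test_that("fitness is oriented lower-is-better with a sentinel for untrainable grammars", {
  recs <- make_train_set()
  cfg <- evolution_config(fitness = "FSCORE", generations = 1)
  kh <- builtin_grammar("KH99p")
  set.seed(5)
  f <- evaluate_fitness(kh, recs, cfg)
  expect_lt(f, 0)      # KH99p predicts some pairs correctly on its own data
  expect_gte(f, -1)

  # grammar that parses nothing in the training set: worst sentinel
  tiny <- scfg_grammar(c("S", "B"), "S",
                       rule_df(c("S", "B"), c("PAIR", "UNPAIRED"), c("B", NA)))
  expect_equal(evaluate_fitness(tiny, recs, cfg), rnascfg:::WORST_FITNESS)

  # mountain fitness of a perfect self-predicting setup is near zero:
  # degenerate grammar predicting the only derivable structure
  g <- scfg_grammar(c("S", "B"), "S",
                    rule_df(c("S", "B"), c("PAIR", "UNPAIRED"), c("B", NA)))
  drecs <- list(rec("ACG", "(.)"), rec("GCU", "(.)"))
  mcfg <- evolution_config(fitness = "MOUNTAIN", generations = 1)
  expect_equal(evaluate_fitness(g, drecs, mcfg), 0)

  # composite complexity term is additive in the rule count: adding a rule
  # that no training derivation can use leaves predictions unchanged, so
  # the fitness difference is exactly the complexity charge
  ccfg <- evolution_config(fitness = "COMPOSITE",
                           composite_terms = c(longest = 0, failure = 0,
                                               complexity = 0.5),
                           generations = 1)
  g3 <- scfg_grammar(c("S", "B"), "S",
                     rule_df(c("S", "S", "B"),
                             c("PAIR", "UNPAIRED", "UNPAIRED"),
                             c("B", NA, NA)))
  g4 <- g3
  g4$rules <- rbind(g4$rules, rule_df("B", "PAIR", "S"))
  drecs2 <- list(rec("ACG", "(.)"), rec("GCU", "(.)"))
  set.seed(6); f3 <- evaluate_fitness(g3, drecs2, ccfg)
  set.seed(6); f4 <- evaluate_fitness(g4, drecs2, ccfg)
  expect_equal(f4 - f3, 0.5)
})

test_that("stochastic elimination keeps the champion and prefers eliminating the worst", {
  pop <- lapply(c(1, 1, 1, 1000), function(f)
    list(grammar = builtin_grammar("KH99p"), fitness = f))
  set.seed(9)
  kept <- select_population(pop, 3)
  expect_length(kept, 3)
  expect_false(1000 %in% vapply(kept, `[[`, numeric(1), "fitness"))

  # equal fitness: uniform elimination, deterministic under a seed
  pop2 <- lapply(rep(2, 6), function(f)
    list(grammar = builtin_grammar("KH99p"), fitness = f))
  set.seed(10); a <- select_population(pop2, 4)
  set.seed(10); b <- select_population(pop2, 4)
  expect_identical(vapply(a, `[[`, numeric(1), "fitness"),
                   vapply(b, `[[`, numeric(1), "fitness"))
})

test_that("evolution runs reproducibly with valid genealogy and non-increasing champion", {
  recs <- make_train_set(n = 10, max_len = 20)
  cfg <- evolution_config(generations = 4, offspring_per_generation = 4,
                          population_size = 8, seed = 42)
  st <- run_evolution(recs, cfg, population = initial_population()[1:8])
  expect_s3_class(st, "search_state")
  expect_length(st$population, 8)
  expect_equal(nrow(st$history), 4)
  expect_true(all(diff(st$history$champion_fitness) <= 0))
  for (p in st$population) {
    expect_length(validate_normal_form(p$grammar), 0)
    expect_true("B -> ." %in% rnascfg:::rule_labels(p$grammar$rules))
  }
  st2 <- run_evolution(recs, cfg, population = initial_population()[1:8])
  expect_identical(st$history, st2$history)
  expect_true(grammar_equal(st$champion$grammar, st2$champion$grammar))
  expect_error(run_evolution(recs, evolution_config(generations = 0)),
               "generations")
})

test_that("local search enumerates the documented neighbourhoods", {
  kh <- builtin_grammar("KH99p")
  expect_length(local_search_grammars(kh, "add1"), 32)
  expect_length(local_search_grammars(kh, "add2"), choose(32, 2))
  expect_length(local_search_grammars(kh, "del1"), 6)
  for (g in local_search_grammars(kh, "del1")) {
    expect_true("B -> ." %in% rnascfg:::rule_labels(g$rules))
    expect_equal(nrow(g$rules), 6)
  }
  # evaluated neighbourhood returns metrics per grammar
  recs <- make_train_set(n = 6, max_len = 15)
  set.seed(2)
  res <- local_search(kh, "del1", recs, evolution_config(generations = 1))
  expect_length(res, 6)
  for (r in res) expect_s3_class(r$metrics, "metric_report")
})

test_that("the two-non-terminal enumeration covers the whole rule power set", {
  sets <- two_nonterminal_rulesets()
  expect_length(sets, 16384)
  sizes <- vapply(sets, nrow, numeric(1))
  expect_equal(sum(sizes == 0), 1)
  expect_equal(sum(sizes == 14), 1)
  expect_equal(sum(choose(14, 0:14)), 16384)
  # a small budgeted brute-force run trains and ranks grammars
  recs <- make_train_set(n = 5, max_len = 12)
  set.seed(3)
  bf <- brute_force_space(recs, evolution_config(generations = 1), budget = 64)
  expect_equal(nrow(bf), 64)
  expect_true(all(diff(bf$sensitivity) <= 0))
  grams <- attr(bf, "grammars")
  for (g in grams[1:10]) {
    bad <- validate_normal_form(g)
    # shape violations never occur; only start-productivity may fail
    expect_true(all(grepl("unproductive start", bad)))
  }
})
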