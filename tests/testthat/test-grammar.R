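test_that("normal-form validation accepts the bundled grammars and flags malformed rules", {
  for (nm in c("KH99p", paste0("GG", 1:6)))
    expect_length(validate_normal_form(builtin_grammar(nm)), 0)

  # unit-rule-like and epsilon-like shapes are reported, not silently fixed
  bad <- list(nonterminals = c("S", "L"), start = "S",
              rules = rule_df(c("S", "L"), c("UNIT", "UNPAIRED"),
                              c("L", NA)))
  v <- validate_normal_form(bad)
  expect_true(any(grepl("unknown kind", v)))

  # undeclared symbols and duplicates
  bad2 <- list(nonterminals = "S", start = "S",
               rules = rule_df(c("S", "S", "S"),
                               c("PAIR", "UNPAIRED", "UNPAIRED"),
                               c("X", NA, NA)))
  v2 <- validate_normal_form(bad2)
  expect_true(any(grepl("not a declared non-terminal", v2)))
  expect_true(any(grepl("duplicate rule", v2)))

  # a start symbol without productions is unproductive
  empty <- list(nonterminals = c("S", "B"), start = "S",
                rules = rule_df("B", "UNPAIRED"))
  expect_true(any(grepl("unproductive start", validate_normal_form(empty))))
})

test_that("grammar-space size follows 2^(m^3+m^2+m) and matches explicit enumeration", {
  expect_identical(count_grammar_space(2), 16384)
  expect_identical(count_grammar_space(3), 549755813888)
  expect_identical(count_grammar_space(1), 8)
  expect_error(count_grammar_space(0), "positive integer")
  # oracle: the rule universe for m symbols has m^3+m^2+m members, and the
  # space is its power set
  for (m in 1:2) {
    nts <- LETTERS[seq_len(m)]
    expect_identical(count_grammar_space(m),
                     2^nrow(all_normal_form_rules(nts)))
  }
})

test_that("addable rules complement the present rules within the rule universe", {
  kh <- builtin_grammar("KH99p")
  add <- addable_rules(kh)
  expect_equal(nrow(add), 32)  # 3^3 + 3^2 + 3 - 7
  # disjoint from the existing rules, and each addition stays valid
  labs <- rnascfg:::rule_labels(kh$rules)
  expect_length(intersect(rnascfg:::rule_labels(add), labs), 0)
  for (i in c(1, 10, 32)) {
    g2 <- kh
    g2$rules <- rbind(kh$rules, add[i, ])
    expect_length(validate_normal_form(g2), 0)
  }
  # saturated grammar: nothing addable
  sat <- scfg_grammar("S", "S", all_normal_form_rules("S"))
  expect_equal(nrow(addable_rules(sat)), 0)
  # toy: {S -> (B), S -> ., B -> .} over {S, B}: 14 possible - 3 present
  toy <- scfg_grammar(c("S", "B"), "S",
                      rule_df(c("S", "S", "B"),
                              c("PAIR", "UNPAIRED", "UNPAIRED"),
                              c("B", NA, NA)))
  expect_equal(nrow(addable_rules(toy)), 11)
})

test_that("bundled grammars match their printed rule sets", {
  kh <- builtin_grammar("KH99p")
  expect_setequal(kh$nonterminals, c("A", "B", "C"))
  expect_equal(nrow(kh$rules), 7)
  expect_identical(kh$start, "A")

  gg6 <- builtin_grammar("GG6")
  expect_setequal(gg6$nonterminals, LETTERS[1:8])
  labs <- rnascfg:::rule_labels(gg6$rules)
  expect_true(all(c("H -> F A", "H -> A F", "H -> H H",
                    "H -> ( B )", "H -> ( H )") %in% labs))

  gg4 <- builtin_grammar("GG4")
  labs4 <- rnascfg:::rule_labels(gg4$rules)
  expect_true(all(c("F -> A B", "G -> F B") %in% labs4))

  gg1 <- builtin_grammar("GG1")
  expect_true(grammar_equal(
    gg1,
    scfg_grammar(c("A", "B", "C"), "A",
                 rbind(kh$rules, rule_df(c("A", "A"), c("BRANCH", "PAIR"),
                                         c("A", "A"), c("A", NA))))))
  expect_error(builtin_grammar("GG7"), "unknown grammar")
})

test_that("grammar files round-trip through read and write", {
  kh <- builtin_grammar("KH99p")
  tf <- withr::local_tempfile(fileext = ".txt")
  write_grammar(kh, tf)
  expect_true(grammar_equal(read_grammar(tf)$grammar, kh))

  # with parameters: probabilities survive to >= 12 significant digits
  set.seed(42)
  p <- uniform_params(kh, jitter = 0.3)
  write_grammar(kh, tf, params = p)
  back <- read_grammar(tf)
  expect_true(grammar_equal(back$grammar, kh))
  expect_equal(back$params$rule_prob, p$rule_prob, tolerance = 1e-12)
  expect_equal(back$params$paired_emit, p$paired_emit, tolerance = 1e-12)

  # inline format example
  tf2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("start: A", "A -> B A | . | ( C )", "B -> . | ( C )",
               "C -> B A | ( C )"), tf2)
  expect_true(grammar_equal(read_grammar(tf2)$grammar, kh))

  # unit rules are a parse error naming the offending alternative
  writeLines(c("start: A", "A -> B", "B -> ."), tf2)
  expect_error(read_grammar(tf2), "not a normal-form rule")
  # probability sums are checked
  writeLines(c("start: A", "A -> . [0.5] | ( A ) [0.4]",
               paste("unpaired:", paste("A 0.25 C 0.25 G 0.25 U 0.25")),
               paste("paired:", paste(rnascfg:::PAIR_NAMES, 1 / 16,
                                      collapse = " "))), tf2)
  expect_error(read_grammar(tf2), "sum to")
})

test_that("grammar equality ignores order but not symbol names", {
  kh <- builtin_grammar("KH99p")
  shuffled <- kh
  shuffled$rules <- kh$rules[rev(seq_len(nrow(kh$rules))), ]
  shuffled$nonterminals <- rev(kh$nonterminals)
  expect_true(grammar_equal(kh, shuffled))
  renamed <- kh
  renamed$rules$lhs[renamed$rules$lhs == "C"] <- "Z"
  renamed$rules$c1[!is.na(renamed$rules$c1) & renamed$rules$c1 == "C"] <- "Z"
  renamed$nonterminals <- c("A", "B", "Z")
  expect_false(grammar_equal(kh, renamed))
})
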