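# Oracle equivalence: every dynamic program is checked against the
# brute-force derivation enumerator on small inputs.

test_that("structure CYK matches enumeration on all short strings for all toy grammars", {
  for (toy in oracle_toys()) {
    memo <- new.env(parent = emptyenv())
    for (n in 1:6) {
      ders <- oracle_derivations(toy$grammar, n, memo = memo)
      strs <- vapply(ders, `[[`, character(1), "str")
      for (s in unique(c(enumerate_structures(n, 1),
                         enumerate_structures(n, 2)))) {
        hit <- which(strs == s)
        got <- structure_cyk(toy$grammar, s, toy$params)
        if (length(hit) == 0) {
          expect_null(got)
        } else {
          best <- max(vapply(ders[hit], oracle_deriv_logp, numeric(1),
                             params = toy$params))
          expect_equal(got$logp, best, tolerance = 1e-10)
        }
        expect_equal(count_derivations(toy$grammar, s), length(hit))
      }
    }
  }
})

test_that("unweighted structure CYK is an existence check and empty strings never parse", {
  t1 <- toy1()
  expect_equal(structure_cyk(t1$grammar, "(.)")$logp, 0)
  expect_null(structure_cyk(t1$grammar, ".."))
  expect_null(structure_cyk(t1$grammar, ""))
  expect_equal(structure_cyk(t1$grammar, "(.)", t1$params)$logp, log(0.6))
})

test_that("derivation counting flags ambiguity and saturates at the cap", {
  t2 <- toy2()
  expect_equal(count_derivations(t2$grammar, "..."), 2)
  expect_equal(count_derivations(builtin_grammar("KH99p"), "(..)"), 1)
  expect_equal(count_derivations(t2$grammar, "(."), 0)
  # a long run of dots under toy2 has Catalan-many derivations; the cap bites
  dots30 <- paste(rep(".", 30), collapse = "")
  expect_equal(count_derivations(t2$grammar, dots30, cap = 100), 100)
})

test_that("derivation sampling is uniform over derivations and seed-reproducible", {
  t2 <- toy2()
  set.seed(11)
  d1 <- sample_derivation(t2$grammar, "...")
  set.seed(11)
  expect_identical(sample_derivation(t2$grammar, "..."), d1)

  # "..." has exactly two derivations: S->SS used once at either split
  set.seed(5)
  # in pre-order the second row is the left child of the top split
  splits <- replicate(4000, sample_derivation(t2$grammar, "...")[2, "end"])
  # binomial(4000, 0.5): 3 sigma is ~0.024
  expect_equal(mean(splits == 1), 0.5, tolerance = 0.03)

  # unambiguous grammar: any seed yields the unique derivation
  kh <- builtin_grammar("KH99p")
  set.seed(1); a <- sample_derivation(kh, "(..)")
  set.seed(999); b <- sample_derivation(kh, "(..)")
  expect_identical(a, b)
  expect_error(sample_derivation(toy1()$grammar, ".."), "no derivation")
})

test_that("inside total matches enumeration and dominates the CYK maximum", {
  set.seed(23)
  for (toy in oracle_toys()) {
    memo <- new.env(parent = emptyenv())
    for (n in 1:5) {
      seqs <- unique(replicate(3, random_sequence(n)))
      for (sq in seqs) {
        orc <- oracle_sequence(toy$grammar, toy$params, sq)
        got <- sequence_inside(toy$grammar, toy$params, sq)
        expect_equal(got$loglik, orc$total, tolerance = 1e-9)
        cyk <- sequence_cyk(toy$grammar, toy$params, sq)
        if (is.finite(orc$best)) {
          expect_equal(cyk$logp, orc$best, tolerance = 1e-9)
          expect_gte(got$loglik + 1e-12, cyk$logp)
        } else {
          expect_null(cyk)
        }
      }
    }
  }
  # worked example: single derivation of "A" under toy1
  t1 <- toy1()
  expect_equal(sequence_inside(t1$grammar, t1$params, "A")$loglik,
               log(0.4 * 0.25))
})

test_that("sequence CYK recovers the maximum-probability structure", {
  t2 <- toy2()
  res <- sequence_cyk(t2$grammar, t2$params, "ACG")
  expect_identical(to_dotbracket(res$structure), "(.)")
  # grammar that cannot tile even lengths without branch rules
  t1 <- toy1()
  expect_null(sequence_cyk(t1$grammar, t1$params, "AC"))
  # determinism on ties: repeated calls agree
  expect_identical(sequence_cyk(t2$grammar, t2$params, "ACGU")$structure,
                   sequence_cyk(t2$grammar, t2$params, "ACGU")$structure)
})

test_that("posterior pair probabilities match enumeration and are internally consistent", {
  set.seed(31)
  for (toy in oracle_toys()) {
    for (n in 3:6) {
      sq <- random_sequence(n)
      orc <- oracle_sequence(toy$grammar, toy$params, sq)
      if (!is.finite(orc$total)) next
      post <- sequence_outside_posteriors(toy$grammar, toy$params, sq)
      expect_equal(post$pair_prob[upper.tri(post$pair_prob)],
                   orc$pair[upper.tri(orc$pair)], tolerance = 1e-9)
      # q(i) complements the pair mass through position i
      mass <- post$unpaired_prob + rowSums(post$pair_prob) +
        colSums(post$pair_prob)
      expect_equal(mass, rep(1, n), tolerance = 1e-9)
    }
  }
  # degenerate grammar: a single derivable structure
  g <- scfg_grammar(c("S", "B"), "S", rule_df(c("S", "B"), c("PAIR", "UNPAIRED"),
                                              c("B", NA)))
  p <- make_params(g, c(1, 1))
  post <- sequence_outside_posteriors(g, p, "ACG")
  expect_equal(post$pair_prob[1, 3], 1)
  expect_equal(post$unpaired_prob[2], 1)
  expect_error(sequence_outside_posteriors(g, p, "AC"), "support")
})

test_that("with uniform emissions posteriors depend on length only", {
  t2 <- toy2()
  p1 <- sequence_outside_posteriors(t2$grammar, t2$params, "AAAA")
  p2 <- sequence_outside_posteriors(t2$grammar, t2$params, "GCGU")
  expect_equal(p1$pair_prob, p2$pair_prob, tolerance = 1e-12)
})

test_that("inside totals are invariant under non-terminal renaming", {
  kh <- toy_kh()
  ren <- kh$grammar
  map <- c(A = "X", B = "Y", C = "Z")
  ren$nonterminals <- unname(map[ren$nonterminals])
  ren$start <- unname(map[ren$start])
  ren$rules$lhs <- unname(map[ren$rules$lhs])
  ren$rules$c1 <- ifelse(is.na(ren$rules$c1), NA, unname(map[ren$rules$c1]))
  ren$rules$c2 <- ifelse(is.na(ren$rules$c2), NA, unname(map[ren$rules$c2]))
  for (sq in c("ACGU", "GGAAACC")) {
    expect_equal(sequence_inside(ren, kh$params, sq)$loglik,
                 sequence_inside(kh$grammar, kh$params, sq)$loglik)
  }
})
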