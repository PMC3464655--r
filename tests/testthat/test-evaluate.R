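test_that("pair-identity metrics follow the stated conventions", {
  trusted <- rna_structure(10, rbind(c(1, 10), c(2, 9), c(3, 8)))
  predicted <- rna_structure(10, rbind(c(1, 10), c(2, 9), c(4, 7)))
  m <- compare_structures(predicted, trusted)
  expect_equal(c(m$tp, m$fp, m$fn), c(2, 1, 1))
  expect_equal(c(m$sensitivity, m$ppv, m$fscore), rep(2 / 3, 3))

  same <- compare_structures(trusted, trusted)
  expect_equal(c(same$sensitivity, same$ppv, same$fscore), c(1, 1, 1))

  # zero-denominator conventions
  dots <- rna_structure(10)
  z <- compare_structures(dots, trusted)
  expect_equal(c(z$sensitivity, z$ppv, z$fscore), c(0, 0, 0))
  z2 <- compare_structures(trusted, dots)
  expect_equal(c(z2$sensitivity, z2$ppv), c(0, 0))
  expect_error(compare_structures(rna_structure(5), trusted), "lengths")
})

test_that("mountain distance is an L1 metric on height profiles", {
  expect_equal(mountain_distance(parse_dotbracket("(())"),
                                 parse_dotbracket("()()")), 2)
  expect_equal(mountain_distance(parse_dotbracket("((..))"),
                                 parse_dotbracket("((..))")), 0)
  # metric axioms on random structure triples
  set.seed(19)
  pool <- enumerate_structures(7, 1)
  for (k in 1:30) {
    s <- lapply(sample(pool, 3, replace = TRUE), parse_dotbracket)
    d12 <- mountain_distance(s[[1]], s[[2]])
    d21 <- mountain_distance(s[[2]], s[[1]])
    d13 <- mountain_distance(s[[1]], s[[3]])
    d23 <- mountain_distance(s[[2]], s[[3]])
    expect_identical(d12, d21)
    expect_gte(d13 + d23 + 1e-12, d12)
    expect_gte(d12, 0)
  }
})

test_that("micro-aggregation pools counts before taking ratios", {
  r1 <- rec("ACGUACGUAC", "((......))")
  r2 <- rec("ACGUACGUAC", "(........)")
  # prediction 1: tp=1 fn=1; prediction 2: tp=1 fp=1
  p1 <- rna_structure(10, rbind(c(1, 10)))
  p2 <- rna_structure(10, rbind(c(1, 10), c(3, 8)))
  agg <- aggregate_metrics(list(r1, r2), list(p1, p2))
  expect_equal(agg$sensitivity, 2 / 3)
  expect_equal(agg$ppv, 2 / 3)
  # single record reduces to compare_structures
  one <- aggregate_metrics(list(r1), list(p1))
  expect_equal(unclass(one)[c("tp", "fp", "fn")],
               unclass(compare_structures(p1, r1$structure))[c("tp", "fp", "fn")])
  expect_error(aggregate_metrics(list(), list()), "non-empty")
})

test_that("relative metrics treat the second prediction set as the truth", {
  a <- list(rna_structure(10, rbind(c(1, 10), c(2, 9))))
  b <- list(rna_structure(10, rbind(c(1, 10), c(3, 8))))
  self <- relative_metrics(a, a)
  expect_equal(c(self$sensitivity, self$ppv), c(1, 1))
  dots <- list(rna_structure(10))
  expect_equal(unlist(relative_metrics(dots, b)), c(sensitivity = 0, ppv = 0))
  ab <- relative_metrics(a, b)
  ba <- relative_metrics(b, a)
  expect_equal(ab$sensitivity, ba$ppv)
  expect_equal(ab$ppv, ba$sensitivity)
})

test_that("the gamma sweep emits one aggregate point per grid value", {
  kh <- toy_kh()
  set.seed(29)
  recs <- sample_records(kh$grammar, kh$params, 6, max_len = 25)
  sw <- gamma_sweep(kh$grammar, kh$params, recs, gamma_grid = c(0.5, 2))
  expect_equal(nrow(sw), 2)
  expect_identical(names(sw), c("gamma", "sensitivity", "ppv"))
  # a single-value grid equals direct aggregation of predict_mea
  preds <- lapply(recs, function(r) predict_mea(kh$grammar, kh$params,
                                                r$sequence, gamma = 2))
  direct <- aggregate_metrics(recs, preds)
  expect_equal(sw$sensitivity[sw$gamma == 2], direct$sensitivity)
  expect_equal(sw$ppv[sw$gamma == 2], direct$ppv)
  expect_error(gamma_sweep(kh$grammar, kh$params, recs, gamma_grid = c(0, 1)),
               "positive")
})

test_that("combined-best picks the per-record F-score winner", {
  r1 <- rec("ACGUACGUAC", "((......))")
  r2 <- rec("ACGUACGUAC", "(........)")
  perfect1 <- r1$structure; perfect2 <- r2$structure
  bad <- rna_structure(10)
  setA <- list(perfect1, bad)
  setB <- list(bad, perfect2)
  m <- combined_best(list(r1, r2), list(setA, setB))
  expect_equal(c(m$sensitivity, m$ppv, m$fscore), c(1, 1, 1))
  # one set reduces to plain aggregation
  m1 <- combined_best(list(r1, r2), list(setA))
  expect_equal(unclass(m1), unclass(aggregate_metrics(list(r1, r2), setA)))
  expect_error(combined_best(list(r1, r2), list(list(perfect1))), "cover")
})
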