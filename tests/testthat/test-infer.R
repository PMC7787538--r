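# Forward chaining: entailment semantics, proof traces, degenerate inputs.

test_that("no rules means nothing inferred and a single implication fires", {
  res <- forward_chain(rule_base(), "MP_P")
  expect_equal(res$inferred, character(0))
  expect_equal(res$combined, "MP_P")
  rb <- parse_rules("R1: MP_P -> MP_Q")
  res2 <- forward_chain(rb, "MP_P")
  expect_equal(res2$inferred, "MP_Q")
  expect_true(setequal(res2$combined, c("MP_P", "MP_Q")))
  # a three-step modus ponens derivation: premise, rule, conclusion
  d <- explain(res2, "MP_Q")
  expect_length(d$steps, 3L)
  expect_equal(vapply(d$steps, `[[`, "", "justification"),
               c("premise", "R1", "modus ponens"))
})

test_that("inference agrees with a truth-table oracle on random rule bases", {
  set.seed(101)
  for (i in 1:60) {
    rb <- rand_rulebase(sample(6:12, 1L), sample(4:8, 1L))
    atoms <- rb$atoms
    detected <- sample(atoms, sample(1:3, 1L))
    res <- suppressWarnings(forward_chain(rb, detected))
    oracle <- truth_table_entailed(rb, detected)
    expect_equal(res$inferred, oracle$inferred)
    expect_equal(res$inconsistent, oracle$inconsistent)
  }
})

test_that("definite-clause bases equal the naive least fixpoint", {
  set.seed(55)
  for (i in 1:40) {
    rb <- rand_definite_rulebase(sample(5:10, 1L), sample(3:8, 1L))
    detected <- sample(rb$atoms, sample(1:3, 1L))
    res <- forward_chain(rb, detected)
    expect_equal(res$inferred, definite_fixpoint(rb, detected))
    expect_false(res$inconsistent)
  }
})

test_that("inference is monotone and idempotent", {
  set.seed(77)
  for (i in 1:25) {
    rb <- rand_rulebase(sample(5:10, 1L), sample(3:6, 1L))
    d1 <- sample(rb$atoms, 1L)
    d2 <- unique(c(d1, sample(rb$atoms, 2L)))
    r1 <- suppressWarnings(forward_chain(rb, d1))
    r2 <- suppressWarnings(forward_chain(rb, d2))
    expect_true(all(r1$combined %in% r2$combined))
    r3 <- suppressWarnings(forward_chain(rb, r1$combined))
    expect_setequal(r3$combined, r1$combined)
  }
})

test_that("every trace replays mechanically and every inferred atom is explainable", {
  set.seed(909)
  for (i in 1:30) {
    rb <- rand_rulebase(sample(5:10, 1L), sample(3:7, 1L))
    detected <- sample(rb$atoms, sample(1:2, 1L))
    res <- suppressWarnings(forward_chain(rb, detected))
    expect_true(verify_trace(res, rb))
    if (!res$inconsistent) {
      for (a in res$inferred) {
        d <- explain(res, a)
        expect_equal(format_formula(d$steps[[length(d$steps)]]$formula), a)
        # supports strictly precede their step
        for (s in d$steps) expect_true(all(s$supports < s$n))
      }
    }
  }
})

test_that("soundness: inferred atoms hold in every model of rules plus premises", {
  set.seed(404)
  for (i in 1:20) {
    rb <- rand_rulebase(sample(5:9, 1L), sample(3:6, 1L))
    detected <- sample(rb$atoms, 1L)
    res <- suppressWarnings(forward_chain(rb, detected))
    if (res$inconsistent) next
    atoms <- sort(union(rb$atoms, detected))
    mat <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(atoms))))
    colnames(mat) <- atoms
    ok <- rep(TRUE, nrow(mat))
    for (r in rb$rules) ok <- ok & eval_formula_rows(f_imp(r$lhs, r$rhs), mat)
    for (a in detected) ok <- ok & mat[, a]
    for (a in res$inferred) expect_true(all(mat[ok, a]))
  }
})

test_that("chained implications explain through stepwise modus ponens", {
  rb <- parse_rules("R1: MP_P -> MP_Q\nR2: MP_Q -> MP_R")
  res <- forward_chain(rb, "MP_P")
  expect_setequal(res$inferred, c("MP_Q", "MP_R"))
  d <- explain(res, "MP_R")
  js <- vapply(d$steps, `[[`, "", "justification")
  expect_true(sum(js == "modus ponens") >= 2 ||
                "hypothetical syllogism" %in% js)
  expect_true(verify_trace(res, rb))
  expect_error(explain(res, "MP_Z"), "not inferred")
})

test_that("contradictory bases flag inconsistency and report all atoms", {
  rb <- parse_rules("R1: MP_A -> MP_B\nR2: MP_A -> !MP_B")
  expect_warning(res <- forward_chain(rb, "MP_A"), "contradictory")
  expect_true(res$inconsistent)
  expect_equal(res$inferred, "MP_B")
})

test_that("detected atoms outside the rule base are carried through", {
  rb <- parse_rules("R1: MP_P -> MP_Q")
  res <- forward_chain(rb, c("MP_P", "MP_NEW"))
  expect_true("MP_NEW" %in% res$combined)
  expect_equal(res$inferred, "MP_Q")
  expect_true(all(res$detected %in% res$combined))
  expect_length(intersect(res$detected, res$inferred), 0L)
})

test_that("the synthetic diabetes rule stand-in infers the four downstream pathways", {
  rb <- sddp_example("t2d_rules")
  res <- forward_chain(rb, c("MP_SMB", "MP_CTM"))
  expect_setequal(res$inferred, c("MP_TRXN", "MP_ATM", "MP_RRR", "MP_TRAN"))
  expect_true(verify_trace(res, rb))
})
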