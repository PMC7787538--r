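# Dominance scoring and risk indicators.

test_that("pairwise outcomes follow per-publication majority of strict wins", {
  W <- table2_matrix()
  # c1 = (3,0,3) loses to c3 = (0,7,5) two publications to one
  expect_equal(pairwise_outcome(W[, "c1"], W[, "c3"]), -1L)
  expect_equal(pairwise_outcome(W[, "c3"], W[, "c1"]), 1L)
  # c3 and c6 split one win each: tie
  expect_equal(pairwise_outcome(W[, "c3"], W[, "c6"]), 0L)
  expect_equal(pairwise_outcome(c(1, 2), c(1, 2)), 0L)
  expect_error(pairwise_outcome(1:3, 1:2), "length")
})

test_that("dominance scores are conserved and the beats matrix antisymmetric", {
  ds <- dominance_scores(table2_matrix())
  expect_equal(sum(ds$scores), 0L)
  expect_true(all(ds$beats == -t(ds$beats)))
  expect_true(all(diag(ds$beats) == 0L))
  # score identity: beats minus losses recomputed from the matrix
  expect_equal(unname(ds$scores),
               unname(rowSums(pmax(ds$beats, 0)) -
                        rowSums(pmax(-ds$beats, 0))))
  # rank formula: competition ranking with skipped ranks after ties
  expect_equal(unname(ds$ranks),
               unname(vapply(ds$scores, function(s) 1L + sum(ds$scores > s),
                             1L)))
})

test_that("a single combination scores zero at rank one", {
  W <- matrix(2L, 2, 1, dimnames = list(c("p1", "p2"), "c1"))
  ds <- dominance_scores(W)
  expect_equal(unname(ds$scores), 0L)
  expect_equal(risk_indicator(ds, "c1"), 1L)
  expect_error(risk_indicator(ds, "c9"), "unknown combination")
})

test_that("random weight matrices match the exhaustive dominance oracle", {
  set.seed(31)
  for (i in 1:20) {
    W <- matrix(rpois(6 * 5, 3), nrow = 5,
                dimnames = list(paste0("p", 1:5), paste0("c", 1:6)))
    ds <- dominance_scores(W)
    oracle <- dominance_oracle(W)
    expect_equal(ds$scores, oracle$scores)
    expect_equal(ds$ranks, oracle$ranks)
    expect_equal(sum(ds$scores), 0L)
  }
})

test_that("scores and ranks are invariant under publication permutation and monotone reweighting", {
  W <- table2_matrix()
  ref <- dominance_scores(W)
  set.seed(6)
  for (i in 1:10) {
    perm <- sample(nrow(W))
    ds <- dominance_scores(W[perm, , drop = FALSE])
    expect_equal(ds$scores, ref$scores)
    expect_equal(ds$ranks, ref$ranks)
  }
  # strictly increasing transforms within one publication preserve all
  # comparisons (only > is ever used)
  W2 <- W
  W2["p2", ] <- W2["p2", ]^2L + 5L
  ds2 <- dominance_scores(W2)
  expect_equal(ds2$scores, ref$scores)
  expect_equal(ds2$ranks, ref$ranks)
})

test_that("combination weights count jointly related sentences per publication", {
  d <- term_dict(c("MA", "MB", "DIS"), c("marker", "marker", "disease"),
                 list("alpha", "beta", "disease1"))
  pws <- list(MP_A = pathway("MP_A", c("MA", "x"), "MA"),
              MP_B = pathway("MP_B", c("MB", "y"), "MB"))
  corpus <- as_corpus(list(
    list(pmid = "p1", sentences = c(
      "alpha activates beta in cells.",          # joint, related
      "alpha rises , whereas beta falls.",       # joint but coordinator-split
      "alpha was measured.",                     # MP_A only
      "alpha binds beta strongly.",              # joint, related
      "alpha interacts with beta here.")),       # joint, related
    list(pmid = "p2", sentences = "beta was elevated.")))
  combos <- list(cA = "MP_A", cAB = c("MP_A", "MP_B"))
  w <- combination_weights(corpus, d, pws, combos)
  # singleton: every sentence mentioning alpha
  expect_equal(unname(w$W[, "cA"]), c(5L, 0L))
  # pair: three planted joint sentences; the coordinator-split one is excluded
  expect_equal(unname(w$W[, "cAB"]), c(3L, 0L))
  expect_error(
    combination_weights(corpus, d, pws, list(bad = "MP_MISSING")),
    "unknown pathway")
})

test_that("abstracts without marker terms weigh zero for every combination", {
  d <- term_dict(c("MA", "DIS"), c("marker", "disease"),
                 list("alpha", "disease1"))
  pws <- list(MP_A = pathway("MP_A", "MA", "MA"))
  corpus <- as_corpus(list(list(pmid = "p1",
                                abstract = "Nothing relevant here. Plain text.")))
  w <- combination_weights(corpus, d, pws, list(c1 = "MP_A"))
  expect_true(all(w$W == 0L))
})

test_that("enumerated combinations are size-capped and deterministic", {
  combos <- enumerate_combinations(c("MP_B", "MP_A", "MP_C"), max_size = 2L)
  expect_length(combos, 6L)
  expect_equal(combos$c1, "MP_A")
  expect_equal(combos$c4, c("MP_A", "MP_B"))
  expect_true(all(vapply(combos, length, 1L) <= 2L))
})
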