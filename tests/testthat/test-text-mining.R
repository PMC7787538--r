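# Information extractor: POST parsing, pronoun resolution, strict
# relatedness rules, z-score filtering.

test_that("bracketed parses load with correct spans and labels", {
  tr <- post_parse("(S (NP BRCA1) (VP is associated with (NP breast cancer)))")
  expect_s3_class(tr, "post_tree")
  expect_equal(post_tokens(tr),
               c("BRCA1", "is", "associated", "with", "breast", "cancer"))
  expect_equal(tr$root$label, "independent-clause")
  expect_equal(tr$root$start, 0L)
  expect_equal(tr$root$end, 6L)
  # children partition the parent span in order
  check_partition <- function(node) {
    if (is.null(node$children)) return(invisible(NULL))
    starts <- vapply(node$children, `[[`, 0L, "start")
    ends <- vapply(node$children, `[[`, 0L, "end")
    expect_equal(starts[1L], node$start)
    expect_equal(ends[length(ends)], node$end)
    if (length(starts) > 1L) {
      expect_equal(starts[-1L], ends[-length(ends)])
    }
    for (ch in node$children) check_partition(ch)
  }
  check_partition(tr$root)
  # unmappable labels collapse to unit
  tr2 <- post_parse("(XYZ (WHAT a) b)")
  expect_equal(tr2$root$label, "unit")
  expect_equal(tr2$root$children[[1L]]$label, "unit")
})

test_that("malformed bracketings fail with an offset", {
  expect_error(post_parse("((S"), "offset 0")
  expect_error(post_parse("(S a"), "missing ')'")
  expect_error(post_parse("(S a) b)"), "trailing")
  expect_error(post_parse("()"), "label")
})

test_that("the worked two-clause sentence decomposes into two clauses at the coordinator", {
  ex <- sddp_example("example1")
  tr <- post_parse(ex$post)
  expect_equal(paste(post_tokens(tr), collapse = " "),
               paste(tokenize_text(ex$sentence), collapse = " "))
  cl <- post_clauses(tr)
  expect_equal(nrow(cl), 2L)
  between <- tr$tokens[(cl$end[1L] + 1L):cl$start[2L]]
  expect_true("whereas" %in% tolower(between))
})

test_that("longest-match mention lookup is case-insensitive and non-overlapping", {
  d <- toy_dict()
  m <- find_mentions(tokenize_text("tp53 and Breast Cancer but not breast"),
                     d)
  expect_equal(m$id, c("TP53", "BC"))
  expect_equal(m$start, c(0L, 2L))
  expect_equal(m$end, c(1L, 4L)) # multi-token surface wins over nothing
  expect_error(find_mentions("x", term_dict(character(0), character(0),
                                            list())),
               "unique|empty")
})

test_that("pronouns are annotated with the closest antecedent of the preceding clause", {
  d <- toy_dict()
  tr <- sentence_post("TP53 is mutated , which elevates risk of sarcoma")
  tr <- resolve_pronouns(tr, d)
  refs <- attr(tr, "pronoun_refs")
  expect_length(refs, 1L)
  expect_equal(refs[[1L]]$ids, "TP53")
  # the pronoun link makes the pair co-occur in the second clause
  rel <- related_pairs(tr, d)
  expect_equal(nrow(rel), 1L)
  expect_equal(unlist(rel[1L, ], use.names = FALSE), c("SARC", "TP53"))
})

test_that("pronoun resolution is identity on pronoun-free sentences and degenerate starts", {
  d <- toy_dict()
  tr <- sentence_post("TP53 is mutated in tumours")
  tr2 <- resolve_pronouns(tr, d)
  expect_length(attr(tr2, "pronoun_refs"), 0L)
  expect_equal(tr2$tokens, tr$tokens)
  # sentence-initial pronoun has no predecessor clause: unannotated
  tr3 <- resolve_pronouns(sentence_post("It is unclear whether TP53 matters"),
                          d)
  expect_length(attr(tr3, "pronoun_refs"), 0L)
})

test_that("cross-clause pairs split by a preposition modifier are unrelated", {
  ex <- sddp_example("example1")
  tr <- resolve_pronouns(post_parse(ex$post), ex$dictionary)
  rel <- related_pairs(tr, ex$dictionary)
  got <- paste(rel$id_a, rel$id_b)
  expect_setequal(got, c("SLC6A2 SLC6A4", "G1287A OCD", "5-HIT OCD",
                         "5-HIT G1287A"))
  # all six cross-coordinator pairs excluded
  for (a in c("SLC6A2", "SLC6A4")) {
    for (b in c("OCD", "G1287A", "5-HIT")) {
      expect_false(paste(min(a, b), max(a, b)) %in% got)
    }
  }
})

test_that("single-clause co-occurrence is related and the empty dictionary errors", {
  d <- toy_dict()
  tr <- sentence_post("BRCA1 is associated with breast cancer")
  rel <- related_pairs(tr, d)
  expect_equal(nrow(rel), 1L)
  expect_equal(c(rel$id_a, rel$id_b), c("BC", "BRCA1"))
  expect_error(related_pairs(tr, term_dict(character(0), character(0),
                                           list())),
               "unique|empty")
})

test_that("relatedness matches the generator's per-sentence ground truth", {
  cfg <- sim_config(seed = 21, n_publications = 8, noise_marker_rate = 0.3,
                    noise_disease_rate = 0.3, whereas_frac = 0.3,
                    pronoun_frac = 0.3)
  sim <- gen_corpus(cfg)
  n_checked <- 0L
  for (rec in sim$corpus) {
    truth_rec <- sim$sentence_truth[sim$sentence_truth$pmid == rec$pmid, ]
    for (k in seq_along(rec$sentences)) {
      tr <- resolve_pronouns(post_parse(rec$parses[[k]]), sim$dictionary)
      rel <- related_pairs(tr, sim$dictionary)
      want <- truth_rec[truth_rec$sentence == k, c("id_a", "id_b")]
      expect_setequal(paste(rel$id_a, rel$id_b), paste(want$id_a, want$id_b))
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 20L)
})

test_that("relatedness is symmetric and grows when the coordinator is removed", {
  d <- sddp_example("example1")$dictionary
  with_coord <- related_pairs(sentence_post(
    "SLC6A2 rises , whereas OCD was linked to G1287A"), d)
  without <- related_pairs(sentence_post(
    "SLC6A2 rises , OCD was linked to G1287A"), d)
  keys <- function(df) paste(df$id_a, df$id_b)
  expect_true(all(keys(with_coord) %in% keys(without)))
  expect_gt(nrow(without), nrow(with_coord))
  # symmetry: the pair set is stored unordered (id_a < id_b) and judging the
  # mirrored sentence gives the same set
  expect_true(all(with_coord$id_a <= with_coord$id_b))
})

test_that("pair z-score matches the closed-form binomial oracle", {
  # null case: observed equals expectation
  expect_equal(pair_zscore(10, 100, 100, 1000), 0)
  # planted enrichment and depletion against the closed form
  expect_equal(pair_zscore(30, 100, 100, 1000), 20 / sqrt(10 * 0.99),
               tolerance = 1e-12)
  expect_equal(pair_zscore(0, 100, 100, 1000), -10 / sqrt(10 * 0.99),
               tolerance = 1e-12)
  expect_error(pair_zscore(1, 0, 5, 10), "positive")
  expect_error(pair_zscore(5, 3, 4, 10), "n_related")
  expect_error(pair_zscore(1, 2, 3, 0), "positive")
})

test_that("z-score sign tracks enrichment above or below expectation", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(50:500, 1L)
    na <- sample(1:30, 1L); nb <- sample(1:30, 1L)
    nr <- sample(0:min(na, nb), 1L)
    e <- (na / n) * (nb / n) * n
    z <- pair_zscore(nr, na, nb, n)
    expect_equal(z > 0, nr > e)
    expect_equal(z < 0, nr < e)
  }
})

test_that("extraction keeps the planted marker first and filters noise and support", {
  cfg <- sim_config(seed = 33, n_publications = 120)
  sim <- gen_corpus(cfg)
  stats <- corpus_pair_stats(sim$corpus, sim$dictionary)
  ex <- extract_markers(sim$corpus, sim$dictionary, "DIS1", stats = stats)
  planted1 <- sim$truth$marker_id[sim$truth$disease_id == "DIS1"]
  expect_true(ex$marker_id[1L] %in% planted1)
  expect_true(all(diff(ex$z) <= 0))
  # pure-noise pairs never pass the default thresholds here
  expect_true(all(ex$marker_id %in% planted1))
  # boundary: a pair supported by min_docs - 1 documents is excluded even
  # with a huge z
  fake <- stats[1L, ]
  fake$n_docs_related <- 2L
  fake$z <- 50
  expect_equal(nrow(extract_markers(sim$corpus, sim$dictionary, "DIS1",
                                    stats = fake, min_docs = 3L)), 0L)
  expect_error(extract_markers(sim$corpus, sim$dictionary, "NOPE"),
               "not in dictionary")
})

test_that("a corpus with no disease mentions extracts nothing", {
  d <- toy_dict()
  corpus <- as_corpus(list(
    list(pmid = "1", abstract = "TP53 and BRCA1 were sequenced. Samples were frozen.")))
  ex <- extract_markers(corpus, d, "SARC")
  expect_equal(nrow(ex), 0L)
})

test_that("extraction is invariant under publication order permutation", {
  cfg <- sim_config(seed = 13, n_publications = 25)
  sim <- gen_corpus(cfg)
  ex1 <- extract_markers(sim$corpus, sim$dictionary, "DIS1", min_docs = 1L)
  perm <- rev(seq_along(sim$corpus))
  shuffled <- as_corpus(unclass(sim$corpus)[perm])
  ex2 <- extract_markers(shuffled, sim$dictionary, "DIS1", min_docs = 1L)
  expect_equal(ex1, ex2)
})
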