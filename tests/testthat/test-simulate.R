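# Synthetic data generators and evaluation metrics.

test_that("corpus generation is a pure function of the configuration", {
  cfg <- sim_config(seed = 1, n_publications = 10)
  a <- gen_corpus(cfg)
  b <- gen_corpus(cfg)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_corpus(a$corpus, p1); write_corpus(b$corpus, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(a$sentence_truth, b$sentence_truth)
  # and sensitive to the seed
  c3 <- gen_corpus(sim_config(seed = 2, n_publications = 10))
  write_corpus(c3$corpus, p2)
  expect_false(identical(readLines(p1), readLines(p2)))
})

test_that("zero noise and one planted pair give exactly that ground truth", {
  cfg <- sim_config(seed = 3, n_publications = 15, n_planted = 1L,
                    planted_prob = 1, whereas_frac = 0, pronoun_frac = 0,
                    noise_marker_rate = 0, noise_disease_rate = 0)
  sim <- gen_corpus(cfg)
  expect_equal(nrow(sim$truth), 1L)
  got <- unique(sim$sentence_truth[, c("id_a", "id_b")])
  expect_equal(nrow(got), 1L)
  expect_setequal(unlist(got, use.names = FALSE),
                  unlist(sim$truth, use.names = FALSE))
  expect_error(gen_corpus(sim_config(n_markers = 0)), "positive")
})

test_that("every planted pair appears in at least one generated sentence", {
  cfg <- sim_config(seed = 12, n_publications = 120)
  sim <- gen_corpus(cfg)
  planted_keys <- paste(pmin(sim$truth$marker_id, sim$truth$disease_id),
                        pmax(sim$truth$marker_id, sim$truth$disease_id))
  seen <- paste(sim$sentence_truth$id_a, sim$sentence_truth$id_b)
  expect_true(all(planted_keys %in% seen))
})

test_that("network and pathway generation respects overlap configuration", {
  cfg <- sim_config(seed = 5, n_molecules = 30, n_pathways = 3,
                    pathway_size = 8, overlap_frac = 0.25)
  a <- gen_network_and_pathways(cfg)
  b <- gen_network_and_pathways(cfg)
  expect_identical(lapply(a$pathways, unclass), lapply(b$pathways, unclass))
  expect_equal(igraph::gsize(a$network), igraph::gsize(b$network))
  n_overlap <- round(0.25 * 8)
  for (i in 1:2) {
    shared <- intersect(a$pathways[[i]]$molecules,
                        a$pathways[[i + 1L]]$molecules)
    expect_length(shared, n_overlap)
  }
  expect_error(gen_network_and_pathways(
    sim_config(n_molecules = 10, n_pathways = 4, pathway_size = 8,
               overlap_frac = 0.1)), "infeasible")
})

test_that("zero overlap produces an edgeless MPIN, nesting a directed one", {
  cfg <- sim_config(seed = 9, n_molecules = 24, n_pathways = 2,
                    pathway_size = 8, overlap_frac = 0)
  sim <- gen_network_and_pathways(cfg)
  mp <- build_mpin(sim$pathways, sim$network, seed = 1)
  expect_equal(nrow(mp$edges), 0L)
  # nested construction: A's molecules inside B, A's marker deeper in B's tree
  g <- igraph::make_graph(~ b - u, u - a, a - m)
  pa <- pathway("MP_A", c("a", "m"), "a")
  pb <- pathway("MP_B", c("b", "u", "a", "m"), "b")
  mp2 <- build_mpin(list(pa, pb), g)
  # lowest common molecule is a: level 0 in A, level 2 in B -> A specific
  expect_equal(mp2$edges$n_com, "a")
  expect_equal(mp2$edges$direction, "y->x")
})

test_that("extraction metrics follow the standard confusion formulas", {
  pairs <- function(m, d) data.frame(marker_id = m, disease_id = d)
  same <- pairs(c("M1", "M2"), c("D1", "D1"))
  s <- score_extraction(same, same)
  expect_equal(c(s$precision, s$recall, s$f_value), c(1, 1, 1))
  disjoint <- score_extraction(pairs("M3", "D2"), same)
  expect_equal(c(disjoint$precision, disjoint$recall, disjoint$f_value),
               c(0, 0, 0))
  expect_true(disjoint$undefined) # F-value denominator collapses
  # TP=8, FP=2, FN=2
  pred <- pairs(paste0("M", 1:10), rep("D1", 10))
  truth <- pairs(paste0("M", c(1:8, 11:12)), rep("D1", 10))
  s3 <- score_extraction(pred, truth)
  expect_equal(c(s3$tp, s3$fp, s3$fn), c(8, 2, 2))
  expect_equal(c(s3$precision, s3$recall, s3$f_value), c(0.8, 0.8, 0.8))
  expect_false(s3$undefined)
  # empty prediction flags undefined precision
  s4 <- score_extraction(pairs(character(0), character(0)), same)
  expect_true(s4$undefined)
  expect_equal(s4$recall, 0)
})

test_that("worked-example fixtures survive writer/reader round trips", {
  w <- sddp_example("table2")
  expect_equal(dim(w$W), c(3L, 10L))
  expect_equal(unname(w$W["p2", ]), c(0, 3, 7, 3, 0, 0, 0, 3, 0, 4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_weights(w, path)
  expect_identical(read_weights(path)$W, w$W)
  ex1 <- sddp_example("example1")
  expect_match(ex1$sentence, "^In some studies")
  expect_equal(length(ex1$dictionary), 5L)
})
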