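# Characteristic trees: shortest-path single-parent transformation.

test_that("a star network hangs every leaf at depth 1 under the hub", {
  g <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(g)$name <- c("hub", paste0("leaf", 1:5))
  t <- build_mct(g, "hub")
  expect_equal(unname(t$depth[paste0("leaf", 1:5)]), rep(1L, 5))
  expect_equal(unname(t$parent[paste0("leaf", 1:5)]), rep("hub", 5))
  expect_equal(t$depth[["hub"]], 0L)
  expect_false("hub" %in% names(t$parent))
})

test_that("a path graph yields increasing depths", {
  g <- igraph::make_graph(~ a - b, b - c)
  t <- build_mct(g, "a")
  expect_equal(unname(t$depth[c("a", "b", "c")]), 0:2)
  expect_error(build_mct(g, "zzz"), "not in network")
})

test_that("depth maps equal igraph breadth-first distances on random graphs", {
  set.seed(20)
  for (i in 1:25) {
    g <- igraph::sample_gnp(30, 0.2)
    igraph::V(g)$name <- sprintf("m%02d", 1:30)
    root <- sample(igraph::V(g)$name, 1L)
    t <- build_mct(g, root, seed = i)
    d <- igraph::distances(g, v = root)[1L, ]
    reach <- names(d)[is.finite(d)]
    expect_setequal(names(t$depth), reach)
    expect_equal(unname(t$depth[reach]), unname(as.integer(d[reach])))
    # single parenthood and shortest-path parents
    expect_equal(length(t$parent), length(t$depth) - 1L)
    for (v in names(t$parent)) {
      p <- t$parent[[v]]
      expect_equal(t$depth[[p]], t$depth[[v]] - 1L)
      expect_true(igraph::are_adjacent(g, p, v))
    }
  }
})

test_that("trees are acyclic and depth maps are seed-independent", {
  set.seed(4)
  g <- igraph::sample_gnp(25, 0.25)
  igraph::V(g)$name <- sprintf("m%02d", 1:25)
  ref <- build_mct(g, "m01", seed = 1)
  for (s in 2:21) {
    t <- build_mct(g, "m01", seed = s)
    expect_identical(t$depth, ref$depth)
    # ancestor walk must reach the root without revisiting
    for (v in names(t$parent)) {
      seen <- character(0)
      cur <- v
      while (cur != t$root) {
        expect_false(cur %in% seen)
        seen <- c(seen, cur)
        cur <- if (cur %in% names(t$parent)) t$parent[[cur]] else t$root
      }
    }
  }
  # deterministic tie-break picks the lexicographically smallest parent
  t1 <- build_mct(g, "m01", deterministic = TRUE)
  t2 <- build_mct(g, "m01", deterministic = TRUE)
  expect_identical(t1, t2)
})

test_that("forests hold one tree per marker over the pathway subnetwork", {
  g <- igraph::make_graph(~ IL8 - CXCL1, CXCL1 - CXCR2, TNF - CXCR2,
                          IL8 - TNF, OUT - CXCR2)
  pw <- pathway("MP_CXC", c("IL8", "CXCL1", "CXCR2", "TNF"),
                c("IL8", "TNF"))
  forest <- mct_forest(pw, g, seed = 1)
  expect_equal(names(forest), c("IL8", "TNF"))
  expect_equal(forest$IL8$root, "IL8")
  expect_equal(forest$TNF$root, "TNF")
  # OUT is not a pathway molecule, so it never enters the trees
  expect_false("OUT" %in% names(forest$IL8$depth))
  # single-marker pathway gives a single tree; isolated marker a singleton
  pw2 <- pathway("MP_ONE", c("IL8"), "IL8")
  f2 <- mct_forest(pw2, g, seed = 1)
  expect_length(f2, 1L)
  expect_equal(f2$IL8$depth, c(IL8 = 0L))
  expect_error(mct_forest(pathway("MP_X", "nope", "nope"), g),
               "absent from network: nope")
})

test_that("molecule levels take the minimum depth across the forest", {
  g <- igraph::make_graph(~ a - m, b - c, c - m, a - b)
  pw <- pathway("MP_AB", c("a", "b", "c", "m"), c("a", "b"))
  forest <- mct_forest(pw, g, seed = 1)
  # m sits at depth 1 under a and depth 2 under b: level is the minimum
  expect_equal(forest$a$depth[["m"]], 1L)
  expect_equal(forest$b$depth[["m"]], 2L)
  expect_equal(molecule_level("m", forest), 1L)
  expect_equal(molecule_level("a", forest["a"]), 0L)
  expect_error(molecule_level("zz", forest), "not in any tree")
  # random forests: exhaustive scan oracle
  set.seed(9)
  for (i in 1:10) {
    gg <- igraph::sample_gnp(15, 0.3)
    igraph::V(gg)$name <- sprintf("n%02d", 1:15)
    pw <- pathway("MP_R", igraph::V(gg)$name,
                  sample(igraph::V(gg)$name, 3L))
    f <- mct_forest(pw, gg, seed = i)
    mols <- unique(unlist(lapply(f, function(t) names(t$depth))))
    for (m in mols) {
      brute <- min(unlist(lapply(f, function(t) {
        if (m %in% names(t$depth)) t$depth[[m]] else NULL
      })))
      expect_equal(molecule_level(m, f), brute)
    }
  }
})
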