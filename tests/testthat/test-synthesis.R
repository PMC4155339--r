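test_that("candidate sampling is exhaustive at s_r = 1 and excludes existing arcs", {
  cfg <- growth_config(s_r = 1, min_sample = 1)
  g <- igraph::make_empty_graph(3, directed = TRUE)
  s <- sample_candidates(g, cfg)
  expect_identical(nrow(s), 6L)
  expect_setequal(paste(s[, 1], s[, 2]),
                  c("1 2", "1 3", "2 1", "2 3", "3 1", "3 2"))

  g2 <- igraph::add_edges(g, c(1, 2))
  s2 <- sample_candidates(g2, cfg)
  expect_identical(nrow(s2), 5L)
  expect_false("1 2" %in% paste(s2[, 1], s2[, 2]))

  full <- igraph::add_edges(g, rep(t(s), 1))
  expect_error(sample_candidates(full, cfg), "complete")
})

test_that("candidate samples never contain duplicates, self-links or existing arcs", {
  set.seed(21)
  g <- igraph::sample_gnm(8, 12, directed = TRUE)
  existing <- paste(igraph::as_edgelist(g)[, 1], igraph::as_edgelist(g)[, 2])
  cfg <- growth_config(s_r = 0.5, min_sample = 5)
  for (rep in 1:300) {
    s <- sample_candidates(g, cfg)
    keys <- paste(s[, 1], s[, 2])
    expect_false(any(duplicated(keys)))
    expect_false(any(s[, 1] == s[, 2]))
    expect_false(any(keys %in% existing))
  }
})

test_that("selection probabilities follow the gated proportional law", {
  expect_equal(selection_probabilities(c(2, 3, 5)), c(0.2, 0.3, 0.5))
  expect_equal(selection_probabilities(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(selection_probabilities(c(-1, 2, 2)), c(0, 0.5, 0.5))
  expect_equal(selection_probabilities(c(-3, -1)), c(0.5, 0.5))
  expect_equal(sum(selection_probabilities(runif(50, -1, 1))), 1)
})

test_that("heuristic distances bound true distances from above", {
  path <- igraph::make_graph(c(rbind(1:9, 2:10)), directed = FALSE)
  bfs <- igraph::distances(path)
  cfg <- growth_config(walks = 5, walk_length = 7)
  set.seed(22)
  hits <- 0
  for (rep in 1:200) {
    ij <- sample(10, 2)
    est <- heuristic_distances(path, ij[1], ij[2], cfg)
    true <- bfs[ij[1], ij[2]]
    expect_gte(est[["d"]], min(true, cfg$walk_length + 1))
    if (true <= cfg$walk_length && est[["d"]] == true) hits <- hits + 1
  }
  expect_gt(hits, 0)
})

test_that("a heavy walk budget finds a direct arc with probability near one", {
  g <- igraph::make_graph(c(1, 2, 1, 3, 3, 4), directed = TRUE)
  cfg <- growth_config(walks = 200, walk_length = 7)
  set.seed(23)
  found <- vapply(1:50, function(r) {
    heuristic_distances(g, 1, 2, cfg)[["d_D"]]
  }, numeric(1))
  expect_true(mean(found == 1) > 0.95)
})

test_that("disconnected endpoints return the cap sentinel", {
  g <- igraph::make_empty_graph(6, directed = TRUE)
  g <- igraph::add_edges(g, c(1, 2, 4, 5))
  cfg <- growth_config(walks = 10, walk_length = 4)
  set.seed(24)
  est <- heuristic_distances(g, 1, 4, cfg)
  expect_identical(unname(est), rep(cfg$walk_length + 1L, 3))
})

test_that("generated networks have the requested size and no illegal arcs", {
  set.seed(25)
  g <- generate_network(parse_program("1.0"), n = 10, m = 20)
  expect_identical(igraph::ecount(g), 20)
  expect_identical(igraph::vcount(g), 10)
  el <- igraph::as_edgelist(g, names = FALSE)
  expect_false(any(el[, 1] == el[, 2]))
  expect_false(any(duplicated(paste(el[, 1], el[, 2]))))

  # determinism under a fixed seed
  set.seed(26)
  g1 <- generate_network(parse_program("k'"), 30, 100)
  set.seed(26)
  g2 <- generate_network(parse_program("k'"), 30, 100)
  expect_identical(edge_set(g1), edge_set(g2))

  # refusal before any work when m exceeds the legal arc count
  expect_error(generate_network(parse_program("1"), 4, 13), "exceeds")
  expect_error(generate_network(parse_program("1", directed = FALSE), 4, 7),
               "exceeds")
})

test_that("zero-weight bootstrap lets preferential attachment grow from scratch", {
  # all weights are 0 on the empty network; the uniform fallback must apply
  set.seed(27)
  g <- generate_network(parse_program("k'"), 20, 40)
  expect_identical(igraph::ecount(g), 40)
})

test_that("preferential attachment yields larger in-degree hubs than uniform growth", {
  set.seed(28)
  n <- 300; m <- 3000
  max_in <- function(p) {
    max(igraph::degree(generate_network(p, n, m), mode = "in"))
  }
  pa <- parse_program("k'")
  er <- parse_program("1.0")
  mx_pa <- vapply(1:30, function(r) max_in(pa), numeric(1))
  mx_er <- vapply(1:30, function(r) max_in(er), numeric(1))
  expect_gt(mean(mx_pa), mean(mx_er))
})

test_that("exhaustive sampling with a uniform rule reproduces the enumeration law", {
  # n = 3 directed, m = 2, s_r = 1: the enumeration oracle gives every
  # ordered arc sequence probability 1/6 * 1/5 = 1/30
  cfg <- growth_config(s_r = 1, min_sample = 1)
  unit <- parse_program("1")
  set.seed(29)
  runs <- 10000
  seqs <- vapply(seq_len(runs), function(r) {
    el <- igraph::as_edgelist(generate_network(unit, 3, 2, cfg),
                              names = FALSE)
    paste(el[1, 1], el[1, 2], el[2, 1], el[2, 2])
  }, character(1))
  counts <- table(seqs)
  expect_identical(length(counts), 30L)
  chi <- stats::chisq.test(as.vector(counts), p = rep(1 / 30, 30))
  expect_gt(chi$p.value, 0.001)
})

test_that("a constant generator reproduces the G(n,m) degree distribution", {
  set.seed(30)
  n <- 100; m <- 500
  const <- parse_program("2.5")
  deg_grown <- unlist(lapply(1:30, function(r) {
    igraph::degree(generate_network(const, n, m), mode = "in")
  }))
  deg_gnm <- unlist(lapply(1:30, function(r) {
    igraph::degree(igraph::sample_gnm(n, m, directed = TRUE), mode = "in")
  }))
  ks <- suppressWarnings(stats::ks.test(deg_grown, deg_gnm))
  expect_gt(ks$p.value, 0.01)
})

test_that("preferential attachment has a heavy in-degree tail versus ER", {
  set.seed(31)
  n <- 300; m <- 3000
  thr <- 10 * (m / n)
  pa <- parse_program("k'")
  er_ccdf <- mean(unlist(lapply(1:30, function(r) {
    igraph::degree(igraph::sample_gnm(n, m, directed = TRUE),
                   mode = "in") >= thr
  })))
  wins <- vapply(1:30, function(r) {
    ccdf <- mean(igraph::degree(generate_network(pa, n, m),
                                mode = "in") >= thr)
    ccdf > er_ccdf
  }, logical(1))
  expect_gte(sum(wins), 29)
})
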