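test_that("evaluation returns variables, applies affinity and protects operators", {
  j_prog <- parse_program("j")
  expect_identical(evaluate_program(j_prog, list(j = 5)), 5)

  psi_prog <- parse_program("(psi 2 1.0 0.0)")
  expect_identical(evaluate_program(psi_prog, list(i = 4, j = 6)), 1)
  expect_identical(evaluate_program(psi_prog, list(i = 4, j = 7)), 0)

  inv_k <- parse_program("(/ 1 k)")
  expect_identical(evaluate_program(inv_k, list(k = 0)), 0)
  expect_identical(evaluate_program(inv_k, list(k = 4)), 0.25)

  expect_identical(evaluate_program(parse_program("(log -1)"), list()), 0)
  expect_identical(evaluate_program(parse_program("(log 0)"), list()), 0)
  expect_identical(evaluate_program(parse_program("(pow 10 400)"), list()),
                   1e300)
  expect_identical(evaluate_program(parse_program("(pow 0 -2)"), list()), 0)
  expect_identical(evaluate_program(parse_program("(exp 1000)"), list()),
                   1e300)

  branch <- parse_program("(gt k 2 10 20)")
  expect_identical(evaluate_program(branch, list(k = 3)), 10)
  expect_identical(evaluate_program(branch, list(k = 2)), 20)
  expect_identical(evaluate_program(parse_program("(eq0 k 7 8)"),
                                    list(k = 0)), 7)
  expect_identical(evaluate_program(parse_program("(eq0 k 7 8)"),
                                    list(k = 1)), 8)

  # purity: repeated evaluation is bit-identical
  set.seed(5)
  for (rep in 1:20) {
    p <- random_program(directed = TRUE)
    ctx <- list(i = 3, j = 9, k = 2, "k'" = 5, d = 2, d_D = 3, d_R = 8)
    expect_identical(evaluate_program(p, ctx), evaluate_program(p, ctx))
  }
})

test_that("evaluation of a program missing context variables errors", {
  expect_error(evaluate_program(parse_program("(+ k d_R)"), list(k = 1)),
               "d_R")
})

test_that("affinity partitions identifiers by congruence", {
  expect_identical(affinity(3, 7, 2, 10, 1), 10)
  expect_identical(affinity(2, 5, 2, 10, 1), 1)
  for (x in 1:20) expect_identical(affinity(x, x + 5, 5, 42, 0), 42)
  # g truncated, g <= 1 puts everyone in one group
  expect_identical(affinity(2, 5, 2.9, 10, 1), 1)
  expect_identical(affinity(2, 5, 0.4, 10, 1), 10)

  # "psi returns a" is an equivalence relation for fixed g
  g <- 4
  same <- function(a, b) affinity(a, b, g, TRUE, FALSE)
  ids <- 1:24
  for (a in ids) expect_true(same(a, a))
  for (a in ids) for (b in ids) {
    expect_identical(same(a, b), same(b, a))
  }
  classes <- split(ids, ids %% g)
  for (cl in classes) {
    for (a in cl) for (b in cl) expect_true(same(a, b))
  }
})

test_that("random programs are reproducible, mode-legal and depth-bounded", {
  set.seed(11)
  p1 <- random_program(directed = TRUE, max_depth = 5)
  set.seed(11)
  p2 <- random_program(directed = TRUE, max_depth = 5)
  expect_identical(format_program(p1), format_program(p2))

  set.seed(12)
  for (rep in 1:500) {
    directed <- rep %% 2 == 0
    p <- random_program(directed = directed, max_depth = 4)
    expect_valid_program(p, directed)
    expect_lte(tree_depth(p$root), 4)
  }
})

test_that("protected semantics keep every random program finite", {
  set.seed(13)
  for (rep in 1:300) {
    p <- random_program(directed = TRUE)
    ctx <- list(i = sample(1e6, 1), j = sample(1e6, 1),
                k = runif(1, 0, 1e6), "k'" = runif(1, 0, 1e6),
                d = sample(8, 1), d_D = sample(8, 1), d_R = sample(8, 1))
    v <- evaluate_program(p, ctx)
    expect_true(is.finite(v))
  }
})

test_that("mutation splices exactly one sub-tree and preserves validity", {
  parent <- parse_program("(+ k 1)")
  # splice semantics at the constant leaf with donor "j"
  child_root <- netgp:::replace_subtree(parent$root, 3L,
                                        netgp:::gp_var("j"))
  expect_identical(format_program(gp_program(child_root)), "(+ k j)")

  set.seed(14)
  c1 <- mutate_program(parent)
  set.seed(14)
  c2 <- mutate_program(parent)
  expect_identical(format_program(c1), format_program(c2))
  # parent untouched
  expect_identical(format_program(parent), "(+ k 1)")

  set.seed(15)
  base <- random_program(directed = TRUE, max_depth = 3)
  for (rep in 1:500) {
    child <- mutate_program(base)
    expect_valid_program(child, TRUE)
  }
  set.seed(16)
  ubase <- random_program(directed = FALSE, max_depth = 3)
  for (rep in 1:100) {
    expect_valid_program(mutate_program(ubase), FALSE)
  }
})

test_that("program length counts nodes", {
  expect_identical(program_length(parse_program("3.5")), 1L)
  expect_identical(program_length(parse_program("(+ k 1)")), 3L)
  expect_identical(program_length(parse_program("(psi 2 1 0)")), 4L)
  expect_identical(program_length(parse_program("(/ 1 i)")), 3L)
})

test_that("parse and format round-trip and reject bad input", {
  p <- parse_program("k'")
  expect_identical(p$root$kind, "var")
  expect_identical(p$root$sym, "k'")
  expect_identical(format_program(parse_program("(/ 1 i)")), "(/ 1 i)")
  expect_identical(format_program(parse_program("( +   k    1 )")),
                   "(+ k 1)")
  # Greek psi accepted as synonym
  expect_identical(format_program(parse_program("(ψ 2 1 0)")),
                   "(psi 2 1 0)")

  expect_error(parse_program("k + "), "token")
  expect_error(parse_program("(+ k"), "end of input")
  expect_error(parse_program("(frobnicate 1 2)"), "operator")
  expect_error(parse_program(""), "empty")
  expect_error(parse_program("(+ 1 2) 3"), "trailing")
  expect_error(parse_program("d_D", directed = FALSE), "illegal")
  expect_error(parse_program("(+ k' 1)", directed = FALSE), "illegal")

  set.seed(17)
  for (rep in 1:1000) {
    directed <- rep %% 2 == 0
    p <- random_program(directed = directed, max_depth = 4)
    txt <- format_program(p)
    q <- parse_program(txt, directed = directed)
    expect_identical(format_program(q), txt)
    expect_identical(q$root, p$root)
  }
})

test_that("program files round-trip with comments ignored", {
  p <- parse_program("(psi 4 10 1)")
  path <- withr::local_tempfile(fileext = ".prog")
  write_program(p, path)
  expect_identical(format_program(read_program(path)), "(psi 4 10 1)")
})

test_that("mode-illegal variables are rejected at construction", {
  expect_error(gp_program(netgp:::gp_var("d_R"), directed = FALSE),
               "illegal")
  expect_silent(gp_program(netgp:::gp_var("d_R"), directed = TRUE))
})
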