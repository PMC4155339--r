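#' @useDynLib netgp, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif
NULL

# Operator table. Codes must stay in sync with the evaluator in src/growth.cpp.
.gp_ops <- data.frame(
  sym   = c("+", "-", "*", "/", "pow", "exp", "log", "abs", "min", "max",
            "gt", "lt", "eq", "eq0", "psi"),
  arity = c(2L, 2L, 2L, 2L, 2L, 1L, 1L, 1L, 2L, 2L, 4L, 4L, 4L, 3L, 3L),
  code  = 1:15,
  stringsAsFactors = FALSE
)

# Variable table. k/k' are degree descriptors of origin/target: out-degree of
# the origin and in-degree of the target in directed mode, endpoint degrees in
# undirected mode (where only k is legal). Codes sync with src/growth.cpp.
.gp_vars <- data.frame(
  sym  = c("i", "j", "k", "k'", "d", "d_D", "d_R"),
  code = 1:7,
  stringsAsFactors = FALSE
)

.gp_vars_directed   <- c("i", "j", "k", "k'", "d", "d_D", "d_R")
.gp_vars_undirected <- c("i", "j", "k", "d")

legal_variables <- function(directed) {
  if (directed) .gp_vars_directed else .gp_vars_undirected
}

op_arity <- function(sym) {
  idx <- match(sym, .gp_ops$sym)
  if (is.na(idx)) stop("unknown operator: ", sym, call. = FALSE)
  .gp_ops$arity[idx]
}

#' Construct generator program nodes
#'
#' A generator program is an expression tree whose leaves are variables or
#' constants and whose internal nodes are operators. Evaluated on a candidate
#' arc it yields the arc's weight.
#'
#' @param sym Operator or variable symbol.
#' @param ... Child nodes (operators only); count must match the operator's
#'   arity.
#' @return A program node (internal representation).
#' @keywords internal
#' @name gp-nodes
NULL

#' @rdname gp-nodes
gp_op <- function(sym, ...) {
  args <- list(...)
  ar <- op_arity(sym)
  if (length(args) != ar)
    stop(sprintf("operator '%s' takes %d argument(s), got %d",
                 sym, ar, length(args)), call. = FALSE)
  ok <- vapply(args, is_gp_node, logical(1))
  if (!all(ok)) stop("operator arguments must be program nodes", call. = FALSE)
  list(kind = "op", sym = sym, args = args)
}

#' @rdname gp-nodes
gp_var <- function(sym) {
  if (!sym %in% .gp_vars$sym)
    stop("unknown variable: ", sym, call. = FALSE)
  list(kind = "var", sym = sym)
}

#' @rdname gp-nodes
#' @param value Finite numeric constant.
gp_const <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("constant must be a single finite number", call. = FALSE)
  list(kind = "const", value = as.numeric(value))
}

is_gp_node <- function(x) {
  is.list(x) && !is.null(x$kind) && x$kind %in% c("op", "var", "const")
}

#' Wrap a node tree into a generator program
#'
#' @param root Root program node.
#' @param directed Logical; directed-mode programs may use the full variable
#'   set `{i, j, k, k', d, d_D, d_R}`, undirected programs only
#'   `{i, j, k, d}`. Illegal variables are a construction-time error.
#' @return An object of class `gp_program`.
#' @export
#' @examples
#' p <- gp_program(gp_op("+", gp_var("k'"), gp_const(1)), directed = TRUE)
#' program_length(p)
gp_program <- function(root, directed = TRUE) {
  if (!is_gp_node(root)) stop("root must be a program node", call. = FALSE)
  vars <- program_variables_node(root)
  bad <- setdiff(vars, legal_variables(directed))
  if (length(bad))
    stop(sprintf("variable(s) %s illegal in %s mode",
                 paste0("'", bad, "'", collapse = ", "),
                 if (directed) "directed" else "undirected"), call. = FALSE)
  structure(list(root = root, directed = directed), class = "gp_program")
}

program_variables_node <- function(node) {
  switch(node$kind,
    var = node$sym,
    const = character(0),
    op = unique(unlist(lapply(node$args, program_variables_node))))
}

#' Variables referenced by a program
#' @param program A `gp_program`.
#' @return Character vector of variable symbols appearing in the tree.
#' @export
program_variables <- function(program) {
  stopifnot(inherits(program, "gp_program"))
  sort(unique(program_variables_node(program$root)))
}

#' Program length (node count)
#'
#' The number of nodes of the expression tree; used as the parsimony measure
#' during search (an upper bound on the description complexity of the model).
#'
#' @param program A `gp_program`.
#' @return Integer node count (>= 1).
#' @export
program_length <- function(program) {
  stopifnot(inherits(program, "gp_program"))
  count_nodes(program$root)
}

count_nodes <- function(node) {
  if (node$kind != "op") return(1L)
  1L + sum(vapply(node$args, count_nodes, integer(1)))
}

# Protection shared by every operator result: NaN collapses to 0, magnitude is
# clamped so no non-finite value escapes a node.
protect_value <- function(x) {
  if (is.nan(x)) return(0)
  if (x > 1e300) return(1e300)
  if (x < -1e300) return(-1e300)
  x
}

#' Evaluate a generator program on one candidate arc
#'
#' @param program A `gp_program`.
#' @param ctx Named list with the variables the program references:
#'   `i`, `j` (1-based sequential identifiers), `k`, `k'` (degree
#'   descriptors), `d`, `d_D`, `d_R` (heuristic hop distances).
#' @return A finite numeric weight. Division by zero and `log` of a
#'   non-positive value return 0; every node's result is clamped to
#'   `[-1e300, 1e300]` so evaluation is total.
#' @export
#' @examples
#' p <- parse_program("(/ 1 k)", directed = TRUE)
#' evaluate_program(p, list(k = 0))  # protected division: 0
evaluate_program <- function(program, ctx) {
  stopifnot(inherits(program, "gp_program"))
  need <- program_variables(program)
  missing <- setdiff(need, names(ctx))
  if (length(missing))
    stop("context lacks variable(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  eval_node(program$root, ctx)
}

eval_node <- function(node, ctx) {
  if (node$kind == "const") return(node$value)
  if (node$kind == "var") return(as.numeric(ctx[[node$sym]]))
  a <- lapply(node$args, eval_node, ctx = ctx)
  r <- switch(node$sym,
    "+"  = a[[1]] + a[[2]],
    "-"  = a[[1]] - a[[2]],
    "*"  = a[[1]] * a[[2]],
    "/"  = if (a[[2]] == 0) 0 else a[[1]] / a[[2]],
    pow  = if (a[[1]] == 0 && a[[2]] < 0) 0 else abs(a[[1]])^a[[2]],
    exp  = exp(a[[1]]),
    log  = if (a[[1]] <= 0) 0 else log(a[[1]]),
    abs  = abs(a[[1]]),
    min  = min(a[[1]], a[[2]]),
    max  = max(a[[1]], a[[2]]),
    gt   = if (a[[1]] > a[[2]]) a[[3]] else a[[4]],
    lt   = if (a[[1]] < a[[2]]) a[[3]] else a[[4]],
    eq   = if (a[[1]] == a[[2]]) a[[3]] else a[[4]],
    eq0  = if (a[[1]] == 0) a[[2]] else a[[3]],
    psi  = affinity(ctx$i, ctx$j, a[[1]], a[[2]], a[[3]]),
    stop("unknown operator: ", node$sym, call. = FALSE))
  protect_value(r)
}

#' Affinity between two node identifiers
#'
#' Partitions the identifier space `1..n` into `g` groups by the modulo
#' operation and returns `a` when `i` and `j` fall in the same group
#' (i.e. are congruent modulo `g`), else `b`. Inside programs it appears as
#' the ternary operator `psi(g, a, b)` with `i` and `j` implicit.
#'
#' @param i,j Node sequential identifiers.
#' @param g Group count; truncated to an integer, values below 1 put all
#'   nodes in one group.
#' @param a,b Values returned for same-group / different-group pairs.
#' @return `a` or `b`.
#' @export
#' @examples
#' affinity(3, 7, 2, 10, 1)  # both odd: 10
#' affinity(2, 5, 2, 10, 1)  # different parity: 1
affinity <- function(i, j, g, a, b) {
  g <- trunc(g)
  if (g < 1) g <- 1
  if (i %% g == j %% g) a else b
}

#' Create a random generator program
#'
#' Grow-style tree generation: at each point a terminal is emitted with
#' probability `p_terminal` (always at `max_depth`), otherwise a uniformly
#' chosen operator whose children are generated recursively. Terminals are
#' constants with probability `p_const`, else a uniformly chosen mode-legal
#' variable. Draws come from the R random number generator, so a fixed seed
#' reproduces the program.
#'
#' @param directed Logical mode; selects the legal variable set.
#' @param max_depth Maximum tree depth (root at depth 0). Default 5.
#' @param p_terminal Probability of placing a terminal before the depth cap.
#'   Default 0.4.
#' @param p_const Probability that a terminal is a constant. Default 0.3.
#' @param const_range Range for uniform ephemeral constants. Default
#'   `c(-5, 5)`.
#' @return A valid `gp_program`.
#' @export
random_program <- function(directed = TRUE, max_depth = 5, p_terminal = 0.4,
                           p_const = 0.3, const_range = c(-5, 5)) {
  stopifnot(max_depth >= 0, p_terminal > 0, p_terminal <= 1)
  vars <- legal_variables(directed)
  grow <- function(depth) {
    if (depth >= max_depth || runif(1) < p_terminal) {
      if (runif(1) < p_const) {
        gp_const(runif(1, const_range[1], const_range[2]))
      } else {
        gp_var(vars[sample.int(length(vars), 1L)])
      }
    } else {
      sym <- .gp_ops$sym[sample.int(nrow(.gp_ops), 1L)]
      do.call(gp_op, c(list(sym), replicate(op_arity(sym), grow(depth + 1L),
                                            simplify = FALSE)))
    }
  }
  gp_program(grow(0L), directed = directed)
}

#' Mutate a generator program by sub-tree replacement
#'
#' Selects a node of the parent uniformly at random, removes the sub-tree
#' rooted there and splices in a sub-tree selected uniformly at random from a
#' freshly created random tree. The parent is not modified.
#'
#' @param parent A `gp_program`.
#' @inheritParams random_program
#' @return A new valid `gp_program` differing from the parent in exactly one
#'   replaced sub-tree.
#' @export
mutate_program <- function(parent, max_depth = 5, p_terminal = 0.4,
                           p_const = 0.3, const_range = c(-5, 5)) {
  stopifnot(inherits(parent, "gp_program"))
  n <- program_length(parent)
  target <- sample.int(n, 1L)
  donor <- random_program(directed = parent$directed, max_depth = max_depth,
                          p_terminal = p_terminal, p_const = p_const,
                          const_range = const_range)
  dn <- program_length(donor)
  dsel <- sample.int(dn, 1L)
  sub <- extract_subtree(donor$root, dsel)
  root <- replace_subtree(parent$root, target, sub)
  gp_program(root, directed = parent$directed)
}

# Preorder node extraction: node number `idx` (1-based) of the tree.
extract_subtree <- function(node, idx) {
  res <- walk_extract(node, idx)
  res$node
}

walk_extract <- function(node, idx) {
  if (idx == 1L) return(list(node = node, used = count_nodes(node)))
  used <- 1L
  if (node$kind == "op") {
    for (child in node$args) {
      sz <- count_nodes(child)
      if (idx - used <= sz) return(walk_extract(child, idx - used))
      used <- used + sz
    }
  }
  stop("node index out of range", call. = FALSE)
}

replace_subtree <- function(node, idx, sub) {
  if (idx == 1L) return(sub)
  if (node$kind != "op") stop("node index out of range", call. = FALSE)
  used <- 1L
  args <- node$args
  for (ci in seq_along(args)) {
    sz <- count_nodes(args[[ci]])
    if (idx - used <= sz) {
      args[[ci]] <- replace_subtree(args[[ci]], idx - used, sub)
      node$args <- args
      return(node)
    }
    used <- used + sz
  }
  stop("node index out of range", call. = FALSE)
}

#' @export
print.gp_program <- function(x, ...) {
  cat("<generator program (", if (x$directed) "directed" else "undirected",
      ", length ", program_length(x), ")>\n", sep = "")
  cat("  ", format_program(x), "\n", sep = "")
  cat("  infix: ", format_program_infix(x), "\n", sep = "")
  invisible(x)
}
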