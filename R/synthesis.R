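# Flatten a program into preorder parallel vectors for the C++ evaluator.
program_flatten <- function(program) {
  stopifnot(inherits(program, "gp_program"))
  kind <- integer(0); code <- integer(0); arity <- integer(0)
  value <- numeric(0)
  walk <- function(node) {
    if (node$kind == "op") {
      kind <<- c(kind, 0L)
      code <<- c(code, .gp_ops$code[match(node$sym, .gp_ops$sym)])
      arity <<- c(arity, op_arity(node$sym))
      value <<- c(value, 0)
      for (child in node$args) walk(child)
    } else if (node$kind == "var") {
      kind <<- c(kind, 1L)
      code <<- c(code, .gp_vars$code[match(node$sym, .gp_vars$sym)])
      arity <<- c(arity, 0L)
      value <<- c(value, 0)
    } else {
      kind <<- c(kind, 2L)
      code <<- c(code, 0L)
      arity <<- c(arity, 0L)
      value <<- c(value, node$value)
    }
  }
  walk(program$root)
  list(kind = kind, code = code, arity = arity, value = value)
}

#' Growth configuration
#'
#' Parameters of the arc-by-arc growth process: the candidate sampling ratio
#' and floor, and the random-walk budget of the heuristic distance estimator.
#'
#' @param s_r Sampling ratio in (0, 1]; each growth step scores
#'   `max(min_sample, round(s_r * n^2))` candidate arcs (capped at the number
#'   of remaining legal arcs).
#' @param min_sample Floor on the candidate sample size.
#' @param walks Number of independent random walks per distance query.
#' @param walk_length Maximum walk length in hops; unreachable queries return
#'   the cap `walk_length + 1`.
#' @return A list of class `growth_config`.
#' @export
growth_config <- function(s_r = 0.001, min_sample = 25, walks = 5,
                          walk_length = 7) {
  stopifnot(s_r > 0, s_r <= 1, min_sample >= 1, walks >= 1, walk_length >= 1)
  structure(list(s_r = s_r, min_sample = as.integer(min_sample),
                 walks = as.integer(walks),
                 walk_length = as.integer(walk_length)),
            class = "growth_config")
}

sample_size_for <- function(n, cfg, remaining) {
  want <- max(cfg$min_sample, round(cfg$s_r * n^2))
  min(want, remaining)
}

#' Sample candidate arcs
#'
#' Draws distinct candidate arcs uniformly from the arcs that do not yet
#' exist in the network (self-links excluded). The sample size follows the
#' growth configuration: `max(min_sample, round(s_r * n^2))`, capped at the
#' number of remaining legal arcs.
#'
#' @param g An igraph network (the partially built state).
#' @param cfg A [growth_config()].
#' @return A two-column integer matrix of candidate arcs (origin, target);
#'   rows are unordered pairs when `g` is undirected (orientation of the
#'   returned pair is random).
#' @export
sample_candidates <- function(g, cfg = growth_config()) {
  n <- igraph::vcount(g)
  directed <- igraph::is_directed(g)
  total <- if (directed) n * (n - 1) else n * (n - 1) / 2
  remaining <- total - igraph::ecount(g)
  if (remaining <= 0)
    stop("network complete: no legal candidate arcs left", call. = FALSE)
  s <- sample_size_for(n, cfg, remaining)
  el <- igraph::as_edgelist(g, names = FALSE)
  keyfun <- function(a, b) {
    if (!directed) {
      lo <- pmin(a, b); hi <- pmax(a, b); a <- lo; b <- hi
    }
    a * (n + 1) + b
  }
  existing <- if (nrow(el)) keyfun(el[, 1], el[, 2]) else numeric(0)
  out <- matrix(0L, nrow = 0, ncol = 2)
  seen <- existing
  while (nrow(out) < s) {
    need <- s - nrow(out)
    a <- sample.int(n, 2 * need + 8, replace = TRUE)
    b <- sample.int(n, 2 * need + 8, replace = TRUE)
    ok <- a != b
    a <- a[ok]; b <- b[ok]
    kk <- keyfun(a, b)
    fresh <- !(kk %in% seen) & !duplicated(kk)
    a <- a[fresh]; b <- b[fresh]; kk <- kk[fresh]
    if (length(a) > need) { a <- a[1:need]; b <- b[1:need]; kk <- kk[1:need] }
    out <- rbind(out, cbind(a, b))
    seen <- c(seen, kk)
  }
  dimnames(out) <- NULL
  out
}

#' Arc selection probabilities
#'
#' Maps candidate weights to selection probabilities: `P` is proportional to
#' `pi(w) * w` where the indicator `pi(w)` is 1 for strictly positive weights
#' and 0 otherwise. When no weight in the sample is strictly positive, all
#' weights are replaced by 1, giving the uniform distribution.
#'
#' @param weights Numeric vector of candidate weights.
#' @return Probability vector of the same length, summing to 1.
#' @export
#' @examples
#' selection_probabilities(c(2, 3, 5))
#' selection_probabilities(c(0, 0, 0))   # uniform fallback
#' selection_probabilities(c(-1, 2, 2))  # negative weight gated to 0
selection_probabilities <- function(weights) {
  stopifnot(is.numeric(weights), length(weights) >= 1)
  gated <- ifelse(weights > 0, weights, 0)
  tot <- sum(gated)
  if (tot <= 0) return(rep(1 / length(weights), length(weights)))
  gated / tot
}

#' Random-walk heuristic distances between two nodes
#'
#' Estimates hop distances by bounded random walks rather than exact search:
#' linking behaviour is modelled as hop-by-hop navigation, not omniscient
#' shortest-path knowledge. Runs `walks` independent walks of at most
#' `walk_length` hops from the origin and returns the earliest hop at which
#' any walk first reaches the target, or the cap `walk_length + 1` if none
#' does. Estimates therefore never undershoot the true shortest-path
#' distance.
#'
#' @param g An igraph network.
#' @param origin,target Node identifiers (1-based), distinct.
#' @param cfg A [growth_config()] supplying the walk budget.
#' @return Named numeric vector with `d` (undirected view), and for directed
#'   networks `d_D` (following arcs) and `d_R` (against arcs); `NA` for the
#'   directed entries of undirected networks.
#' @export
heuristic_distances <- function(g, origin, target, cfg = growth_config()) {
  stopifnot(origin != target)
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  res <- walk_distances_cpp(el, n, igraph::is_directed(g),
                            as.integer(origin), as.integer(target),
                            cfg$walks, cfg$walk_length)
  c(d = res[1], d_D = res[2], d_R = res[3])
}

#' Grow a network from a generator program
#'
#' Runs the generative process: all `n` nodes exist from the start; at each
#' of `m` steps a sample of candidate arcs is drawn, weighted by the program
#' (the arc context reflects the state before the step), and one arc is
#' selected with probability proportional to its gated weight
#' (see [selection_probabilities()]). Self-links and duplicate arcs are never
#' created. Draws come from the R RNG, so a fixed seed reproduces the
#' network exactly.
#'
#' @param program A `gp_program`; its mode fixes the directedness of the
#'   result.
#' @param n Number of nodes.
#' @param m Number of arcs; must not exceed the number of legal arcs.
#' @param cfg A [growth_config()].
#' @return An igraph network with `n` nodes (identifiers 1..n) and `m` arcs.
#' @export
#' @examples
#' set.seed(1)
#' g <- generate_network(parse_program("k'"), n = 50, m = 200)
#' igraph::ecount(g)
generate_network <- function(program, n, m, cfg = growth_config()) {
  stopifnot(inherits(program, "gp_program"), n >= 2, m >= 1)
  directed <- program$directed
  legal <- if (directed) n * (n - 1) else n * (n - 1) / 2
  if (m > legal)
    stop(sprintf("m = %d exceeds the %d legal arcs for n = %d", m, legal, n),
         call. = FALSE)
  flat <- program_flatten(program)
  edges <- grow_network_cpp(flat, as.integer(n), as.integer(m), directed,
                            cfg$s_r, cfg$min_sample, cfg$walks,
                            cfg$walk_length)
  g <- igraph::make_empty_graph(n = n, directed = directed)
  igraph::add_edges(g, as.vector(t(edges)))
}
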