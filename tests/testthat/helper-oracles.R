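# Independent oracles used across the suite.

# Exact 1-D optimal transport cost via the monotone (quantile) coupling:
# enumerates the optimal plan explicitly instead of integrating the CDF
# difference, so it exercises a different algorithm than the implementation.
oracle_emd_transport <- function(p, q, pos) {
  cp <- cumsum(p)
  cq <- cumsum(q)
  brk <- sort(unique(c(0, cp, cq)))
  cost <- 0
  for (t in seq_len(length(brk) - 1)) {
    mass <- brk[t + 1] - brk[t]
    if (mass <= 0) next
    mid <- (brk[t] + brk[t + 1]) / 2
    ip <- which(cp >= mid - 1e-15)[1]
    iq <- which(cq >= mid - 1e-15)[1]
    cost <- cost + mass * abs(pos[ip] - pos[iq])
  }
  cost
}

# Reference triads in standard census order, as edge lists on nodes 1..3.
triad_reference <- list(
  "003"  = matrix(integer(0), ncol = 2),
  "012"  = rbind(c(1, 2)),
  "102"  = rbind(c(1, 2), c(2, 1)),
  "021D" = rbind(c(2, 1), c(2, 3)),
  "021U" = rbind(c(1, 2), c(3, 2)),
  "021C" = rbind(c(1, 2), c(2, 3)),
  "111D" = rbind(c(1, 2), c(2, 1), c(3, 2)),
  "111U" = rbind(c(1, 2), c(2, 1), c(2, 3)),
  "030T" = rbind(c(1, 2), c(3, 2), c(1, 3)),
  "030C" = rbind(c(3, 2), c(2, 1), c(1, 3)),
  "201"  = rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 2)),
  "120D" = rbind(c(2, 1), c(2, 3), c(1, 3), c(3, 1)),
  "120U" = rbind(c(1, 2), c(3, 2), c(1, 3), c(3, 1)),
  "120C" = rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 1)),
  "210"  = rbind(c(1, 2), c(2, 3), c(3, 2), c(1, 3), c(3, 1)),
  "300"  = rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))
)

triad_code <- function(adj) {
  # 6-bit code of a 3-node digraph from its boolean adjacency matrix
  bits <- c(adj[1, 2], adj[2, 1], adj[1, 3], adj[3, 1], adj[2, 3], adj[3, 2])
  sum(bits * 2^(0:5))
}

triad_canonical <- function(adj) {
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  min(vapply(perms, function(pp) triad_code(adj[pp, pp]), numeric(1)))
}

triad_lookup <- local({
  map <- new.env(parent = emptyenv())
  for (nm in names(triad_reference)) {
    el <- triad_reference[[nm]]
    adj <- matrix(FALSE, 3, 3)
    if (nrow(el)) adj[el] <- TRUE
    assign(as.character(triad_canonical(adj)), nm, envir = map)
  }
  map
})

# Exhaustive triple-enumeration census of the 13 connected directed classes.
oracle_triad_counts <- function(g) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  counts <- stats::setNames(numeric(16), names(triad_reference))
  trips <- utils::combn(n, 3)
  for (t in seq_len(ncol(trips))) {
    sub <- A[trips[, t], trips[, t]]
    cls <- get(as.character(triad_canonical(sub)), envir = triad_lookup)
    counts[cls] <- counts[cls] + 1
  }
  counts[4:16]
}

tree_depth <- function(node) {
  if (node$kind != "op") return(0L)
  1L + max(vapply(node$args, tree_depth, integer(1)))
}

expect_valid_program <- function(p, directed) {
  expect_s3_class(p, "gp_program")
  expect_identical(p$directed, directed)
  vars <- program_variables(p)
  legal <- if (directed) c("i", "j", "k", "k'", "d", "d_D", "d_R")
           else c("i", "j", "k", "d")
  expect_true(all(vars %in% legal))
  # round-trip while we are at it
  expect_identical(format_program(parse_program(format_program(p),
                                                directed = directed)),
                   format_program(p))
}

edge_set <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  if (!igraph::is_directed(g)) {
    el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  }
  sort(paste(el[, 1], el[, 2]))
}
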