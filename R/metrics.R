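#' Earth mover's distance between two 1-D distributions
#'
#' Optimal-transport cost between two probability distributions on a shared
#' ordered support, with ground distance equal to the spacing between bin
#' positions. For the 1-D case this is the integral of the absolute CDF
#' difference.
#'
#' @param p,q Non-negative mass vectors of equal length, each summing to 1.
#' @param positions Increasing numeric bin positions (default unit spacing).
#' @return Non-negative scalar; 0 iff `p == q`.
#' @export
#' @examples
#' emd_1d(c(0.75, 0.25), c(0.25, 0.75))  # 0.5
emd_1d <- function(p, q, positions = seq_along(p) - 1) {
  if (length(p) == 0) stop("empty support", call. = FALSE)
  stopifnot(length(p) == length(q), length(positions) == length(p),
            all(p >= 0), all(q >= 0))
  if (abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8)
    stop("distributions must each have total mass 1", call. = FALSE)
  if (length(p) == 1) return(0)
  cdf_diff <- cumsum(p - q)
  sum(abs(cdf_diff[-length(p)]) * diff(positions))
}

#' Ratio-based dissimilarity between two count vectors
#'
#' A cheap symmetric divergence used for distance distributions and triadic
#' profiles: with add-one smoothing of the raw counts, the mean over bins of
#' `max(x+1, y+1) / min(x+1, y+1) - 1`. Zero iff the counts are equal;
#' grows with per-bin disagreement.
#'
#' @param x,y Non-negative count vectors on the same support.
#' @return Non-negative scalar.
#' @export
ratio_dissimilarity <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1, all(x >= 0), all(y >= 0))
  xs <- x + 1
  ys <- y + 1
  mean(pmax(xs, ys) / pmin(xs, ys) - 1)
}

#' Triadic profile of a network
#'
#' Directed networks: the frequency vector over the 13 weakly connected
#' 3-node digraph isomorphism classes (standard triad-census order with the
#' three classes containing an isolated vertex dropped). Undirected
#' networks: frequencies of open triples and triangles.
#'
#' @param g An igraph network with at least 3 nodes.
#' @return Normalized frequency vector (sums to 1 when any connected triad
#'   exists, otherwise all zeros); raw class counts in attribute `"counts"`.
#' @export
triadic_profile <- function(g) {
  counts <- triad_counts(g)
  tot <- sum(counts)
  prof <- if (tot > 0) counts / tot else counts * 0
  attr(prof, "counts") <- counts
  prof
}

triad_counts <- function(g) {
  stopifnot(igraph::vcount(g) >= 3)
  if (igraph::is_directed(g)) {
    tc <- suppressWarnings(igraph::triad_census(g))
    counts <- tc[4:16]
    names(counts) <- c("021D", "021U", "021C", "111D", "111U", "030T",
                       "030C", "201", "120D", "120U", "120C", "210", "300")
  } else {
    tri <- sum(igraph::count_triangles(g)) / 3
    paths2 <- sum(choose(igraph::degree(g), 2))
    counts <- c(open = paths2 - 3 * tri, triangle = tri)
  }
  counts
}

#' Shortest-path distance distribution
#'
#' Distribution of finite shortest-path hop counts over node pairs (ordered
#' pairs for the directed view, unordered for the undirected view), with an
#' explicit bucket for unreachable pairs. Exhaustive BFS for networks of up
#' to 1000 nodes; larger networks are sampled from 1000 source nodes.
#'
#' @param g An igraph network.
#' @param directed Use directed distances (only meaningful for directed
#'   networks); `FALSE` measures on the undirected view.
#' @param max_exact Largest node count for which all sources are used.
#' @return List with `counts` (named vector over hops `1..max`) and
#'   `unreachable` (count of unreachable pairs).
#' @export
distance_distribution <- function(g, directed = igraph::is_directed(g),
                                  max_exact = 1000) {
  n <- igraph::vcount(g)
  mode <- if (directed && igraph::is_directed(g)) "out" else "all"
  if (n <= max_exact) {
    D <- igraph::distances(g, mode = mode)
    if (mode == "all") {
      vals <- D[upper.tri(D)]
    } else {
      vals <- D[row(D) != col(D)]
    }
  } else {
    src <- sample.int(n, max_exact)
    D <- igraph::distances(g, v = src, mode = mode)
    # drop each source's self-distance; keep everything else
    D[cbind(seq_along(src), src)] <- NA
    vals <- as.vector(D)
    vals <- vals[!is.na(vals)]
  }
  unreach <- sum(!is.finite(vals))
  finite <- vals[is.finite(vals)]
  maxhop <- if (length(finite)) max(finite) else 0
  counts <- if (maxhop > 0) tabulate(finite, nbins = maxhop) else numeric(0)
  if (maxhop > 0) names(counts) <- seq_len(maxhop)
  list(counts = counts, unreachable = unreach)
}

#' PageRank value set of a network
#'
#' PageRank centralities with damping 0.85 (exact algebraic solution via
#' igraph). The reverse variant scores the arc-reversed network, capturing
#' "source" rather than "sink" centrality.
#'
#' @param g An igraph network.
#' @param reverse Reverse all arcs first (directed networks only).
#' @return Numeric vector of PageRank values summing to 1.
#' @export
pagerank_values <- function(g, reverse = FALSE) {
  if (reverse && igraph::is_directed(g)) g <- igraph::reverse_edges(g)
  igraph::page_rank(g, damping = 0.85)$vector
}

metric_names <- function(directed) {
  if (directed) c("k_in", "k_out", "pr_d", "pr_r", "d_d", "d_u", "triadic")
  else c("k", "pr", "d_u", "triadic")
}

#' Feature bundle of a network
#'
#' Extracts every feature distribution entering the fitness function:
#' degree sequences (in/out for directed networks), direct and reverse
#' PageRank value sets, directed and undirected distance distributions, and
#' the triadic profile.
#'
#' @param g An igraph network.
#' @return A list of class `network_features`.
#' @export
network_features <- function(g) {
  directed <- igraph::is_directed(g)
  f <- if (directed) {
    list(directed = TRUE,
         k_in = igraph::degree(g, mode = "in"),
         k_out = igraph::degree(g, mode = "out"),
         pr_d = pagerank_values(g),
         pr_r = pagerank_values(g, reverse = TRUE),
         d_d = distance_distribution(g, directed = TRUE),
         d_u = distance_distribution(g, directed = FALSE),
         triad = triad_counts(g))
  } else {
    list(directed = FALSE,
         k = igraph::degree(g),
         pr = pagerank_values(g),
         d_u = distance_distribution(g, directed = FALSE),
         triad = triad_counts(g))
  }
  structure(f, class = "network_features")
}

as_features <- function(x) {
  if (inherits(x, "network_features")) x else network_features(x)
}

dissim_degree <- function(x, y) {
  hi <- max(x, y, 0)
  p <- tabulate(x + 1, nbins = hi + 1)
  q <- tabulate(y + 1, nbins = hi + 1)
  emd_1d(p / sum(p), q / sum(q), positions = 0:hi)
}

dissim_pagerank <- function(v1, v2, bins = 50) {
  lo <- min(v1, v2)
  hi <- max(v1, v2)
  if (hi <= lo) return(0)
  brk <- seq(lo, hi, length.out = bins + 1)
  width <- brk[2] - brk[1]
  p <- tabulate(pmin(findInterval(v1, brk, rightmost.closed = TRUE), bins),
                nbins = bins)
  q <- tabulate(pmin(findInterval(v2, brk, rightmost.closed = TRUE), bins),
                nbins = bins)
  centers <- brk[-1] - width / 2
  emd_1d(p / sum(p), q / sum(q), positions = centers)
}

dissim_distance <- function(h1, h2) {
  hops <- max(length(h1$counts), length(h2$counts))
  pad <- function(h) c(h$counts, numeric(hops - length(h$counts)),
                       h$unreachable)
  ratio_dissimilarity(pad(h1), pad(h2))
}

#' Per-metric dissimilarities between two networks
#'
#' @param target,candidate igraph networks (or precomputed
#'   [network_features()]) of matching directedness.
#' @return Named vector of raw dissimilarities `D_m`: degree EMDs, PageRank
#'   EMDs, ratio dissimilarities of the distance distributions, and the
#'   ratio dissimilarity of the triadic profile counts.
#' @export
network_dissimilarities <- function(target, candidate) {
  ft <- as_features(target)
  fc <- as_features(candidate)
  if (ft$directed != fc$directed)
    stop("target and candidate must have matching directedness",
         call. = FALSE)
  if (ft$directed) {
    c(k_in = dissim_degree(ft$k_in, fc$k_in),
      k_out = dissim_degree(ft$k_out, fc$k_out),
      pr_d = dissim_pagerank(ft$pr_d, fc$pr_d),
      pr_r = dissim_pagerank(ft$pr_r, fc$pr_r),
      d_d = dissim_distance(ft$d_d, fc$d_d),
      d_u = dissim_distance(ft$d_u, fc$d_u),
      triadic = ratio_dissimilarity(ft$triad, fc$triad))
  } else {
    c(k = dissim_degree(ft$k, fc$k),
      pr = dissim_pagerank(ft$pr, fc$pr),
      d_u = dissim_distance(ft$d_u, fc$d_u),
      triadic = ratio_dissimilarity(ft$triad, fc$triad))
  }
}

#' Erdős–Rényi dissimilarity baseline for a target network
#'
#' For each metric, the mean dissimilarity between the target and `reps`
#' G(n, m) random networks matched in node and arc count. Dividing candidate
#' dissimilarities by these baselines puts all metrics on a common scale on
#' which 1 means "no better than random".
#'
#' @param target igraph network.
#' @param reps Number of random networks (default 30).
#' @return Named vector of class `er_baseline` with per-metric baseline
#'   means.
#' @export
er_baseline <- function(target, reps = 30) {
  ft <- as_features(target)
  n <- if (ft$directed) length(ft$k_in) else length(ft$k)
  m <- if (ft$directed) sum(ft$k_in) else sum(ft$k) / 2
  D <- vapply(seq_len(reps), function(s) {
    er <- igraph::sample_gnm(n, m, directed = ft$directed)
    network_dissimilarities(ft, er)
  }, numeric(length(metric_names(ft$directed))))
  structure(rowMeans(D), class = "er_baseline")
}

#' Fitness of a candidate network against a target
#'
#' Divides every raw dissimilarity `D_m` by the ER baseline `b_m` and takes
#' the worst (largest) ratio as the fitness. A fitness of 1 means the
#' candidate matches the target no better than a size-matched random
#' network; 0 means an exact match on every metric.
#'
#' @param target igraph network or precomputed features.
#' @param candidate igraph network or precomputed features.
#' @param baselines Per-metric baselines from [er_baseline()] (computed from
#'   the target if omitted).
#' @return A list of class `dissimilarity_vector` with elements `D`, `b`,
#'   `ratios` and `fitness`. A zero baseline yields ratio 0 when `D_m` is
#'   also 0, otherwise `Inf`.
#' @export
network_fitness <- function(target, candidate, baselines = NULL) {
  ft <- as_features(target)
  if (is.null(baselines)) baselines <- er_baseline(ft)
  D <- network_dissimilarities(ft, candidate)
  b <- as.numeric(baselines)
  r <- ifelse(b == 0, ifelse(D == 0, 0, Inf), D / b)
  names(r) <- names(D)
  structure(list(D = D, b = stats::setNames(b, names(D)), ratios = r,
                 fitness = max(r)),
            class = "dissimilarity_vector")
}

#' @export
print.dissimilarity_vector <- function(x, ...) {
  tab <- data.frame(D = x$D, baseline = x$b, ratio = x$ratios)
  print(round(tab, 4))
  cat("fitness (max ratio):", format(x$fitness, digits = 6), "\n")
  invisible(x)
}
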