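#' Read a network file
#'
#' Accepts plain two-column edge lists (whitespace separated, `#` comment
#' lines ignored) and GML files (by `.gml` extension). Node labels may be
#' arbitrary strings; they are mapped to 1-based sequential identifiers in
#' order of first appearance, and the original labels are kept as the vertex
#' attribute `label`. Directedness of an edge list is read from a
#' `# directed: true/false` header comment, overridable with the `directed`
#' argument. Self-loops and duplicate arcs are rejected — the growth model
#' cannot produce them.
#'
#' @param path File path.
#' @param directed Logical override; default `NULL` uses the file header
#'   (edge lists, defaulting to directed) or the GML content.
#' @return An igraph network with nodes 1..n.
#' @export
read_network <- function(path, directed = NULL) {
  if (grepl("\\.gml$", path, ignore.case = TRUE)) {
    g <- igraph::read_graph(path, format = "gml")
    if (!is.null(directed) && directed != igraph::is_directed(g))
      g <- if (directed) igraph::as_directed(g, mode = "arbitrary")
           else igraph::as_undirected(g, mode = "each")
    el <- igraph::as_edgelist(g, names = FALSE)
    labels <- if ("label" %in% igraph::vertex_attr_names(g))
      as.character(igraph::V(g)$label) else as.character(seq_len(igraph::vcount(g)))
    return(build_network(el[, 1], el[, 2], labels, igraph::is_directed(g),
                         src = path))
  }
  lines <- readLines(path, warn = FALSE)
  header_dir <- NA
  hd <- grep("^\\s*#\\s*directed\\s*:", lines, value = TRUE)
  if (length(hd))
    header_dir <- grepl("true", hd[1], ignore.case = TRUE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  a <- character(length(rows))
  b <- character(length(rows))
  for (t in seq_along(rows)) {
    parts <- strsplit(trimws(lines[rows[t]]), "\\s+")[[1]]
    if (length(parts) < 2)
      stop(sprintf("malformed edge on line %d of %s: '%s'", rows[t], path,
                   lines[rows[t]]), call. = FALSE)
    a[t] <- parts[1]
    b[t] <- parts[2]
  }
  if (is.null(directed)) directed <- if (is.na(header_dir)) TRUE else header_dir
  hn <- grep("^\\s*#\\s*nodes\\s*:", lines, value = TRUE)
  n_header <- if (length(hn)) as.integer(sub(".*:\\s*", "", hn[1])) else NA
  if (all(grepl("^[0-9]+$", c(a, b))) && !any(c(a, b) == "0")) {
    # pure positive-integer labels are kept as the node identifiers
    from <- as.integer(a)
    to <- as.integer(b)
    n <- max(from, to, n_header, na.rm = TRUE)
    build_network(from, to, as.character(seq_len(n)), directed, src = path)
  } else {
    labels <- unique(c(rbind(a, b)))
    build_network(match(a, labels), match(b, labels), labels, directed,
                  src = path)
  }
}

build_network <- function(from, to, labels, directed, src = "input") {
  if (any(from == to))
    stop("self-loop found in ", src, "; the growth model forbids self-links",
         call. = FALSE)
  n <- length(labels)
  key <- if (directed) from * (n + 1) + to
         else pmin(from, to) * (n + 1) + pmax(from, to)
  if (anyDuplicated(key))
    stop("duplicate arc found in ", src,
         "; the growth model forbids duplicate links", call. = FALSE)
  g <- igraph::make_empty_graph(n = n, directed = directed)
  g <- igraph::add_edges(g, as.vector(rbind(from, to)))
  igraph::V(g)$label <- labels
  g
}

#' Write a network file
#'
#' Edge lists are written as whitespace-separated 1-based identifier pairs
#' with a `# directed:` header; `.gml` paths are written as GML. The
#' label-to-identifier map (when labels differ from identifiers) is recorded
#' in header comments of edge lists and in GML `label` fields.
#'
#' @param g An igraph network.
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_network <- function(g, path) {
  if (grepl("\\.gml$", path, ignore.case = TRUE)) {
    if (!"label" %in% igraph::vertex_attr_names(g))
      igraph::V(g)$label <- as.character(seq_len(igraph::vcount(g)))
    igraph::write_graph(g, path, format = "gml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  hdr <- c(sprintf("# directed: %s",
                   tolower(as.character(igraph::is_directed(g)))),
           sprintf("# nodes: %d", igraph::vcount(g)))
  if ("label" %in% igraph::vertex_attr_names(g)) {
    labs <- igraph::V(g)$label
    if (!identical(as.character(seq_along(labs)), as.character(labs)))
      hdr <- c(hdr, sprintf("# label %d %s", seq_along(labs), labs))
  }
  writeLines(c(hdr, sprintf("%d %d", el[, 1], el[, 2])), path)
  invisible(path)
}

#' Built-in fixture generators
#'
#' Produces a (program, network) pair for one of four canonical growth
#' rules: `ER` (constant weight), `PA` (target-degree preferential
#' attachment), `hyperbolic` (arc propensity falling hyperbolically with the
#' origin identifier) and `affinity` (identifier groups with within-group
#' preference, `psi(g, 10, 1)`).
#'
#' @param kind One of `"ER"`, `"PA"`, `"hyperbolic"`, `"affinity"`.
#' @param n,m Network size; `fixture_sizes()` lists the five preset sizes.
#' @param seed Optional integer seed for a reproducible network.
#' @param dir Optional directory; when given, the program and network are
#'   written to `<kind>_<n>_<m>.prog` / `.edges` there.
#' @param directed Program mode (default directed).
#' @param groups Group count of the affinity fixture.
#' @param cfg A [growth_config()].
#' @return List with `program` (a `gp_program`), `network` (igraph), and
#'   file paths when `dir` was given.
#' @export
make_fixture <- function(kind = c("ER", "PA", "hyperbolic", "affinity"),
                         n, m, seed = NULL, dir = NULL, directed = TRUE,
                         groups = 4, cfg = growth_config()) {
  kind <- match.arg(kind)
  text <- switch(kind,
    ER = "1",
    PA = if (directed) "k'" else "k",
    hyperbolic = "(/ 1 i)",
    affinity = sprintf("(psi %d 10 1)", groups))
  program <- parse_program(text, directed = directed)
  if (!is.null(seed)) set.seed(seed)
  network <- generate_network(program, n, m, cfg)
  out <- list(program = program, network = network)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    stem <- file.path(dir, sprintf("%s_%d_%d", tolower(kind), n, m))
    out$program_file <- write_program(program, paste0(stem, ".prog"))
    out$network_file <- write_network(network, paste0(stem, ".edges"))
  }
  out
}

#' @rdname make_fixture
#' @export
fixture_sizes <- function() {
  data.frame(n = c(100L, 200L, 300L, 400L, 500L),
             m = c(1000L, 2000L, 3000L, 4000L, 5000L))
}

#' Run configuration
#'
#' Bundles every tunable of a search run and round-trips losslessly through
#' YAML, so a run is fully described by one small config file.
#'
#' @param mode `"directed"` or `"undirected"`.
#' @param s_r,min_sample,walks,walk_length See [growth_config()].
#' @param tolerance Anti-bloat tolerance.
#' @param stall_limit Stop after this many stable generations.
#' @param seed Integer seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(mode = c("directed", "undirected"), s_r = 0.001,
                       min_sample = 25, walks = 5, walk_length = 7,
                       tolerance = 0.10, stall_limit = 1000, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(tolerance >= 0, stall_limit >= 1)
  structure(list(mode = mode, s_r = s_r, min_sample = as.integer(min_sample),
                 walks = as.integer(walks),
                 walk_length = as.integer(walk_length),
                 tolerance = tolerance, stall_limit = as.integer(stall_limit),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
as_growth_config <- function(config) {
  growth_config(s_r = config$s_r, min_sample = config$min_sample,
                walks = config$walks, walk_length = config$walk_length)
}
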