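#' Canonical generators
#'
#' The two classical growth rules expressible in one node: `er`, a constant
#' weight (uniform random attachment, the Erdős–Rényi growth limit), and
#' `pa`, the degree of the target node (preferential attachment).
#'
#' @param directed Program mode.
#' @return Named list of `gp_program`s.
#' @export
canonical_generators <- function(directed = TRUE) {
  list(er = parse_program("1", directed = directed),
       pa = parse_program(if (directed) "k'" else "k", directed = directed))
}

#' Evolutionary search for a generator reproducing a target network
#'
#' A two-individual mutation-only search. The state holds `w_o`, the
#' best-fitness program found so far, and `w_s`, the shortest evaluated
#' program whose fitness is within `tolerance` (default 10%) of `w_o`'s —
#' the anti-bloat rule; possibly `w_o == w_s`. Each generation clones a
#' parent drawn uniformly from `{w_o, w_s}`, mutates it by sub-tree
#' replacement, grows one synthetic network at the target's size, and scores
#' it with the ER-normalized minimax fitness. `w_o` is replaced on strict
#' improvement; `w_s` is re-derived over the archive of all evaluated
#' programs whenever anything changes. The search stops after `stall_limit`
#' generations without change to either individual and returns `w_s`.
#'
#' @param target igraph network to reproduce.
#' @param cfg A [growth_config()].
#' @param tolerance Anti-bloat tolerance (default 0.10): `w_s` must satisfy
#'   `fitness(w_s) <= (1 + tolerance) * fitness(w_o)`.
#' @param stall_limit Stable generations before stopping (default 1000).
#' @param max_generations Hard cap on generations (safety valve).
#' @param er_reps Random networks used for the fitness baseline.
#' @param seed Optional integer seed; fixes the full trajectory.
#' @param eval_reps Synthetic networks grown per fitness evaluation
#'   (default 1; the fitness is averaged when larger).
#' @inheritParams random_program
#' @param log_file Optional path; one JSON line is appended per accepted
#'   change (generation, event, fitness, ratios, program, length).
#' @param verbose Print accepted changes to stderr.
#' @return List of class `netgp_search` with `w_s` (the result), `w_o`,
#'   their fitnesses, the per-change `log`, the evaluation `archive`
#'   (data.frame: generation, fitness, length, program) and bookkeeping
#'   fields.
#' @export
evolve <- function(target, cfg = growth_config(), tolerance = 0.10,
                   stall_limit = 1000, max_generations = Inf, er_reps = 30,
                   seed = NULL, eval_reps = 1, max_depth = 5,
                   p_terminal = 0.4, p_const = 0.3, const_range = c(-5, 5),
                   log_file = NULL, verbose = FALSE) {
  stopifnot(tolerance >= 0, stall_limit >= 1)
  if (!is.null(seed)) set.seed(seed)
  directed <- igraph::is_directed(target)
  n <- igraph::vcount(target)
  m <- igraph::ecount(target)
  ft <- network_features(target)
  b <- er_baseline(ft, reps = er_reps)

  rp <- function() random_program(directed, max_depth, p_terminal, p_const,
                                  const_range)
  mut <- function(p) mutate_program(p, max_depth, p_terminal, p_const,
                                    const_range)
  score <- function(p) {
    fits <- lapply(seq_len(eval_reps), function(r) {
      network_fitness(ft, generate_network(p, n, m, cfg), b)
    })
    f <- mean(vapply(fits, `[[`, numeric(1), "fitness"))
    list(fitness = f, ratios = fits[[1]]$ratios)
  }

  arch_fit <- numeric(0)
  arch_len <- integer(0)
  arch_text <- character(0)
  arch_gen <- integer(0)
  log <- list()
  logline <- function(gen, event, fitness, ratios, prog, len) {
    entry <- list(generation = gen, event = event, fitness = fitness,
                  ratios = as.list(ratios), program = format_program(prog),
                  length = len)
    log[[length(log) + 1L]] <<- entry
    if (!is.null(log_file))
      cat(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), "\n",
          file = log_file, append = TRUE, sep = "")
    if (verbose)
      message(sprintf("gen %d [%s] fitness %.4f len %d: %s", gen, event,
                      fitness, len, format_program(prog)))
  }

  w_r <- rp()
  sc <- score(w_r)
  arch_fit <- c(arch_fit, sc$fitness)
  arch_len <- c(arch_len, program_length(w_r))
  arch_text <- c(arch_text, format_program(w_r))
  arch_gen <- c(arch_gen, 0L)
  w_o <- list(program = w_r, fitness = sc$fitness,
              length = program_length(w_r), idx = 1L)
  w_s <- w_o
  logline(0L, "init", sc$fitness, sc$ratios, w_r, w_o$length)

  pick_ws <- function(f_o) {
    qual <- which(arch_fit <= (1 + tolerance) * f_o)
    qual <- qual[order(arch_len[qual], arch_fit[qual], qual)]
    qual[1L]
  }

  stall <- 0L
  gen <- 0L
  while (stall < stall_limit && gen < max_generations) {
    gen <- gen + 1L
    parent <- if (runif(1) < 0.5) w_o$program else w_s$program
    child <- mut(parent)
    sc <- score(child)
    arch_fit <- c(arch_fit, sc$fitness)
    arch_len <- c(arch_len, program_length(child))
    arch_text <- c(arch_text, format_program(child))
    arch_gen <- c(arch_gen, gen)
    cidx <- length(arch_fit)
    changed <- FALSE
    if (sc$fitness < w_o$fitness) {
      w_o <- list(program = child, fitness = sc$fitness,
                  length = arch_len[cidx], idx = cidx)
      changed <- TRUE
      logline(gen, "best", sc$fitness, sc$ratios, child, arch_len[cidx])
    }
    sidx <- pick_ws(w_o$fitness)
    if (sidx != w_s$idx) {
      prog_s <- if (sidx == cidx) child else
        parse_program(arch_text[sidx], directed = directed)
      w_s <- list(program = prog_s, fitness = arch_fit[sidx],
                  length = arch_len[sidx], idx = sidx)
      changed <- TRUE
      logline(gen, "short", w_s$fitness,
              if (sidx == cidx) sc$ratios else NULL, prog_s, w_s$length)
    }
    stall <- if (changed) 0L else stall + 1L
  }

  structure(list(w_s = w_s$program, w_o = w_o$program,
                 fitness_s = w_s$fitness, fitness_o = w_o$fitness,
                 length_s = w_s$length, length_o = w_o$length,
                 generations = gen, stall = stall, tolerance = tolerance,
                 log = log,
                 archive = data.frame(generation = arch_gen,
                                      fitness = arch_fit, length = arch_len,
                                      program = arch_text,
                                      stringsAsFactors = FALSE),
                 baselines = b, n = n, m = m, directed = directed),
            class = "netgp_search")
}

#' @export
print.netgp_search <- function(x, ...) {
  cat("<netgp evolutionary search>\n")
  cat(sprintf("  generations: %d (stalled %d)\n", x$generations, x$stall))
  cat(sprintf("  w_s: %s  (fitness %.4f, length %d)\n",
              format_program(x$w_s), x$fitness_s, x$length_s))
  cat(sprintf("  w_o: %s  (fitness %.4f, length %d)\n",
              format_program(x$w_o), x$fitness_o, x$length_o))
  invisible(x)
}

#' Calibrate the recovery-classification threshold
#'
#' Classifying a found program as a behavioural recovery of a canonical
#' generator needs a scale for "behaviourally equal". Since the generator
#' dissimilarity of a program with itself is exactly zero, the informative
#' scale is the separation between the canonical generator and its closest
#' canonical competitor: the threshold is half the mean dissimilarity
#' between `canonical` and `alternative` at the experiment's network size.
#'
#' @param canonical,alternative `gp_program`s of the same mode.
#' @param n,m Network size of the recovery experiment.
#' @param cfg A [growth_config()].
#' @param reps Replicate dissimilarity measurements averaged.
#' @return Positive scalar threshold.
#' @export
calibrate_recovery_threshold <- function(canonical, alternative, n, m,
                                         cfg = growth_config(), reps = 5) {
  ds <- vapply(seq_len(reps), function(r) {
    generator_dissimilarity(canonical, alternative, n, m, cfg, reps = 1)$d
  }, numeric(1))
  mean(ds) / 2
}

#' Classify a search result against a canonical generator
#'
#' A found program is a *correct* recovery when its behavioural generator
#' dissimilarity to the canonical program is at or below the threshold, and
#' an *exact, bloat-free* recovery when it is syntactically the canonical
#' program (any single positive constant counts as the constant generator).
#'
#' @param found,canonical `gp_program`s of the same mode.
#' @param threshold Dissimilarity threshold, e.g. from
#'   [calibrate_recovery_threshold()].
#' @param n,m Network size at which dissimilarity is measured.
#' @param cfg A [growth_config()].
#' @param reps Replicates passed to [generator_dissimilarity()].
#' @return List with `correct`, `exact`, and the measured dissimilarity `d`.
#' @export
classify_recovery <- function(found, canonical, threshold, n, m,
                              cfg = growth_config(), reps = 3) {
  d <- generator_dissimilarity(found, canonical, n, m, cfg, reps = reps)$d
  exact <- if (is_positive_constant(canonical)) {
    is_positive_constant(found)
  } else {
    identical(format_program(found), format_program(canonical))
  }
  list(correct = d <= threshold, exact = exact, d = d)
}

is_positive_constant <- function(program) {
  program$root$kind == "const" && program$root$value > 0
}
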