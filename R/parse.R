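#' Parse a generator program from text
#'
#' The canonical text form is a prefix s-expression, e.g. `"(+ k' 1)"` or
#' `"(psi 2 10 1)"`. Atoms are numeric constants or variable symbols
#' (`i`, `j`, `k`, `k'`, `d`, `d_D`, `d_R`); `"ψ"` is accepted as a synonym
#' for `psi`. Lines starting with `#` are ignored, so a program file may
#' carry comments.
#'
#' @param text Program text (a single s-expression).
#' @param directed Logical mode; variables illegal in the mode are a parse
#'   error.
#' @return A `gp_program`.
#' @export
#' @examples
#' parse_program("(/ 1 i)", directed = TRUE)   # hyperbolic identifier rule
#' parse_program("k'", directed = TRUE)        # preferential attachment
parse_program <- function(text, directed = TRUE) {
  stopifnot(is.character(text))
  text <- paste(text, collapse = "\n")
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[!grepl("^\\s*#", lines)]
  text <- paste(lines, collapse = " ")
  toks <- tokenize_program(text)
  if (length(toks$value) == 0L)
    stop("empty program text", call. = FALSE)
  st <- new.env(parent = emptyenv())
  st$pos <- 1L
  node <- parse_expr(toks, st)
  if (st$pos <= length(toks$value))
    stop(sprintf("unexpected trailing token '%s' at position %d",
                 toks$value[st$pos], toks$offset[st$pos]), call. = FALSE)
  gp_program(node, directed = directed)
}

tokenize_program <- function(text) {
  text <- gsub("ψ", "psi", text)  # accept the Greek name
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  value <- character(0)
  offset <- integer(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      value <- c(value, ch); offset <- c(offset, i); i <- i + 1L; next
    }
    j <- i
    while (j <= n && !grepl("^\\s$", chars[j]) && !chars[j] %in% c("(", ")"))
      j <- j + 1L
    value <- c(value, paste(chars[i:(j - 1L)], collapse = ""))
    offset <- c(offset, i)
    i <- j
  }
  list(value = value, offset = offset)
}

parse_expr <- function(toks, st) {
  if (st$pos > length(toks$value))
    stop("unexpected end of input", call. = FALSE)
  tok <- toks$value[st$pos]
  off <- toks$offset[st$pos]
  st$pos <- st$pos + 1L
  if (tok == "(") {
    if (st$pos > length(toks$value))
      stop("unexpected end of input after '('", call. = FALSE)
    op <- toks$value[st$pos]
    opoff <- toks$offset[st$pos]
    st$pos <- st$pos + 1L
    if (!op %in% .gp_ops$sym)
      stop(sprintf("unknown operator '%s' at position %d", op, opoff),
           call. = FALSE)
    ar <- op_arity(op)
    args <- vector("list", ar)
    for (t in seq_len(ar)) args[[t]] <- parse_expr(toks, st)
    if (st$pos > length(toks$value) || toks$value[st$pos] != ")")
      stop(sprintf("expected ')' to close '%s' started at position %d",
                   op, off), call. = FALSE)
    st$pos <- st$pos + 1L
    do.call(gp_op, c(list(op), args))
  } else if (tok == ")") {
    stop(sprintf("unexpected ')' at position %d", off), call. = FALSE)
  } else if (tok %in% .gp_vars$sym) {
    gp_var(tok)
  } else {
    v <- suppressWarnings(as.numeric(tok))
    if (is.na(v))
      stop(sprintf("unknown token '%s' at position %d", tok, off),
           call. = FALSE)
    gp_const(v)
  }
}

#' Format a generator program as canonical text
#'
#' Writes the canonical prefix s-expression. `parse_program(format_program(p))`
#' is structurally identical to `p`; constants are printed with full (17
#' significant digit) precision so the round trip is exact.
#'
#' @param program A `gp_program`.
#' @return A single string.
#' @export
format_program <- function(program) {
  stopifnot(inherits(program, "gp_program"))
  format_node(program$root)
}

format_node <- function(node) {
  switch(node$kind,
    const = format_constant(node$value),
    var = node$sym,
    op = paste0("(", node$sym, " ",
                paste(vapply(node$args, format_node, character(1)),
                      collapse = " "), ")"))
}

format_constant <- function(v) {
  if (v == round(v) && abs(v) < 1e15) return(sprintf("%.0f", v))
  s <- sprintf("%.17g", v)
  # shortest representation that still round-trips exactly
  for (digits in 1:16) {
    cand <- sprintf("%.*g", digits, v)
    if (as.numeric(cand) == v) return(cand)
  }
  s
}

#' Format a generator program as an infix expression
#'
#' A human-readable pretty-printer for reports; arithmetic operators are
#' written infix, functions and conditionals in call notation. Not meant to
#' be parsed back.
#'
#' @param program A `gp_program`.
#' @return A single string.
#' @export
format_program_infix <- function(program) {
  stopifnot(inherits(program, "gp_program"))
  infix_node(program$root, top = TRUE)
}

infix_node <- function(node, top = FALSE) {
  if (node$kind == "const") return(format_constant(node$value))
  if (node$kind == "var") return(node$sym)
  args <- vapply(node$args, infix_node, character(1))
  if (node$sym %in% c("+", "-", "*", "/")) {
    s <- paste(args[1], node$sym, args[2])
    if (top) s else paste0("(", s, ")")
  } else if (node$sym == "pow") {
    paste0(if (top) "" else "", "(", args[1], " ^ ", args[2], ")")
  } else if (node$sym %in% c("gt", "lt", "eq")) {
    cmp <- c(gt = ">", lt = "<", eq = "=")[[node$sym]]
    sprintf("if(%s %s %s, %s, %s)", args[1], cmp, args[2], args[3], args[4])
  } else if (node$sym == "eq0") {
    sprintf("if(%s = 0, %s, %s)", args[1], args[2], args[3])
  } else {
    paste0(node$sym, "(", paste(args, collapse = ", "), ")")
  }
}

#' Read / write a program file
#'
#' Program files are UTF-8 text holding one s-expression; `#`-prefixed lines
#' are comments.
#'
#' @param path File path.
#' @param directed Logical mode used when parsing.
#' @return `read_program` returns a `gp_program`; `write_program` returns
#'   `path` invisibly.
#' @export
read_program <- function(path, directed = TRUE) {
  parse_program(readLines(path, warn = FALSE), directed = directed)
}

#' @rdname read_program
#' @param program A `gp_program` to write.
#' @export
write_program <- function(program, path) {
  writeLines(c(paste0("# netgp generator program (",
                      if (program$directed) "directed" else "undirected", ")"),
               format_program(program)), path)
  invisible(path)
}
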