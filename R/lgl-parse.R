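#' Parse LGL source into statements
#'
#' Parses LGL text into an abstract statement list. Each semicolon-terminated
#' statement becomes one element, in source order. A statement is an optional
#' `label :` prefix (a named-graph definition) followed by a chain of operands
#' joined by `->` / `<-` arrows. An operand is an item or comma-separated item
#' set, optionally followed by a fork (`<` with `/`-opened branches and a
#' final `\`-opened branch). Items may carry flag suffixes in square brackets
#' (`B[F]`), an `@` reference prefix, or be the void placeholder `.`.
#'
#' The comma operator binds tighter than the arrow operator, so
#' `A -> B, C` connects `A` to both `B` and `C`.
#'
#' @param text LGL source text (single string), or a file path via [lgl_read()].
#' @return An object of class `lgl_program`: a list of statements. Each
#'   statement is a list with fields `label` (string or `NULL`), `chain`
#'   (operands + arrow directions) and `line`.
#' @seealso [lgl_evaluate()] to turn statements into graph objects,
#'   [lgl_render()] for the canonical pretty-printer.
#' @examples
#' lgl_parse("G1: A -> B, C;")
#' @export
lgl_parse <- function(text) {
  toks <- lgl_tokenize(text)
  p <- new.env(parent = emptyenv())
  p$toks <- toks
  p$pos <- 1L
  p$n <- nrow(toks)
  stmts <- list()
  while (p$pos <= p$n) {
    stmts[[length(stmts) + 1L]] <- parse_statement(p)
  }
  structure(stmts, class = "lgl_program")
}

#' Read and parse a standalone `.lgl` file
#'
#' @param path Path to a UTF-8 encoded LGL file.
#' @return An `lgl_program`, as from [lgl_parse()].
#' @export
lgl_read <- function(path) {
  lgl_parse(paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                  collapse = "\n"))
}

# -- recursive-descent helpers ----------------------------------------------

peek_kind <- function(p, offset = 0L) {
  i <- p$pos + offset
  if (i > p$n) "" else p$toks$kind[[i]]
}

cur_line <- function(p) {
  if (p$pos <= p$n) p$toks$line[[p$pos]]
  else if (p$n > 0L) p$toks$line[[p$n]]
  else 1L
}

advance <- function(p) {
  tok <- list(kind = p$toks$kind[[p$pos]], text = p$toks$text[[p$pos]],
              line = p$toks$line[[p$pos]])
  p$pos <- p$pos + 1L
  tok
}

expect <- function(p, kind, what) {
  if (peek_kind(p) != kind) {
    got <- if (p$pos > p$n) "end of input"
           else sprintf("'%s'", p$toks$text[[p$pos]])
    stop_lgl_syntax(cur_line(p), sprintf("expected %s but found %s", what, got))
  }
  advance(p)
}

parse_statement <- function(p) {
  line <- cur_line(p)
  label <- NULL
  if (peek_kind(p) == "id" && peek_kind(p, 1L) == "colon") {
    label <- advance(p)$text
    advance(p) # colon
  }
  chain <- parse_chain(p)
  expect(p, "semi", "';'")
  list(label = label, chain = chain, line = line)
}

parse_chain <- function(p) {
  operands <- list(parse_operand(p))
  arrows <- character(0)
  while (peek_kind(p) %in% c("arrow_r", "arrow_l")) {
    arrows[[length(arrows) + 1L]] <-
      if (advance(p)$kind == "arrow_r") "right" else "left"
    operands[[length(operands) + 1L]] <- parse_operand(p)
  }
  list(operands = operands, arrows = arrows)
}

parse_operand <- function(p) {
  items <- list(parse_item(p))
  while (peek_kind(p) == "comma") {
    advance(p)
    items[[length(items) + 1L]] <- parse_item(p)
  }
  fork <- NULL
  if (peek_kind(p) == "fork") {
    fork <- parse_fork(p)
  }
  list(items = items, fork = fork)
}

# `parent < /b1 /b2 \bk` — every branch but the last opens with `/`,
# the last with `\`; a branch is itself an operand (possibly forked),
# which is what makes forks nest to arbitrary depth.
parse_fork <- function(p) {
  advance(p) # '<'
  branches <- list()
  repeat {
    k <- peek_kind(p)
    if (k == "slash") {
      advance(p)
      branches[[length(branches) + 1L]] <- parse_operand(p)
    } else if (k == "backslash") {
      advance(p)
      branches[[length(branches) + 1L]] <- parse_operand(p)
      break
    } else {
      stop_lgl_syntax(cur_line(p),
                      "expected a fork branch opened by '/' or '\\'")
    }
  }
  list(branches = branches)
}

parse_item <- function(p) {
  line <- cur_line(p)
  if (peek_kind(p) == "dot") {
    advance(p)
    return(list(name = ".", flags = character(0), is_ref = FALSE,
                is_void = TRUE, line = line))
  }
  is_ref <- FALSE
  if (peek_kind(p) == "at") {
    advance(p)
    is_ref <- TRUE
  }
  tok <- expect(p, "id", "an item name")
  flags <- character(0)
  if (peek_kind(p) == "lbracket") {
    advance(p)
    while (peek_kind(p) == "id") {
      flags <- c(flags, strsplit(advance(p)$text, "", fixed = TRUE)[[1]])
    }
    expect(p, "rbracket", "']'")
  }
  list(name = tok$text, flags = unique(flags), is_ref = is_ref,
       is_void = FALSE, line = line)
}

# -- canonical pretty-printer -----------------------------------------------

#' Render parsed LGL back to canonical text
#'
#' The canonical form round-trips: `lgl_parse(lgl_render(x))` reproduces `x`
#' (up to source line numbers).
#'
#' @param x An `lgl_program` from [lgl_parse()].
#' @return A single string of LGL source, one statement per line.
#' @export
lgl_render <- function(x) {
  stopifnot(inherits(x, "lgl_program"))
  paste(vapply(x, render_statement, character(1)), collapse = "\n")
}

render_statement <- function(s) {
  head <- if (is.null(s$label)) "" else paste0(s$label, ": ")
  paste0(head, render_chain(s$chain), ";")
}

render_chain <- function(chain) {
  out <- render_operand(chain$operands[[1]])
  for (i in seq_along(chain$arrows)) {
    arr <- if (chain$arrows[[i]] == "right") "->" else "<-"
    out <- paste(out, arr, render_operand(chain$operands[[i + 1L]]))
  }
  out
}

render_operand <- function(op) {
  txt <- paste(vapply(op$items, render_item, character(1)), collapse = ", ")
  if (!is.null(op$fork)) {
    br <- op$fork$branches
    k <- length(br)
    parts <- character(k)
    for (i in seq_len(k)) {
      opener <- if (i < k) "/" else "\\"
      parts[[i]] <- paste0(opener, render_operand(br[[i]]))
    }
    txt <- paste(txt, "<", paste(parts, collapse = " "))
  }
  txt
}

render_item <- function(it) {
  if (it$is_void) return(".")
  out <- paste0(if (it$is_ref) "@" else "", it$name)
  if (length(it$flags)) out <- paste0(out, "[", paste(it$flags, collapse = ""), "]")
  out
}

#' @export
print.lgl_program <- function(x, ...) {
  cat("<lgl_program> ", length(x), " statement(s)\n", sep = "")
  cat(lgl_render(x), "\n", sep = "")
  invisible(x)
}
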