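#' Tokenize LGL source text
#'
#' Splits LGL text into a flat token stream. The pipe character `|` and
#' newlines are whitespace: they may be inserted anywhere between tokens to
#' give a pipeline definition a visual, graph-like layout without changing
#' its meaning. Comments run from `#` to end of line.
#'
#' @param text A single character string of LGL source.
#' @return A data.frame with columns `kind`, `text` and `line` (1-based
#'   physical line on which each token starts). Token kinds are:
#'   `id`, `arrow_r` (`->`), `arrow_l` (`<-`), `comma`, `colon`, `semi`,
#'   `at`, `fork` (`<`), `slash`, `backslash`, `lbracket`, `rbracket`,
#'   `dot` (the void item `.`).
#' @examples
#' lgl_tokenize("A -> B, C;")
#' @export
lgl_tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  kinds <- character(0)
  texts <- character(0)
  lines <- integer(0)
  push <- function(kind, txt, line) {
    kinds[[length(kinds) + 1L]] <<- kind
    texts[[length(texts) + 1L]] <<- txt
    lines[[length(lines) + 1L]] <<- line
  }
  i <- 1L
  line <- 1L
  while (i <= n) {
    ch <- chars[[i]]
    if (ch == "\n") {
      line <- line + 1L
      i <- i + 1L
    } else if (ch %in% c(" ", "\t", "\r", "|")) {
      i <- i + 1L
    } else if (ch == "#") {
      while (i <= n && chars[[i]] != "\n") i <- i + 1L
    } else if (grepl("[A-Za-z_]", ch)) {
      j <- i
      while (j < n && grepl("[A-Za-z0-9_]", chars[[j + 1L]])) j <- j + 1L
      push("id", paste(chars[i:j], collapse = ""), line)
      i <- j + 1L
    } else if (ch == "-") {
      if (i < n && chars[[i + 1L]] == ">") {
        push("arrow_r", "->", line)
        i <- i + 2L
      } else {
        stop_lgl_lex(line, "'-' must be part of '->'")
      }
    } else if (ch == "<") {
      if (i < n && chars[[i + 1L]] == "-") {
        push("arrow_l", "<-", line)
        i <- i + 2L
      } else {
        push("fork", "<", line)
        i <- i + 1L
      }
    } else {
      kind <- switch(ch,
        "," = "comma", ":" = "colon", ";" = "semi", "@" = "at",
        "/" = "slash", "\\" = "backslash", "[" = "lbracket",
        "]" = "rbracket", "." = "dot", NULL
      )
      if (is.null(kind)) {
        stop_lgl_lex(line, sprintf("illegal character '%s'", ch))
      }
      push(kind, ch, line)
      i <- i + 1L
    }
  }
  data.frame(kind = kinds, text = texts, line = lines,
             stringsAsFactors = FALSE)
}

stop_lgl_lex <- function(line, msg) {
  stop(errorCondition(
    sprintf("LGL lexical error at line %d: %s", line, msg),
    line = line, class = c("lgl_lex_error", "lgl_error")
  ))
}

stop_lgl_syntax <- function(line, msg) {
  stop(errorCondition(
    sprintf("LGL syntax error at line %d: %s", line, msg),
    line = line, class = c("lgl_syntax_error", "lgl_error")
  ))
}

stop_lgl_eval <- function(msg, line = NA_integer_) {
  where <- if (is.na(line)) "" else sprintf(" at line %d", line)
  stop(errorCondition(
    sprintf("LGL evaluation error%s: %s", where, msg),
    line = line, class = c("lgl_eval_error", "lgl_error")
  ))
}
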