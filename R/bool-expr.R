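## Boolean expression ASTs: constants, variables, !, &, | with n-ary
## flattened AND/OR. The printed operator symbols are & (AND), | (OR), ! (NOT).

#' Construct Boolean expression nodes
#'
#' `bool_const()`, `bool_var()`, `bool_not()`, `bool_and()` and `bool_or()`
#' build the abstract syntax tree used to represent a node's update rule.
#' AND/OR are n-ary and flattened: `bool_and(a, bool_and(b, c))` has three
#' children. These are normally produced by [parse_expression()] rather than
#' constructed by hand.
#'
#' @param value 0 or 1.
#' @param name variable (node) name; must match `[A-Za-z][A-Za-z0-9]*`.
#' @param child,... child expressions.
#' @return An object of class `bool_expr`, a list with field `kind` (one of
#'   `"const"`, `"var"`, `"not"`, `"and"`, `"or"`) plus `value` (const),
#'   `name` (var) or `children` (not/and/or).
#' @export
bool_const <- function(value) {
  value <- as.integer(value)
  if (!value %in% c(0L, 1L)) stop("constant must be 0 or 1", call. = FALSE)
  structure(list(kind = "const", value = value), class = "bool_expr")
}

#' @rdname bool_const
#' @export
bool_var <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !grepl("^[A-Za-z][A-Za-z0-9]*$", name)) {
    stop("variable name must match [A-Za-z][A-Za-z0-9]*: ",
         deparse(name), call. = FALSE)
  }
  structure(list(kind = "var", name = name), class = "bool_expr")
}

#' @rdname bool_const
#' @export
bool_not <- function(child) {
  stopifnot(inherits(child, "bool_expr"))
  structure(list(kind = "not", children = list(child)), class = "bool_expr")
}

.flatten_nary <- function(kind, args) {
  kids <- list()
  for (a in args) {
    stopifnot(inherits(a, "bool_expr"))
    if (a$kind == kind) kids <- c(kids, a$children) else kids <- c(kids, list(a))
  }
  if (length(kids) < 2L) {
    stop(toupper(kind), " requires at least two operands", call. = FALSE)
  }
  structure(list(kind = kind, children = kids), class = "bool_expr")
}

#' @rdname bool_const
#' @export
bool_and <- function(...) .flatten_nary("and", list(...))

#' @rdname bool_const
#' @export
bool_or <- function(...) .flatten_nary("or", list(...))

is_bool_expr <- function(x) inherits(x, "bool_expr")

## ---------------------------------------------------------------------------
## Tokenizer + recursive-descent parser.
## Grammar:  or   := and ('|' and)*
##           and  := unary ('&' unary)*
##           unary:= '!' unary | primary
##           prim := IDENT | '0' | '1' | '(' or ')'
## Precedence ! > & > |, & and | left-associative, n-ary chains flattened.

.tokenize_expr <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^[ \t\r\n]$", ch)) { i <- i + 1L; next }
    if (ch %in% c("!", "&", "|", "(", ")")) {
      tokens[[length(tokens) + 1L]] <- list(type = ch, text = ch, pos = i)
      i <- i + 1L
      next
    }
    if (grepl("^[01]$", ch)) {
      # a literal bit; must not start an identifier (identifiers start with a letter)
      nxt <- if (i < n) substr(text, i + 1L, i + 1L) else ""
      if (grepl("^[A-Za-z0-9]$", nxt)) {
        stop(sprintf("parse error at position %d: illegal token starting with '%s'",
                     i, ch), call. = FALSE)
      }
      tokens[[length(tokens) + 1L]] <- list(type = "const", text = ch, pos = i)
      i <- i + 1L
      next
    }
    if (grepl("^[A-Za-z]$", ch)) {
      j <- i
      while (j < n && grepl("^[A-Za-z0-9]$", substr(text, j + 1L, j + 1L))) j <- j + 1L
      tokens[[length(tokens) + 1L]] <-
        list(type = "ident", text = substr(text, i, j), pos = i)
      i <- j + 1L
      next
    }
    stop(sprintf("parse error at position %d: illegal token '%s'", i, ch),
         call. = FALSE)
  }
  tokens
}

#' Parse a Boolean rule string into an expression tree
#'
#' Accepts identifiers, the literals `0` and `1`, unary `!`, binary `&` and
#' `|`, and parentheses, with precedence `!` > `&` > `|`. Chains of the same
#' operator are flattened to a single n-ary node, so `"A & B & C"` parses to
#' one AND with three children. Whitespace is insignificant. Malformed input
#' (unbalanced parentheses, dangling operators, illegal characters) raises an
#' error naming the offending position; nothing is silently repaired.
#'
#' @param text a single rule string, e.g. `"CFOS & CJUN & !dNFAT"`.
#' @return A [bool_expr][bool_const] tree.
#' @examples
#' e <- parse_expression("(PD1 & !SHP2) | (LCK & !ERK)")
#' format_expression(e)
#' @export
parse_expression <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    stop("rule text must be a nonempty string", call. = FALSE)
  }
  tokens <- .tokenize_expr(text)
  if (length(tokens) == 0L) stop("rule text must be nonempty", call. = FALSE)
  pos <- 1L

  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  advance <- function() { tok <- tokens[[pos]]; pos <<- pos + 1L; tok }
  fail <- function(tok, msg) {
    at <- if (is.null(tok)) paste0("position ", nchar(text) + 1L, " (end of input)")
          else paste0("position ", tok$pos)
    stop(sprintf("parse error at %s: %s", at, msg), call. = FALSE)
  }

  parse_or <- function() {
    parts <- list(parse_and())
    while (!is.null(peek()) && peek()$type == "|") {
      advance()
      parts[[length(parts) + 1L]] <- parse_and()
    }
    if (length(parts) == 1L) parts[[1L]] else .flatten_nary("or", parts)
  }
  parse_and <- function() {
    parts <- list(parse_unary())
    while (!is.null(peek()) && peek()$type == "&") {
      advance()
      parts[[length(parts) + 1L]] <- parse_unary()
    }
    if (length(parts) == 1L) parts[[1L]] else .flatten_nary("and", parts)
  }
  parse_unary <- function() {
    tok <- peek()
    if (is.null(tok)) fail(tok, "expected an operand")
    if (tok$type == "!") { advance(); return(bool_not(parse_unary())) }
    parse_primary()
  }
  parse_primary <- function() {
    tok <- peek()
    if (is.null(tok)) fail(tok, "expected an operand")
    if (tok$type == "const") { advance(); return(bool_const(as.integer(tok$text))) }
    if (tok$type == "ident") { advance(); return(bool_var(tok$text)) }
    if (tok$type == "(") {
      open <- advance()
      inner <- parse_or()
      tok <- peek()
      if (is.null(tok) || tok$type != ")") {
        fail(open, "unbalanced parenthesis (no matching ')')")
      }
      advance()
      return(inner)
    }
    fail(tok, sprintf("unexpected '%s'", tok$text))
  }

  expr <- parse_or()
  tok <- peek()
  if (!is.null(tok)) {
    if (tok$type == ")") fail(tok, "unbalanced parenthesis (unmatched ')')")
    fail(tok, sprintf("unexpected trailing '%s'", tok$text))
  }
  expr
}

#' Evaluate a Boolean expression against a complete state
#'
#' Pure standard Boolean semantics. Every variable referenced by `expr` must
#' be present in `state`; a missing variable is an error naming it.
#'
#' @param expr a [bool_expr][bool_const].
#' @param state named vector (or list) of 0/1 values, one per node.
#' @return integer 0 or 1.
#' @export
eval_expression <- function(expr, state) {
  stopifnot(is_bool_expr(expr))
  if (is.list(state)) state <- unlist(state)
  rec <- function(e) {
    switch(e$kind,
      const = e$value,
      var = {
        if (!e$name %in% names(state)) {
          stop("variable not present in state: ", e$name, call. = FALSE)
        }
        as.integer(state[[e$name]])
      },
      not = 1L - rec(e$children[[1L]]),
      and = {
        for (c in e$children) if (rec(c) == 0L) return(0L)
        1L
      },
      or = {
        for (c in e$children) if (rec(c) == 1L) return(1L)
        0L
      },
      stop("unknown expression kind: ", e$kind, call. = FALSE)
    )
  }
  rec(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a Boolean expression back to rule text
#'
#' Produces text that [parse_expression()] parses back to a logically
#' equivalent tree. Parentheses are inserted only where precedence requires.
#'
#' @param expr a [bool_expr][bool_const].
#' @return a single string.
#' @export
format_expression <- function(expr) {
  stopifnot(is_bool_expr(expr))
  # prec: or = 1, and = 2, not = 3, atoms = 4
  rec <- function(e) {
    switch(e$kind,
      const = list(text = as.character(e$value), prec = 4L),
      var = list(text = e$name, prec = 4L),
      not = {
        c1 <- rec(e$children[[1L]])
        t1 <- if (c1$prec < 3L) paste0("(", c1$text, ")") else c1$text
        list(text = paste0("!", t1), prec = 3L)
      },
      and = {
        parts <- vapply(e$children, function(ch) {
          c1 <- rec(ch)
          if (c1$prec < 2L) paste0("(", c1$text, ")") else c1$text
        }, character(1))
        list(text = paste(parts, collapse = " & "), prec = 2L)
      },
      or = {
        parts <- vapply(e$children, function(ch) rec(ch)$text, character(1))
        list(text = paste(parts, collapse = " | "), prec = 1L)
      }
    )
  }
  rec(expr)$text
}

#' @export
format.bool_expr <- function(x, ...) format_expression(x)

#' @export
print.bool_expr <- function(x, ...) {
  cat("<bool_expr> ", format_expression(x), "\n", sep = "")
  invisible(x)
}

#' Variables referenced by an expression
#'
#' @param expr a [bool_expr][bool_const].
#' @return character vector of unique variable names, in first-appearance order.
#' @export
expression_vars <- function(expr) {
  stopifnot(is_bool_expr(expr))
  out <- character(0)
  rec <- function(e) {
    if (e$kind == "var") out <<- c(out, e$name)
    else if (!is.null(e$children)) for (c in e$children) rec(c)
  }
  rec(expr)
  unique(out)
}

#' Regulator signs within an expression
#'
#' For each variable, reports whether its occurrences sit under an even
#' number of negations (`"activating"`), an odd number (`"inhibitory"`), or
#' both (`"dual"`). This is the syntactic sign used to label dependency-graph
#' edges.
#'
#' @param expr a [bool_expr][bool_const].
#' @return named character vector: variable -> sign.
#' @export
expression_signs <- function(expr) {
  stopifnot(is_bool_expr(expr))
  parity <- list()  # name -> set of parities seen (0 even, 1 odd)
  rec <- function(e, p) {
    if (e$kind == "var") {
      parity[[e$name]] <<- union(parity[[e$name]] %||% integer(0), p)
    } else if (e$kind == "not") {
      rec(e$children[[1L]], 1L - p)
    } else if (!is.null(e$children)) {
      for (c in e$children) rec(c, p)
    }
  }
  rec(expr, 0L)
  vapply(parity, function(ps) {
    if (length(ps) == 2L) "dual" else if (ps == 0L) "activating" else "inhibitory"
  }, character(1))
}
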