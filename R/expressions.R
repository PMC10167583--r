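# A minimal expression language for patient-level inference. Document-level
# aggregates are combined into derived variables ("discharged with VTE",
# "admission with VTE", new-onset in-hospital VTE) by expressions stored in
# the knowledge base, so the aggregation logic is configuration, not code.
#
# Grammar (loosest to tightest binding):
#   OR < AND < NOT < comparison (= == != < <= > >=) < + - < * /
#      < UNION INTERSECT DIFFERENCE < COUNT(...) ( ... ) literal name
# Keywords are case-insensitive; names are case-sensitive. Values are
# booleans, numbers, or sets (character vectors).

tokenize_expression <- function(expr) {
  tokens <- list()
  s <- expr
  pos <- 1L
  pat <- list(
    ws = "^\\s+",
    number = "^[0-9]+(\\.[0-9]+)?",
    ident = "^[A-Za-z_][A-Za-z0-9_]*",
    op = "^(==|!=|<=|>=|=|<|>|\\+|-|\\*|/|\\(|\\))"
  )
  while (nzchar(s)) {
    matched <- FALSE
    for (kind in names(pat)) {
      m <- regexpr(pat[[kind]], s, perl = TRUE)
      if (m == 1L) {
        len <- attr(m, "match.length")
        tok <- substr(s, 1L, len)
        if (kind != "ws") {
          if (kind == "ident" && toupper(tok) %in% EXPRESSION_KEYWORDS) {
            tokens[[length(tokens) + 1L]] <- list(kind = "keyword", value = toupper(tok))
          } else {
            tokens[[length(tokens) + 1L]] <- list(kind = kind, value = tok)
          }
        }
        s <- substr(s, len + 1L, nchar(s))
        pos <- pos + len
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      stop(sprintf("expression parse error at position %d: '%s'", pos, s),
           call. = FALSE)
    }
  }
  tokens
}

# recursive-descent parser producing nested lists (op, args)
parse_expression <- function(expr) {
  tokens <- tokenize_expression(expr)
  state <- new.env(parent = emptyenv())
  state$tokens <- tokens
  state$i <- 1L

  peek <- function() if (state$i <= length(state$tokens)) state$tokens[[state$i]] else NULL
  advance <- function() {
    tok <- peek()
    state$i <- state$i + 1L
    tok
  }
  expect <- function(kind, value = NULL) {
    tok <- advance()
    if (is.null(tok) || tok$kind != kind || (!is.null(value) && tok$value != value)) {
      stop(sprintf("expression parse error: expected %s near token %d",
                   if (is.null(value)) kind else value, state$i - 1L), call. = FALSE)
    }
    tok
  }
  at_keyword <- function(kw) {
    tok <- peek()
    !is.null(tok) && tok$kind == "keyword" && tok$value %in% kw
  }
  at_op <- function(ops) {
    tok <- peek()
    !is.null(tok) && tok$kind == "op" && tok$value %in% ops
  }

  p_or <- function() {
    node <- p_and()
    while (at_keyword("OR")) {
      advance()
      node <- list(op = "OR", args = list(node, p_and()))
    }
    node
  }
  p_and <- function() {
    node <- p_not()
    while (at_keyword("AND")) {
      advance()
      node <- list(op = "AND", args = list(node, p_not()))
    }
    node
  }
  p_not <- function() {
    if (at_keyword("NOT")) {
      advance()
      return(list(op = "NOT", args = list(p_not())))
    }
    p_cmp()
  }
  p_cmp <- function() {
    node <- p_add()
    if (at_op(c("==", "=", "!=", "<=", ">=", "<", ">"))) {
      op <- advance()$value
      if (op == "=") op <- "=="
      node <- list(op = op, args = list(node, p_add()))
    }
    node
  }
  p_add <- function() {
    node <- p_mul()
    while (at_op(c("+", "-"))) {
      op <- advance()$value
      node <- list(op = op, args = list(node, p_mul()))
    }
    node
  }
  p_mul <- function() {
    node <- p_set()
    while (at_op(c("*", "/"))) {
      op <- advance()$value
      node <- list(op = op, args = list(node, p_set()))
    }
    node
  }
  p_set <- function() {
    node <- p_primary()
    while (at_keyword(c("UNION", "INTERSECT", "DIFFERENCE"))) {
      op <- advance()$value
      node <- list(op = op, args = list(node, p_primary()))
    }
    node
  }
  p_primary <- function() {
    tok <- peek()
    if (is.null(tok)) stop("expression parse error: unexpected end", call. = FALSE)
    if (tok$kind == "keyword" && tok$value == "COUNT") {
      advance()
      expect("op", "(")
      inner <- p_or()
      expect("op", ")")
      return(list(op = "COUNT", args = list(inner)))
    }
    if (tok$kind == "keyword" && tok$value %in% c("TRUE", "FALSE")) {
      advance()
      return(list(op = "literal", value = tok$value == "TRUE"))
    }
    if (tok$kind == "op" && tok$value == "(") {
      advance()
      inner <- p_or()
      expect("op", ")")
      return(inner)
    }
    if (tok$kind == "number") {
      advance()
      return(list(op = "literal", value = as.numeric(tok$value)))
    }
    if (tok$kind == "ident") {
      advance()
      return(list(op = "name", value = tok$value))
    }
    stop(sprintf("expression parse error: unexpected token '%s'", tok$value),
         call. = FALSE)
  }

  node <- p_or()
  if (!is.null(peek())) {
    stop(sprintf("expression parse error: trailing token '%s'", peek()$value),
         call. = FALSE)
  }
  node
}

# names referenced by an expression (used for KB dependency validation)
expression_names <- function(expr) {
  tokens <- tokenize_expression(expr)
  unique(vapply(Filter(function(t) t$kind == "ident", tokens),
                `[[`, character(1), "value"))
}

value_type <- function(v) {
  if (is.logical(v) && length(v) == 1L) "boolean"
  else if (is.numeric(v) && length(v) == 1L) "number"
  else if (is.character(v)) "set"
  else "unknown"
}

require_type <- function(v, type, op) {
  if (value_type(v) != type) {
    stop(sprintf("type mismatch: %s requires a %s operand, got %s",
                 op, type, value_type(v)), call. = FALSE)
  }
  v
}

eval_node <- function(node, bindings) {
  op <- node$op
  if (op == "literal") return(node$value)
  if (op == "name") {
    if (!node$value %in% names(bindings)) {
      stop(sprintf("unbound name '%s'", node$value), call. = FALSE)
    }
    return(bindings[[node$value]])
  }
  args <- lapply(node$args, eval_node, bindings = bindings)
  switch(op,
    "OR" = require_type(args[[1]], "boolean", "OR") || require_type(args[[2]], "boolean", "OR"),
    "AND" = require_type(args[[1]], "boolean", "AND") && require_type(args[[2]], "boolean", "AND"),
    "NOT" = !require_type(args[[1]], "boolean", "NOT"),
    "COUNT" = length(require_type(args[[1]], "set", "COUNT")),
    "UNION" = union(require_type(args[[1]], "set", "UNION"),
                    require_type(args[[2]], "set", "UNION")),
    "INTERSECT" = intersect(require_type(args[[1]], "set", "INTERSECT"),
                            require_type(args[[2]], "set", "INTERSECT")),
    "DIFFERENCE" = setdiff(require_type(args[[1]], "set", "DIFFERENCE"),
                           require_type(args[[2]], "set", "DIFFERENCE")),
    "+" = require_type(args[[1]], "number", "+") + require_type(args[[2]], "number", "+"),
    "-" = require_type(args[[1]], "number", "-") - require_type(args[[2]], "number", "-"),
    "*" = require_type(args[[1]], "number", "*") * require_type(args[[2]], "number", "*"),
    "/" = require_type(args[[1]], "number", "/") / require_type(args[[2]], "number", "/"),
    "==" = compare_values(args[[1]], args[[2]], `==`, "=="),
    "!=" = compare_values(args[[1]], args[[2]], `!=`, "!="),
    "<" = compare_numbers(args[[1]], args[[2]], `<`, "<"),
    "<=" = compare_numbers(args[[1]], args[[2]], `<=`, "<="),
    ">" = compare_numbers(args[[1]], args[[2]], `>`, ">"),
    ">=" = compare_numbers(args[[1]], args[[2]], `>=`, ">="),
    stop("unknown operator ", op, call. = FALSE)
  )
}

compare_numbers <- function(a, b, f, op) {
  f(require_type(a, "number", op), require_type(b, "number", op))
}

compare_values <- function(a, b, f, op) {
  ta <- value_type(a); tb <- value_type(b)
  if (ta == "set" || tb == "set") {
    stop(sprintf("type mismatch: %s is not defined for sets (use COUNT)", op),
         call. = FALSE)
  }
  if (ta != tb) {
    stop(sprintf("type mismatch: %s between %s and %s", op, ta, tb), call. = FALSE)
  }
  f(a, b)
}

#' Evaluate a patient-level expression
#'
#' Evaluates one expression of the knowledge-base expression language
#' against a set of named bindings. The language supports boolean logic
#' (`AND`, `OR`, `NOT`), arithmetic (`+ - * /`), comparisons
#' (`= == != < <= > >=`), set operations (`UNION`, `INTERSECT`,
#' `DIFFERENCE`, `COUNT(...)`) and parentheses, with standard precedence
#' (`NOT` binds tighter than `AND`, which binds tighter than `OR`;
#' arithmetic binds tighter than comparison). Keywords are case-insensitive.
#'
#' @param expr Expression string, e.g.
#'   `"discharged_with_vte AND NOT admission_with_vte"`.
#' @param bindings Named list mapping names to booleans, numbers, or sets
#'   (character vectors).
#' @return The value of the expression (boolean, number, or set).
#'   Referencing an unbound name, or applying an operator to the wrong type,
#'   is an error.
#' @export
#' @examples
#' eval_expression("discharged_with_vte AND NOT admission_with_vte",
#'                 list(discharged_with_vte = TRUE, admission_with_vte = FALSE))
#' eval_expression("COUNT(a UNION b) >= 2", list(a = "d1", b = "d2"))
eval_expression <- function(expr, bindings = list()) {
  eval_node(parse_expression(expr), bindings)
}
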