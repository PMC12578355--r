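# Expression trees for symbolic regression: nested lists with nodes
#   list(op = "add"|"sub"|"mul"|"pow", args = list(left, right))
#   list(op = "sin"|"cos"|"log"|"exp", args = list(child))
#   list(op = "var", name = "x1")          (leaf)
#   list(op = "const", value = 3.5)        (leaf)
# Complexity is the node count (operators + leaves). Evaluation uses
# protected semantics so any expression is finite on any finite input.

SR_BINARY <- c("add", "sub", "mul", "pow")
SR_UNARY <- c("sin", "cos", "log", "exp")

e_var <- function(name) list(op = "var", name = name)
e_const <- function(value) list(op = "const", value = value)
e_call <- function(op, ...) list(op = op, args = list(...))

#' Parse an infix formula string into an expression tree
#'
#' Supports `+`, `-` (binary and unary), `*`, `^` or `pow(a,b)`, `sin`,
#' `cos`, `log`, `exp`, variables and numeric literals.
#'
#' @param text a string such as `"2*x1 + sin(x2)"`.
#' @return an expression tree.
#' @export
parse_expression <- function(text) {
  from_lang(str2lang(text))
}

from_lang <- function(e) {
  if (is.numeric(e)) return(e_const(as.numeric(e)))
  if (is.name(e)) return(e_var(as.character(e)))
  if (!is.call(e)) stop_config("unsupported expression element")
  op <- as.character(e[[1]])
  args <- as.list(e)[-1]
  if (op == "(") return(from_lang(args[[1]]))
  if (op == "-" && length(args) == 1)
    return(e_call("mul", e_const(-1), from_lang(args[[1]])))
  map <- c(`+` = "add", `-` = "sub", `*` = "mul", `^` = "pow", pow = "pow",
           sin = "sin", cos = "cos", log = "log", exp = "exp")
  if (!op %in% names(map)) stop_config("unsupported operator: ", op)
  do.call(e_call, c(list(map[[op]]), lapply(args, from_lang)))
}

#' Evaluate an expression tree with protected operator semantics
#'
#' `log(x)` evaluates as `log(|x| + 1e-12)`, `exp` clips its argument to
#' \[-50, 50\], and `pow(a, b)` is the sign-safe magnitude power
#' `exp(clip(b' log(|a| + 1e-12)))` with the exponent `b` clipped to
#' \[-5, 5\]; outputs are always finite.
#'
#' @param expr an expression tree or infix string.
#' @param inputs data.frame (or named list of equal-length vectors) with one
#'   column per variable.
#' @return numeric vector of predictions.
#' @export
evaluate_expression <- function(expr, inputs) {
  if (is.character(expr)) expr <- parse_expression(expr)
  n <- length(inputs[[1]])
  ev <- function(node) {
    switch(node$op,
      var = {
        v <- inputs[[node$name]]
        if (is.null(v)) stop_data("undeclared variable: ", node$name)
        v
      },
      const = rep(node$value, n),
      add = ev(node$args[[1]]) + ev(node$args[[2]]),
      sub = ev(node$args[[1]]) - ev(node$args[[2]]),
      mul = ev(node$args[[1]]) * ev(node$args[[2]]),
      pow = {
        a <- ev(node$args[[1]]); b <- clamp(ev(node$args[[2]]), -5, 5)
        exp(clamp(b * log(abs(a) + 1e-12), -50, 50))
      },
      sin = sin(ev(node$args[[1]])),
      cos = cos(ev(node$args[[1]])),
      log = log(abs(ev(node$args[[1]])) + 1e-12),
      exp = exp(clamp(ev(node$args[[1]]), -50, 50)),
      stop_config("unknown op: ", node$op))
  }
  out <- ev(expr)
  out[!is.finite(out)] <- 0   # belt and braces; protections keep this rare
  out
}

#' Expression complexity (node count)
#' @param expr expression tree.
#' @return integer number of nodes (operators + leaves).
#' @export
expression_complexity <- function(expr) {
  if (expr$op %in% c("var", "const")) return(1L)
  1L + sum(vapply(expr$args, expression_complexity, integer(1)))
}

#' Variables used by an expression
#' @param expr expression tree or infix string.
#' @return character vector of distinct variable names.
#' @export
expression_variables <- function(expr) {
  if (is.character(expr)) expr <- parse_expression(expr)
  if (expr$op == "var") return(expr$name)
  if (expr$op == "const") return(character(0))
  unique(unlist(lapply(expr$args, expression_variables)))
}

#' Render an expression tree as an infix string
#' @param expr expression tree.
#' @return character scalar.
#' @export
format_expression <- function(expr) {
  f <- function(node) {
    switch(node$op,
      var = node$name,
      const = formatC(node$value, format = "g", digits = 6),
      add = paste0("(", f(node$args[[1]]), " + ", f(node$args[[2]]), ")"),
      sub = paste0("(", f(node$args[[1]]), " - ", f(node$args[[2]]), ")"),
      mul = paste0("(", f(node$args[[1]]), " * ", f(node$args[[2]]), ")"),
      pow = paste0("pow(", f(node$args[[1]]), ", ", f(node$args[[2]]), ")"),
      paste0(node$op, "(", f(node$args[[1]]), ")"))
  }
  f(expr)
}

# --- tree surgery (internal) --------------------------------------------------

# Paths to every node as integer vectors; c() is the root.
node_paths <- function(expr) {
  out <- list(integer(0))
  if (!expr$op %in% c("var", "const")) {
    for (i in seq_along(expr$args)) {
      sub <- node_paths(expr$args[[i]])
      out <- c(out, lapply(sub, function(p) c(i, p)))
    }
  }
  out
}

get_node <- function(expr, path) {
  for (i in path) expr <- expr$args[[i]]
  expr
}

set_node <- function(expr, path, value) {
  if (!length(path)) return(value)
  expr$args[[path[1]]] <- set_node(expr$args[[path[1]]], path[-1], value)
  expr
}

const_paths <- function(expr) {
  Filter(function(p) get_node(expr, p)$op == "const", node_paths(expr))
}
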