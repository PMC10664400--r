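# Symbolic expression utilities: the model grammar admits identifiers, real
# literals, + - * / ^ (with ** as alias), unary minus, parentheses, and the
# functions exp, log, sqrt. Expressions are stored as R language objects.

.allowed_funs <- c("+", "-", "*", "/", "^", "(", "exp", "log", "sqrt")

#' Parse a model expression string
#'
#' Parses an arithmetic expression under the model grammar (identifiers,
#' reals, `+ - * / ^`, `**` accepted as a power alias, `exp`, `log`, `sqrt`).
#'
#' @param text Single character string.
#' @return A language object (or numeric for literal constants).
#' @keywords internal
parse_expr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("**", "^", text, fixed = TRUE)
  e <- tryCatch(
    str2lang(text),
    error = function(err) {
      stop(errorCondition(
        sprintf("malformed expression '%s': %s", text, conditionMessage(err)),
        class = c("odeident_malformed_expression", "odeident_error")
      ))
    }
  )
  check_grammar(e, text)
  e
}

check_grammar <- function(e, text) {
  if (is.numeric(e) || is.symbol(e)) return(invisible(TRUE))
  if (is.call(e)) {
    fn <- as.character(e[[1L]])
    if (!fn %in% .allowed_funs) {
      stop(errorCondition(
        sprintf("function '%s' is not part of the model grammar (in '%s')", fn, text),
        class = c("odeident_malformed_expression", "odeident_error")
      ))
    }
    for (i in seq_along(e)[-1L]) check_grammar(e[[i]], text)
    return(invisible(TRUE))
  }
  stop(errorCondition(
    sprintf("unsupported token in expression '%s'", text),
    class = c("odeident_malformed_expression", "odeident_error")
  ))
}

#' Symbols used by an expression
#' @keywords internal
expr_symbols <- function(e) all.vars(e)

#' Count nodes of an expression tree
#' @keywords internal
expr_size <- function(e) {
  if (!is.call(e)) return(1L)
  1L + sum(vapply(as.list(e)[-1L], expr_size, integer(1L)))
}

#' Differentiate an expression with respect to a symbol
#' @keywords internal
d_expr <- function(e, name) {
  if (!(name %in% all.vars(e))) return(0)
  stats::D(e, name)
}

#' Substitute symbols in an expression
#'
#' @param e language object or numeric.
#' @param subs named list mapping symbol names to language objects or numerics.
#' @keywords internal
subst_expr <- function(e, subs) {
  if (length(subs) == 0L) return(e)
  do.call(substitute, list(e, subs))
}

#' Deterministically simplify trivial arithmetic
#'
#' Folds `0 * x`, `x + 0`, `x^1`, unary minus of literals and similar
#' neutral-element patterns left behind by `stats::D`. Keeps Lie-derivative
#' stacks from swelling; performs no algebraic rewriting beyond these rules.
#' @keywords internal
simplify_expr <- function(e) {
  if (!is.call(e)) return(e)
  args <- lapply(as.list(e)[-1L], simplify_expr)
  fn <- as.character(e[[1L]])
  is0 <- function(x) is.numeric(x) && length(x) == 1L && x == 0
  is1 <- function(x) is.numeric(x) && length(x) == 1L && x == 1
  num <- function(x) is.numeric(x) && length(x) == 1L
  if (fn == "(") return(args[[1L]])
  if (fn == "+" && length(args) == 2L) {
    if (is0(args[[1L]])) return(args[[2L]])
    if (is0(args[[2L]])) return(args[[1L]])
    if (num(args[[1L]]) && num(args[[2L]])) return(args[[1L]] + args[[2L]])
  } else if (fn == "-" && length(args) == 2L) {
    if (is0(args[[2L]])) return(args[[1L]])
    if (num(args[[1L]]) && num(args[[2L]])) return(args[[1L]] - args[[2L]])
    if (is0(args[[1L]])) return(simplify_expr(call("-", args[[2L]])))
  } else if (fn == "-" && length(args) == 1L) {
    if (num(args[[1L]])) return(-args[[1L]])
  } else if (fn == "*") {
    if (is0(args[[1L]]) || is0(args[[2L]])) return(0)
    if (is1(args[[1L]])) return(args[[2L]])
    if (is1(args[[2L]])) return(args[[1L]])
    if (num(args[[1L]]) && num(args[[2L]])) return(args[[1L]] * args[[2L]])
  } else if (fn == "/") {
    if (is0(args[[1L]])) return(0)
    if (is1(args[[2L]])) return(args[[1L]])
  } else if (fn == "^") {
    if (is1(args[[2L]])) return(args[[1L]])
    if (is0(args[[2L]])) return(1)
    if (is1(args[[1L]])) return(1)
  }
  as.call(c(e[[1L]], args))
}

#' Build a fast numeric evaluator for a list of expressions
#'
#' @param exprs list of language objects.
#' @param env environment holding constant bindings.
#' @return function(values) taking a named list/environment of symbol values
#'   and returning a numeric vector.
#' @keywords internal
make_evaluator <- function(exprs, consts = list()) {
  base <- list2env(consts, parent = baseenv())
  function(values) {
    ev <- list2env(as.list(values), parent = base)
    vapply(exprs, function(e) eval(e, ev), numeric(1L))
  }
}
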