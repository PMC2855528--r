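#' Expressions attached to HFPNe elements
#'
#' Thresholds, rates, updates and delays in an HFPNe are closed-form
#' arithmetic/boolean expressions over place variables (e.g. `"m_1/5"`).
#' The grammar is deliberately small: numeric and string literals, place
#' variables, `+ - * /`, parentheses, comparisons, `& | !`, and functions
#' registered through [register_expr_function()].  Evaluation is
#' deterministic and side-effect free; anything outside the grammar is
#' rejected when the expression is built.
#'
#' @param text Expression source text (a single string), or a bare number.
#' @return An object of class `hfpne_expr` carrying the source text, the
#'   parsed call and the set of referenced variables.
#' @examples
#' e <- hfpne_expr("m_1/5")
#' eval_expr(e, list(m_1 = 10))   # 2
#' @export
hfpne_expr <- function(text) {
  if (inherits(text, "hfpne_expr")) return(text)
  if (is.numeric(text) && length(text) == 1L) text <- format(text, digits = 17)
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  parsed <- tryCatch(parse(text = text, keep.source = FALSE),
                     error = function(e) stop("cannot parse expression '", text,
                                              "': ", conditionMessage(e), call. = FALSE))
  if (length(parsed) != 1L)
    stop("expression '", text, "' must be a single expression", call. = FALSE)
  expr <- parsed[[1L]]
  vars <- character(0)
  check <- function(e) {
    if (is.numeric(e) || is.character(e) || is.logical(e)) return(invisible())
    if (is.name(e)) {
      nm <- as.character(e)
      if (nm %in% c("TRUE", "FALSE", "pi")) return(invisible())
      vars <<- union(vars, nm)
      return(invisible())
    }
    if (is.call(e)) {
      op <- as.character(e[[1L]])
      ok <- op %in% c("+", "-", "*", "/", "(", "<", ">", "<=", ">=", "==", "!=",
                      "&", "|", "!", "&&", "||") ||
        op %in% ls(.expr_registry)
      if (!ok)
        stop("expression '", text, "': '", op,
             "' is not in the expression grammar (register it with ",
             "register_expr_function() if it is a named function)", call. = FALSE)
      for (i in seq_along(e)[-1L]) check(e[[i]])
      return(invisible())
    }
    stop("expression '", text, "': unsupported construct", call. = FALSE)
  }
  check(expr)
  structure(list(text = text, expr = expr, vars = vars,
                 const = if (length(vars) == 0L && (is.numeric(expr) || is.logical(expr)))
                   expr else NULL),
            class = "hfpne_expr")
}

#' @export
print.hfpne_expr <- function(x, ...) {
  cat("<hfpne_expr> ", x$text, "\n", sep = "")
  invisible(x)
}

#' @export
format.hfpne_expr <- function(x, ...) x$text

# Registry of named functions usable inside generic update expressions.
.expr_registry <- new.env(parent = emptyenv())

#' Register a named function for use in expressions
#'
#' Generic transitions may need operations beyond arithmetic (string edits,
#' table lookups).  Rather than allowing arbitrary inline code, such
#' operations are registered once under a name and called from expression
#' text.  Registered functions must be pure.
#'
#' @param name Function name as used in expression text.
#' @param fn A pure R function.
#' @export
register_expr_function <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .expr_registry)
  invisible(name)
}

# Sealed evaluation scope: arithmetic and boolean operators plus the
# registry.  `/` raises on a zero divisor instead of returning Inf.
.expr_ops <- local({
  e <- new.env(parent = emptyenv())
  for (op in c("+", "-", "*", "(", "<", ">", "<=", ">=", "==", "!=",
               "&", "|", "!", "&&", "||"))
    assign(op, get(op, baseenv()), envir = e)
  assign("pi", pi, envir = e)
  assign("/", function(a, b) {
    if (is.numeric(b) && any(b == 0))
      stop("division by zero", call. = FALSE)
    a / b
  }, envir = e)
  e
})

#' Evaluate an expression against a marking
#'
#' @param expr An [hfpne_expr()].
#' @param marking A named list/environment binding every place variable the
#'   expression references, or an `hfpne_marking`.
#' @return The expression's value (numeric, logical or character).
#' @export
eval_expr <- function(expr, marking) {
  expr <- hfpne_expr(expr)
  if (!is.null(expr$const)) return(expr$const)
  env <- marking_env(marking)
  missing <- expr$vars[!vapply(expr$vars, exists, logical(1),
                               envir = env, inherits = FALSE)]
  # registered functions are resolved through the ops scope, not the marking
  missing <- setdiff(missing, ls(.expr_registry))
  if (length(missing))
    stop("unbound variable(s) in expression '", expr$text, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  eval(expr$expr, envir = env)
}

# Coerce the accepted marking representations to an environment chained to
# the sealed operator scope (lookups cannot escape into user scope).
marking_env <- function(marking) {
  if (is.environment(marking)) return(marking)
  if (inherits(marking, "hfpne_marking")) marking <- marking$marks
  stopifnot(is.list(marking))
  ops <- .expr_ops
  if (length(ls(.expr_registry))) {
    ops <- new.env(parent = .expr_ops)
    for (nm in ls(.expr_registry)) assign(nm, get(nm, .expr_registry), envir = ops)
  }
  list2env(marking, envir = new.env(parent = ops))
}
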