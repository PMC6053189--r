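## Logical-rule abstract syntax trees and their parser.
##
## An expression is a nested list with class "BoolExpr":
##   list(kind = "var",   name = <node id>)
##   list(kind = "const", value = TRUE/FALSE)
##   list(kind = "not",   args = list(<expr>))
##   list(kind = "and"|"or", args = list(<expr>, <expr>, ...))
## Node identifiers are kept verbatim, including hyphens ("14-3-3s",
## "Cdc2-CycB"); a trailing GINsim level suffix ":<digits>" is stripped at
## parse time (all nodes are binary).

.bxVar <- function(name) structure(list(kind = "var", name = name), class = "BoolExpr")
.bxConst <- function(value) structure(list(kind = "const", value = isTRUE(value)), class = "BoolExpr")
.bxNot <- function(x) structure(list(kind = "not", args = list(x)), class = "BoolExpr")
.bxNary <- function(kind, args) {
  if (length(args) == 1L) return(args[[1L]])
  structure(list(kind = kind, args = args), class = "BoolExpr")
}

#' Parse a logical rule
#'
#' Parses a rule written with the operators \code{AND}, \code{OR}, \code{NOT}
#' (case-insensitive; the symbols \code{&}/\code{&&}, \code{|}/\code{||} and
#' \code{!} are accepted as synonyms) into an abstract syntax tree. Operator
#' precedence is \code{NOT} > \code{AND} > \code{OR}, with parentheses
#' overriding. Identifiers may contain letters, digits, dots, underscores and
#' hyphens; the tokenizer never splits on hyphens, so \code{14-3-3s} is a
#' single identifier. A trailing level annotation such as \code{p53-MAIN:1}
#' is stripped. The constants \code{0}/\code{1} (also \code{TRUE}/\code{FALSE})
#' denote fixed truth values.
#'
#' @param text A single rule string, e.g. \code{"p53-Arrest OR p53-Killer"}.
#' @return A \code{BoolExpr} (nested list) representing the rule.
#' @seealso [ruleToString()], [evaluateRule()], [ruleVariables()]
#' @examples
#' e <- parseRule("NOT a AND b OR c")
#' ruleToString(e)
#' @export
parseRule <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stop("rule text must be a single non-empty string")
  toks <- .tokenizeRule(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  e <- .parseOr(st, text)
  if (st$pos <= length(st$toks)) {
    t <- st$toks[[st$pos]]
    stop(sprintf("syntax error in rule at position %d: unexpected '%s'", t$at, t$text))
  }
  e
}

## Token list: each token is list(type, text, at) with 1-based character offset.
.tokenizeRule <- function(text) {
  n <- nchar(text)
  toks <- list()
  i <- 1L
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(type = ch, text = ch, at = i)
      i <- i + 1L
      next
    }
    if (ch %in% c("&", "|")) {
      len <- if (substr(text, i + 1L, i + 1L) == ch) 2L else 1L
      toks[[length(toks) + 1L]] <- list(type = if (ch == "&") "AND" else "OR",
                                        text = substr(text, i, i + len - 1L), at = i)
      i <- i + len
      next
    }
    if (ch == "!") {
      toks[[length(toks) + 1L]] <- list(type = "NOT", text = "!", at = i)
      i <- i + 1L
      next
    }
    m <- regmatches(substr(text, i, n), regexpr("^[A-Za-z0-9_.:-]+", substr(text, i, n)))
    if (length(m) == 0L)
      stop(sprintf("syntax error in rule at position %d: unexpected character '%s'", i, ch))
    word <- m[[1L]]
    up <- toupper(word)
    type <- if (up %in% c("AND", "OR", "NOT")) up else "IDENT"
    toks[[length(toks) + 1L]] <- list(type = type, text = word, at = i)
    i <- i + nchar(word)
  }
  toks
}

.peek <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]] else NULL

.parseOr <- function(st, text) {
  args <- list(.parseAnd(st, text))
  while (!is.null(t <- .peek(st)) && t$type == "OR") {
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- .parseAnd(st, text)
  }
  .bxNary("or", args)
}

.parseAnd <- function(st, text) {
  args <- list(.parseNot(st, text))
  while (!is.null(t <- .peek(st)) && t$type == "AND") {
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- .parseNot(st, text)
  }
  .bxNary("and", args)
}

.parseNot <- function(st, text) {
  t <- .peek(st)
  if (!is.null(t) && t$type == "NOT") {
    st$pos <- st$pos + 1L
    return(.bxNot(.parseNot(st, text)))
  }
  .parseAtom(st, text)
}

.parseAtom <- function(st, text) {
  t <- .peek(st)
  if (is.null(t))
    stop(sprintf("syntax error in rule at position %d: unexpected end of input", nchar(text) + 1L))
  if (t$type == "(") {
    st$pos <- st$pos + 1L
    e <- .parseOr(st, text)
    t2 <- .peek(st)
    if (is.null(t2) || t2$type != ")")
      stop(sprintf("syntax error in rule at position %d: expected ')'",
                   if (is.null(t2)) nchar(text) + 1L else t2$at))
    st$pos <- st$pos + 1L
    return(e)
  }
  if (t$type == "IDENT") {
    st$pos <- st$pos + 1L
    word <- sub(":[0-9]+$", "", t$text)   # strip level suffix, e.g. "p53-MAIN:1"
    if (word %in% c("0", "FALSE", "false", "False")) return(.bxConst(FALSE))
    if (word %in% c("1", "TRUE", "true", "True")) return(.bxConst(TRUE))
    if (!nzchar(word))
      stop(sprintf("syntax error in rule at position %d: bare level suffix '%s'", t$at, t$text))
    return(.bxVar(word))
  }
  stop(sprintf("syntax error in rule at position %d: unexpected '%s'", t$at, t$text))
}

#' Write a rule AST back to text
#'
#' Produces a string that re-parses to an expression with the identical truth
#' table. Parentheses are emitted only where precedence requires them.
#'
#' @param expr A \code{BoolExpr}.
#' @param style \code{"words"} writes \code{AND}/\code{OR}/\code{NOT};
#'   \code{"symbols"} writes \code{&}/\code{|}/\code{!} (the usual .bnet
#'   dialect).
#' @return A single character string.
#' @examples
#' ruleToString(parseRule("NOT a AND b OR c"))
#' @export
ruleToString <- function(expr, style = c("words", "symbols")) {
  style <- match.arg(style)
  ops <- if (style == "words") c(and = " AND ", or = " OR ", not = "NOT ") else
    c(and = " & ", or = " | ", not = "!")
  .prec <- function(kind) switch(kind, or = 1L, and = 2L, not = 3L, 4L)
  rec <- function(e, parentPrec) {
    out <- switch(e$kind,
      var = e$name,
      const = if (e$value) "1" else "0",
      not = paste0(ops[["not"]], rec(e$args[[1L]], .prec("not"))),
      and = paste(vapply(e$args, rec, "", parentPrec = .prec("and")), collapse = ops[["and"]]),
      or = paste(vapply(e$args, rec, "", parentPrec = .prec("or")), collapse = ops[["or"]]))
    if (.prec(e$kind) < parentPrec) out <- paste0("(", out, ")")
    out
  }
  rec(expr, 0L)
}

#' Variables of a rule
#'
#' @param expr A \code{BoolExpr}.
#' @return Character vector of distinct node identifiers appearing in the
#'   rule, in first-appearance order.
#' @export
ruleVariables <- function(expr) {
  rec <- function(e) switch(e$kind,
    var = e$name,
    const = character(0),
    unlist(lapply(e$args, rec), use.names = FALSE))
  unique(rec(expr))
}

#' Evaluate a rule
#'
#' Evaluates a \code{BoolExpr} under an assignment of its variables. The
#' assignment may be vectorized: each variable may map to a logical vector of
#' a common length, in which case the rule is evaluated elementwise (this is
#' how the engine evaluates a rule over a whole state space in one pass).
#'
#' @param expr A \code{BoolExpr}.
#' @param values A named list (or named logical vector) mapping every variable
#'   of \code{expr} to \code{TRUE}/\code{FALSE} (scalars or equal-length
#'   vectors).
#' @return A logical scalar or vector.
#' @examples
#' p21 <- parseRule("(p53-Arrest OR p53-Killer) AND NOT c-Myc")
#' evaluateRule(p21, c(`p53-Arrest` = TRUE, `p53-Killer` = FALSE, `c-Myc` = FALSE))
#' @export
evaluateRule <- function(expr, values) {
  if (!is.list(values)) values <- as.list(values)
  rec <- function(e) {
    switch(e$kind,
      var = {
        v <- values[[e$name]]
        if (is.null(v)) stop(sprintf("unassigned variable '%s' in rule", e$name))
        v
      },
      const = e$value,
      not = !rec(e$args[[1L]]),
      and = Reduce(`&`, lapply(e$args, rec)),
      or = Reduce(`|`, lapply(e$args, rec)))
  }
  rec(expr)
}

#' @export
print.BoolExpr <- function(x, ...) {
  cat("BoolExpr:", ruleToString(x), "\n")
  invisible(x)
}
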